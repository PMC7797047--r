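#' Pick the reference negC guide from the centre of the control distribution
#'
#' Computes a provisional slope for every negC guide from the log2 of its
#' share of total reads (pooled over barcodes) per timepoint, regressed on
#' generations, and returns the guide with the median provisional slope
#' (lower median for an even count; ties broken by guide id).
#'
#' @param gc A [GuideCounts-class].
#' @param negc_ids negC guide ids (default: rows with `strategy == "negC"`
#'   in `rowData`).
#' @param doublings_per_hour mixed-population growth rate used to rescale
#'   hours to generations.
#' @return The selected reference guide id.
#' @export
pickReferenceNegc <- function(gc, negc_ids = NULL,
                              doublings_per_hour = 0.94) {
    stopifnot(is(gc, "GuideCounts"))
    if (is.null(negc_ids)) {
        rd <- rowData(gc)
        stopifnot("strategy" %in% colnames(rd))
        negc_ids <- rownames(gc)[rd$strategy == "negC"]
    }
    stopifnot(length(negc_ids) >= 3L)
    cd <- colData(gc)
    cnt <- SummarizedExperiment::assay(gc, "counts")
    hours <- scheduleHours(gc)
    # pooled counts per guide per timepoint
    pooled <- vapply(hours, function(h)
        rowSums(cnt[, cd$hour == h, drop = FALSE]), numeric(nrow(cnt)))
    tot <- colSums(pooled)
    nc <- pooled[negc_ids, , drop = FALSE]
    full <- rowSums(nc == 0) == 0L
    if (!any(full))
        stop("no negC guide has full timepoint coverage", call. = FALSE)
    gen <- hours * doublings_per_hour
    slopes <- apply(log2(sweep(nc[full, , drop = FALSE], 2, tot, "/")),
                    1, function(y) olsFit(gen, y)$slope)
    ord <- order(slopes)
    med <- slopes[ord[(length(ord) + 1L) %/% 2L]]  # lower median
    min(names(slopes)[slopes == med])              # ties: first by id
}

# closed-form ordinary least squares of y on x
olsFit <- function(x, y) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    slope <- sum((x - mx) * (y - my)) / sxx
    intercept <- my - slope * mx
    res <- y - intercept - slope * x
    sse <- sum(res^2)
    sst <- sum((y - my)^2)
    r2 <- if (sse < 1e-12) 1 else if (sst == 0) 0 else 1 - sse / sst
    list(slope = slope, intercept = intercept, r2 = r2, n = n)
}

#' Relative allele frequencies against the reference control
#'
#' For each (guide, barcode) lineage computes
#' `f(t) = log2(n_sg/n_nc)_t - log2(n_sg/n_nc)_{t=0}` against the reference
#' negC guide within the same barcode, with the time axis rescaled to
#' generations (`hours * doublings_per_hour`). `f` is `NA` where either
#' count is zero (except at t = 0, where `f = 0` by construction whenever
#' the lineage is present).
#'
#' @param gc A [GuideCounts-class].
#' @param reference reference guide id.
#' @param doublings_per_hour mixed-population doubling rate.
#' @return data.frame with columns `guide_id`, `barcode`, `hour`,
#'   `generations`, `f`, `depth_sg`, `depth_nc`. Lineages whose t = 0 count
#'   is zero are dropped with a warning.
#' @export
computeFrequency <- function(gc, reference, doublings_per_hour = 0.94) {
    stopifnot(is(gc, "GuideCounts"), reference %in% rownames(gc))
    hours <- scheduleHours(gc)
    gen <- hours * doublings_per_hour
    out <- list()
    dropped <- 0L
    for (bc in countBarcodes(gc)) {
        m <- barcodeCounts(gc, bc)
        nc <- m[reference, ]
        lf <- log2(m) - matrix(log2(nc), nrow(m), ncol(m), byrow = TRUE)
        f <- lf - lf[, 1]
        f[m == 0 | matrix(nc == 0, nrow(m), ncol(m), byrow = TRUE)] <- NA
        ok <- m[, 1] > 0 & nc[1] > 0
        dropped <- dropped + sum(!ok)
        f[ok, 1] <- 0
        out[[bc]] <- data.frame(
            guide_id = rep(rownames(m)[ok], times = length(hours)),
            barcode = bc,
            hour = rep(hours, each = sum(ok)),
            generations = rep(gen, each = sum(ok)),
            f = as.vector(f[ok, ]),
            depth_sg = as.vector(m[ok, ]),
            depth_nc = rep(nc, each = sum(ok)),
            stringsAsFactors = FALSE)
    }
    if (dropped > 0L)
        warning(dropped, " lineages dropped: zero count at t = 0",
                call. = FALSE)
    do.call(rbind, out)
}

#' Fit one lineage's relative growth rate
#'
#' Ordinary least squares of `f` on generations. Points are taken in
#' schedule order until the first whose guide depth falls below
#' `depth_floor`; that point is included in the fit, but no later point is
#' used. A point with zero counts (undefined `f`) truncates the series
#' before itself.
#'
#' @param fs data.frame for one (guide, barcode) lineage with columns
#'   `generations`, `f`, `depth_sg` in schedule order.
#' @param depth_floor sequencing-depth truncation threshold (default 10).
#' @return list with `slope`, `intercept`, `r2`, `n_points_used`, or
#'   `NULL` when fewer than two usable points remain.
#' @export
fitRelativeGrowth <- function(fs, depth_floor = 10L) {
    n_used <- 0L
    for (i in seq_len(nrow(fs))) {
        if (is.na(fs$f[i]) || fs$depth_sg[i] == 0L) break
        n_used <- i
        if (fs$depth_sg[i] < depth_floor) break
    }
    if (n_used < 2L) return(NULL)
    fit <- olsFit(fs$generations[seq_len(n_used)], fs$f[seq_len(n_used)])
    list(slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
         n_points_used = n_used)
}

#' Dixon Q critical values (two-tailed, 95% confidence, r10 statistic)
#'
#' @param n sample size (3-7 supported).
#' @return Critical Q value.
#' @export
dixonQCritical <- function(n) {
    crit <- c(`3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625,
              `7` = 0.568)
    v <- crit[as.character(n)]
    if (is.na(v)) stop("Dixon Q critical value tabulated for n = 3..7",
                       call. = FALSE)
    unname(v)
}

#' Dixon Q statistic for the most extreme value
#'
#' @param x numeric sample (length >= 3).
#' @return list with `q` (gap-to-range ratio of the more extreme tail) and
#'   `index` (position of the tested value in `x`).
#' @export
dixonQ <- function(x) {
    stopifnot(length(x) >= 3L)
    o <- order(x)
    s <- x[o]
    rng <- s[length(s)] - s[1]
    if (rng == 0) return(list(q = 0, index = NA_integer_))
    q_low <- (s[2] - s[1]) / rng
    q_high <- (s[length(s)] - s[length(s) - 1L]) / rng
    if (q_high >= q_low) list(q = q_high, index = o[length(o)])
    else list(q = q_low, index = o[1])
}

#' Escaper correction across internal replicates of one guide
#'
#' Pipeline: (1) remove replicate fits with R-squared below `r2_min`,
#' unless the slope lies in the exemption interval around zero (flat
#' series legitimately fit poorly); (2) Dixon Q test at 95% confidence on
#' the surviving slopes, removing at most the single most extreme
#' replicate; (3) require at least `min_replicates` survivors; (4) mean,
#' SD and SEM over the survivors.
#'
#' @param fits data.frame of per-barcode fits for one guide with columns
#'   `barcode`, `slope`, `r2`.
#' @param r2_min R-squared filter threshold (default 0.70).
#' @param exempt closed slope interval exempt from the R-squared filter
#'   (default `c(-0.05, 0.05)`).
#' @param min_replicates minimum surviving replicates (default 3).
#' @return list with `rejected` (logical), `mean_raw`, `sd`, `sem`,
#'   `n_replicates`, and `removed` (data.frame `barcode`, `reason` with
#'   reasons among `low_R2`, `q_test`, `too_few_replicates`).
#' @export
escaperCorrect <- function(fits, r2_min = 0.70, exempt = c(-0.05, 0.05),
                           min_replicates = 3L) {
    removed <- data.frame(barcode = character(), reason = character(),
                          stringsAsFactors = FALSE)
    exemptMask <- fits$slope >= exempt[1] & fits$slope <= exempt[2]
    bad_r2 <- fits$r2 < r2_min & !exemptMask
    if (any(bad_r2))
        removed <- rbind(removed,
                         data.frame(barcode = fits$barcode[bad_r2],
                                    reason = "low_R2"))
    keep <- fits[!bad_r2, , drop = FALSE]
    if (nrow(keep) >= 3L) {
        dq <- dixonQ(keep$slope)
        if (!is.na(dq$index) && dq$q > dixonQCritical(nrow(keep))) {
            removed <- rbind(removed,
                             data.frame(barcode = keep$barcode[dq$index],
                                        reason = "q_test"))
            keep <- keep[-dq$index, , drop = FALSE]
        }
    }
    if (nrow(keep) < min_replicates) {
        removed <- rbind(removed,
                         data.frame(barcode = keep$barcode,
                                    reason = "too_few_replicates"))
        return(list(rejected = TRUE, mean_raw = NA_real_, sd = NA_real_,
                    sem = NA_real_, n_replicates = nrow(keep),
                    removed = removed))
    }
    m <- mean(keep$slope)
    s <- stats::sd(keep$slope)
    list(rejected = FALSE, mean_raw = m, sd = s,
         sem = s / sqrt(nrow(keep)), n_replicates = nrow(keep),
         removed = removed, kept_barcodes = keep$barcode,
         kept_slopes = keep$slope)
}

#' Rescale raw growth rates to the normalized 0-1 scale
#'
#' `normalized = (raw + |floor_raw|) / |floor_raw|`: the empirically
#' observed growth floor (a severe parent knockdown) maps to 0, the
#' reference control to 1. Values outside `[0, 1]` are permitted, not
#' clipped.
#'
#' @param mean_raw raw relative growth (doublings per generation,
#'   reference = 0); vectorized.
#' @param floor_raw raw growth of the empirical floor (must be negative;
#'   default -1.23).
#' @return Normalized growth values.
#' @export
normalizeGrowth <- function(mean_raw, floor_raw = -1.23) {
    if (floor_raw >= 0)
        stop("floor_raw must be negative", call. = FALSE)
    (mean_raw + abs(floor_raw)) / abs(floor_raw)
}

#' Estimate escaper-corrected growth rates for every guide
#'
#' Full pipeline over a count tensor: reference selection, relative
#' frequencies, per-lineage truncated OLS fits, escaper correction per
#' guide, and floor normalization.
#'
#' @param gc A [GuideCounts-class] whose `rowData` carries `gene_id`,
#'   `role`, `strategy`, `n_mut`.
#' @param reference reference guide id, or `"auto"` to pick via
#'   [pickReferenceNegc()].
#' @param doublings_per_hour mixed-population doubling rate (0.94 for
#'   glucose, 0.53 for glycerol).
#' @param floor_raw normalization floor, or `"auto"` to use the most
#'   negative parent-guide mean with all replicates surviving.
#' @param depth_floor,r2_min,exempt,min_replicates filter settings (see
#'   [fitRelativeGrowth()] and [escaperCorrect()]).
#' @return list with `estimates` (one row per retained guide:
#'   `guide_id`, `gene_id`, `role`, `strategy`, `n_mut`, `mean_raw`, `sd`,
#'   `sem`, `n_replicates`, `normalized`), `fits` (all per-lineage fits
#'   with a `kept` flag), `removed` (barcode removals with reasons,
#'   including whole-guide rejections), `reference` and `floor_raw`.
#' @export
estimateGrowth <- function(gc, reference = "auto",
                           doublings_per_hour = 0.94, floor_raw = -1.23,
                           depth_floor = 10L, r2_min = 0.70,
                           exempt = c(-0.05, 0.05), min_replicates = 3L) {
    stopifnot(is(gc, "GuideCounts"))
    rd <- as.data.frame(rowData(gc))
    if (identical(reference, "auto"))
        reference <- pickReferenceNegc(gc,
                                       doublings_per_hour =
                                           doublings_per_hour)
    freq <- computeFrequency(gc, reference, doublings_per_hour)
    key <- paste(freq$guide_id, freq$barcode)
    fits <- lapply(split(freq, key), function(fs) {
        fs <- fs[order(fs$generations), ]
        fit <- fitRelativeGrowth(fs, depth_floor)
        if (is.null(fit)) return(NULL)
        data.frame(guide_id = fs$guide_id[1], barcode = fs$barcode[1],
                   slope = fit$slope, intercept = fit$intercept,
                   r2 = fit$r2, n_points_used = fit$n_points_used,
                   stringsAsFactors = FALSE)
    })
    fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
    rownames(fits) <- NULL
    est <- list(); removed <- list(); kept_flags <- list()
    for (g in unique(fits$guide_id)) {
        gf <- fits[fits$guide_id == g, , drop = FALSE]
        ec <- escaperCorrect(gf, r2_min, exempt, min_replicates)
        if (nrow(ec$removed))
            removed[[g]] <- data.frame(guide_id = g, ec$removed)
        if (ec$rejected) next
        kept_flags[[g]] <- data.frame(guide_id = g,
                                      barcode = ec$kept_barcodes,
                                      stringsAsFactors = FALSE)
        est[[g]] <- data.frame(guide_id = g, mean_raw = ec$mean_raw,
                               sd = ec$sd, sem = ec$sem,
                               n_replicates = ec$n_replicates,
                               stringsAsFactors = FALSE)
    }
    estimates <- do.call(rbind, est)
    rownames(estimates) <- NULL
    anno_cols <- intersect(c("gene_id", "role", "strategy", "n_mut"),
                           colnames(rd))
    estimates <- cbind(estimates,
                       rd[match(estimates$guide_id, rd$guide_id),
                          anno_cols, drop = FALSE])
    kept <- do.call(rbind, kept_flags)
    fits$kept <- paste(fits$guide_id, fits$barcode) %in%
        paste(kept$guide_id, kept$barcode)
    if (identical(floor_raw, "auto")) {
        par_est <- estimates[estimates$strategy == "parent", , drop = FALSE]
        nmax <- length(countBarcodes(gc))
        cand <- par_est[par_est$n_replicates == nmax, , drop = FALSE]
        if (!nrow(cand)) cand <- par_est
        if (!nrow(cand))
            stop("no parent guide available to set the floor",
                 call. = FALSE)
        floor_raw <- min(cand$mean_raw)
    }
    estimates$normalized <- normalizeGrowth(estimates$mean_raw, floor_raw)
    removed <- if (length(removed)) do.call(rbind, c(removed,
                                                     make.row.names = FALSE))
        else data.frame(guide_id = character(), barcode = character(),
                        reason = character())
    list(estimates = estimates, fits = fits, removed = removed,
         reference = reference, floor_raw = floor_raw,
         environment = environmentName(gc))
}

#' Per-endpoint timecourse slopes for one lineage
#'
#' Diagnostic fits of growth-rate stability over time: one two-point slope
#' per later timepoint (t = 0 against that point, both ends requiring
#' depth at least `depth_floor`), plus the all-points OLS fit. No
#' R-squared or replicate filtering is applied.
#'
#' @param fs one lineage's frequency series (columns `generations`, `f`,
#'   `depth_sg`, `hour`), in schedule order.
#' @param depth_floor minimum depth at both endpoints (default 10).
#' @return data.frame with columns `endpoint_hour` (NA for the all-points
#'   fit) and `slope`.
#' @export
timecourseGrowth <- function(fs, depth_floor = 10L) {
    fs <- fs[order(fs$generations), ]
    stopifnot(nrow(fs) >= 2L, fs$generations[1] == 0)
    ok0 <- fs$depth_sg[1] >= depth_floor
    rows <- lapply(seq_len(nrow(fs))[-1], function(i) {
        if (!ok0 || is.na(fs$f[i]) || fs$depth_sg[i] < depth_floor)
            return(NULL)
        data.frame(endpoint_hour = fs$hour[i],
                   slope = (fs$f[i] - fs$f[1]) /
                       (fs$generations[i] - fs$generations[1]))
    })
    use <- !is.na(fs$f)
    all_fit <- if (sum(use) >= 2L)
        olsFit(fs$generations[use], fs$f[use])$slope else NA_real_
    rbind(do.call(rbind, rows),
          data.frame(endpoint_hour = NA_real_, slope = all_fit))
}

#' Uncorrected endpoint growth rates (no barcodes, two timepoints)
#'
#' The comparison condition for escaper correction: counts are pooled
#' across all barcodes, and a single two-point slope is computed between
#' t = 0 and the final timepoint, with no depth, R-squared or replicate
#' filtering.
#'
#' @param gc A [GuideCounts-class].
#' @param reference reference guide id.
#' @param doublings_per_hour mixed-population doubling rate.
#' @return data.frame with columns `guide_id` and `slope` (NA where a
#'   zero count makes the ratio undefined).
#' @export
uncorrectedGrowth <- function(gc, reference, doublings_per_hour = 0.94) {
    stopifnot(is(gc, "GuideCounts"))
    cd <- colData(gc)
    cnt <- SummarizedExperiment::assay(gc, "counts")
    hours <- scheduleHours(gc)
    h_last <- hours[length(hours)]
    c0 <- rowSums(cnt[, cd$hour == 0, drop = FALSE])
    cT <- rowSums(cnt[, cd$hour == h_last, drop = FALSE])
    f <- log2(cT / cT[reference]) - log2(c0 / c0[reference])
    f[c0 == 0 | cT == 0] <- NA
    data.frame(guide_id = rownames(cnt),
               slope = f / (h_last * doublings_per_hour),
               stringsAsFactors = FALSE)
}
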