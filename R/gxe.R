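#' Fit a constrained four-parameter logistic titration curve
#'
#' Fits `g(m) = min + (max - min) * m^hill / (ig50^hill + m^hill)` to one
#' replicate's (mutation count, normalized growth) points by bounded least
#' squares. `meanL` is the mean growth of the three fewest-mutation
#' points, `meanH` of the three most-mutated. When `|meanH - meanL|` is
#' below `flat_tol` the curve is reported flat (`min = meanL`,
#' `max = meanH`, Hill and IG-50 absent) without optimization. Otherwise
#' the optimizer starts from (min = meanL, max = meanH, hill = 1,
#' ig50 = 6) with min and max bounded to `[0, 1.15]`, IG-50 to `[0, 14]`
#' and the Hill coefficient unbounded.
#'
#' @param points data.frame with columns `n_mut` and `normalized`.
#' @param min_points minimum number of points required (default 8).
#' @param flat_tol flat-curve threshold on `|meanH - meanL|`
#'   (default 0.05, strict).
#' @return list with `min`, `max`, `hill`, `ig50` (NA when flat), `cost`
#'   (sum of squared residuals), `flat`, `n_points`; or `NULL` when fewer
#'   than `min_points` points are supplied.
#' @export
fitLogisticReplicate <- function(points, min_points = 8L,
                                 flat_tol = 0.05) {
    points <- points[!is.na(points$normalized), , drop = FALSE]
    if (nrow(points) < min_points) return(NULL)
    points <- points[order(points$n_mut), ]
    m <- points$n_mut
    y <- points$normalized
    meanL <- mean(y[seq_len(3)])
    meanH <- mean(y[seq(length(y) - 2L, length(y))])
    if (abs(meanH - meanL) < flat_tol) {
        return(list(min = meanL, max = meanH, hill = NA_real_,
                    ig50 = NA_real_,
                    cost = sum((y - mean(y))^2), flat = TRUE,
                    n_points = length(y)))
    }
    clip <- function(v) pmin(pmax(v, 0), 1.15)
    start <- c(min = clip(meanL), max = clip(meanH), hill = 1, ig50 = 6)
    lower <- c(0, 0, -Inf, 0)
    upper <- c(1.15, 1.15, Inf, 14)
    p <- tryCatch({
        fit <- suppressWarnings(stats::nls(
            y ~ hillGrowth(m, mn, mx, h, i50),
            data = data.frame(m = m, y = y),
            start = list(mn = start[1], mx = start[2], h = 1, i50 = 6),
            lower = lower, upper = upper, algorithm = "port",
            control = stats::nls.control(maxiter = 500,
                                         warnOnly = TRUE)))
        unname(stats::coef(fit))
    }, error = function(e) {
        fit <- suppressWarnings(minpack.lm::nls.lm(
            par = start, lower = lower, upper = upper,
            fn = function(p) hillGrowth(m, p[1], p[2], p[3], p[4]) - y,
            control = minpack.lm::nls.lm.control(maxiter = 500)))
        unname(fit$par)
    })
    cost <- sum((hillGrowth(m, p[1], p[2], p[3], p[4]) - y)^2)
    list(min = p[1], max = p[2], hill = p[3], ig50 = p[4], cost = cost,
         flat = FALSE, n_points = length(y))
}

#' Per-replicate titration points from a growth-estimation result
#'
#' Extracts, per gene and internal-replicate barcode, the (mutation
#' count, normalized growth) points of one parent's compounding series
#' (the parent itself contributes `n_mut = 0`), using only replicate fits
#' that survived escaper correction.
#'
#' @param res result list from [estimateGrowth()].
#' @param role parent role whose series to use (default `"SG1"`).
#' @return data.frame with columns `gene_id`, `barcode`, `n_mut`,
#'   `normalized`.
#' @export
replicateTitration <- function(res, role = "SG1") {
    est <- res$estimates
    sel <- est$role %in% role &
        est$strategy %in% c("parent", "compounding")
    anno <- est[sel, c("guide_id", "gene_id", "n_mut")]
    fits <- res$fits[res$fits$kept &
                     res$fits$guide_id %in% anno$guide_id, , drop = FALSE]
    i <- match(fits$guide_id, anno$guide_id)
    data.frame(gene_id = anno$gene_id[i], barcode = fits$barcode,
               n_mut = anno$n_mut[i],
               normalized = normalizeGrowth(fits$slope, res$floor_raw),
               stringsAsFactors = FALSE)
}

#' Fit per-replicate logistic curves for one gene and environment
#'
#' @param titration per-replicate titration points (one gene), as from
#'   [replicateTitration()].
#' @param gene_id,environment labels attached to the output.
#' @param min_points minimum points per replicate fit (default 8).
#' @param flat_tol flat-curve threshold (default 0.05).
#' @return list with `fits` (data.frame, one row per fitted replicate) and
#'   `medians` (named list of per-parameter medians; parameters absent in
#'   a replicate are excluded from its median).
#' @export
geneEnvFit <- function(titration, gene_id, environment,
                       min_points = 8L, flat_tol = 0.05) {
    rows <- lapply(split(titration, titration$barcode), function(tb) {
        fit <- fitLogisticReplicate(tb[, c("n_mut", "normalized")],
                                    min_points, flat_tol)
        if (is.null(fit)) return(NULL)
        data.frame(gene_id = gene_id, environment = environment,
                   barcode = tb$barcode[1], min = fit$min,
                   max = fit$max, hill = fit$hill, ig50 = fit$ig50,
                   cost = fit$cost, flat = fit$flat,
                   n_points = fit$n_points, stringsAsFactors = FALSE)
    })
    fits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    medians <- if (is.null(fits)) NULL else
        lapply(c(min = "min", max = "max", hill = "hill", ig50 = "ig50"),
               function(p) stats::median(fits[[p]], na.rm = TRUE))
    list(fits = fits, medians = medians)
}

welchOrNA <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Call gene-by-environment interactions from logistic fit parameters
#'
#' For every gene present in both environments, compares each logistic
#' parameter's replicate-level estimates between environments with
#' Welch's t-test. Genes sigmoidal in exactly one environment receive
#' p = 0 for both IG-50 and Hill. SGoF correction is applied separately
#' per parameter over all genes. Interaction classes: `none` (no
#' significant parameter), `min_detectable` (min significant — visible at
#' maximal knockdown), `titration_only` (min not significant but at least
#' one of IG-50, Hill, max is).
#'
#' @param fits_env1,fits_env2 replicate fit tables (as the `fits` element
#'   of [geneEnvFit()], concatenated over genes) for the two environments.
#' @param gamma,alpha SGoF settings (default 0.05 each).
#' @return data.frame with one row per gene: per-parameter p-values,
#'   per-parameter significance after SGoF, and `interaction_class`.
#' @export
detectGxe <- function(fits_env1, fits_env2, gamma = 0.05, alpha = 0.05) {
    genes <- intersect(unique(fits_env1$gene_id),
                       unique(fits_env2$gene_id))
    params <- c("min", "max", "hill", "ig50")
    pv <- matrix(NA_real_, length(genes), length(params),
                 dimnames = list(genes, params))
    for (g in genes) {
        f1 <- fits_env1[fits_env1$gene_id == g, , drop = FALSE]
        f2 <- fits_env2[fits_env2$gene_id == g, , drop = FALSE]
        for (p in params) pv[g, p] <- welchOrNA(f1[[p]], f2[[p]])
        sig1 <- sum(!is.na(f1$ig50)) >= 2L
        sig2 <- sum(!is.na(f2$ig50)) >= 2L
        if (xor(sig1, sig2)) pv[g, c("hill", "ig50")] <- 0
    }
    sig <- matrix(FALSE, length(genes), length(params),
                  dimnames = list(genes, params))
    for (p in params) {
        idx <- which(!is.na(pv[, p]))
        if (!length(idx)) next
        rej <- sgof(pv[idx, p], gamma, alpha)$rejected
        sig[idx[rej], p] <- TRUE
        # assigned zeros mark qualitative flat-vs-sigmoidal differences
        # and are always treated as rejected
        sig[!is.na(pv[, p]) & pv[, p] == 0, p] <- TRUE
    }
    cls <- vapply(genes, function(g) {
        if (sig[g, "min"]) "min_detectable"
        else if (any(sig[g, c("max", "hill", "ig50")])) "titration_only"
        else "none"
    }, character(1))
    data.frame(gene_id = genes,
               p_min = pv[, "min"], p_max = pv[, "max"],
               p_hill = pv[, "hill"], p_ig50 = pv[, "ig50"],
               sig_min = sig[, "min"], sig_max = sig[, "max"],
               sig_hill = sig[, "hill"], sig_ig50 = sig[, "ig50"],
               interaction_class = cls, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Full gene-by-environment analysis from two growth-estimation results
#'
#' Builds per-replicate titration series for each environment, applies the
#' gene eligibility rules (the fewest-mutation measurable guide must show
#' normalized growth at or below `eligibility` in at least one
#' environment; at least `min_replicates` replicate fits per environment),
#' fits the constrained logistic per replicate, and calls interactions.
#'
#' @param res_env1,res_env2 results from [estimateGrowth()] for the two
#'   environments.
#' @param role parent series to analyse (default `"SG1"`).
#' @param eligibility normalized-growth eligibility threshold
#'   (default 0.75, inclusive).
#' @param min_replicates minimum replicate fits per environment
#'   (default 3).
#' @param min_points,flat_tol per-replicate fit settings.
#' @param gamma,alpha SGoF settings.
#' @return list with `fits` (all replicate fits, both environments),
#'   `medians` (per gene x environment parameter medians), `calls` (from
#'   [detectGxe()]) and `skipped` (ineligible genes with reasons).
#' @export
gxeAnalysis <- function(res_env1, res_env2, role = "SG1",
                        eligibility = 0.75, min_replicates = 3L,
                        min_points = 8L, flat_tol = 0.05,
                        gamma = 0.05, alpha = 0.05) {
    titr <- list(replicateTitration(res_env1, role),
                 replicateTitration(res_env2, role))
    envs <- c(environmentName_safe(res_env1), environmentName_safe(res_env2))
    lowestNorm <- function(res) {
        est <- res$estimates
        sel <- est$role %in% role &
            est$strategy %in% c("parent", "compounding")
        vapply(split(est[sel, ], est$gene_id[sel]), function(ge)
            ge$normalized[which.min(ge$n_mut)], numeric(1))
    }
    l1 <- lowestNorm(res_env1); l2 <- lowestNorm(res_env2)
    genes <- union(names(l1), names(l2))
    eligible <- vapply(genes, function(g) {
        v <- c(l1[g], l2[g])
        any(!is.na(v) & v <= eligibility)
    }, logical(1))
    skipped <- data.frame(gene_id = genes[!eligible],
                          reason = rep("no_strong_knockdown",
                                       sum(!eligible)),
                          stringsAsFactors = FALSE)
    genes <- genes[eligible]
    all_fits <- list(); medians <- list()
    for (ei in 1:2) {
        for (g in genes) {
            tg <- titr[[ei]][titr[[ei]]$gene_id == g, , drop = FALSE]
            if (!nrow(tg)) next
            gf <- geneEnvFit(tg, g, envs[ei], min_points, flat_tol)
            if (is.null(gf$fits)) next
            all_fits[[paste(g, ei)]] <- gf$fits
            medians[[paste(g, ei)]] <- data.frame(
                gene_id = g, environment = envs[ei],
                n_replicates = nrow(gf$fits),
                min = gf$medians$min, max = gf$medians$max,
                hill = gf$medians$hill, ig50 = gf$medians$ig50,
                stringsAsFactors = FALSE)
        }
    }
    fits <- do.call(rbind, all_fits)
    rownames(fits) <- NULL
    med <- do.call(rbind, medians)
    rownames(med) <- NULL
    enough <- function(env) {
        tab <- table(fits$gene_id[fits$environment == env])
        names(tab)[tab >= min_replicates]
    }
    ok <- intersect(enough(envs[1]), enough(envs[2]))
    drop2 <- setdiff(genes, ok)
    if (length(drop2))
        skipped <- rbind(skipped,
                         data.frame(gene_id = drop2,
                                    reason = "too_few_replicate_fits"))
    f1 <- fits[fits$environment == envs[1] & fits$gene_id %in% ok, ]
    f2 <- fits[fits$environment == envs[2] & fits$gene_id %in% ok, ]
    calls <- if (length(ok)) detectGxe(f1, f2, gamma, alpha) else
        data.frame()
    list(fits = fits, medians = med, calls = calls, skipped = skipped)
}

environmentName_safe <- function(res) {
    if (!is.null(res$environment)) res$environment else "env"
}
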