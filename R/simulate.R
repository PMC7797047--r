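#' Hill-type logistic titration curve
#'
#' Normalized growth as a function of the number of compounding spacer
#' mutations: `g(m) = min + (max - min) * m^hill / (ig50^hill + m^hill)`,
#' with `g(0) = min` (full knockdown at the unmutated parent) rising toward
#' `max` as mismatches accumulate and CRISPRi activity is lost.
#'
#' @param m number of mutations (vectorized, >= 0).
#' @param min,max growth floor/ceiling on the normalized scale.
#' @param hill Hill coefficient.
#' @param ig50 mutation count at half-maximal growth.
#' @return Numeric vector of normalized growth values.
#' @export
hillGrowth <- function(m, min, max, hill, ig50) {
    ratio <- numeric(length(m))
    zero <- m == 0
    # limit of m^hill / (ig50^hill + m^hill) as m -> 0+
    ratio[zero] <- if (hill > 0) 0 else if (hill < 0) 1 else 0.5
    if (any(!zero))
        ratio[!zero] <- if (ig50 <= 0) 1 else
            m[!zero]^hill / (ig50^hill + m[!zero]^hill)
    min + (max - min) * ratio
}

defaultPositionEffect <- function() {
    # fraction of knockdown retained when a single spacer position is
    # mutated: near 0 in the seed region (-1..-8), approaching 1 distally
    k <- 1:20
    stats::setNames((k / 20)^1.5, paste0("-", k))
}

#' Ground-truth model for the pooled-selection simulator
#'
#' Draws (or accepts) per-gene, per-environment logistic titration
#' parameters and fixes the nuisance processes: the raw growth floor, the
#' mixed-population doubling rates, escaper frequency, sequencing depth and
#' replicate jitter. Defaults emulate the platform's study conditions:
#' 6 internal replicate barcodes, 7 glucose timepoints over 14 h at
#' 0.94 doublings/h, a raw growth floor of -1.23 doublings/generation, and
#' sparse (1%) escaper lineages.
#'
#' @param gene_ids character vector of gene ids.
#' @param environments named numeric vector of doublings per hour per
#'   environment (default `c(glucose = 0.94, glycerol = 0.53)`).
#' @param params optional data.frame (`gene_id`, `environment`, `min`,
#'   `max`, `hill`, `ig50`) overriding the random draw.
#' @param seed RNG seed for the parameter draw.
#' @param floor_raw raw growth rate of a complete kill (default -1.23).
#' @param escape_prob per-lineage escaper probability (default 0.01).
#' @param depth reads per sequenced timepoint (default 1e6).
#' @param replicate_jitter_sd replicate-to-replicate SD of normalized
#'   growth (default 0.01).
#' @param position_effect named retention fractions for single-position
#'   mutations (names `"-1"`..`"-20"`).
#' @param min_range,max_range,hill_range,ig50_range uniform draw ranges for
#'   the logistic parameters.
#' @return A list of class `TruthModel`.
#' @export
simulateTruth <- function(gene_ids,
                          environments = c(glucose = 0.94,
                                           glycerol = 0.53),
                          params = NULL, seed = 1L, floor_raw = -1.23,
                          escape_prob = 0.01, depth = 1e6,
                          replicate_jitter_sd = 0.01,
                          position_effect = defaultPositionEffect(),
                          min_range = c(0, 0.7),
                          max_range = c(0.9, 1.1),
                          hill_range = c(1, 4),
                          ig50_range = c(3, 11)) {
    stopifnot(floor_raw < 0, !is.null(names(environments)))
    if (is.null(params)) {
        set.seed(seed)
        grid <- expand.grid(gene_id = gene_ids,
                            environment = names(environments),
                            stringsAsFactors = FALSE)
        n <- nrow(grid)
        params <- data.frame(
            grid,
            min = stats::runif(n, min_range[1], min_range[2]),
            max = stats::runif(n, max_range[1], max_range[2]),
            hill = stats::runif(n, hill_range[1], hill_range[2]),
            ig50 = stats::runif(n, ig50_range[1], ig50_range[2]),
            stringsAsFactors = FALSE)
    }
    stopifnot(all(params$min >= 0), all(params$max <= 1.15),
              all(params$min <= params$max),
              all(params$ig50 >= 0 & params$ig50 <= 14))
    structure(list(params = params, environments = environments,
                   floor_raw = floor_raw, escape_prob = escape_prob,
                   depth = depth,
                   replicate_jitter_sd = replicate_jitter_sd,
                   position_effect = position_effect, seed = seed),
              class = "TruthModel")
}

#' Ground-truth normalized growth of one guide variant
#'
#' negC controls grow like wildtype (exactly 1). Parents and compounding
#' variants follow the gene's logistic curve evaluated at `n_mut`. Single
#' and double mismatch variants use the attenuation model
#' `min + (max - min) * (1 - prod(retention[positions]))`: each mutated
#' position retains a position-specific fraction of the knockdown, and the
#' residual knockdown is the product over mutated positions.
#'
#' @param truth A `TruthModel`.
#' @param variant one row of a library `variants` table.
#' @param env environment name.
#' @return Normalized growth in `[0, 1.15]`.
#' @export
guideTruthGrowth <- function(truth, variant, env) {
    if (variant$strategy == "negC") return(1)
    p <- truth$params[truth$params$gene_id == variant$gene_id &
                      truth$params$environment == env, , drop = FALSE]
    if (!nrow(p))
        stop("gene ", variant$gene_id, " absent from truth model",
             call. = FALSE)
    if (variant$strategy %in% c("parent", "compounding"))
        return(hillGrowth(variant$n_mut, p$min, p$max, p$hill, p$ig50))
    pos <- parsePositions(variant$mutated_positions)
    ret <- truth$position_effect[as.character(pos)]
    p$min + (p$max - p$min) * (1 - prod(ret))
}

defaultSchedule <- function(env) {
    if (identical(env, "glycerol")) c(0, 2, 6, 10, 14)
    else c(0, 2, 4, 6, 10, 12, 14)
}

#' Simulate a pooled turbidostat selection
#'
#' Each (guide, barcode) lineage grows exponentially relative to the
#' wildtype reference: abundance `A(t) = 2^(rho * g(t))` with
#' `g(t) = hours * doublings_per_hour` generations and raw relative growth
#' `rho = (normalized - 1) * |floor_raw|` (so negC lineages are flat).
#' Replicate jitter perturbs each lineage's normalized growth
#' (Gaussian, truncated to `[0, 1.15]`). With probability `escape_prob`, a
#' lineage escapes CRISPRi at a uniform random time, after which it grows
#' at the wildtype rate (its relative abundance freezes). Sequencing draws
#' multinomial counts of size `depth` over all lineages per timepoint.
#'
#' @param truth A `TruthModel` from [simulateTruth()].
#' @param lib A [TitrationLibrary-class].
#' @param env environment name (must be in `truth$environments`).
#' @param schedule_hours hour schedule (default: 0..14 every 2 h minus the
#'   8 h point for glucose; 0, 2, 6, 10, 14 for glycerol).
#' @param seed RNG seed.
#' @param escape_time_range range for uniform escape times (default the
#'   full schedule).
#' @param forced_escapers optional data.frame (`guide_id`, `barcode`,
#'   `escape_time_hours`) of lineages that escape deterministically, in
#'   addition to the random escaper process.
#' @param sampling `"multinomial"` (default) draws sequencing counts;
#'   `"expected"` emits the exact expected (real-valued) counts — the
#'   infinite-depth limit, useful for noise-free checks.
#' @return list with `counts` (a [GuideCounts-class]), `escapers`
#'   (data.frame `guide_id`, `barcode`, `escape_time_hours`) and
#'   `lineage_truth` (per-lineage normalized/raw growth actually applied).
#' @export
simulateCounts <- function(truth, lib, env, schedule_hours = NULL,
                           seed = 1L, escape_time_range = NULL,
                           forced_escapers = NULL,
                           sampling = c("multinomial", "expected")) {
    sampling <- match.arg(sampling)
    stopifnot(inherits(truth, "TruthModel"), is(lib, "TitrationLibrary"))
    if (!env %in% names(truth$environments))
        stop("environment ", env, " not in truth model", call. = FALSE)
    if (is.null(schedule_hours)) schedule_hours <- defaultSchedule(env)
    if (is.null(escape_time_range))
        escape_time_range <- c(0, max(schedule_hours))
    dph <- truth$environments[[env]]
    v <- as.data.frame(guideVariants(lib))
    barcodes <- lib@barcodes
    set.seed(seed)

    base_norm <- vapply(seq_len(nrow(v)), function(i)
        guideTruthGrowth(truth, v[i, ], env), numeric(1))

    ng <- nrow(v); nb <- length(barcodes)
    # lineage index: guide fastest, then barcode
    norm <- rep(base_norm, times = nb) +
        stats::rnorm(ng * nb, 0, truth$replicate_jitter_sd)
    norm <- pmin(pmax(norm, 0), 1.15)
    rho <- (norm - 1) * abs(truth$floor_raw)

    escaped <- stats::runif(ng * nb) < truth$escape_prob
    t_esc <- rep(NA_real_, ng * nb)
    t_esc[escaped] <- stats::runif(sum(escaped), escape_time_range[1],
                                   escape_time_range[2])
    if (!is.null(forced_escapers)) {
        idx <- match(forced_escapers$guide_id, v$guide_id) +
            ng * (match(forced_escapers$barcode, barcodes) - 1L)
        stopifnot(!anyNA(idx))
        escaped[idx] <- TRUE
        t_esc[idx] <- forced_escapers$escape_time_hours
    }

    nt <- length(schedule_hours)
    counts <- array(if (sampling == "multinomial") 0L else 0,
                    dim = c(ng, nb, nt),
                    dimnames = list(v$guide_id, barcodes,
                                    schedule_hours))
    for (ti in seq_len(nt)) {
        h <- schedule_hours[ti]
        eff_h <- ifelse(escaped & t_esc < h, t_esc, h)
        w <- 2^(rho * eff_h * dph)
        counts[, , ti] <- if (sampling == "multinomial")
            as.integer(stats::rmultinom(1, truth$depth, w / sum(w)))
        else truth$depth * w / sum(w)
    }
    esc <- data.frame(guide_id = rep(v$guide_id, times = nb)[escaped],
                      barcode = rep(barcodes, each = ng)[escaped],
                      escape_time_hours = t_esc[escaped],
                      stringsAsFactors = FALSE)
    lineage <- data.frame(guide_id = rep(v$guide_id, times = nb),
                          barcode = rep(barcodes, each = ng),
                          normalized = norm, rho = rho,
                          escaped = escaped, stringsAsFactors = FALSE)
    gc <- GuideCounts(counts, schedule_hours = schedule_hours,
                      environment = env,
                      rowData = v[, c("guide_id", "gene_id", "role",
                                      "strategy", "n_mut")])
    list(counts = gc, escapers = esc, lineage_truth = lineage)
}

#' Amplicon read layout
#'
#' Fixed flanking sequences with the 20-nt spacer and the 6-nt barcode at
#' fixed offsets, mimicking the sequenced sgRNA expression cassette.
#'
#' @param flank5,mid,flank3 constant segments 5' of the spacer, between
#'   spacer and barcode, and 3' of the barcode.
#' @return list of class `ReadLayout` with segment strings and the derived
#'   spacer/barcode offsets (1-based).
#' @export
readLayout <- function(flank5 = "ACGCTAGCTAGGTATTAACC",
                       mid = "GTTTAAGAGCTATGCTGGAA",
                       flank3 = "ACAGCATAGCAAGT") {
    structure(list(flank5 = flank5, mid = mid, flank3 = flank3,
                   spacer_start = nchar(flank5) + 1L,
                   barcode_start = nchar(flank5) + 20L + nchar(mid) + 1L,
                   read_length = nchar(flank5) + 20L + nchar(mid) + 6L +
                       nchar(flank3)),
              class = "ReadLayout")
}

#' Emit simulated amplicon reads for a count tensor
#'
#' Writes one FASTQ per timepoint with one read per count: the guide's
#' spacer and the lineage barcode embedded in the fixed layout, constant
#' per-base quality `qual`. With probability `corrupt_rate` a read has one
#' random spacer base flipped (a sequencing error that must be discarded by
#' exact matching downstream).
#'
#' @param gc A [GuideCounts-class].
#' @param lib A [TitrationLibrary-class].
#' @param dir output directory (created if needed).
#' @param layout A [readLayout()].
#' @param qual constant Phred quality (default 37).
#' @param corrupt_rate per-read corruption probability (default 0).
#' @param seed RNG seed for corruption.
#' @return data.frame with columns `hour` and `file`.
#' @export
emitReads <- function(gc, lib, dir, layout = readLayout(), qual = 37L,
                      corrupt_rate = 0, seed = 1L) {
    stopifnot(is(gc, "GuideCounts"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    v <- as.data.frame(guideVariants(lib))
    spacer_of <- stats::setNames(v$spacer, v$guide_id)
    set.seed(seed)
    cd <- colData(gc)
    cnt <- SummarizedExperiment::assay(gc, "counts")
    out <- lapply(scheduleHours(gc), function(h) {
        sel <- which(cd$hour == h)
        seqs <- character(0)
        for (j in sel) {
            nz <- which(cnt[, j] > 0L)
            if (!length(nz)) next
            reps <- cnt[nz, j]
            sp <- rep(spacer_of[rownames(cnt)[nz]], reps)
            seqs <- c(seqs, paste0(layout$flank5, sp, layout$mid,
                                   cd$barcode[j], layout$flank3))
        }
        if (corrupt_rate > 0 && length(seqs)) {
            hit <- which(stats::runif(length(seqs)) < corrupt_rate)
            for (i in hit) {
                pos <- layout$spacer_start +
                    sample.int(20L, 1L) - 1L
                old <- substr(seqs[i], pos, pos)
                substr(seqs[i], pos, pos) <-
                    sample(setdiff(BASES, old), 1L)
            }
        }
        file <- file.path(dir, sprintf("reads_t%02g.fastq", h))
        writeFastq(seqs, rep(qual, length(seqs)), file)
        data.frame(hour = h, file = file, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

# minimal FASTQ writer: one constant quality per read (Phred+33)
writeFastq <- function(seqs, quals, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!length(seqs)) return(invisible(path))
    qchar <- vapply(seq_along(seqs), function(i)
        strrep(rawToChar(as.raw(quals[i] + 33L)), nchar(seqs[i])),
        character(1))
    writeLines(paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n",
                      qchar), con)
    invisible(path)
}
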