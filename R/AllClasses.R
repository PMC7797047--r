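#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Default internal-replicate barcodes
#'
#' The six 6-nt plasmid barcodes used to track internal replicates of each
#' sgRNA construct.
#'
#' @return Character vector of six 6-nt barcodes.
#' @export
#' @examples
#' defaultBarcodes()
defaultBarcodes <- function() {
    c("CTTTCA", "ATCATG", "GCATGG", "GTATGA", "AGTCTA", "CCTAGT")
}

#' TitrationLibrary: a designed titratable sgRNA library
#'
#' Container for a set of sgRNA variants (parents, compounding / single /
#' double mismatch series, scrambled negative controls), the internal
#' replicate barcodes, and the gene targets the library was designed
#' against.
#'
#' The `variants` slot is a [S4Vectors::DataFrame] with one row per guide and
#' columns `guide_id`, `gene_id`, `role` (SG1/SG2/SG3 or NA for controls),
#' `strategy` (`parent`, `single`, `double`, `compounding`, `negC`),
#' `n_mut`, `mutated_positions` (comma-joined negative integers, `""` for
#' none), `spacer` (20-nt) and `pam_offset`.
#'
#' @slot variants DataFrame of guide variants (see Details).
#' @slot barcodes character vector of 6-nt internal replicate barcodes.
#' @slot genes DataFrame with columns `gene_id`, `cds`, `essential`.
#'
#' @aliases TitrationLibrary-class
#' @export
setClass("TitrationLibrary",
    slots = c(variants = "DataFrame", barcodes = "character",
              genes = "DataFrame"))

setValidity("TitrationLibrary", function(object) {
    v <- object@variants
    msg <- character()
    need <- c("guide_id", "gene_id", "role", "strategy", "n_mut",
              "mutated_positions", "spacer", "pam_offset")
    if (!all(need %in% colnames(v)))
        msg <- c(msg, paste("variants must have columns:",
                            paste(setdiff(need, colnames(v)), collapse = ", ")))
    else {
        if (anyDuplicated(v$guide_id))
            msg <- c(msg, "guide_id values must be unique")
        if (nrow(v) && any(nchar(v$spacer) != 20L))
            msg <- c(msg, "all spacers must be 20 nt")
        bad <- !v$strategy %in% c("parent", "single", "double",
                                  "compounding", "negC")
        if (any(bad))
            msg <- c(msg, "unknown strategy value")
    }
    if (length(object@barcodes) &&
        any(nchar(object@barcodes) != 6L))
        msg <- c(msg, "barcodes must be 6 nt")
    if (length(msg)) msg else TRUE
})

#' Construct a TitrationLibrary
#'
#' @param variants data.frame or DataFrame of guide variants.
#' @param barcodes character vector of 6-nt barcodes
#'   (default [defaultBarcodes()]).
#' @param genes data.frame or DataFrame of gene targets (may be empty).
#' @return A [TitrationLibrary-class] object.
#' @export
TitrationLibrary <- function(variants, barcodes = defaultBarcodes(),
                             genes = S4Vectors::DataFrame()) {
    new("TitrationLibrary",
        variants = S4Vectors::DataFrame(variants, check.names = FALSE),
        barcodes = as.character(barcodes),
        genes = S4Vectors::DataFrame(genes, check.names = FALSE))
}

setMethod("show", "TitrationLibrary", function(object) {
    v <- object@variants
    cat("TitrationLibrary with", nrow(v), "guide variants for",
        length(unique(v$gene_id[v$strategy != "negC"])), "genes\n")
    if (nrow(v)) {
        tab <- table(v$strategy)
        cat("  strategies:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    cat("  barcodes:", paste(object@barcodes, collapse = ", "), "\n")
})

#' @rdname TitrationLibrary
#' @param x A `TitrationLibrary`.
#' @export
guideVariants <- function(x) {
    stopifnot(is(x, "TitrationLibrary"))
    x@variants
}

#' @rdname TitrationLibrary
#' @export
geneTargets <- function(x) {
    stopifnot(is(x, "TitrationLibrary"))
    x@genes
}

#' @rdname TitrationLibrary
#' @export
negcIds <- function(x) {
    v <- guideVariants(x)
    v$guide_id[v$strategy == "negC"]
}

#' GuideCounts: sgRNA read counts across barcodes and timepoints
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' `counts` assay with one row per guide and one column per
#' (barcode, timepoint) sample. `colData` carries `barcode` and `hour`;
#' `metadata` carries the environment label and the hour schedule.
#'
#' @aliases GuideCounts-class
#' @export
setClass("GuideCounts", contains = "SummarizedExperiment")

setValidity("GuideCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("missing 'counts' assay")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    cd <- colData(object)
    if (!all(c("barcode", "hour") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'barcode' and 'hour'")
    sch <- metadata(object)$schedule_hours
    if (is.null(sch) || length(sch) < 1L || sch[1] != 0 ||
        any(diff(sch) <= 0))
        msg <- c(msg,
            "schedule_hours must start at 0 and be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Construct a GuideCounts object
#'
#' @param counts integer matrix, guides x (barcode,timepoint) samples, or a
#'   3-d array indexed (guide, barcode, timepoint).
#' @param barcode,hour per-column barcode / hour (ignored for array input).
#' @param schedule_hours ordered hour schedule beginning at 0.
#' @param environment environment label (e.g. `"glucose"`).
#' @param rowData optional per-guide annotation (gene, strategy, n_mut, ...).
#' @return A [GuideCounts-class] object.
#' @export
GuideCounts <- function(counts, barcode = NULL, hour = NULL,
                        schedule_hours = NULL, environment = "glucose",
                        rowData = NULL) {
    if (is.array(counts) && length(dim(counts)) == 3L) {
        dn <- dimnames(counts)
        stopifnot(!is.null(dn))
        nb <- dim(counts)[2]; nt <- dim(counts)[3]
        if (is.null(schedule_hours))
            schedule_hours <- as.numeric(dn[[3]])
        barcode <- rep(dn[[2]], times = nt)
        hour <- rep(schedule_hours, each = nb)
        counts <- matrix(aperm(counts, c(1, 2, 3)), nrow = dim(counts)[1],
                         dimnames = list(dn[[1]], NULL))
    }
    stopifnot(!is.null(barcode), !is.null(hour))
    if (is.null(schedule_hours)) schedule_hours <- sort(unique(hour))
    cd <- S4Vectors::DataFrame(barcode = barcode, hour = hour)
    colnames(counts) <- paste(cd$barcode, cd$hour, sep = "_t")
    args <- list(assays = list(counts = counts), colData = cd,
                 metadata = list(schedule_hours = schedule_hours,
                                 environment = environment))
    if (!is.null(rowData)) args$rowData <- rowData
    se <- do.call(SummarizedExperiment, args)
    new("GuideCounts", se)
}

#' @rdname GuideCounts
#' @param x A `GuideCounts`.
#' @export
scheduleHours <- function(x) metadata(x)$schedule_hours

#' @rdname GuideCounts
#' @export
environmentName <- function(x) metadata(x)$environment

#' @rdname GuideCounts
#' @export
countBarcodes <- function(x) unique(colData(x)$barcode)

#' Extract one guide x timepoint count matrix for a barcode
#'
#' @param x A `GuideCounts`.
#' @param barcode a single barcode present in `x`.
#' @return Integer matrix, guides x timepoints (columns in schedule order).
#' @export
barcodeCounts <- function(x, barcode) {
    cd <- colData(x)
    sel <- which(cd$barcode == barcode)
    stopifnot(length(sel) > 0L)
    sel <- sel[order(cd$hour[sel])]
    m <- SummarizedExperiment::assay(x, "counts")[, sel, drop = FALSE]
    colnames(m) <- as.character(cd$hour[sel])
    m
}
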