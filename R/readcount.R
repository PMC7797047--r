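#' Count quality-filtered reads into a guide x barcode x timepoint tensor
#'
#' A read is counted iff (i) its spacer region exactly matches a library
#' spacer, (ii) every base of the decision-relevant region has Phred
#' quality strictly greater than `q_min`, and (iii) its 6-nt barcode
#' exactly matches a configured barcode. No fuzzy matching or mismatch
#' rescue is applied. All other reads are tallied in a per-reason discard
#' report.
#'
#' A full design contains one sequence-identical guide pair per mutated
#' parent (the first compounding variant and the single mutant at
#' position -20 share a spacer); reads for such a spacer are credited to
#' the first matching library entry, since sequencing cannot distinguish
#' them.
#'
#' @param files data.frame with columns `hour` and `file` (FASTQ,
#'   Phred+33), one file per timepoint, as produced by [emitReads()].
#' @param lib A [TitrationLibrary-class].
#' @param layout A [readLayout()].
#' @param q_min quality threshold; bases must exceed it (default 30).
#' @param q_region `"decision"` restricts the quality filter to the spacer
#'   and barcode bases; `"whole"` applies it to every base of the read.
#' @param environment environment label for the output tensor.
#' @return list with `counts` (a [GuideCounts-class]) and `discarded`
#'   (data.frame `hour`, `reason`, `n`).
#' @export
countReads <- function(files, lib, layout = readLayout(), q_min = 30L,
                       q_region = c("decision", "whole"),
                       environment = "glucose") {
    q_region <- match.arg(q_region)
    stopifnot(is(lib, "TitrationLibrary"),
              all(c("hour", "file") %in% colnames(files)))
    v <- as.data.frame(guideVariants(lib))
    barcodes <- lib@barcodes
    hours <- sort(files$hour)
    ng <- nrow(v); nb <- length(barcodes); nt <- length(hours)
    counts <- array(0L, dim = c(ng, nb, nt),
                    dimnames = list(v$guide_id, barcodes, hours))
    disc <- list()
    for (i in seq_len(nrow(files))) {
        h <- files$hour[i]
        ti <- match(h, hours)
        reads <- suppressWarnings(
            Biostrings::readQualityScaledDNAStringSet(files$file[i]))
        if (!length(reads)) next
        seqs <- as.character(reads)
        quals <- as(Biostrings::quality(reads), "IntegerList")
        if (any(nchar(seqs) < layout$barcode_start + 5L))
            stop("malformed read shorter than the layout in ",
                 files$file[i], call. = FALSE)
        spacer <- substr(seqs, layout$spacer_start,
                         layout$spacer_start + 19L)
        bc <- substr(seqs, layout$barcode_start, layout$barcode_start + 5L)
        ok_q <- vapply(seq_along(seqs), function(r) {
            q <- quals[[r]]
            idx <- if (q_region == "whole") seq_along(q) else
                c(layout$spacer_start:(layout$spacer_start + 19L),
                  layout$barcode_start:(layout$barcode_start + 5L))
            all(q[idx] > q_min)
        }, logical(1))
        gi <- match(spacer, v$spacer)
        bi <- match(bc, barcodes)
        reason <- rep(NA_character_, length(seqs))
        reason[is.na(bi)] <- "unknown_barcode"
        reason[is.na(gi)] <- "unmatched_spacer"
        reason[!ok_q] <- "low_quality"
        keep <- is.na(reason)
        if (any(keep)) {
            tab <- table(factor(gi[keep], levels = seq_len(ng)),
                         factor(bi[keep], levels = seq_len(nb)))
            counts[, , ti] <- counts[, , ti] +
                matrix(as.integer(tab), ng, nb)
        }
        if (any(!keep)) {
            t2 <- table(reason[!keep])
            disc[[length(disc) + 1L]] <- data.frame(
                hour = h, reason = names(t2), n = as.integer(t2),
                stringsAsFactors = FALSE)
        }
    }
    discarded <- if (length(disc)) do.call(rbind, disc) else
        data.frame(hour = numeric(), reason = character(), n = integer())
    gc <- GuideCounts(counts, schedule_hours = hours,
                      environment = environment,
                      rowData = v[, c("guide_id", "gene_id", "role",
                                      "strategy", "n_mut")])
    list(counts = gc, discarded = discarded)
}

#' Write / read a count tensor as TSV
#'
#' One row per (guide, barcode, hour) in stable (guide, barcode, hour)
#' order, with columns `guide_id`, `barcode`, `hour`, `count`.
#'
#' @param gc A [GuideCounts-class].
#' @param path output path.
#' @return `writeCountTable` returns `path` invisibly.
#' @export
writeCountTable <- function(gc, path) {
    stopifnot(is(gc, "GuideCounts"))
    cd <- colData(gc)
    cnt <- SummarizedExperiment::assay(gc, "counts")
    df <- do.call(rbind, lapply(seq_len(ncol(cnt)), function(j)
        data.frame(guide_id = rownames(cnt), barcode = cd$barcode[j],
                   hour = cd$hour[j], count = cnt[, j],
                   stringsAsFactors = FALSE)))
    df <- df[order(df$guide_id, df$barcode, df$hour), ]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# environment: ", environmentName(gc)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountTable
#' @param environment environment label override (default: the `#
#'   environment:` header when present).
#' @param lib optional [TitrationLibrary-class]; when given, guide
#'   annotation (gene, role, strategy, mutation count) is attached as
#'   `rowData`, which the growth estimator needs to locate negC controls.
#' @return `readCountTable` returns a [GuideCounts-class].
#' @export
readCountTable <- function(path, environment = NULL, lib = NULL) {
    first <- readLines(path, n = 1L)
    if (is.null(environment))
        environment <- if (startsWith(first, "# environment:"))
            trimws(sub("# environment:", "", first)) else "glucose"
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    stopifnot(all(c("guide_id", "barcode", "hour", "count") %in%
                  colnames(df)))
    if (any(df$count < 0)) stop("negative counts in ", path, call. = FALSE)
    key <- paste(df$guide_id, df$barcode, df$hour)
    if (anyDuplicated(key))
        stop("duplicate (guide, barcode, hour) rows in ", path,
             call. = FALSE)
    hours <- sort(unique(df$hour))
    if (hours[1] != 0)
        stop("hour schedule must start at 0", call. = FALSE)
    guides <- sort(unique(df$guide_id))
    barcodes <- sort(unique(df$barcode))
    full <- length(guides) * length(barcodes) * length(hours)
    if (nrow(df) < full)
        warning("missing (guide, barcode, hour) combinations read as 0",
                call. = FALSE)
    counts <- array(0L, dim = c(length(guides), length(barcodes),
                                length(hours)),
                    dimnames = list(guides, barcodes, hours))
    counts[cbind(match(df$guide_id, guides), match(df$barcode, barcodes),
                 match(df$hour, hours))] <- as.integer(df$count)
    rd <- NULL
    if (!is.null(lib)) {
        v <- as.data.frame(guideVariants(lib))
        rd <- v[match(guides, v$guide_id),
                c("guide_id", "gene_id", "role", "strategy", "n_mut")]
        if (anyNA(rd$guide_id))
            stop("count table contains guides absent from the library",
                 call. = FALSE)
    }
    GuideCounts(counts, schedule_hours = hours, environment = environment,
                rowData = rd)
}
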