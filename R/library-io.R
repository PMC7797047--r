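#' Read gene targets from a multi-FASTA of coding sequences
#'
#' @param path FASTA file; record names are taken as gene ids (up to the
#'   first whitespace).
#' @param essential optional character vector of essential gene ids.
#' @return list of [geneTarget()]s.
#' @export
readGeneFasta <- function(path, essential = character()) {
    seqs <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    mapply(function(id, s) geneTarget(id, s, id %in% essential),
           ids, as.character(seqs), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write / read a titration library as TSV
#'
#' The TSV carries one row per guide with the columns of the `variants`
#' table; barcodes are stored in a `# barcodes:` header comment.
#'
#' @param lib A [TitrationLibrary-class].
#' @param path output path.
#' @return `writeLibraryTsv` returns `path` invisibly; `readLibraryTsv`
#'   returns a [TitrationLibrary-class].
#' @export
writeLibraryTsv <- function(lib, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# barcodes: ", paste(lib@barcodes, collapse = ",")),
               con)
    utils::write.table(as.data.frame(guideVariants(lib)), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeLibraryTsv
#' @export
readLibraryTsv <- function(path) {
    first <- readLines(path, n = 1L)
    barcodes <- defaultBarcodes()
    if (startsWith(first, "# barcodes:"))
        barcodes <- strsplit(trimws(sub("# barcodes:", "", first)),
                             ",")[[1]]
    v <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    v$mutated_positions[is.na(v$mutated_positions)] <- ""
    TitrationLibrary(v, barcodes = barcodes)
}

#' Write library spacers as FASTA
#'
#' @param lib A [TitrationLibrary-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpacerFasta <- function(lib, path) {
    v <- guideVariants(lib)
    x <- Biostrings::DNAStringSet(v$spacer)
    names(x) <- v$guide_id
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}
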