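# Small sequence helpers shared across modules. Spacer coordinates follow
# the CRISPRi convention: position -1 is the PAM-proximal base, -20 the
# PAM-distal base. For a spacer string written 5'->3' (the reverse
# complement of the protospacer), position -k is string index 21-k.

BASES <- c("A", "C", "G", "T")

revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complementBase <- function(b) {
    chartr("ACGT", "TGCA", b)
}

gcFraction <- function(spacer) {
    ch <- strsplit(spacer, "")[[1]]
    mean(ch %in% c("G", "C"))
}

maxBaseRun <- function(seq, base = "T") {
    ch <- strsplit(seq, "")[[1]]
    r <- rle(ch)
    runs <- r$lengths[r$values == base]
    if (length(runs)) max(runs) else 0L
}

# spacer position -k (k in 1..20) -> string index
spacerIndex <- function(k) 21L - as.integer(k)

# flip the listed spacer positions to their complement base
mutateSpacer <- function(spacer, positions) {
    ch <- strsplit(spacer, "")[[1]]
    idx <- spacerIndex(abs(positions))
    ch[idx] <- complementBase(ch[idx])
    paste(ch, collapse = "")
}

checkDna <- function(x, what = "sequence") {
    if (grepl("[^ACGT]", x))
        stop(what, " must contain only A/C/G/T", call. = FALSE)
    invisible(x)
}

fmtPositions <- function(positions) {
    if (!length(positions)) return("")
    paste(sort(as.integer(positions), decreasing = TRUE), collapse = ",")
}

parsePositions <- function(s) {
    if (is.na(s) || !nzchar(s)) return(integer())
    as.integer(strsplit(s, ",")[[1]])
}
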