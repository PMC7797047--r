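#' Create a gene target
#'
#' @param gene_id gene identifier.
#' @param cds coding sequence (sense strand, A/C/G/T, beginning at the start
#'   codon), at least 23 nt.
#' @param essential logical annotation flag (not used by the design rules).
#' @return A list of class `GeneTarget`.
#' @export
geneTarget <- function(gene_id, cds, essential = FALSE) {
    cds <- toupper(cds)
    checkDna(cds, "cds")
    if (nchar(cds) < 23L)
        stop("cds must be at least 23 nt", call. = FALSE)
    structure(list(gene_id = gene_id, cds = cds,
                   essential = isTRUE(essential)),
              class = "GeneTarget")
}

#' Scan a coding sequence for CCN PAM sites
#'
#' Finds every CCN protospacer-adjacent motif on the sense strand with at
#' least 20 nt downstream, and returns one candidate parent sgRNA per site.
#' The protospacer is the 20 nt immediately 3' of the CCN; the spacer is its
#' reverse complement, so spacer position -1 pairs opposite the sense base
#' adjacent to the motif.
#'
#' @param gene A [geneTarget()].
#' @return data.frame with columns `gene_id`, `pam_offset` (1-based position
#'   of the first C), `protospacer`, `spacer`, `gc_fraction`, ordered by
#'   `pam_offset`. Zero rows when no motif fits.
#' @export
scanPamCandidates <- function(gene) {
    stopifnot(inherits(gene, "GeneTarget"))
    ch <- strsplit(gene$cds, "")[[1]]
    n <- length(ch)
    # first C of CCN at i; need 20 nt after the motif: i + 22 <= n
    lim <- n - 22L
    if (lim < 1L)
        return(emptyCandidates())
    idx <- which(ch[seq_len(lim)] == "C" & ch[seq_len(lim) + 1L] == "C")
    if (!length(idx))
        return(emptyCandidates())
    proto <- vapply(idx, function(i)
        substr(gene$cds, i + 3L, i + 22L), character(1))
    spacer <- revComp(proto)
    data.frame(gene_id = gene$gene_id, pam_offset = idx,
               protospacer = proto, spacer = spacer,
               gc_fraction = vapply(spacer, gcFraction, numeric(1),
                                    USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
}

emptyCandidates <- function() {
    data.frame(gene_id = character(), pam_offset = integer(),
               protospacer = character(), spacer = character(),
               gc_fraction = numeric(), stringsAsFactors = FALSE)
}

#' Sequence-composition filters for candidate sgRNAs
#'
#' A candidate passes when its spacer GC fraction lies strictly inside
#' (`gc_min`, `gc_max`) and its longest run of consecutive T does not exceed
#' `polyT_max`. Boundary values fail.
#'
#' @param candidate one candidate row (list/data.frame row with `spacer`).
#' @param gc_min,gc_max strict GC bounds (defaults 0.45 and 0.80).
#' @param polyT_max longest permitted T homopolymer (default 4).
#' @return list with `pass` (logical) and `reasons` (character vector among
#'   `gc_low`, `gc_high`, `polyT`; empty when passing).
#' @export
applySequenceFilters <- function(candidate, gc_min = 0.45, gc_max = 0.80,
                                 polyT_max = 4L) {
    spacer <- candidate$spacer
    gc <- gcFraction(spacer)
    reasons <- character()
    if (gc <= gc_min) reasons <- c(reasons, "gc_low")
    if (gc >= gc_max) reasons <- c(reasons, "gc_high")
    if (maxBaseRun(spacer, "T") > polyT_max) reasons <- c(reasons, "polyT")
    list(pass = length(reasons) == 0L, reasons = reasons)
}

# Sliding-window identity of a 20-mer against one strand of one sequence.
# Returns integer vector of matches (0..20) per start position.
slidingIdentity <- function(query, subject) {
    q <- strsplit(query, "")[[1]]
    s <- strsplit(subject, "")[[1]]
    L <- length(s) - 19L
    if (L < 1L) return(integer())
    hits <- integer(L)
    for (k in 1:20) hits <- hits + (s[k:(k + L - 1L)] == q[k])
    hits
}

#' Screen a candidate sgRNA for off-target binding potential
#'
#' Slides the 20-nt protospacer over both strands of every background
#' sequence and applies three redesign rules: (i) an exact 20/20 match at
#' more than one locus; (ii) a site with identity strictly between 90% and
#' 100% that is adjacent to a PAM; (iii) a site with identity strictly
#' between 75% and 90% whose PAM-proximal eight positions (spacer -1..-8)
#' match perfectly and which is adjacent to a PAM. PAM adjacency means a
#' CC dinucleotide within 3 nt 5' of a sense-orientation site (or GG within
#' 3 nt 3' of an antisense site).
#'
#' @param candidate candidate row with `protospacer`.
#' @param background character vector of background sequences (A/C/G/T).
#' @param min_report minimum identity fraction for reporting a site.
#' @return list with `verdict` (`"pass"` or `"redesign"`) and `sites`, a
#'   data.frame of matched loci with the rule flags.
#' @export
screenOffTargets <- function(candidate, background, min_report = 0.75) {
    if (missing(background) || length(background) == 0L)
        stop("off-target screening requested with empty background",
             call. = FALSE)
    proto <- candidate$protospacer
    sites <- list()
    for (si in seq_along(background)) {
        bg <- toupper(background[[si]])
        checkDna(bg, "background sequence")
        for (strand in c("+", "-")) {
            query <- if (strand == "+") proto else revComp(proto)
            hits <- slidingIdentity(query, bg)
            for (pos in which(hits / 20 > min_report)) {
                h <- hits[pos] / 20
                end <- pos + 19L
                if (strand == "+") {
                    ctx <- substr(bg, max(1L, pos - 5L), pos - 1L)
                    pam <- grepl("CC", ctx, fixed = TRUE)
                    r1 <- substr(bg, pos, pos + 7L) == substr(proto, 1, 8)
                } else {
                    ctx <- substr(bg, end + 1L, min(nchar(bg), end + 5L))
                    pam <- grepl("GG", ctx, fixed = TRUE)
                    # antisense site: PAM-proximal protospacer bases sit at
                    # the window's 3' end, reverse-complemented
                    r1 <- substr(bg, end - 7L, end) ==
                        substr(revComp(proto), 13, 20)
                }
                sites[[length(sites) + 1L]] <- data.frame(
                    background = si, start = pos, strand = strand,
                    identity = h, pam_adjacent = pam,
                    region1_perfect = r1, stringsAsFactors = FALSE)
            }
        }
    }
    sites <- if (length(sites)) do.call(rbind, sites) else
        data.frame(background = integer(), start = integer(),
                   strand = character(), identity = numeric(),
                   pam_adjacent = logical(), region1_perfect = logical())
    exact <- sum(sites$identity == 1)
    rule1 <- exact >= 2L
    rule2 <- any(sites$identity > 0.90 & sites$identity < 1 &
                 sites$pam_adjacent)
    rule3 <- any(sites$identity > 0.75 & sites$identity < 0.90 &
                 sites$region1_perfect & sites$pam_adjacent)
    list(verdict = if (rule1 || rule2 || rule3) "redesign" else "pass",
         sites = sites)
}

#' Assign SG1/SG2/SG3 roles among filtered candidates
#'
#' SG1 is the candidate with the smallest PAM offset at most `max_start`
#' (150 bp); SG2 the next smallest such candidate whose 20-nt protospacer
#' window does not overlap SG1's; SG3 the candidate with the smallest offset
#' at least `sg3_min` (200 bp). Roles with no qualifying candidate are
#' simply absent.
#'
#' @param candidates data.frame of candidates that already passed the
#'   sequence and off-target filters.
#' @param max_start maximum PAM offset for SG1/SG2.
#' @param sg3_min minimum PAM offset for SG3.
#' @return data.frame of up to three rows with a `role` column.
#' @export
selectParents <- function(candidates, max_start = 150L, sg3_min = 200L) {
    out <- candidates[0, , drop = FALSE]
    if (nrow(out) >= 0) out$role <- character(0)
    if (!nrow(candidates)) return(out)
    cand <- candidates[order(candidates$pam_offset), , drop = FALSE]
    early <- cand[cand$pam_offset <= max_start, , drop = FALSE]
    picks <- list()
    if (nrow(early)) {
        sg1 <- early[1, , drop = FALSE]
        sg1$role <- "SG1"
        picks$SG1 <- sg1
        # protospacer occupies pam_offset+3 .. pam_offset+22
        rest <- early[-1, , drop = FALSE]
        ok <- abs(rest$pam_offset - sg1$pam_offset) > 19L
        if (any(ok)) {
            sg2 <- rest[which(ok)[1], , drop = FALSE]
            sg2$role <- "SG2"
            picks$SG2 <- sg2
        }
    }
    late <- cand[cand$pam_offset >= sg3_min, , drop = FALSE]
    if (nrow(late)) {
        sg3 <- late[1, , drop = FALSE]
        sg3$role <- "SG3"
        picks$SG3 <- sg3
    }
    if (!length(picks)) return(out)
    do.call(rbind, unname(picks))
}

variantRow <- function(parent, strategy, positions, suffix) {
    n_mut <- length(positions)
    data.frame(
        guide_id = paste(parent$gene_id, parent$role, suffix, sep = "_"),
        gene_id = parent$gene_id, role = parent$role, strategy = strategy,
        n_mut = n_mut, mutated_positions = fmtPositions(positions),
        spacer = if (n_mut) mutateSpacer(parent$spacer, positions) else
            parent$spacer,
        pam_offset = parent$pam_offset, stringsAsFactors = FALSE)
}

#' Compounding mismatch series for one parent sgRNA
#'
#' Variant k (k = 1..14) carries complement mutations at spacer positions
#' -20 down to -(21-k): mismatches accumulate from the PAM-distal end
#' toward position -7.
#'
#' @param parent one parent row (with `gene_id`, `role`, `spacer`,
#'   `pam_offset`).
#' @param n_series series length (default 14).
#' @return data.frame of `n_series` guide variants.
#' @export
mutateCompounding <- function(parent, n_series = 14L) {
    do.call(rbind, lapply(seq_len(n_series), function(k) {
        pos <- -(20L:(21L - k))
        variantRow(parent, "compounding", pos, sprintf("comp%02d", k))
    }))
}

#' Single mismatch series for one parent sgRNA
#'
#' One variant per position in \{-1, -2, -5, -8, -10..-20\} (15 variants),
#' each mutated to the complement base.
#'
#' @inheritParams mutateCompounding
#' @return data.frame of 15 guide variants.
#' @export
mutateSingles <- function(parent) {
    positions <- c(-1L, -2L, -5L, -8L, -(10L:20L))
    do.call(rbind, lapply(positions, function(p)
        variantRow(parent, "single", p, sprintf("single%03d", -p))))
}

#' Double mismatch series for one parent sgRNA
#'
#' The five printed position pairs -2/-12, -12/-14, -15/-17, -11/-18 and
#' -13/-19, each mutated to complement bases.
#'
#' @inheritParams mutateCompounding
#' @return data.frame of 5 guide variants.
#' @export
mutateDoubles <- function(parent) {
    pairs <- list(c(-2L, -12L), c(-12L, -14L), c(-15L, -17L),
                  c(-11L, -18L), c(-13L, -19L))
    do.call(rbind, lapply(pairs, function(p)
        variantRow(parent, "double", p,
                   sprintf("double%03d_%03d", -p[1], -p[2]))))
}

#' Scrambled non-targeting control sgRNAs
#'
#' Draws random 20-mers, keeps those passing the GC/poly-T filters (and the
#' off-target screen when a background is supplied), until `n` controls are
#' collected. Reproducible from `seed`.
#'
#' @param n number of controls (default 45).
#' @param seed RNG seed.
#' @param background optional background sequences for off-target screening.
#' @param gc_min,gc_max,polyT_max filter settings as in
#'   [applySequenceFilters()].
#' @param max_draws bail-out bound on candidate draws.
#' @return data.frame of `n` negC guide variants.
#' @export
makeNegc <- function(n = 45L, seed = 1L, background = NULL,
                     gc_min = 0.45, gc_max = 0.80, polyT_max = 4L,
                     max_draws = 1000L * n) {
    stopifnot(n >= 1L)
    set.seed(seed)
    spacers <- character(0)
    draws <- 0L
    while (length(spacers) < n && draws < max_draws) {
        draws <- draws + 1L
        sp <- paste(sample(BASES, 20, replace = TRUE), collapse = "")
        f <- applySequenceFilters(list(spacer = sp), gc_min, gc_max,
                                  polyT_max)
        if (!f$pass) next
        if (!is.null(background)) {
            v <- screenOffTargets(list(protospacer = revComp(sp)),
                                  background)
            if (v$verdict != "pass") next
        }
        if (sp %in% spacers) next
        spacers <- c(spacers, sp)
    }
    if (length(spacers) < n)
        stop("could not draw ", n, " filtered controls in ", max_draws,
             " attempts", call. = FALSE)
    data.frame(guide_id = sprintf("negC_rand_%02d", seq_len(n)),
               gene_id = NA_character_, role = NA_character_,
               strategy = "negC", n_mut = 0L, mutated_positions = "",
               spacer = spacers, pam_offset = NA_integer_,
               stringsAsFactors = FALSE)
}

#' Design the full titration library for a set of genes
#'
#' Per gene: scan CCN sites, apply composition filters (and the off-target
#' screen when a background is given), assign SG1/SG2/SG3 parents, and
#' expand SG1 and SG3 into compounding (14), single (15) and double (5)
#' mismatch series. SG2 is kept as an unmutated control. Scrambled negC
#' controls are appended.
#'
#' @param genes list of [geneTarget()]s.
#' @param background optional background sequences for off-target screening.
#' @param n_negc number of scrambled controls (default 45).
#' @param seed RNG seed for the controls.
#' @param barcodes internal replicate barcodes.
#' @param gc_min,gc_max,polyT_max composition filter settings.
#' @return A [TitrationLibrary-class].
#' @export
designLibrary <- function(genes, background = NULL, n_negc = 45L, seed = 1L,
                          barcodes = defaultBarcodes(), gc_min = 0.45,
                          gc_max = 0.80, polyT_max = 4L) {
    if (inherits(genes, "GeneTarget")) genes <- list(genes)
    per_gene <- lapply(genes, function(g) {
        cand <- scanPamCandidates(g)
        if (!nrow(cand)) return(NULL)
        keep <- vapply(seq_len(nrow(cand)), function(i)
            applySequenceFilters(cand[i, ], gc_min, gc_max, polyT_max)$pass,
            logical(1))
        cand <- cand[keep, , drop = FALSE]
        if (!is.null(background) && nrow(cand)) {
            keep <- vapply(seq_len(nrow(cand)), function(i)
                screenOffTargets(cand[i, ], background)$verdict == "pass",
                logical(1))
            cand <- cand[keep, , drop = FALSE]
        }
        parents <- selectParents(cand)
        if (!nrow(parents)) return(NULL)
        rows <- lapply(seq_len(nrow(parents)), function(i) {
            p <- as.list(parents[i, ])
            base <- variantRow(p, "parent", integer(), "parent")
            if (p$role %in% c("SG1", "SG3"))
                rbind(base, mutateCompounding(p), mutateSingles(p),
                      mutateDoubles(p))
            else base
        })
        do.call(rbind, rows)
    })
    variants <- do.call(rbind, c(per_gene[!vapply(per_gene, is.null,
                                                  logical(1))],
                                 list(makeNegc(n_negc, seed, background,
                                               gc_min, gc_max, polyT_max))))
    gene_df <- data.frame(
        gene_id = vapply(genes, `[[`, character(1), "gene_id"),
        cds = vapply(genes, `[[`, character(1), "cds"),
        essential = vapply(genes, `[[`, logical(1), "essential"),
        stringsAsFactors = FALSE)
    TitrationLibrary(variants, barcodes = barcodes, genes = gene_df)
}

#' Restrict a library to the compact 16-guide design
#'
#' Keeps, per gene, the SG1 and SG3 parents plus their compounding variants
#' with 4-10 mutations (2 + 2x7 = 16 guides when both parents exist; fewer
#' with a warning when a parent is missing).
#'
#' @param lib A [TitrationLibrary-class].
#' @param keep_negc retain negC controls alongside the compact set
#'   (default `FALSE`).
#' @return A [TitrationLibrary-class] restricted to the compact design.
#' @export
compactSubset <- function(lib, keep_negc = FALSE) {
    v <- as.data.frame(guideVariants(lib))
    targ <- v[!is.na(v$gene_id) & v$role %in% c("SG1", "SG3") &
              (v$strategy == "parent" |
               (v$strategy == "compounding" & v$n_mut >= 4L &
                v$n_mut <= 10L)), , drop = FALSE]
    for (g in unique(targ$gene_id)) {
        roles <- unique(targ$role[targ$gene_id == g &
                                  targ$strategy == "parent"])
        if (length(roles) < 2L)
            warning("gene ", g, " lacks parent ",
                    paste(setdiff(c("SG1", "SG3"), roles), collapse = "/"),
                    "; compact set is incomplete", call. = FALSE)
    }
    if (keep_negc)
        targ <- rbind(targ, v[v$strategy == "negC", , drop = FALSE])
    TitrationLibrary(targ, barcodes = lib@barcodes, genes = lib@genes)
}
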