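test_that("CCN scanning finds every motif with room for a 20-mer", {
    # forced single motif: CC then 21 A
    g <- geneTarget("g1", paste0("CC", strrep("A", 21)))
    cand <- scanPamCandidates(g)
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$pam_offset, 1L)
    expect_equal(cand$protospacer, strrep("A", 20))
    expect_equal(cand$spacer, strrep("T", 20))

    # no C at all -> no candidates
    g2 <- geneTarget("g2", paste(rep(c("A", "G", "T"), 20), collapse = ""))
    expect_equal(nrow(scanPamCandidates(g2)), 0L)

    # random 500-mer agrees with an exhaustive substring-scan oracle
    set.seed(42)
    for (i in 1:5) {
        cds <- randomDna(500)
        cand <- scanPamCandidates(geneTarget(paste0("r", i), cds))
        expect_equal(cand$pam_offset, oracleScanPam(cds))
        expect_false(is.unsorted(cand$pam_offset))
        # spacer is always the reverse complement of the protospacer
        expect_equal(cand$spacer, as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(cand$protospacer))))
    }
})

test_that("sequence filters enforce strict GC bounds and the poly-T rule", {
    expect_equal(applySequenceFilters(list(spacer = strrep("G", 20)))$reasons,
                 "gc_high")
    f <- applySequenceFilters(list(spacer = "ATTTTTGCGCGCGCGCGCAT"))
    expect_true("polyT" %in% f$reasons)
    ok <- applySequenceFilters(list(spacer = "AGCTAGCTAGCTAGCTAGCT"))
    expect_true(ok$pass)
    expect_length(ok$reasons, 0)
    # boundaries are exclusive: GC exactly 45% and exactly 80% both fail
    gc9 <- paste0(strrep("G", 9), strrep("A", 11))     # 45%
    gc16 <- paste0(strrep("G", 16), strrep("A", 4))    # 80%
    expect_false(applySequenceFilters(list(spacer = gc9))$pass)
    expect_false(applySequenceFilters(list(spacer = gc16))$pass)
    # a run of exactly four T is allowed
    expect_false("polyT" %in% applySequenceFilters(
        list(spacer = "ATTTTGCGCGCGCGCGCGAT"))$reasons)
})

test_that("off-target screening applies the three redesign rules", {
    proto <- "ATGCATGCATGCATGCATGC"
    cand <- list(protospacer = proto)
    pad <- function(...) paste0(...)

    # rule i: the exact 20-mer at two loci
    bg <- pad(randomDna(30), proto, randomDna(30), proto, randomDna(30))
    expect_equal(screenOffTargets(cand, bg)$verdict, "redesign")

    # one exact locus alone (the guide's own site) is fine
    bg1 <- pad(randomDna(30), proto, randomDna(30))
    expect_equal(screenOffTargets(cand, bg1)$verdict, "pass")

    # rule ii: 19/20 identity adjacent to a CCN PAM
    near <- paste0("T", substr(proto, 2, 20))
    bg2 <- pad(randomDna(20), "CCA", near, randomDna(20))
    v2 <- screenOffTargets(cand, bg2)
    expect_equal(v2$verdict, "redesign")
    expect_true(any(v2$sites$identity > 0.9 & v2$sites$identity < 1))

    # 16/20 identity with a seed-region mismatch cannot fire rule iii
    flip <- function(s, at) {
        for (k in at) substr(s, k, k) <- chartr("ACGT", "TGCA",
                                                substr(s, k, k))
        s
    }
    far <- flip(proto, c(1, 12, 15, 18))  # one mismatch in region 1
    bg3 <- pad(randomDna(20), "CCG", far, randomDna(20))
    expect_equal(screenOffTargets(cand, bg3)$verdict, "pass")

    # rule iii fires when region 1 is perfect and a PAM is adjacent
    far2 <- flip(proto, c(10, 13, 16, 19))
    bg4 <- pad(randomDna(20), "CCG", far2, randomDna(20))
    v4 <- screenOffTargets(cand, bg4)
    expect_equal(v4$verdict, "redesign")

    expect_error(screenOffTargets(cand, character()), "empty background")
})

test_that("off-target site detection matches a brute-force identity scan", {
    set.seed(7)
    for (i in 1:5) {
        proto <- randomDna(20)
        bg <- randomDna(3000)
        got <- screenOffTargets(list(protospacer = proto), bg)$sites
        want <- oracleOffTargetSites(proto, bg)
        expect_equal(nrow(got), nrow(want))
        if (nrow(got)) {
            o1 <- order(got$start, got$strand)
            o2 <- order(want$start, want$strand)
            expect_equal(got$start[o1], want$start[o2])
            expect_equal(got$identity[o1], want$identity[o2])
        }
    }
})

test_that("parent selection follows the positional rules", {
    mk <- function(offs) data.frame(
        gene_id = "g", pam_offset = offs,
        protospacer = vapply(offs, function(o) randomDna(20), ""),
        spacer = vapply(offs, function(o) randomDna(20), ""),
        gc_fraction = 0.5, stringsAsFactors = FALSE)

    p <- selectParents(mk(c(10, 40, 210)))
    expect_equal(p$pam_offset[match(c("SG1", "SG2", "SG3"), p$role)],
                 c(10, 40, 210))

    # 25 overlaps SG1@10 (window distance <= 19), 90 does not; SG3 takes
    # the smallest offset >= 200
    p2 <- selectParents(mk(c(10, 25, 90, 250, 205)))
    expect_equal(p2$pam_offset[match(c("SG1", "SG2", "SG3"), p2$role)],
                 c(10, 90, 205))

    # nothing within 150 bp: SG1/SG2 unassigned
    p3 <- selectParents(mk(c(160, 300)))
    expect_false(any(c("SG1", "SG2") %in% p3$role))
    expect_equal(p3$pam_offset[p3$role == "SG3"], 300)

    # input order invariance
    set.seed(9)
    offs <- sample(c(12, 33, 61, 140, 155, 201, 240, 380))
    a <- selectParents(mk(offs))[, c("role", "pam_offset")]
    b <- selectParents(mk(sort(offs)))[, c("role", "pam_offset")]
    a <- a[order(a$role), ]
    b <- b[order(b$role), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
})

test_that("compounding series adds complement mutations from -20 inward", {
    par <- manualParent()
    vs <- mutateCompounding(par)
    expect_equal(nrow(vs), 14L)
    expect_equal(vs$n_mut, 1:14)
    pos <- lapply(vs$mutated_positions, function(s)
        sort(as.integer(strsplit(s, ",")[[1]])))
    # base case and full-series position sets
    expect_equal(pos[[1]], -20L)
    expect_equal(pos[[14]], -(20:7))
    # monotone nesting
    for (k in 1:13) expect_true(all(pos[[k]] %in% pos[[k + 1]]))
    # Hamming distance equals n_mut; positions -6..-1 never touched
    sp <- strsplit(par$spacer, "")[[1]]
    for (k in 1:14) {
        vk <- strsplit(vs$spacer[k], "")[[1]]
        expect_equal(sum(vk != sp), k)
        expect_equal(vk[15:20], sp[15:20])  # string tail = positions -6..-1
    }
    # involution: re-applying the same mutation map restores the parent
    twice <- vapply(seq_len(14), function(k) {
        v <- list(gene_id = "geneX", role = "SG1", spacer = vs$spacer[k],
                  pam_offset = 10L)
        mutateCompounding(v)$spacer[k]
    }, character(1))
    expect_equal(twice, rep(par$spacer, 14))
})

test_that("single and double mismatch series use the printed positions", {
    par <- manualParent()
    sg <- mutateSingles(par)
    expect_equal(nrow(sg), 15L)
    expect_true(all(sg$n_mut == 1L))
    pos <- as.integer(sg$mutated_positions)
    expect_setequal(pos, c(-1, -2, -5, -8, -(10:20)))
    expect_false(-3L %in% pos)
    # the -1 variant differs from the parent only at the PAM-proximal base
    v1 <- sg$spacer[pos == -1L]
    sp <- strsplit(par$spacer, "")[[1]]
    d <- which(strsplit(v1, "")[[1]] != sp)
    expect_equal(d, 20L)

    db <- mutateDoubles(par)
    expect_equal(nrow(db), 5L)
    expect_true(all(db$n_mut == 2L))
    sets <- lapply(db$mutated_positions, function(s)
        sort(as.integer(strsplit(s, ",")[[1]])))
    expect_setequal(vapply(sets, paste, "", collapse = "/"),
                    c("-12/-2", "-14/-12", "-17/-15", "-18/-11",
                      "-19/-13"))
})

test_that("negC controls are reproducible and pass the filters", {
    a <- makeNegc(45, seed = 5)
    b <- makeNegc(45, seed = 5)
    expect_equal(nrow(a), 45L)
    expect_identical(a$spacer, b$spacer)
    expect_false(anyDuplicated(a$spacer) > 0)
    for (sp in a$spacer)
        expect_true(applySequenceFilters(list(spacer = sp))$pass)
    c2 <- makeNegc(10, seed = 6)
    expect_false(identical(a$spacer[1:10], c2$spacer))
})

test_that("the compact subset keeps parents plus compounding 4-10", {
    lib <- tinyLibrary()
    cl <- compactSubset(lib)
    v <- as.data.frame(guideVariants(cl))
    for (g in unique(v$gene_id)) {
        vg <- v[v$gene_id == g, ]
        expect_equal(nrow(vg), 16L)
        expect_equal(sum(vg$strategy == "parent"), 2L)
        expect_setequal(vg$n_mut[vg$strategy == "compounding" &
                                 vg$role == "SG1"], 4:10)
        expect_setequal(vg$n_mut[vg$strategy == "compounding" &
                                 vg$role == "SG3"], 4:10)
    }
    expect_equal(nrow(v), 16L * length(unique(v$gene_id)))

    # a gene lacking SG3 yields the 8-guide half set, with a warning
    full <- as.data.frame(guideVariants(lib))
    sub <- full[!(full$gene_id == full$gene_id[1] & full$role %in% "SG3"), ]
    lib2 <- TitrationLibrary(sub)
    expect_warning(c2 <- compactSubset(lib2), "lacks parent")
    v2 <- as.data.frame(guideVariants(c2))
    expect_equal(sum(v2$gene_id == full$gene_id[1]), 8L)
})

test_that("a designed library round-trips through TSV and FASTA", {
    lib <- tinyLibrary()
    tsv <- tempfile(fileext = ".tsv")
    writeLibraryTsv(lib, tsv)
    lib2 <- readLibraryTsv(tsv)
    expect_equal(as.data.frame(guideVariants(lib2)),
                 as.data.frame(guideVariants(lib)))
    expect_equal(lib2@barcodes, lib@barcodes)

    fa <- tempfile(fileext = ".fasta")
    writeSpacerFasta(lib, fa)
    seqs <- Biostrings::readDNAStringSet(fa)
    v <- as.data.frame(guideVariants(lib))
    expect_equal(as.character(seqs[v$guide_id[10]]),
                 setNames(v$spacer[10], v$guide_id[10]))
})

test_that("full designs contain the expected per-gene series", {
    lib <- tinyLibrary()
    v <- as.data.frame(guideVariants(lib))
    for (g in unique(stats::na.omit(v$gene_id))) {
        vg <- v[!is.na(v$gene_id) & v$gene_id == g, ]
        expect_setequal(vg$role[vg$strategy == "parent"],
                        c("SG1", "SG2", "SG3"))
        # 3 parents + 2 x (14 compounding + 15 single + 5 double)
        expect_equal(nrow(vg), 3L + 2L * 34L)
    }
    expect_equal(sum(v$strategy == "negC"), 45L)
})
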