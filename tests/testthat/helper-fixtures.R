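# Shared fixtures and independent oracles. Fixtures are generated in code
# (seeded) and cached for the session; oracles are deliberately naive
# re-implementations used to cross-check the package's fast paths.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
    if (!exists(name, envir = .fixture_cache))
        assign(name, make(), envir = .fixture_cache)
    get(name, envir = .fixture_cache)
}

tinyGenes <- function() fixture("tinyGenes", function()
    randomGeneSet(3, 450, seed = 101))

tinyLibrary <- function() fixture("tinyLibrary", function()
    designLibrary(tinyGenes(), n_negc = 45, seed = 102))

tinyTruth <- function() fixture("tinyTruth", function()
    simulateTruth(vapply(tinyGenes(), `[[`, character(1), "gene_id"),
                  seed = 103, depth = 2e5))

# a hand-constructed parent guide for mutation-series tests
manualParent <- function(spacer = "ATGCATGCATGCATGCATGC") {
    list(gene_id = "geneX", role = "SG1", spacer = spacer,
         protospacer = as.character(
             Biostrings::reverseComplement(Biostrings::DNAString(spacer))),
         pam_offset = 10L, gc_fraction = 0.5)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# --- oracles -----------------------------------------------------------

# exhaustive CCN scan by direct substring inspection
oracleScanPam <- function(cds) {
    offs <- integer()
    for (i in seq_len(max(0L, nchar(cds) - 22L)))
        if (substr(cds, i, i + 1L) == "CC") offs <- c(offs, i)
    offs
}

# textbook Welch test with Satterthwaite df
oracleWelch <- function(x, y) {
    v1 <- var(x) / length(x); v2 <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    2 * pt(-abs(t), df)
}

# OLS via the normal equations
oracleOls <- function(x, y) {
    X <- cbind(1, x)
    b <- solve(t(X) %*% X, t(X) %*% y)
    list(intercept = b[1], slope = b[2])
}

# one-pass SGoF by direct binomial tail counting
oracleSgof <- function(p, gamma = 0.05, alpha = 0.05) {
    n <- length(p)
    count <- sum(p <= gamma)
    rej <- 0L
    while (count > 0L &&
           sum(dbinom(count:n, n, gamma)) < alpha) {
        rej <- rej + 1L
        count <- count - 1L
    }
    rej
}

# 2^n subset enumeration for the largest all-pairs-significant set
bruteForceSteps <- function(ids, means, sig_pairs) {
    n <- length(ids)
    sig <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    diag(sig) <- TRUE
    for (k in seq_len(nrow(sig_pairs))) {
        sig[sig_pairs$a[k], sig_pairs$b[k]] <- TRUE
        sig[sig_pairs$b[k], sig_pairs$a[k]] <- TRUE
    }
    bits <- 2^(seq_len(n) - 1L)
    best <- list(size = 0L, range = -Inf, var = -Inf, lex = "")
    for (mask in seq_len(2^n) - 1L) {
        mem <- which(bitwAnd(mask, bits) > 0L)
        if (length(mem) < best$size) next
        if (!all(sig[mem, mem])) next
        mids <- sort(ids[mem])
        cand <- list(size = length(mem),
                     range = if (length(mem)) diff(range(means[ids[mem]]))
                             else 0,
                     var = if (length(mem) > 1L) var(means[ids[mem]])
                           else 0,
                     lex = paste(mids, collapse = "|"))
        better <- cand$size > best$size ||
            (cand$size == best$size && cand$range > best$range) ||
            (cand$size == best$size && cand$range == best$range &&
             cand$var > best$var) ||
            (cand$size == best$size && cand$range == best$range &&
             cand$var == best$var && cand$lex < best$lex)
        if (better) best <- cand
    }
    best
}

# brute-force sliding-window identity scan over both strands
oracleOffTargetSites <- function(proto, bg) {
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(proto)))
    out <- list()
    for (strand in c("+", "-")) {
        q <- strsplit(if (strand == "+") proto else rc, "")[[1]]
        s <- strsplit(bg, "")[[1]]
        for (pos in seq_len(max(0L, length(s) - 19L))) {
            idn <- sum(s[pos:(pos + 19L)] == q) / 20
            if (idn > 0.75)
                out[[length(out) + 1L]] <-
                    data.frame(start = pos, strand = strand,
                               identity = idn)
        }
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(start = integer(), strand = character(),
                   identity = numeric())
}
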