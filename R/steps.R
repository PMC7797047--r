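#' Pairwise Welch tests between guides targeting one gene
#'
#' Two-sided Welch (unequal-variance) t-tests over every unordered pair of
#' guides, computed from replicate-level slope estimates. When both
#' samples are constant the test is undefined: p is set to 1 for identical
#' samples and to 0 for distinct constant samples.
#'
#' @param samples named list of numeric vectors (replicate slopes per
#'   guide), each of length >= 2.
#' @return data.frame with columns `a`, `b`, `p`, one row per unordered
#'   pair.
#' @export
pairwiseWelch <- function(samples) {
    ids <- names(samples)
    stopifnot(!is.null(ids), length(ids) >= 2L,
              all(lengths(samples) >= 2L))
    n <- lengths(samples)
    m <- vapply(samples, mean, numeric(1))
    v <- vapply(samples, stats::var, numeric(1))
    pairs <- utils::combn(seq_along(ids), 2)
    i <- pairs[1, ]; j <- pairs[2, ]
    se2 <- v[i] / n[i] + v[j] / n[j]
    tstat <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                   (v[j] / n[j])^2 / (n[j] - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    # both samples constant: t and df are undefined
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(abs(m[i] - m[j])[degenerate] < 1e-12, 1, 0)
    data.frame(a = ids[i], b = ids[j], p = unname(p),
               stringsAsFactors = FALSE)
}

#' Sequential goodness-of-fit (SGoF) multiple-testing correction
#'
#' Counts the p-values at or below `gamma` and compares that count against
#' its Binomial(n, gamma) null expectation with a one-tailed exact test at
#' level `alpha`. While the current count is significantly in excess, the
#' smallest remaining p-value is rejected and the count decremented; the
#' rejected hypotheses are therefore the smallest p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param gamma within-test significance threshold (default 0.05).
#' @param alpha metatest level (default 0.05).
#' @return list with `n_rejected` and `rejected` (integer indices into
#'   `p`, smallest p-values first).
#' @export
sgof <- function(p, gamma = 0.05, alpha = 0.05) {
    stopifnot(all(p >= 0 & p <= 1))
    n <- length(p)
    count <- sum(p <= gamma)
    n_rej <- 0L
    while (count > 0L &&
           stats::pbinom(count - 1L, n, gamma, lower.tail = FALSE) < alpha) {
        n_rej <- n_rej + 1L
        count <- count - 1L
    }
    list(n_rejected = n_rej,
         rejected = if (n_rej) order(p)[seq_len(n_rej)] else integer())
}

#' Largest set of mutually distinguishable guides
#'
#' Finds a maximum-cardinality subset of guides in which every pair is
#' significant — a maximum clique in the significance graph, solved
#' exactly. Ties between maximum cliques are broken by larger dynamic
#' range (max - min of the member mean growth rates), then larger variance
#' of the member means, then lexicographically smallest member id set.
#'
#' @param guide_ids character vector of guides under consideration.
#' @param means named numeric vector of mean growth per guide.
#' @param sig_pairs data.frame with columns `a`, `b` listing the
#'   significant (distinguishable) pairs.
#' @return list with `n_steps` and `member_guides` (ordered by mean
#'   growth).
#' @export
maxDistinguishableSet <- function(guide_ids, means, sig_pairs) {
    n <- length(guide_ids)
    stopifnot(n >= 1L)
    keep <- sig_pairs$a %in% guide_ids & sig_pairs$b %in% guide_ids
    el <- sig_pairs[keep, c("a", "b"), drop = FALSE]
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = guide_ids)
    cliques <- igraph::largest_cliques(g)
    members <- lapply(cliques, function(cl)
        sort(igraph::V(g)$name[as.integer(cl)]))
    if (length(members) > 1L) {
        rng <- vapply(members, function(m)
            diff(range(means[m])), numeric(1))
        vr <- vapply(members, function(m)
            stats::var(means[m]), numeric(1))
        vr[is.na(vr)] <- 0
        lex <- vapply(members, paste, character(1), collapse = "|")
        best <- order(-rng, -vr, lex)[1]
    } else best <- 1L
    m <- members[[best]]
    m <- m[order(means[m])]
    list(n_steps = length(m), member_guides = m)
}

scopeGuides <- function(est, scope) {
    switch(scope,
        all = est$strategy %in% c("parent", "single", "double",
                                  "compounding"),
        single = est$strategy == "single" |
            (est$strategy == "parent" & est$role %in% c("SG1", "SG3")),
        compounding = est$strategy == "compounding" |
            (est$strategy == "parent" & est$role %in% c("SG1", "SG3")),
        compact = (est$strategy == "parent" &
                   est$role %in% c("SG1", "SG3")) |
            (est$strategy == "compounding" & est$role %in% c("SG1", "SG3") &
             est$n_mut >= 4L & est$n_mut <= 10L),
        stop("unknown scope ", scope, call. = FALSE))
}

#' Count statistically resolvable growth effects per gene
#'
#' For one library scope: per-gene pairwise Welch tests on replicate-level
#' slopes, SGoF correction over the pooled p-values of all genes, then the
#' largest mutually distinguishable guide set per gene. Genes are eligible
#' when they carry both SG1 and SG3 titrating guides and at least one
#' parent guide with normalized growth below `eligibility`.
#'
#' @param estimates estimate table from [estimateGrowth()].
#' @param fits per-lineage fit table from [estimateGrowth()] (only rows
#'   with `kept = TRUE` are used).
#' @param scope one of `"all"`, `"single"`, `"compounding"`, `"compact"`.
#' @param eligibility parent normalized-growth threshold (default 0.75,
#'   strict).
#' @param gamma,alpha SGoF settings.
#' @return list with `steps` (data.frame `gene_id`, `scope`, `n_steps`,
#'   `member_guides`), `pairs` (all tested pairs with p-values and
#'   significance flags) and `skipped` (ineligible genes with reasons).
#' @export
countResolvableSteps <- function(estimates, fits,
                                 scope = c("all", "single", "compounding",
                                           "compact"),
                                 eligibility = 0.75, gamma = 0.05,
                                 alpha = 0.05) {
    scope <- match.arg(scope)
    est <- estimates[!is.na(estimates$gene_id), , drop = FALSE]
    skipped <- list()
    eligible <- character()
    for (g in unique(est$gene_id)) {
        ge <- est[est$gene_id == g, , drop = FALSE]
        has_titration <- all(c("SG1", "SG3") %in%
                             ge$role[ge$strategy %in%
                                     c("single", "double", "compounding")])
        strong_parent <- any(ge$normalized[ge$strategy == "parent"] <
                             eligibility)
        if (has_titration && strong_parent) eligible <- c(eligible, g)
        else skipped[[g]] <- data.frame(
            gene_id = g,
            reason = if (!has_titration) "missing_titration_series"
                     else "no_strong_parent")
    }
    est <- est[est$gene_id %in% eligible & scopeGuides(est, scope), ,
               drop = FALSE]
    kept <- fits[fits$kept & fits$guide_id %in% est$guide_id, ,
                 drop = FALSE]
    pair_tabs <- lapply(unique(est$gene_id), function(g) {
        ids <- est$guide_id[est$gene_id == g]
        samples <- split(kept$slope, factor(kept$guide_id, levels = ids))
        samples <- samples[lengths(samples) >= 2L]
        if (length(samples) < 2L) return(NULL)
        cbind(gene_id = g, pairwiseWelch(samples))
    })
    pairs <- do.call(rbind, pair_tabs[!vapply(pair_tabs, is.null,
                                              logical(1))])
    if (is.null(pairs))
        return(list(steps = data.frame(), pairs = data.frame(),
                    skipped = do.call(rbind, skipped)))
    sg <- sgof(pairs$p, gamma, alpha)
    pairs$significant <- seq_len(nrow(pairs)) %in% sg$rejected
    means <- stats::setNames(est$mean_raw, est$guide_id)
    steps <- do.call(rbind, lapply(unique(pairs$gene_id), function(g) {
        ids <- est$guide_id[est$gene_id == g]
        sp <- pairs[pairs$gene_id == g & pairs$significant, ,
                    drop = FALSE]
        res <- maxDistinguishableSet(ids, means, sp)
        data.frame(gene_id = g, scope = scope, n_steps = res$n_steps,
                   member_guides = paste(res$member_guides,
                                         collapse = ","),
                   stringsAsFactors = FALSE)
    }))
    list(steps = steps, pairs = pairs,
         skipped = if (length(skipped)) do.call(rbind, skipped) else
             data.frame(gene_id = character(), reason = character()))
}

#' Resolvable-step comparison across library scopes
#'
#' Runs [countResolvableSteps()] for each requested scope; SGoF pooling is
#' redone within each scope.
#'
#' @inheritParams countResolvableSteps
#' @param scopes scopes to evaluate.
#' @return data.frame of per-gene step counts across scopes.
#' @export
strategyComparison <- function(estimates, fits,
                               scopes = c("single", "compounding", "all",
                                          "compact"),
                               eligibility = 0.75, gamma = 0.05,
                               alpha = 0.05) {
    do.call(rbind, lapply(scopes, function(sc)
        countResolvableSteps(estimates, fits, sc, eligibility, gamma,
                             alpha)$steps))
}
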