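#' Random gene targets amenable to full library design
#'
#' Draws random coding sequences and keeps those for which the design
#' rules yield all three parents (SG1, SG2 within the first 150 bp, SG3 at
#' 200+ bp), so a complete titration series can be built per gene.
#' Intended for simulation studies and tests.
#'
#' @param n number of genes.
#' @param cds_length sequence length (default 500 nt).
#' @param seed RNG seed.
#' @param prefix gene id prefix.
#' @return list of [geneTarget()]s of length `n`.
#' @export
randomGeneSet <- function(n, cds_length = 500L, seed = 1L,
                          prefix = "gene") {
    set.seed(seed)
    genes <- vector("list", n)
    for (i in seq_len(n)) {
        for (try in 1:500) {
            cds <- paste(c("ATG",
                           sample(BASES, cds_length - 3L,
                                  replace = TRUE)), collapse = "")
            g <- geneTarget(sprintf("%s%02d", prefix, i), cds)
            cand <- scanPamCandidates(g)
            if (!nrow(cand)) next
            keep <- vapply(seq_len(nrow(cand)), function(k)
                applySequenceFilters(cand[k, ])$pass, logical(1))
            par <- selectParents(cand[keep, , drop = FALSE])
            if (all(c("SG1", "SG2", "SG3") %in% par$role)) {
                genes[[i]] <- g
                break
            }
        }
        if (is.null(genes[[i]]))
            stop("failed to draw a designable gene", call. = FALSE)
    }
    genes
}

#' Default run configuration
#'
#' All thresholds default to the platform's standard analysis settings:
#' sequencing-depth truncation at 10 counts, R-squared filter 0.70 with a
#' +/-0.05 slope exemption, Dixon Q at 95% confidence, at least 3
#' surviving replicates, SGoF gamma and metatest alpha 0.05, logistic
#' bounds min/max in [0, 1.15] and IG-50 in [0, 14] with starts
#' (meanL, meanH, 1, 6), and eligibility at normalized growth 0.75.
#'
#' @return Nested list, serializable to YAML.
#' @export
defaultRunConfig <- function() {
    list(
        seed = 1L,
        genes = list(n = 8L, cds_length = 500L),
        library = list(n_negc = 45L, compact = FALSE),
        environments = list(
            glucose = list(doublings_per_hour = 0.94,
                           schedule_hours = c(0, 2, 4, 6, 10, 12, 14)),
            glycerol = list(doublings_per_hour = 0.53,
                            schedule_hours = c(0, 2, 6, 10, 14))),
        truth = list(depth = 2e5, escape_prob = 0.01,
                     replicate_jitter_sd = 0.01, floor_raw = -1.23),
        thresholds = list(depth_floor = 10L, r2_min = 0.70,
                          exempt = c(-0.05, 0.05), min_replicates = 3L,
                          gamma = 0.05, alpha = 0.05,
                          eligibility = 0.75, min_points = 8L,
                          flat_tol = 0.05),
        scopes = c("compounding", "compact"))
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the full design-simulate-analyse pipeline
#'
#' Orchestrates library design, pooled-selection simulation per
#' environment, growth-rate estimation with escaper correction,
#' resolvable-step counting, and (with two environments) the
#' gene-by-environment analysis. Every stage's outputs are written as TSV
#' reports into the run directory, together with a log of dropped records
#' and stage decisions. Deterministic given the config seeds.
#'
#' @param config a config list (see [defaultRunConfig()]) or path to a
#'   YAML file with the same structure. `config$genes` may instead carry
#'   `fasta: <path>` to design against real coding sequences.
#' @param out_dir run directory (default `"titracrispr_run"`).
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        out_dir = "titracrispr_run") {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config), !is.null(config$environments))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logf <- file.path(out_dir, "log.txt")
    logs <- character()
    note <- function(...) logs <<- c(logs, paste0(...))
    seed <- as.integer(config$seed %||% 1L)
    th <- utils::modifyList(defaultRunConfig()$thresholds,
                            config$thresholds %||% list())
    tr <- utils::modifyList(defaultRunConfig()$truth,
                            config$truth %||% list())

    # --- design ---
    genes <- if (!is.null(config$genes$fasta))
        readGeneFasta(config$genes$fasta)
    else randomGeneSet(config$genes$n %||% 8L,
                       config$genes$cds_length %||% 500L, seed)
    lib <- designLibrary(genes, n_negc = config$library$n_negc %||% 45L,
                         seed = seed)
    if (isTRUE(config$library$compact))
        lib <- compactSubset(lib, keep_negc = TRUE)
    writeLibraryTsv(lib, file.path(out_dir, "library.tsv"))
    writeSpacerFasta(lib, file.path(out_dir, "spacers.fasta"))
    note("design: ", nrow(guideVariants(lib)), " guides for ",
         length(genes), " genes")

    # --- simulate + growth per environment ---
    env_names <- names(config$environments)
    dph <- vapply(config$environments, function(e)
        e$doublings_per_hour, numeric(1))
    truth <- simulateTruth(vapply(genes, `[[`, character(1), "gene_id"),
                           environments = dph, seed = seed + 1L,
                           floor_raw = tr$floor_raw,
                           escape_prob = tr$escape_prob,
                           depth = tr$depth,
                           replicate_jitter_sd = tr$replicate_jitter_sd)
    writeTsv(truth$params, file.path(out_dir, "truth_params.tsv"))
    sims <- list(); results <- list()
    for (ei in seq_along(env_names)) {
        env <- env_names[ei]
        sch <- config$environments[[env]]$schedule_hours
        sim <- simulateCounts(truth, lib, env, schedule_hours = sch,
                              seed = seed + 10L + ei)
        sims[[env]] <- sim
        writeCountTable(sim$counts,
                        file.path(out_dir, paste0("counts_", env, ".tsv")))
        writeTsv(sim$escapers,
                 file.path(out_dir, paste0("escapers_", env, ".tsv")))
        res <- estimateGrowth(sim$counts, reference = "auto",
                              doublings_per_hour = dph[[env]],
                              floor_raw = tr$floor_raw,
                              depth_floor = th$depth_floor,
                              r2_min = th$r2_min, exempt = th$exempt,
                              min_replicates = th$min_replicates)
        results[[env]] <- res
        writeTsv(res$estimates,
                 file.path(out_dir, paste0("estimates_", env, ".tsv")))
        writeTsv(res$fits,
                 file.path(out_dir, paste0("fits_", env, ".tsv")))
        writeTsv(res$removed,
                 file.path(out_dir, paste0("removed_", env, ".tsv")))
        note("growth[", env, "]: ", nrow(res$estimates),
             " guides estimated, reference = ", res$reference,
             ", ", nrow(res$removed), " replicate removals")
    }

    # --- resolvable steps (first environment) ---
    res1 <- results[[1]]
    steps <- strategyComparison(res1$estimates, res1$fits,
                                scopes = config$scopes %||% "compounding",
                                eligibility = th$eligibility,
                                gamma = th$gamma, alpha = th$alpha)
    writeTsv(steps, file.path(out_dir, "steps.tsv"))
    note("steps: ", nrow(steps), " gene x scope results")

    # --- gene-by-environment (needs two environments) ---
    gxe <- NULL
    if (length(env_names) >= 2L) {
        gxe <- gxeAnalysis(results[[1]], results[[2]],
                           eligibility = th$eligibility,
                           min_replicates = th$min_replicates,
                           min_points = th$min_points,
                           flat_tol = th$flat_tol,
                           gamma = th$gamma, alpha = th$alpha)
        writeTsv(gxe$fits, file.path(out_dir, "logistic_fits.tsv"))
        writeTsv(gxe$medians, file.path(out_dir, "logistic_medians.tsv"))
        writeTsv(gxe$calls, file.path(out_dir, "gxe_calls.tsv"))
        note("gxe: ", nrow(gxe$calls), " genes called, ",
             sum(gxe$calls$interaction_class == "titration_only"),
             " titration-only interactions")
    } else note("gxe: skipped, fewer than two environments")

    writeLines(logs, logf)
    invisible(list(library = lib, truth = truth, simulations = sims,
                   growth = results, steps = steps, gxe = gxe,
                   out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
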