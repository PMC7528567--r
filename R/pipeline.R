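.PIPELINE_STAGES <- c("qc", "ewas", "dmr", "enrichment", "mqtl",
                      "sensitivity", "candidates")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the requested stages in the fixed order qc, ewas, dmr,
#' enrichment, mqtl, sensitivity, candidates, writing every output table
#' as TSV plus a log of the package version, seed and thresholds.
#' Identical config and seed produce identical result files.
#'
#' Config entries (list or YAML path): \code{seed}; \code{stages};
#' either \code{synthetic} (\code{preset} "gambian"/"indian",
#' \code{n_probes}) or \code{inputs} (\code{methylation},
#' \code{covariates}, \code{annotation}, \code{genotypes},
#' \code{cpg_sets}); optional \code{ewas} (\code{exposure},
#' \code{covariates}, \code{n_pcs}, \code{fdr}), \code{dmr}
#' (\code{seed_p}, \code{max_gap}, \code{bandwidth}, \code{min_cpgs}),
#' \code{enrichment} (\code{B}, \code{p_thr}, \code{effect_thr}).
#'
#' @param config list or YAML file path.
#' @param out_dir output directory (created if absent).
#' @param seed overrides the config seed.
#' @return (invisibly) list of in-memory stage results.
#' @export
runPipeline <- function(config, out_dir, seed = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stages <- config$stages %||% .PIPELINE_STAGES
    unknown <- setdiff(stages, .PIPELINE_STAGES)
    if (length(unknown) > 0)
        stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
    stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
    seed <- seed %||% config$seed %||% 1L
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- c(sprintf("ewastrial %s",
                     as.character(utils::packageVersion("ewastrial"))),
             sprintf("seed: %d", as.integer(seed)),
             sprintf("stages: %s", paste(stages, collapse = ", ")))
    state <- list()

    if (!is.null(config$synthetic)) {
        preset <- config$synthetic$preset %||% "gambian"
        np <- config$synthetic$n_probes %||% 2000
        spec <- if (preset == "indian")
            indianCohortSpec(n_probes = np, seed = seed) else
            gambianCohortSpec(n_probes = np, seed = seed)
        sim <- simulateCohort(spec)
        state$methyl <- sim$methyl
        state$truth <- sim$truth
        if ("mqtl" %in% stages) {
            g <- simulateGenotypes(spec, sim, seed = seed + 1L)
            state$methyl <- g$methyl
            state$genotypes <- g$genotypes
            state$truth <- g$truth
        }
        writeResultsTsv(state$truth$probes,
                        file.path(out_dir, "truth_ledger.tsv"))
        log <- c(log, sprintf("synthetic: %s preset, %d probes, %d samples",
                              preset, np, ncol(state$methyl)))
    } else if (!is.null(config$inputs)) {
        inp <- config$inputs
        if (!is.null(inp$methylation)) {
            ann <- if (!is.null(inp$annotation))
                readAnnotation(inp$annotation) else NULL
            cov <- if (!is.null(inp$covariates))
                readCovariates(inp$covariates) else NULL
            state$methyl <- readMethylation(inp$methylation,
                                            annotation = ann,
                                            covariates = cov)
        }
        if (!is.null(inp$genotypes))
            state$genotypes <- readGenotypes(inp$genotypes)
        if (!is.null(inp$cpg_sets))
            state$cpg_sets <- lapply(inp$cpg_sets, readCpGSet)
    }

    needs_methyl <- intersect(stages, c("qc", "ewas", "dmr", "enrichment",
                                        "mqtl", "sensitivity"))
    if (length(needs_methyl) > 0 && is.null(state$methyl))
        stop("stage(s) ", paste(needs_methyl, collapse = ", "),
             " require methylation input")

    for (stage in stages) {
        state <- switch(stage,
            qc = .stage_qc(state, config, out_dir),
            ewas = .stage_ewas(state, config, out_dir),
            dmr = .stage_dmr(state, config, out_dir),
            enrichment = .stage_enrichment(state, config, out_dir, seed),
            mqtl = .stage_mqtl(state, config, out_dir),
            sensitivity = .stage_sensitivity(state, config, out_dir, seed),
            candidates = .stage_candidates(state, config, out_dir, seed))
        log <- c(log, sprintf("stage %s: done", stage))
    }
    writeLines(log, file.path(out_dir, "pipeline_log.txt"))
    invisible(state)
}

.ewas_design <- function(state, config) {
    cov <- covariates(state$methyl)
    cfg <- config$ewas %||% list()
    # cell fractions sum to 1: one type (Gran) is left out as reference
    adj <- cfg$covariates %||%
        intersect(c("sex", "age", "batch", "season",
                    "CD4T", "CD8T", "NK", "Bcell", "Mono"),
                  names(cov))
    designSpec(exposure = cfg$exposure %||% "arm",
               covariates = adj, n_pcs = cfg$n_pcs %||% 0)
}

.stage_qc <- function(state, config, out_dir) {
    sq <- filterSamples(state$methyl)
    pq <- filterProbes(sq$methyl)
    state$methyl <- pq$methyl
    report <- data.frame(
        id = c(sq$report$sample_id, pq$report$probe_id),
        type = c(rep("sample", nrow(sq$report)),
                 rep("probe", nrow(pq$report))),
        reason = c(sq$report$reason, pq$report$reason),
        stringsAsFactors = FALSE)
    writeResultsTsv(report, file.path(out_dir, "qc_report.tsv"))
    state
}

.stage_ewas <- function(state, config, out_dir) {
    des <- .ewas_design(state, config)
    tab <- fitSiteModels(state$methyl, des)
    rr <- rankAndReport(tab, (config$ewas %||% list())$fdr %||% 0.05)
    state$ewas <- rr$table
    state$dmps <- rr$dmps
    writeResultsTsv(rr$table, file.path(out_dir, "ewas_table.tsv"))
    writeResultsTsv(rr$dmps, file.path(out_dir, "dmps.tsv"))
    state
}

.stage_dmr <- function(state, config, out_dir) {
    if (is.null(state$ewas)) stop("dmr stage requires ewas results")
    cfg <- config$dmr %||% list()
    sites <- state$ewas[order(state$ewas$chrom, state$ewas$pos), ]
    sites <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        p = sites$p, t = sites$t,
                        effect = sites$estimate,
                        probe_id = sites$probe,
                        stringsAsFactors = FALSE)
    acf <- suppressWarnings(estimateAutocorrelation(sites))
    scan <- scanRegions(sites, acf, seed_p = cfg$seed_p %||% 0.05,
                        max_gap = cfg$max_gap %||% 500,
                        min_cpgs = cfg$min_cpgs %||% 3)
    kern <- kernelRegions(sites, bandwidth = cfg$bandwidth %||% 1000,
                          min_cpgs = cfg$min_cpgs %||% 3)
    cons <- consensusRegions(scan, kern)
    state$regions_scan <- scan
    state$regions_kernel <- kern
    writeResultsTsv(cons, file.path(out_dir, "regions.tsv"))
    writeResultsTsv(cons[cons$found_by_both, , drop = FALSE],
                    file.path(out_dir, "consensus.tsv"))
    state
}

.stage_enrichment <- function(state, config, out_dir, seed) {
    if (is.null(state$ewas)) stop("enrichment stage requires ewas results")
    cfg <- config$enrichment %||% list()
    sets <- state$cpg_sets
    if (is.null(sets) && !is.null(state$truth)) {
        tp <- state$truth$probes
        sets <- list(cpgSet("ME", tp$probe_id[tp$is_me]),
                     cpgSet("ICR", tp$probe_id[tp$is_icr]))
    }
    if (is.null(sets)) stop("enrichment stage requires CpG sets")
    des <- .ewas_design(state, config)
    vars <- apply(betas(state$methyl), 1L, stats::var)
    sub <- selectSubthreshold(state$ewas,
                              p_thr = cfg$p_thr %||% 0.05,
                              effect_thr = cfg$effect_thr %||% 0.02)
    rows <- list()
    for (i in seq_along(sets)) {
        s <- sets[[i]]
        res <- permutationEnrichment(state$methyl, des, s,
                                     B = cfg$B %||% 200,
                                     seed = seed + 100L + i)
        ctrl <- varianceMatch(s, rownames(state$methyl), vars)
        res_ctrl <- permutationEnrichment(state$methyl, des, ctrl,
                                          B = cfg$B %||% 200,
                                          seed = seed + 200L + i)
        rows[[i]] <- data.frame(
            set = s$name, set_size = s$size,
            n_subthreshold_total = length(sub),
            n_overlap = res$n_overlap, permutation_p = res$permutation_p,
            B = res$B, control_overlap = res_ctrl$n_overlap,
            control_p = res_ctrl$permutation_p, stringsAsFactors = FALSE)
    }
    state$enrichment <- do.call(rbind, rows)
    writeResultsTsv(state$enrichment,
                    file.path(out_dir, "enrichment.tsv"))
    state
}

.stage_mqtl <- function(state, config, out_dir) {
    if (is.null(state$genotypes)) stop("mqtl stage requires genotypes")
    qc <- genotypeQC(state$genotypes)
    targets <- if (!is.null(state$regions_scan) &&
                   length(state$regions_scan) > 0)
        unique(unlist(state$regions_scan$probe_ids)) else
        if (!is.null(state$truth))
            state$truth$probes$probe_id[!is.na(
                state$truth$probes$region_id)] else
        stop("mqtl stage requires region targets")
    pairs <- mqtlScreen(state$methyl, qc$genotypes, targets)
    gxe <- gxeScreen(state$methyl, qc$genotypes, targets)
    writeResultsTsv(pairs, file.path(out_dir, "mqtl_pairs.tsv"))
    writeResultsTsv(gxe, file.path(out_dir, "gxe_pairs.tsv"))
    top <- pairs[which.min(pairs$p), ]
    cmp <- modelCompare(betas(state$methyl)[top$probe, ],
                        dosages(qc$genotypes)[top$snp, ],
                        covariates(state$methyl)$arm)
    writeResultsTsv(cmp$models, file.path(out_dir, "model_compare.tsv"))
    state$mqtl <- pairs
    state
}

.stage_sensitivity <- function(state, config, out_dir, seed) {
    if (is.null(state$ewas)) stop("sensitivity stage requires ewas results")
    top <- state$ewas[which.min(state$ewas$p), ]
    cov <- covariates(state$methyl)
    rc <- balancedResampleCI(betas(state$methyl)[top$probe, ],
                             cov$arm, cov$sex,
                             n_resamples = (config$sensitivity %||%
                                            list())$n_resamples %||% 1000,
                             seed = seed + 300L)
    out <- data.frame(probe = top$probe, estimate = rc$estimate,
                      resample_mean = rc$resample_mean,
                      ci_lower = rc$ci_lower, ci_upper = rc$ci_upper,
                      n_resamples = rc$n_resamples)
    if ("season" %in% names(cov)) {
        des <- .ewas_design(state, config)
        des$covariates <- setdiff(des$covariates, "season")
        it <- interactionTest(state$methyl[top$probe, ], des, "season")
        out$season_interaction_p <- it$p[1L]
    }
    writeResultsTsv(out, file.path(out_dir, "sensitivity.tsv"))
    state$sensitivity <- out
    state
}

.stage_candidates <- function(state, config, out_dir, seed) {
    sim <- simulateCandidatePanel(seed = seed + 400L)
    qc <- pyroQC(sim$panel, sim$controls)
    res <- candidatesAnalysis(qc$panel, sim$covariates)
    writeResultsTsv(res$regions, file.path(out_dir, "candidates.tsv"))
    writeResultsTsv(res$sites, file.path(out_dir, "candidate_sites.tsv"))
    if (!is.null(qc$cv))
        writeResultsTsv(qc$cv, file.path(out_dir, "candidate_cv.tsv"))
    state$candidates <- res
    state
}
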