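# shared fixture builders; everything is generated in code

# minimal experiment: np probes x n samples, balanced two-arm cohort with
# a handful of covariates, betas near 0.5 unless a matrix is supplied
tiny_me <- function(np = 20, n = 40, betas = NULL, seed = 42) {
    set.seed(seed)
    if (is.null(betas))
        betas <- matrix(plogis(rnorm(np * n, 0, 0.5)), np, n)
    rownames(betas) <- sprintf("cg%05d", seq_len(np))
    colnames(betas) <- sprintf("S%03d", seq_len(n))
    ann <- data.frame(probe_id = rownames(betas), chrom = "chr1",
                      pos = seq_len(np) * 1000L)
    cov <- data.frame(
        sample_id = colnames(betas),
        arm = factor(rep(c("control", "intervention"), length.out = n),
                     levels = c("control", "intervention")),
        sex = factor(rep(c("F", "M"), each = n / 2)),
        age = runif(n, 8, 10))
    MethylationExperiment(betas, ann, cov)
}

# cohort spec with every nuisance component switched off except what the
# caller turns on; used for targeted construction oracles
quiet_spec <- function(n_probes = 50, noise_sd = 0, dmr_specs = list(),
                       n_true_dmps = 0, seed = 1, ...) {
    simulationSpec(n_probes = n_probes, n_true_dmps = n_true_dmps,
                   dmr_specs = dmr_specs, n_me_probes = 0,
                   n_icr_probes = 0, cell_sd = 0, batch_sd = 0,
                   noise_sd = noise_sd, detect_fail_rate = 0,
                   bead_fail_rate = 0, seed = seed, ...)
}

# small working cohort with noise but no structure beyond the arms
small_null_cohort <- function(n_probes = 300, seed = 1) {
    simulateCohort(quiet_spec(n_probes = n_probes, noise_sd = 0.2,
                              seed = seed))
}

default_design <- function() {
    designSpec("arm", c("sex", "age", "batch", "season",
                        "CD4T", "CD8T", "NK", "Bcell", "Mono"))
}

# brute-force BH step-up used as the independent oracle
bh_oracle <- function(p, m = length(p)) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    for (k in seq_len(n)) {
        vals <- vapply(k:n, function(j) p[o[j]] * m / j, numeric(1))
        q[o[k]] <- min(1, min(vals))
    }
    q
}
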