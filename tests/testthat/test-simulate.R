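test_that("simulation is deterministic given a seed", {
    s1 <- simulateCohort(quiet_spec(n_probes = 100, noise_sd = 0.2,
                                    seed = 5))
    s2 <- simulateCohort(quiet_spec(n_probes = 100, noise_sd = 0.2,
                                    seed = 5))
    expect_identical(betas(s1$methyl), betas(s2$methyl))
    expect_identical(s1$truth$probes, s2$truth$probes)
})

test_that("zero effects and zero noise give exactly equal group means", {
    sim <- simulateCohort(quiet_spec(n_probes = 60, noise_sd = 0,
                                     seed = 2))
    db <- deltaBeta(sim$methyl)
    expect_true(all(abs(db) < 1e-12))
})

test_that("an injected DMR effect is recovered in the group difference", {
    reps <- 25
    d_at_dmr <- vapply(seq_len(reps), function(r) {
        spec <- quiet_spec(
            n_probes = 120, noise_sd = 0.2, seed = 1000 + r,
            dmr_specs = list(list(n_cpgs = 10, effect = -0.03,
                                  spacing = 150)))
        sim <- simulateCohort(spec)
        tp <- sim$truth$probes
        mean(deltaBeta(sim$methyl)[tp$probe_id[tp$is_true_dmp]])
    }, numeric(1))
    se <- sd(d_at_dmr) / sqrt(reps)
    expect_lt(abs(mean(d_at_dmr) + 0.03), 3 * se + 0.002)
})

test_that("betas stay in range and the ledger resolves to probes", {
    sim <- simulateCohort(gambianCohortSpec(n_probes = 1500, seed = 9))
    b <- betas(sim$methyl)
    expect_true(all(b >= 0 & b <= 1))
    expect_true(all(sim$truth$probes$probe_id %in% rownames(b)))
    expect_equal(sum(sim$truth$probes$is_me), round(0.025 * 1500))
    reg <- sim$truth$regions
    expect_equal(reg$n_cpgs, c(10, 4))
    # inclusive span equals (n_cpgs - 1) * spacing + 1
    expect_equal(reg$end[1] - reg$start[1] + 1L, 9L * 150L + 1L)
})

test_that("hypervariable probes show higher interindividual variance", {
    sim <- simulateCohort(
        simulationSpec(n_probes = 600, n_me_probes = 100,
                       n_icr_probes = 100, cell_sd = 0, batch_sd = 0,
                       noise_sd = 0.2, seed = 4))
    v <- apply(betas(sim$methyl), 1, var)
    tp <- sim$truth$probes
    expect_gt(median(v[tp$is_me]), 5 * median(v[!tp$is_me & !tp$is_icr]))
    m <- rowMeans(betas(sim$methyl))[tp$is_icr]
    expect_true(all(abs(m - 0.5) < 0.15))
})

test_that("infeasible effect sizes are rejected", {
    spec <- quiet_spec(n_probes = 60, noise_sd = 0.2,
                       dmr_specs = list(list(n_cpgs = 5, effect = -1.5,
                                             spacing = 150)), seed = 1)
    expect_error(simulateCohort(spec), "infeasible")
})

test_that("genotypes follow Hardy-Weinberg at the stated MAF", {
    spec <- quiet_spec(
        n_probes = 60, noise_sd = 0.2, seed = 6,
        sex_imbalance = list(intervention = c(M = 250, F = 250),
                             control = c(M = 250, F = 250)),
        mqtl_specs = list(list(snp_id = "s1", targets = "cg0000001",
                               slope = 0.0, maf = 0.3)))
    sim <- simulateCohort(spec)
    g <- simulateGenotypes(spec, sim, n_null_snps = 0, seed = 7)
    d <- dosages(g$genotypes)["s1", ]
    n <- length(d)
    freq <- c(mean(d == 0), mean(d == 1), mean(d == 2))
    expected <- c(0.49, 0.42, 0.09)
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(freq - expected) < 4 * se))
})

test_that("mQTL slopes are recovered by regression on dosage", {
    spec <- quiet_spec(
        n_probes = 60, noise_sd = 0.2, seed = 8,
        mqtl_specs = list(list(snp_id = "s1", targets = "cg0000010",
                               slope = 0.03, maf = 0.3)))
    sim <- simulateCohort(spec)
    g <- simulateGenotypes(spec, sim, n_null_snps = 0, seed = 9)
    y <- betas(g$methyl)["cg0000010", ]
    d <- dosages(g$genotypes)["s1", ]
    fit <- summary(lm(y ~ d))
    expect_lt(abs(fit$coefficients["d", "Estimate"] - 0.03),
              3 * fit$coefficients["d", "Std. Error"])
    expect_error(simulateGenotypes(
        quiet_spec(n_probes = 10, seed = 1,
                   mqtl_specs = list(list(snp_id = "s1",
                                          targets = "cg0000001",
                                          slope = 0.03, maf = 0.7))),
        sim), "MAF")
})

test_that("genotype is independent of randomized arm assignment", {
    ps <- vapply(1:20, function(r) {
        spec <- quiet_spec(
            n_probes = 20, noise_sd = 0.2, seed = 100 + r,
            mqtl_specs = list(list(snp_id = "s1", targets = "cg0000001",
                                   slope = 0.03, maf = 0.3)))
        sim <- simulateCohort(spec)
        g <- simulateGenotypes(spec, sim, n_null_snps = 0,
                               seed = 200 + r)
        d <- dosages(g$genotypes)["s1", ]
        arm <- covariates(sim$methyl)$arm
        suppressWarnings(chisq.test(table(d, arm))$p.value)
    }, numeric(1))
    expect_gt(mean(ps), 0.2)        # no systematic association
    expect_lt(mean(ps < 0.05), 0.3)
})

test_that("candidate panel correlation structure matches its parameters", {
    sim <- simulateCandidatePanel(n_regions = 4, cpgs_per_region = 4,
                                  n_samples = 92, rho_within = 0,
                                  outlier_frac = 0, seed = 12)
    # rho_within = 0: inter-CpG correlations near zero
    w <- reshape(sim$panel[c("probe", "sample", "value")],
                 direction = "wide", idvar = "sample",
                 timevar = "probe")
    cm <- cor(as.matrix(w[, -1]))
    expect_lt(max(abs(cm[upper.tri(cm)])), 0.35)

    sim2 <- simulateCandidatePanel(n_regions = 2, cpgs_per_region = 4,
                                   n_samples = 92, outlier_frac = 0.03,
                                   seed = 13)
    out <- sim2$panel[sim2$panel$flag, ]
    expect_gt(nrow(out), 0)
    for (i in seq_len(nrow(out))) {
        v <- sim2$panel$value[sim2$panel$probe == out$probe[i]]
        med <- median(v)
        iqr <- unname(diff(quantile(v, c(0.25, 0.75), type = 7)))
        expect_gt(abs(out$value[i] - med), 3 * iqr)
    }
    expect_identical(
        simulateCandidatePanel(seed = 3)$panel,
        simulateCandidatePanel(seed = 3)$panel)
    expect_error(simulateCandidatePanel(cpgs_per_region = 1), ">= 2")
    expect_error(simulateCandidatePanel(rho_tech = 1.2), "correlation")
})

test_that("positive-control CV sits in the low-percent band", {
    sim <- simulateCandidatePanel(n_regions = 10, seed = 14,
                                  n_control_reps = 8)
    cv <- pyroQC(sim$panel, sim$controls)$cv
    expect_true(all(cv$cv_percent > 0.3 & cv$cv_percent < 10))
})
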