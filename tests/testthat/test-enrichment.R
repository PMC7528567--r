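test_that("subthreshold selection applies strict p and inclusive effect cuts", {
    ewas <- data.frame(probe = c("a", "b", "c", "d", "e"),
                       p = c(0.04, 0.04, 0.06, 0.05, 0.01),
                       delta_beta = c(-0.025, 0.01, 0.05, 0.02, 0.02))
    expect_setequal(selectSubthreshold(ewas), c("a", "e"))
    # boundary: |delta| exactly 0.02 is included, p exactly 0.05 is not
    expect_true("e" %in% selectSubthreshold(ewas))
    expect_false("d" %in% selectSubthreshold(ewas))
})

test_that("variance matching finds exact duplicates and near-optimal pairs", {
    v_t <- c(t1 = 0.5, t2 = 0.3, t3 = 0.1)
    v_pool <- c(p1 = 0.5, p2 = 0.3, p3 = 0.1, p4 = 0.9)
    ctrl <- varianceMatch(names(v_t), names(v_pool), c(v_t, v_pool))
    expect_setequal(ctrl$probe_ids, c("p1", "p2", "p3"))
    expect_equal(ctrl$size, 3L)

    # brute-force optimal assignment on a small instance
    set.seed(71)
    vt <- runif(5); names(vt) <- sprintf("t%d", 1:5)
    vp <- runif(8); names(vp) <- sprintf("p%d", 1:8)
    greedy <- varianceMatch(names(vt), names(vp), c(vt, vp))
    greedy_cost <- mean(abs(vt - vp[greedy$probe_ids]))
    all_perms <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in all_perms(v[-i]))
                out[[length(out) + 1]] <- c(v[i], rest)
        out
    }
    best <- Inf
    for (cm in combn(8, 5, simplify = FALSE))
        for (pp in all_perms(cm)) {
            cost <- mean(abs(vt - vp[pp]))
            if (cost < best) best <- cost
        }
    expect_lte(greedy_cost, best * 1.01 + 1e-12)
    expect_error(varianceMatch(names(vp), names(vt), c(vt, vp)),
                 "exhausted")
})

test_that("overlap counting equals set intersection", {
    expect_equal(overlapCount(c("a", "b"), c("c", "d")), 0L)
    expect_equal(overlapCount(letters[1:5], cpgSet("s", letters[1:10])),
                 5L)
    set.seed(72)
    for (r in 1:5) {
        a <- sample(sprintf("cg%03d", 1:100), 30)
        b <- sample(sprintf("cg%03d", 1:100), 40)
        expect_equal(overlapCount(a, b), sum(a %in% b))
    }
})

test_that("permutation enrichment is deterministic, bounded and powered", {
    spec <- quiet_spec(n_probes = 400, noise_sd = 0.2, seed = 73)
    sim <- simulateCohort(spec)
    me <- sim$methyl
    des <- default_design()
    set_ids <- rownames(me)[1:50]
    r1 <- suppressWarnings(permutationEnrichment(
        me, des, cpgSet("s", set_ids), B = 100, seed = 5))
    r2 <- suppressWarnings(permutationEnrichment(
        me, des, cpgSet("s", set_ids), B = 100, seed = 5))
    expect_identical(r1$permutation_p, r2$permutation_p)
    expect_gte(r1$permutation_p, 1 / 101)
    expect_lte(r1$permutation_p, 1)
    expect_error(permutationEnrichment(me, des, set_ids, B = 50),
                 "B must be")

    # effects concentrated in the set are detected
    spec2 <- quiet_spec(n_probes = 400, noise_sd = 0.2, seed = 74,
                        n_true_dmps = 40)
    sim2 <- simulateCohort(spec2)
    tp <- sim2$truth$probes
    target <- cpgSet("hit", c(tp$probe_id[tp$is_true_dmp],
                              tp$probe_id[!tp$is_true_dmp][1:60]))
    r_pow <- suppressWarnings(permutationEnrichment(
        sim2$methyl, des, target, B = 200, seed = 6))
    expect_lte(r_pow$permutation_p, 0.02)

    # variance-matched control of the enriched target stays null
    vars <- apply(betas(sim2$methyl), 1, var)
    ctrl <- varianceMatch(target, rownames(sim2$methyl), vars)
    r_ctrl <- suppressWarnings(permutationEnrichment(
        sim2$methyl, des, ctrl, B = 200, seed = 7))
    expect_gt(r_ctrl$permutation_p, 0.05)

    flat <- MethylationExperiment(
        matrix(0.5, 10, ncol(me),
               dimnames = list(sprintf("f%d", 1:10), colnames(me))),
        covariates = covariates(me))
    expect_error(permutationEnrichment(flat, des, set_ids, B = 100),
                 "degenerate|zero variance")
})

test_that("the residualized permutation fit equals a full OLS refit", {
    sim <- small_null_cohort(n_probes = 50, seed = 75)
    me <- sim$methyl
    Y <- betas(me)
    cov <- covariates(me)
    des <- default_design()
    d <- ewastrial:::.build_design(cov, des, Y = Y)
    fwl <- ewastrial:::.fwl_setup(Y, d$X, d$coef_col)
    set.seed(1)
    perm <- sample(ncol(me))
    arm01 <- as.numeric(cov$arm == "intervention")
    fast <- ewastrial:::.fwl_stats(fwl, d$X[perm, d$coef_col],
                                   arm01[perm])
    Xp <- d$X
    Xp[, d$coef_col] <- d$X[perm, d$coef_col]
    slow <- ewastrial:::.ols_matrix(Y, Xp, d$coef_col)
    expect_equal(unname(fast$estimate), unname(slow$estimate),
                 tolerance = 1e-10)
    expect_equal(unname(fast$se), unname(slow$se), tolerance = 1e-8)
    expect_equal(unname(fast$p), unname(slow$p), tolerance = 1e-8)
})
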