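# independent oracle: enumerate heterozygote counts with exact
# combinatorial probabilities expressed through choose()
hwe_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    na <- 2 * naa + nAa
    hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    counts <- vapply(hets, function(h) {
        aa <- (na - h) / 2
        choose(n, h) * choose(n - h, aa) * 2^h
    }, numeric(1))
    pr <- counts / sum(counts)
    sum(pr[pr <= pr[hets == nAa] * (1 + 1e-9)])
}

test_that("HWE exact test matches enumeration and its anchors", {
    expect_equal(hweExact(25, 50, 25), 1, tolerance = 1e-9)
    expect_equal(hweExact(100, 0, 0), 1)
    set.seed(81)
    for (r in 1:40) {
        n <- sample(3:50, 1)
        x <- as.vector(rmultinom(1, n, c(0.4, 0.4, 0.2)))
        expect_equal(hweExact(x[1], x[2], x[3]),
                     hwe_oracle(x[1], x[2], x[3]), tolerance = 1e-10)
    }
    # strongly out-of-equilibrium table is near zero
    expect_lt(hweExact(50, 0, 50), 1e-20)
})

test_that("genotype filters match a brute-force rule application", {
    set.seed(82)
    n_snp <- 60; n <- 200
    maf <- runif(n_snp, 0.01, 0.5)
    d <- matrix(rbinom(n_snp * n, 2, rep(maf, n)), n_snp, n,
                dimnames = list(sprintf("rs%03d", 1:n_snp),
                                sprintf("S%03d", 1:n)))
    # force some missingness patterns and one HWE-violating SNP
    d[1, 1:20] <- NA                 # 10% missing
    d[2, 1:10] <- NA                 # exactly 5% -> kept
    d[3, ] <- rep(c(0L, 2L), each = n / 2)  # no hets
    ge <- GenotypeExperiment(d, data.frame(
        snp_id = rownames(d), chrom = "chr1", pos = 1:n_snp * 100,
        ref = "A", alt = "G"))
    res <- genotypeQC(ge)
    af <- rowMeans(d, na.rm = TRUE) / 2
    manual_maf <- pmin(af, 1 - af)
    manual_miss <- rowMeans(is.na(d))
    manual_hwe <- vapply(seq_len(n_snp), function(i)
        hwe_oracle(sum(d[i, ] == 0, na.rm = TRUE),
                   sum(d[i, ] == 1, na.rm = TRUE),
                   sum(d[i, ] == 2, na.rm = TRUE)), numeric(1))
    drop <- manual_maf < 0.05 | manual_miss > 0.05 | manual_hwe < 0.001
    expect_setequal(rownames(dosages(res$genotypes)),
                    rownames(d)[!drop])
    expect_true("rs002" %in% rownames(dosages(res$genotypes)) ||
                manual_maf[2] < 0.05)
    expect_false("rs003" %in% rownames(dosages(res$genotypes)))
    # report is complete and order-independent by construction
    expect_equal(nrow(res$report), n_snp)
})

test_that("mQTL screen recovers an injected slope with the stated sign", {
    spec <- quiet_spec(
        n_probes = 80, noise_sd = 0.2, seed = 83,
        dmr_specs = list(list(n_cpgs = 5, effect = -0.03,
                              spacing = 150)),
        mqtl_specs = list(list(snp_id = "snp_dmr1", targets = "dmr1",
                               slope = 0.03, maf = 0.3)))
    sim <- simulateCohort(spec)
    g <- simulateGenotypes(spec, sim, n_null_snps = 10, seed = 84)
    targets <- g$truth$mqtl$probe_id
    res <- mqtlScreen(g$methyl, g$genotypes, targets)
    hit <- res[res$snp == "snp_dmr1", ]
    expect_true(all(abs(hit$slope - 0.03) < 3 * hit$se))
    expect_true(all(hit$slope > 0))
    # the causal SNP attains the pair-minimum p
    expect_equal(res$snp[which.min(res$p)], "snp_dmr1")

    # permuted genotypes: no signal
    g2 <- g$genotypes
    set.seed(99)
    perm <- sample(ncol(g2))
    d2 <- dosages(g2)[, perm]
    colnames(d2) <- colnames(dosages(g2))
    gr <- SummarizedExperiment::rowRanges(g2)
    ge_perm <- GenotypeExperiment(d2, data.frame(
        snp_id = names(gr), chrom = as.character(
            GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr), ref = gr$ref, alt = gr$alt))
    res_perm <- mqtlScreen(g$methyl, ge_perm, targets)
    expect_gt(min(res_perm$fdr), 0.05)
})

test_that("interaction screen is null without G-by-E structure", {
    spec <- quiet_spec(
        n_probes = 40, noise_sd = 0.2, seed = 85,
        dmr_specs = list(list(n_cpgs = 5, effect = -0.03,
                              spacing = 150)),
        mqtl_specs = list(list(snp_id = "snp_dmr1", targets = "dmr1",
                               slope = 0.03, maf = 0.3)))
    sim <- simulateCohort(spec)
    g <- simulateGenotypes(spec, sim, n_null_snps = 5, seed = 86)
    res <- gxeScreen(g$methyl, g$genotypes, g$truth$mqtl$probe_id)
    expect_gt(min(res$fdr), 0.05)
    expect_gt(mean(res$p), 0.25)
})

test_that("model comparison obeys nesting and picks the generating model", {
    set.seed(87)
    wins <- 0L
    for (r in 1:25) {
        n <- 289
        dos <- rbinom(n, 2, 0.3)
        arm <- rep(c("control", "intervention"), length.out = n)
        y <- 0.5 + 0.03 * dos - 0.03 * (arm == "intervention") +
            rnorm(n, 0, 0.04)
        cmp <- modelCompare(y, dos, arm)
        rss <- setNames(cmp$models$rss, cmp$models$model)
        expect_lte(rss[["GxE"]], rss[["G+E"]] + 1e-12)
        expect_lte(rss[["G+E"]], min(rss[["G"]], rss[["E"]]) + 1e-12)
        if (cmp$best_model == "G+E") wins <- wins + 1L
    }
    expect_gte(wins, 15L)

    # constant response: degenerate but error-free
    cmp0 <- modelCompare(rep(0.5, 60), rbinom(60, 2, 0.3),
                         rep(c("control", "intervention"), 30))
    expect_true(all(cmp0$models$adj_r2 == 0))
})
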