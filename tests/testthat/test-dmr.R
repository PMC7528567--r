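test_that("Stouffer-Liptak matches closed forms", {
    # independence: plain Stouffer
    p2 <- stoufferLiptak(c(0.05, 0.05))
    expect_equal(p2, pnorm(2 * qnorm(0.95) / sqrt(2),
                           lower.tail = FALSE), tolerance = 1e-12)
    expect_equal(round(p2, 4), 0.0100)
    # complete dependence leaves the evidence unchanged
    expect_equal(stoufferLiptak(c(0.05, 0.05),
                                matrix(1, 2, 2)), 0.05,
                 tolerance = 1e-10)
    # single p passes through
    expect_equal(stoufferLiptak(0.123), 0.123)
    # general identity-correlation case vs direct formula
    set.seed(51)
    for (k in c(3, 6)) {
        p <- runif(k)
        expect_equal(stoufferLiptak(p),
                     pnorm(sum(qnorm(1 - p)) / sqrt(k),
                           lower.tail = FALSE), tolerance = 1e-12)
    }
})

test_that("Stouffer-Liptak is monotone and repairs non-PSD inputs", {
    set.seed(52)
    C <- matrix(0.3, 4, 4); diag(C) <- 1
    p <- runif(4, 0.01, 0.9)
    base <- stoufferLiptak(p, C)
    for (i in 1:4) {
        p2 <- p; p2[i] <- p2[i] / 2
        expect_lte(stoufferLiptak(p2, C), base)
    }
    bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
    expect_message(stoufferLiptak(c(0.1, 0.2, 0.3), bad), "PSD")
    expect_message(stoufferLiptak(c(0, 0.5)), "clamped")
    expect_error(stoufferLiptak(c(0.1, 0.2),
                                matrix(c(1, 0.2, 0.5, 1), 2, 2)),
                 "symmetric")
})

test_that("signal autocorrelation is estimated by distance bin", {
    set.seed(53)
    # independent p at random positions: all bins near zero
    n <- 20000
    pos <- sort(sample.int(4e6, n))
    sites <- data.frame(chrom = "chr1", pos = pos, p = runif(n),
                        effect = rnorm(n))
    acf <- estimateAutocorrelation(sites, max_lag = 1000,
                                   bin_width = 200)
    expect_true(all(acf$cor[acf$n_pairs > 100] < 0.05))

    # duplicated p at zero distance: first bin correlation ~ 1
    sites2 <- data.frame(chrom = "chr1",
                         pos = rep(seq(1, 2e5, by = 2000), each = 2),
                         p = rep(runif(100), each = 2),
                         effect = rep(rnorm(100), each = 2))
    acf2 <- suppressWarnings(
        estimateAutocorrelation(sites2, max_lag = 1000, bin_width = 100))
    expect_gt(acf2$cor[1], 0.95)

    # AR(1) z at 100-bp spacing: first-bin estimate near rho
    rho <- 0.5
    z <- as.numeric(arima.sim(list(ar = rho), 20000))
    z <- z / sd(z)
    p <- 2 * pnorm(-abs(z))
    sites3 <- data.frame(chrom = "chr1", pos = seq_len(20000) * 100,
                         p = p, effect = sign(z))
    acf3 <- estimateAutocorrelation(sites3, max_lag = 500,
                                    bin_width = 100)
    expect_lt(abs(acf3$cor[1] - rho), 0.1)
    expect_error(estimateAutocorrelation(
        data.frame(chrom = "chr1", pos = c(5, 1), p = c(0.5, 0.5))),
        "sorted")
})

test_that("scan region caller seeds, clusters and adjusts as specified", {
    # flat p: no regions
    flat <- data.frame(chrom = "chr1", pos = seq_len(100) * 100,
                       p = rep(0.5, 100))
    expect_length(scanRegions(flat), 0)

    # a cluster of significant sites forms one contiguous region
    set.seed(54)
    pos <- c(seq(1000, 1900, by = 100), seq(50000, 59000, by = 1000))
    p <- c(rep(1e-6, 10), runif(10, 0.2, 1))
    sites <- data.frame(chrom = "chr1", pos = pos, p = p,
                        probe_id = sprintf("s%02d", seq_along(pos)),
                        effect = -1)
    gr <- scanRegions(sites, acf = NULL, max_gap = 500)
    expect_length(gr, 1)
    expect_equal(GenomicRanges::start(gr), 1000)
    expect_equal(GenomicRanges::end(gr), 1900)
    expect_equal(gr$n_cpgs, 10)
    # members contiguous in position order
    expect_identical(unlist(gr$probe_ids, use.names = FALSE),
                     sprintf("s%02d", 1:10))
    # Sidak-adjusted p is never smaller than the raw combined p
    expect_gte(gr$region_p_adj, gr$region_p_raw)
    expect_true(gr$direction_consistent)

    # region covering all scanned bases: adjustment changes nothing
    solo <- data.frame(chrom = "chr1", pos = seq(100, 1000, by = 100),
                       p = rep(1e-4, 10))
    gs <- scanRegions(solo, acf = NULL)
    expect_equal(gs$region_p_adj,
                 1 - (1 - gs$region_p_raw)^1, tolerance = 1e-12)
})

test_that("kernel region caller needs a minimum run of significant sites", {
    set.seed(55)
    pos <- seq_len(200) * 5000
    t_stats <- rnorm(200)
    t_stats[100] <- 12            # isolated strong site
    p <- 2 * pt(-abs(t_stats), df = 280)
    sites <- data.frame(chrom = "chr1", pos = pos, p = p, t = t_stats)
    expect_length(kernelRegions(sites, min_cpgs = 3), 0)
})

test_that("consensus join flags shared and private regions", {
    r1 <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(100, 5000),
                                                  c(500, 6000)))
    r1$n_cpgs <- c(5L, 4L); r1$min_p <- c(1e-8, 1e-5)
    r1$region_p_raw <- c(1e-10, 1e-6); r1$region_p_adj <- c(1e-8, 1e-4)
    r1$method <- "scan"
    r1$probe_ids <- IRanges::CharacterList(list(letters[1:5],
                                                letters[6:9]))
    r1$direction_consistent <- TRUE
    same <- consensusRegions(r1, r1)
    expect_true(all(same$found_by_both))
    r2 <- GenomicRanges::shift(r1, 10000)
    none <- consensusRegions(r1, r2)
    expect_false(any(none$found_by_both))
    expect_equal(sort(unique(same$method)), c("kernel", "scan"))
    # empty inputs are tolerated
    empty <- consensusRegions(r1[0], r2)
    expect_false(any(empty$found_by_both))
})

test_that("both callers recover an injected region on a simulated cohort", {
    spec <- quiet_spec(
        n_probes = 600, noise_sd = 0.2, seed = 57,
        dmr_specs = list(list(n_cpgs = 10, effect = -0.03,
                              spacing = 150)))
    sim <- simulateCohort(spec)
    tab <- fitSiteModels(sim$methyl, default_design())
    tab <- tab[order(tab$chrom, tab$pos), ]
    sites <- data.frame(chrom = tab$chrom, pos = tab$pos, p = tab$p,
                        t = tab$t, effect = tab$estimate,
                        probe_id = tab$probe)
    acf <- suppressWarnings(estimateAutocorrelation(sites))
    scan <- scanRegions(sites, acf)
    kern <- kernelRegions(sites)
    truth <- sim$truth$regions
    expect_gte(length(scan), 1)
    expect_gte(length(kern), 1)
    expect_setequal(unlist(scan$probe_ids[1], use.names = FALSE),
                    strsplit(truth$probe_ids[1], ",")[[1]])
    cons <- consensusRegions(scan, kern)
    expect_true(any(cons$found_by_both))
})
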