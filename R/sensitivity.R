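#' Balanced-resampling confidence interval for one CpG
#'
#' Robustness check against sex imbalance between arms: each resample
#' draws, without replacement, \code{min(n_M, n_F)} males and the same
#' number of females within each arm (so every resample is exactly
#' sex-balanced per arm), refits the EWAS model and records the
#' intervention coefficient; the CI is the 2.5th/97.5th percentile of the
#' resampled coefficients.
#'
#' @param y betas for one CpG.
#' @param arm arm labels per sample.
#' @param sex sex labels per sample ("M"/"F").
#' @param cov optional data.frame of adjustment covariates.
#' @param n_resamples number of balanced resamples.
#' @param seed RNG seed; fixed seed gives identical CIs.
#' @return list: estimate (full data), resample_mean, ci_lower,
#'   ci_upper, n_resamples.
#' @export
balancedResampleCI <- function(y, arm, sex, cov = NULL,
                               n_resamples = 10000, seed = NULL) {
    arm01 <- as.numeric(arm == "intervention")
    sexM <- sex == "M"
    for (a in c(0, 1))
        if (!any(sexM[arm01 == a]) || !any(!sexM[arm01 == a]))
            stop("a sex is absent in one arm")
    X <- cbind(`(Intercept)` = 1, arm = arm01)
    if (!is.null(cov))
        X <- cbind(X, stats::model.matrix(~ . - 1, data = cov))
    full <- .ols_row(y, X, 2L)
    groups <- split(seq_along(y), list(arm01, sexM))
    draws <- lapply(c("0", "1"), function(a) {
        nm <- length(groups[[paste0(a, ".TRUE")]])
        nf <- length(groups[[paste0(a, ".FALSE")]])
        min(nm, nf)
    })
    .with_seed(seed, {
        est <- vapply(seq_len(n_resamples), function(b) {
            idx <- unlist(lapply(c("0", "1"), function(a) {
                k <- draws[[match(a, c("0", "1"))]]
                c(sample(groups[[paste0(a, ".TRUE")]], k),
                  sample(groups[[paste0(a, ".FALSE")]], k))
            }))
            fit <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
            fit$coefficients[2L]
        }, numeric(1))
        ci <- stats::quantile(est, c(0.025, 0.975), names = FALSE)
        list(estimate = full$estimate, resample_mean = mean(est),
             ci_lower = ci[1L], ci_upper = ci[2L],
             n_resamples = n_resamples)
    })
}

#' Exposure-by-modifier interaction test per CpG
#'
#' Adds exposure-by-modifier interaction term(s) to the site model; for
#' modifiers with more than two levels a joint F-test of the interaction
#' terms is used, otherwise a two-sided t; BH across the tested CpGs.
#'
#' @param me a \linkS4class{MethylationExperiment} (optionally a probe
#'   subset).
#' @param design a \code{\link{designSpec}}; the modifier must not be the
#'   exposure.
#' @param modifier colData column interacting with the exposure.
#' @return data.frame: probe, interaction (single-df case), p, fdr.
#' @export
interactionTest <- function(me, design, modifier) {
    cov <- covariates(me)
    if (!modifier %in% names(cov)) stop("modifier not found")
    mv <- cov[[modifier]]
    if (length(unique(mv[!is.na(mv)])) < 2) stop("modifier is constant")
    Y <- betas(me)
    vars <- unique(c(design$exposure, design$covariates, modifier))
    base_f <- paste("~", paste(vars, collapse = " + "))
    X0 <- stats::model.matrix(stats::as.formula(base_f), data = cov)
    X1 <- stats::model.matrix(stats::as.formula(
        paste(base_f, "+", design$exposure, ":", modifier)), data = cov)
    if (qr(X1)$rank < ncol(X1)) stop("collinear modifier")
    n_int <- ncol(X1) - ncol(X0)
    rows <- lapply(seq_len(nrow(Y)), function(i) {
        y <- Y[i, ]
        ok <- !is.na(y)
        f0 <- stats::lm.fit(X0[ok, , drop = FALSE], y[ok])
        f1 <- stats::lm.fit(X1[ok, , drop = FALSE], y[ok])
        rss0 <- sum(f0$residuals^2)
        rss1 <- sum(f1$residuals^2)
        df2 <- sum(ok) - ncol(X1)
        Fst <- ((rss0 - rss1) / n_int) / (rss1 / df2)
        p <- stats::pf(Fst, n_int, df2, lower.tail = FALSE)
        est <- if (n_int == 1L) f1$coefficients[ncol(X1)] else NA_real_
        data.frame(probe = rownames(Y)[i], interaction = est, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhFdr(out$p)
    out
}

#' Per-stratum intervention effects with between-stratum z-test
#'
#' Fits the site model independently in each stratum and compares each
#' pair of strata with
#' \eqn{z = (b_1 - b_2) / \sqrt{SE_1^2 + SE_2^2}} (two-sided p).
#'
#' @param me a \linkS4class{MethylationExperiment} subset (one or few
#'   probes).
#' @param design a \code{\link{designSpec}}.
#' @param strata colData column defining the strata (each stratum needs
#'   at least \code{min_n} samples).
#' @param min_n minimum per-stratum size.
#' @return list with \code{estimates} (probe, stratum, estimate, se, n)
#'   and \code{differences} (probe, stratum_1, stratum_2, diff, z, p).
#' @export
stratifiedEffects <- function(me, design, strata, min_n = 20) {
    cov <- covariates(me)
    sv <- factor(cov[[strata]])
    tab <- table(sv)
    if (any(tab < min_n))
        stop("stratum too small: ",
             paste(names(tab)[tab < min_n], collapse = ", "))
    ests <- list(); diffs <- list()
    per <- lapply(levels(sv), function(lv) {
        sub <- me[, sv == lv]
        d <- .build_design(covariates(sub), design, Y = betas(sub))
        f <- .ols_matrix(betas(sub), d$X, d$coef_col)
        data.frame(probe = rownames(sub), stratum = lv,
                   estimate = f$estimate, se = f$se,
                   n = ncol(sub), stringsAsFactors = FALSE)
    })
    estimates <- do.call(rbind, per)
    lv <- levels(sv)
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
        if (j <= i) next
        a <- per[[i]]; b <- per[[j]]
        z <- (a$estimate - b$estimate) / sqrt(a$se^2 + b$se^2)
        diffs[[length(diffs) + 1L]] <- data.frame(
            probe = a$probe, stratum_1 = lv[i], stratum_2 = lv[j],
            diff = a$estimate - b$estimate, z = z,
            p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
    }
    list(estimates = estimates, differences = do.call(rbind, diffs))
}

#' Flag CpGs with SNPs near the probe sequence
#'
#' Flags a CpG when any supplied SNP lies within \code{window} bp of the
#' CpG position (inclusive, symmetric). The symmetric window approximates
#' the probe footprint when strand information is unavailable.
#'
#' @param annotation probe annotation data.frame (probe_id, chrom, pos)
#'   or a \linkS4class{MethylationExperiment}.
#' @param snp_positions data.frame with \code{chrom} and \code{pos}.
#' @param window half-window in bp (SNP at exactly \code{window} bp is
#'   flagged).
#' @return data.frame: probe_id, snp_in_probe (logical), n_snps.
#' @export
snpInProbeFlags <- function(annotation, snp_positions, window = 50) {
    ann <- if (is(annotation, "MethylationExperiment"))
        probeAnnotation(annotation) else annotation
    probes <- GRanges(ann$chrom,
                      IRanges(pmax(1L, ann$pos - window),
                              ann$pos + window))
    snps <- GRanges(snp_positions$chrom,
                    IRanges(snp_positions$pos, width = 1L))
    hits <- GenomicRanges::countOverlaps(probes, snps)
    data.frame(probe_id = ann$probe_id, snp_in_probe = hits > 0,
               n_snps = hits, stringsAsFactors = FALSE)
}
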