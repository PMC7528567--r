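#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: the p-value sums the probabilities of all
#' heterozygote counts (given the allele counts) that are as or less
#' likely than the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value.
#' @export
hweExact <- function(n_AA, n_Aa, n_aa) {
    stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
    n <- n_AA + n_Aa + n_aa
    if (n < 1) stop("at least one genotype required")
    n_a <- 2 * n_aa + n_Aa          # minor-ish allele count as given
    # possible heterozygote counts share parity with the allele count
    hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
    logp <- vapply(hets, function(h) {
        aa <- (n_a - h) / 2
        AA <- n - h - aa
        lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
            h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) -
            lgamma(2 * n + 1)
    }, numeric(1))
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    obs <- pr[hets == n_Aa]
    min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Genotype QC filtering
#'
#' Drops SNPs with exact HWE p below \code{hwe_p}, minor allele frequency
#' below \code{maf_min}, or missingness above \code{miss_max}; boundary
#' values (exactly 5\% MAF or missingness) are kept.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param hwe_p,maf_min,miss_max thresholds.
#' @return list with filtered \code{genotypes} and a \code{report}
#'   data.frame (snp_id, maf, missingness, hwe_p, excluded, reason).
#' @export
genotypeQC <- function(ge, hwe_p = 0.001, maf_min = 0.05,
                       miss_max = 0.05) {
    d <- dosages(ge)
    miss <- rowMeans(is.na(d))
    af <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    hwe <- vapply(seq_len(nrow(d)), function(i) {
        x <- d[i, ]
        hweExact(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                 sum(x == 2, na.rm = TRUE))
    }, numeric(1))
    reason <- rep(NA_character_, nrow(d))
    reason[maf < maf_min] <- "maf"
    reason[is.na(reason) & miss > miss_max] <- "missingness"
    reason[is.na(reason) & hwe < hwe_p] <- "hwe"
    report <- data.frame(snp_id = rownames(d), maf = maf,
                         missingness = miss, hwe_p = hwe,
                         excluded = !is.na(reason), reason = reason,
                         stringsAsFactors = FALSE)
    list(genotypes = ge[is.na(reason), ], report = report)
}

.pair_design <- function(cov, adjust) {
    adjust <- intersect(adjust, names(cov))
    if (length(adjust) == 0) return(matrix(1, nrow(cov), 1,
        dimnames = list(NULL, "(Intercept)")))
    stats::model.matrix(stats::as.formula(
        paste("~", paste(adjust, collapse = " + "))), data = cov)
}

#' mQTL screen at target CpGs
#'
#' Per (CpG, SNP) pair: OLS of beta on dosage plus arm and adjustment
#' covariates, complete cases per pair; BH-FDR across all pairs. Positive
#' slopes mean each alt allele increases methylation.
#'
#' @param me a \linkS4class{MethylationExperiment}.
#' @param ge a (QC'd) \linkS4class{GenotypeExperiment}.
#' @param targets probe ids tested (typically region-member CpGs).
#' @param adjust colData columns used for adjustment.
#' @return data.frame: probe, snp, slope, se, t, p, fdr, n.
#' @export
mqtlScreen <- function(me, ge, targets,
                       adjust = c("arm", "sex", "age", "batch")) {
    .pair_screen(me, ge, targets, adjust, interaction = FALSE)
}

#' Genotype-by-intervention interaction screen
#'
#' Adds a dosage-by-arm interaction to the mQTL model; the reported test
#' is the two-sided t on the interaction coefficient with BH across
#' pairs.
#'
#' @inheritParams mqtlScreen
#' @return data.frame: probe, snp, interaction, se, t, p, fdr, n.
#' @export
gxeScreen <- function(me, ge, targets,
                      adjust = c("sex", "age", "batch")) {
    .pair_screen(me, ge, targets, adjust, interaction = TRUE)
}

.pair_screen <- function(me, ge, targets, adjust, interaction) {
    stopifnot(all(targets %in% rownames(me)))
    common <- intersect(colnames(me), colnames(ge))
    if (length(common) == 0) stop("no shared samples")
    Y <- betas(me)[targets, common, drop = FALSE]
    D <- dosages(ge)[, common, drop = FALSE]
    cov <- covariates(me)[common, , drop = FALSE]
    arm01 <- as.numeric(cov$arm == "intervention")
    Xbase <- .pair_design(cov, adjust)
    if (interaction) Xbase <- cbind(Xbase, arm = arm01)
    rows <- vector("list", length(targets) * nrow(D))
    ri <- 0L
    for (s in seq_len(nrow(D))) {
        dos <- D[s, ]
        ok <- !is.na(dos)
        X <- cbind(Xbase[ok, , drop = FALSE], dosage = dos[ok])
        cc <- if (interaction) {
            X <- cbind(X, gxe = dos[ok] * arm01[ok])
            ncol(X)
        } else ncol(X)
        Yok <- Y[, ok, drop = FALSE]
        for (t_i in seq_along(targets)) {
            y <- Yok[t_i, ]
            f <- if (anyNA(y)) .ols_row(y, X, cc) else
                .ols_matrix(matrix(y, 1L), X, cc)
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
                probe = targets[t_i], snp = rownames(D)[s],
                estimate = f$estimate, se = f$se, t = f$t, p = f$p,
                n = sum(ok & !is.na(y)), stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    names(out)[names(out) == "estimate"] <-
        if (interaction) "interaction" else "slope"
    out$fdr <- bhFdr(out$p)
    out
}

#' Compare G, E, G+E and GxE models for one CpG
#'
#' Fits the four nested models (all with the same adjustment covariates):
#' genotype only, intervention only, both main effects, and both plus
#' interaction. Reports coefficients, adjusted R-squared and
#' \eqn{AIC = n \ln(RSS/n) + 2k} (constant omitted; comparisons depend
#' only on consistency); the best model minimises AIC.
#'
#' @param y methylation values for one CpG.
#' @param dosage additive allelic dosage per sample.
#' @param arm arm factor/labels per sample.
#' @param cov optional data.frame of adjustment covariates.
#' @return list with \code{models} (model, aic, adj_r2, and coefficient
#'   columns) and \code{best_model}.
#' @export
modelCompare <- function(y, dosage, arm, cov = NULL) {
    arm01 <- as.numeric(arm == "intervention")
    base <- data.frame(y = y, G = dosage, E = arm01)
    if (!is.null(cov)) base <- cbind(base, cov)
    base <- base[stats::complete.cases(base), , drop = FALSE]
    adj <- if (is.null(cov)) "" else
        paste("+", paste(names(cov), collapse = " + "))
    forms <- list(G = paste("y ~ G", adj),
                  E = paste("y ~ E", adj),
                  `G+E` = paste("y ~ G + E", adj),
                  `GxE` = paste("y ~ G * E", adj))
    n <- nrow(base)
    rows <- lapply(names(forms), function(nm) {
        fit <- stats::lm(stats::as.formula(forms[[nm]]), data = base)
        rss <- sum(stats::residuals(fit)^2)
        k <- length(stats::coef(fit))
        tss <- sum((base$y - mean(base$y))^2)
        adj_r2 <- if (tss == 0) 0 else
            1 - (rss / (n - k)) / (tss / (n - 1))
        aic <- if (rss == 0) -Inf else n * log(rss / n) + 2 * k
        cf <- stats::coef(fit)
        data.frame(model = nm, aic = aic, adj_r2 = adj_r2,
                   coef_G = if ("G" %in% names(cf)) cf[["G"]] else NA,
                   coef_E = if ("E" %in% names(cf)) cf[["E"]] else NA,
                   coef_GxE = if ("G:E" %in% names(cf)) cf[["G:E"]] else NA,
                   rss = rss, stringsAsFactors = FALSE)
    })
    models <- do.call(rbind, rows)
    list(models = models,
         best_model = models$model[which.min(models$aic)])
}
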