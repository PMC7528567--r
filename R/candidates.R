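#' Huber robust regression for one CpG
#'
#' M-estimation by iteratively reweighted least squares (Huber psi,
#' tuning constant \code{c} = 1.345, MAD scale with consistency factor
#' 1.4826), as implemented by \code{MASS::rlm}; two-sided p from the
#' asymptotic normal on the robust SE.
#'
#' @param y numeric response (methylation values).
#' @param X design matrix (with intercept column) or data.frame of
#'   covariates to be expanded via \code{model.matrix}.
#' @param coef name or index of the coefficient of interest (default the
#'   first post-intercept column).
#' @param c_huber Huber tuning constant.
#' @param maxit,acc IRLS iteration cap and convergence tolerance.
#' @return list: estimate, se, z, p for the tracked coefficient, the full
#'   coefficient table, and a \code{converged} flag.
#' @export
robustFit <- function(y, X, coef = 2L, c_huber = 1.345, maxit = 50,
                      acc = 1e-8) {
    if (is.data.frame(X))
        X <- stats::model.matrix(~ ., data = X)
    ok <- stats::complete.cases(y, X)
    y <- y[ok]; X <- X[ok, , drop = FALSE]
    if (length(y) <= ncol(X) + 5)
        stop("too few observations for robust fit")
    fit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = c_huber,
                     scale.est = "MAD", maxit = maxit, acc = acc)
    if (!fit$converged)
        warning("robust fit did not converge in ", maxit, " iterations")
    sm <- summary(fit)$coefficients
    est <- sm[, "Value"]
    se <- sm[, "Std. Error"]
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    ci <- if (is.character(coef)) match(coef, rownames(sm)) else coef
    list(estimate = est[ci], se = se[ci], z = z[ci], p = p[ci],
         coefficients = data.frame(term = rownames(sm), estimate = est,
                                   se = se, z = z, p = p,
                                   row.names = NULL),
         converged = fit$converged)
}

#' Empirical Brown's method for correlated p-values
#'
#' Fisher-style combination of dependent p-values calibrated by
#' covariances estimated from the underlying data. Each data row is
#' standardized across samples and transformed to
#' \eqn{w = -2 \log} of its right-tail empirical CDF value (with an
#' \eqn{n + 1} denominator); the Fisher statistic
#' \eqn{X = \sum -2 \ln p_i} is referred to a scaled chi-square with
#' \eqn{f = \mathrm{var} / (2\,\mathrm{mean})},
#' \eqn{\mathrm{df} = 2\,\mathrm{mean}^2 / \mathrm{var}}, where
#' mean \eqn{= 2k} and var \eqn{= 4k + 2\sum_{i<j} \mathrm{cov}(w_i, w_j)}.
#' The variance is floored at \eqn{4k} (reducing to Fisher) if the
#' empirical covariance sum is negative.
#'
#' @param p p-values from tests on the rows of \code{data_matrix}.
#' @param data_matrix member-CpG methylation, rows matching \code{p},
#'   columns = samples.
#' @return list: p (combined), df, scale, fisher_p.
#' @export
empiricalBrown <- function(p, data_matrix) {
    k <- length(p)
    if (k == 1L) return(list(p = p, df = 2, scale = 1,
                             fisher_p = p))
    data_matrix <- as.matrix(data_matrix)
    stopifnot(nrow(data_matrix) == k)
    n <- ncol(data_matrix)
    s <- t(scale(t(data_matrix)))
    w <- t(apply(s, 1L, function(x) {
        r <- rank(-x, ties.method = "max")   # right-tail ecdf
        -2 * log(r / (n + 1))
    }))
    cw <- stats::cov(t(w))
    cov_sum <- sum(cw[upper.tri(cw)])
    mean_x <- 2 * k
    var_x <- 4 * k + 2 * cov_sum
    if (var_x <= 0) {
        warning("estimated variance non-positive; floored at 4k ",
                "(reduces to Fisher)")
        var_x <- 4 * k
    }
    f <- var_x / (2 * mean_x)
    df <- 2 * mean_x^2 / var_x
    X <- sum(-2 * log(.clamp_p(p)))
    fisher_p <- stats::pchisq(X, df = 2 * k, lower.tail = FALSE)
    list(p = stats::pchisq(X / f, df = df, lower.tail = FALSE),
         df = df, scale = f, fisher_p = fisher_p)
}

#' Candidate-locus analysis
#'
#' Per-CpG Huber robust regression of methylation on intervention status
#' with the panel covariates (plate, age, sex, cell counts, season where
#' present), region-level combination of the per-CpG p-values by
#' \code{\link{empiricalBrown}}, and BH-FDR across the candidate regions.
#' Single-CpG regions pass their robust-fit p through unchanged.
#'
#' @param panel QC'd long panel data.frame: region, probe, sample, value.
#' @param covariates per-sample covariate data.frame (rownames = sample
#'   ids) with an \code{arm} column.
#' @param adjust covariate columns used for adjustment (those present are
#'   used; missing ones are skipped).
#' @return list with \code{regions} (region, n_cpgs, brown_p, fdr) and
#'   \code{sites} (per-CpG robust-fit rows).
#' @export
candidatesAnalysis <- function(panel, covariates,
                               adjust = c("plate", "age", "sex",
                                          "cell_gran", "season")) {
    adjust <- intersect(adjust, names(covariates))
    site_rows <- list()
    region_rows <- list()
    for (rg in unique(panel$region)) {
        sub <- panel[panel$region == rg, , drop = FALSE]
        probes <- unique(sub$probe)
        pvec <- c()
        mat <- NULL
        kept <- character(0)
        for (pr in probes) {
            d <- sub[sub$probe == pr, , drop = FALSE]
            cv <- covariates[d$sample, , drop = FALSE]
            Xdf <- cbind(arm = as.numeric(cv$arm == "intervention"),
                         cv[, adjust, drop = FALSE])
            fit <- tryCatch(robustFit(d$value, Xdf, coef = "arm"),
                            error = function(e) NULL)
            if (is.null(fit)) next
            kept <- c(kept, pr)
            pvec <- c(pvec, fit$p)
            v <- d$value[match(rownames(covariates), d$sample)]
            mat <- rbind(mat, v)
            site_rows[[length(site_rows) + 1L]] <- data.frame(
                region = rg, probe = pr, estimate = fit$estimate,
                se = fit$se, p = fit$p, converged = fit$converged,
                stringsAsFactors = FALSE)
        }
        if (length(kept) == 0) {
            warning("region '", rg, "' dropped: all CpGs failed QC/fit")
            next
        }
        mat_cc <- mat[, colSums(is.na(mat)) == 0, drop = FALSE]
        bp <- if (length(kept) == 1L) pvec[1L] else
            empiricalBrown(pvec, mat_cc)$p
        region_rows[[length(region_rows) + 1L]] <- data.frame(
            region = rg, n_cpgs = length(kept), brown_p = bp,
            stringsAsFactors = FALSE)
    }
    regions <- do.call(rbind, region_rows)
    regions$fdr <- bhFdr(regions$brown_p)
    list(regions = regions, sites = do.call(rbind, site_rows))
}

#' Spearman rank concordance of paired measurements
#'
#' Rank correlation with average ranks for ties; p by the t
#' approximation. Used for platform (technical) and cross-tissue
#' replicate agreement.
#'
#' @param x,y paired numeric vectors.
#' @return list: rho, p, n (complete pairs).
#' @export
concordance <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 10) stop("fewer than 10 complete pairs")
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        stop("constant vector")
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
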