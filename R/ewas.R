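#' Specify an EWAS design
#'
#' @param exposure colData column tested (binary arm or continuous, e.g.
#'   maternal BMI).
#' @param covariates character vector of adjustment colData columns; must
#'   not contain the exposure.
#' @param n_pcs number of principal components of the beta matrix added as
#'   derived covariates.
#' @param moderate shrink residual variances toward a common prior
#'   (empirical-Bayes moderation via \code{limma::squeezeVar}); off by
#'   default -- plain OLS t-tests.
#' @param logit analyse logit-transformed betas (M-value-like scale)
#'   instead of raw betas; off by default.
#' @return object of class \code{DesignSpec}.
#' @export
designSpec <- function(exposure, covariates = character(), n_pcs = 0,
                       moderate = FALSE, logit = FALSE) {
    if (exposure %in% covariates)
        stop("exposure must not be among the adjustment covariates")
    structure(list(exposure = exposure, covariates = covariates,
                   n_pcs = n_pcs, moderate = moderate, logit = logit),
              class = "DesignSpec")
}

# model matrix with the exposure as the first post-intercept term;
# returns the matrix and the tracked exposure column index
.build_design <- function(cov, design, Y = NULL) {
    vars <- c(design$exposure, design$covariates)
    for (v in vars) if (!v %in% names(cov))
        stop("covariate '", v, "' not found")
    fml <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
    X <- stats::model.matrix(fml, data = cov)
    if (nrow(X) < nrow(cov))
        stop("missing values in design covariates are not supported")
    if (design$n_pcs > 0) {
        if (is.null(Y)) stop("beta matrix required for PC covariates")
        pc <- stats::prcomp(t(Y), center = TRUE, scale. = FALSE,
                            rank. = design$n_pcs)
        X <- cbind(X, pc$x[, seq_len(design$n_pcs), drop = FALSE])
    }
    asn <- attr(X, "assign")
    expos_cols <- which(asn == 1L)
    if (length(expos_cols) != 1L)
        stop("exposure must be binary or continuous (single coefficient)")
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
    list(X = X, coef_col = expos_cols)
}

#' Per-CpG linear-model EWAS
#'
#' Ordinary least squares of methylation on the exposure plus adjustment
#' covariates, fitted independently at every CpG; two-sided t-test on the
#' exposure coefficient; Benjamini-Hochberg FDR across probes; probes with
#' missing betas are fitted on their complete cases.
#'
#' @param me a \linkS4class{MethylationExperiment}.
#' @param design a \code{\link{designSpec}}.
#' @return EWAS table: probe, chrom, pos, gene, estimate, se, t, df, p,
#'   fdr, delta_beta, rank (ascending p).
#' @export
fitSiteModels <- function(me, design) {
    Y <- betas(me)
    cov <- covariates(me)
    if (design$logit) Y <- stats::qlogis(.clamp01(Y, tol = 1e-6))
    d <- .build_design(cov, design, Y = Y)
    X <- d$X
    if (nrow(X) - ncol(X) < 10)
        stop("fewer than 10 residual degrees of freedom")
    has_na <- rowSums(is.na(Y)) > 0
    if (all(has_na & rowSums(!is.na(Y)) == 0))
        stop("all-missing CpGs")
    res <- list(estimate = numeric(nrow(Y)), se = numeric(nrow(Y)),
                t = numeric(nrow(Y)), df = numeric(nrow(Y)),
                s2 = numeric(nrow(Y)), p = numeric(nrow(Y)))
    if (any(!has_na)) {
        f <- .ols_matrix(Y[!has_na, , drop = FALSE], X, d$coef_col)
        for (nm in names(res)) res[[nm]][!has_na] <- f[[nm]]
    }
    for (i in which(has_na)) {
        f <- .ols_row(Y[i, ], X, d$coef_col)
        for (nm in names(res)) res[[nm]][i] <- f[[nm]]
    }
    if (design$moderate) {
        ok <- !is.na(res$s2)
        sq <- limma::squeezeVar(res$s2[ok], res$df[ok])
        se_mod <- res$se
        se_mod[ok] <- res$se[ok] * sqrt(sq$var.post / res$s2[ok])
        t_mod <- res$estimate / se_mod
        df_mod <- res$df + sq$df.prior
        res$se <- se_mod
        res$t <- t_mod
        res$p <- 2 * stats::pt(-abs(t_mod), df_mod)
        res$df <- df_mod
    }
    ann <- probeAnnotation(me)
    db <- if ("arm" %in% names(cov)) deltaBeta(me) else
        rep(NA_real_, nrow(Y))
    tab <- data.frame(probe = rownames(Y), chrom = ann$chrom,
                      pos = ann$pos, gene = ann$gene,
                      estimate = res$estimate, se = res$se, t = res$t,
                      df = res$df, p = res$p, stringsAsFactors = FALSE)
    tab$fdr <- bhFdr(tab$p)
    tab$delta_beta <- db
    tab$rank <- rank(tab$p, ties.method = "first")
    rownames(tab) <- NULL
    tab
}

#' Unadjusted per-CpG mean beta difference
#'
#' Mean(intervention) minus mean(control); negative values indicate lower
#' methylation in the intervention arm.
#'
#' @param me a \linkS4class{MethylationExperiment} with an \code{arm}
#'   covariate, or a beta matrix (then pass \code{arm}).
#' @param arm optional factor/character of arm labels per sample.
#' @return named numeric vector of delta beta per probe.
#' @export
deltaBeta <- function(me, arm = NULL) {
    Y <- if (is(me, "MethylationExperiment")) betas(me) else as.matrix(me)
    if (is.null(arm)) arm <- covariates(me)$arm
    iv <- arm == "intervention"
    if (!any(iv) || !any(!iv)) stop("both arms must be non-empty")
    rowMeans(Y[, iv, drop = FALSE], na.rm = TRUE) -
        rowMeans(Y[, !iv, drop = FALSE], na.rm = TRUE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' \eqn{q_{(k)} = \min_{j \ge k} p_{(j)} m / j}, capped at 1, with ties
#' broken by stable order. \code{m_total} supports adjusting a printed
#' top list against the full test count of the original screen (e.g. a
#' table of top-ranked probes from an 800k-probe array).
#'
#' @param p numeric p-values in \eqn{[0,1]}.
#' @param m_total total number of tests (defaults to \code{length(p)};
#'   must be at least that).
#' @return adjusted values in the input order.
#' @export
bhFdr <- function(p, m_total = length(p)) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
    n <- length(p)
    if (m_total < n) stop("m_total must be >= length(p)")
    ok <- !is.na(p)
    q <- rep(NA_real_, n)
    pn <- p[ok]
    k <- length(pn)
    o <- order(pn, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m_total / (k:1) * pn[o]))[ro]
    q
}

#' Rank probes and extract DMPs
#'
#' @param ewas an EWAS table from \code{\link{fitSiteModels}}.
#' @param fdr_threshold FDR cut for calling DMPs.
#' @return list with \code{table} (ranked, with a \code{neg_log10_p}
#'   volcano column) and \code{dmps} (rows with fdr < threshold).
#' @export
rankAndReport <- function(ewas, fdr_threshold = 0.05) {
    tab <- ewas[order(ewas$p), , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    tab$neg_log10_p <- -log10(.clamp_p(tab$p))
    list(table = tab,
         dmps = tab[!is.na(tab$fdr) & tab$fdr < fdr_threshold, ,
                    drop = FALSE])
}
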