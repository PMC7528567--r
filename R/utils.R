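## internal helpers shared across modules

# Run code with a temporary RNG state; restores the caller's stream so that
# explicit `seed` arguments do not perturb global reproducibility.
.with_seed <- function(seed, code) {
    if (is.null(seed)) return(code)
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit({
        if (had) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(seed)
    code
}

.clamp01 <- function(x, tol = 1e-12) {
    x[x < tol] <- tol
    x[x > 1 - tol] <- 1 - tol
    x
}

.clamp_p <- function(p, floor = 1e-300) {
    p[p < floor] <- floor
    p[p > 1] <- 1
    p
}

# Ordinary least squares of every row of Y on design X, vectorised.
# Returns estimates/SE/t/p for one tracked column of X. Rows of Y must be
# complete (no NA); callers route NA-containing rows through .ols_row().
.ols_matrix <- function(Y, X, coef_col) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
    XtXinv <- chol2inv(qr.R(qx))
    n <- ncol(Y)
    k <- ncol(X)
    df <- n - k
    B <- Y %*% X                       # p x k cross-products
    C <- B %*% XtXinv                  # coefficients
    rss <- rowSums(Y * Y) - rowSums(C * B)
    rss[rss < 0] <- 0
    s2 <- rss / df
    se <- sqrt(s2 * XtXinv[coef_col, coef_col])
    est <- C[, coef_col]
    tt <- est / se
    list(estimate = est, se = se, t = tt, df = df, s2 = s2,
         p = 2 * stats::pt(-abs(tt), df))
}

.ols_row <- function(y, X, coef_col) {
    ok <- !is.na(y)
    if (sum(ok) <= ncol(X))
        return(list(estimate = NA_real_, se = NA_real_, t = NA_real_,
                    df = NA_real_, s2 = NA_real_, p = NA_real_))
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    df <- sum(ok) - fit$rank
    s2 <- sum(fit$residuals^2) / df
    R <- qr.R(fit$qr)
    XtXinv <- chol2inv(R)
    se <- sqrt(s2 * XtXinv[coef_col, coef_col])
    est <- fit$coefficients[coef_col]
    tt <- est / se
    list(estimate = est, se = se, t = tt, df = df, s2 = s2,
         p = 2 * stats::pt(-abs(tt), df))
}

# type-7 interquartile range, stated explicitly because QC rules depend on it
.iqr7 <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7,
                         names = FALSE)
    q[2] - q[1]
}

.stop_if_not_sorted <- function(chrom, pos) {
    for (ch in unique(chrom)) {
        p <- pos[chrom == ch]
        if (is.unsorted(p)) stop("sites must be position-sorted within ",
                                 "chromosome '", ch, "'")
    }
    invisible(TRUE)
}
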