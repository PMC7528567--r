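#' Select subthreshold intervention signals
#'
#' CpGs at nominal \code{p < p_thr} (strict) with an absolute beta
#' difference of at least \code{effect_thr} (inclusive).
#'
#' @param ewas EWAS table with \code{p} and \code{delta_beta} columns.
#' @param p_thr nominal p threshold (strict).
#' @param effect_thr absolute delta-beta threshold (inclusive).
#' @return character vector of probe ids.
#' @export
selectSubthreshold <- function(ewas, p_thr = 0.05, effect_thr = 0.02) {
    sel <- !is.na(ewas$p) & ewas$p < p_thr &
        !is.na(ewas$delta_beta) & abs(ewas$delta_beta) >= effect_thr
    ewas$probe[sel]
}

#' Variance-matched control CpG set
#'
#' Greedy nearest-variance 1:1 matching without replacement, processing
#' target CpGs in descending variance; the control set is disjoint from
#' the target set and of equal size.
#'
#' @param target_set a \code{\link{cpgSet}} or character vector of probe
#'   ids.
#' @param pool character vector of all candidate probe ids.
#' @param variances named per-CpG beta variances covering target and pool.
#' @return a \code{CpGSet} of matched controls.
#' @export
varianceMatch <- function(target_set, pool, variances) {
    targets <- if (inherits(target_set, "CpGSet")) target_set$probe_ids
               else as.character(target_set)
    pool <- setdiff(pool, targets)
    if (length(pool) < length(targets)) stop("control pool exhausted")
    tv <- variances[targets]
    pv <- variances[pool]
    ord <- order(tv, decreasing = TRUE)
    available <- rep(TRUE, length(pool))
    chosen <- character(length(targets))
    for (i in ord) {
        j <- which.min(abs(pv - tv[i]) + ifelse(available, 0, Inf))
        chosen[i] <- pool[j]
        available[j] <- FALSE
    }
    cpgSet(paste0("variance_matched_control"), chosen)
}

#' Count subthreshold CpGs inside a CpG set
#' @param subthreshold character vector of subthreshold probe ids.
#' @param cpg_set a \code{CpGSet} or character vector.
#' @return integer overlap count.
#' @export
overlapCount <- function(subthreshold, cpg_set) {
    ids <- if (inherits(cpg_set, "CpGSet")) cpg_set$probe_ids else cpg_set
    length(intersect(subthreshold, ids))
}

#' Sample-permutation enrichment test for a CpG set
#'
#' The observed statistic is the overlap between the subthreshold CpGs of
#' the real-label EWAS and the set. For each of \code{B} permutations the
#' intervention labels are permuted across samples (covariates stay with
#' their samples), the covariate-adjusted EWAS is re-fitted in full, the
#' subthreshold selection is re-applied and the overlap recounted;
#' \eqn{p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\}) / (B + 1)}.
#'
#' @param me a \linkS4class{MethylationExperiment} (complete betas).
#' @param design a \code{\link{designSpec}} with a binary arm exposure.
#' @param cpg_set a \code{CpGSet} or character vector of probe ids.
#' @param B number of permutations (>= 100).
#' @param p_thr,effect_thr subthreshold selection thresholds.
#' @param seed RNG seed; same seed gives the same p.
#' @return list: set_name, set_size, n_subthreshold_total, n_overlap,
#'   permutation_p, B.
#' @export
permutationEnrichment <- function(me, design, cpg_set, B = 1000,
                                  p_thr = 0.05, effect_thr = 0.02,
                                  seed = NULL) {
    if (B < 100) stop("B must be >= 100")
    ids <- if (inherits(cpg_set, "CpGSet")) cpg_set$probe_ids else cpg_set
    set_name <- if (inherits(cpg_set, "CpGSet")) cpg_set$name else "set"
    Y <- betas(me)
    if (anyNA(Y)) stop("permutation enrichment requires complete betas")
    if (all(apply(Y, 1L, stats::sd) == 0))
        stop("degenerate input: all probes have zero variance")
    cov <- covariates(me)
    d <- .build_design(cov, design, Y = Y)
    arm01 <- as.numeric(cov[[design$exposure]] == "intervention")
    fwl <- .fwl_setup(Y, d$X, d$coef_col)
    obs_fit <- .fwl_stats(fwl, d$X[, d$coef_col], arm01)
    sub_obs <- rownames(Y)[obs_fit$p < p_thr &
                           abs(obs_fit$delta_beta) >= effect_thr]
    n_obs <- length(intersect(sub_obs, ids))
    in_set <- rownames(Y) %in% ids
    n_empty <- 0L
    .with_seed(seed, {
        count <- 0L
        for (b in seq_len(B)) {
            perm <- sample.int(length(arm01))
            fit <- .fwl_stats(fwl, d$X[perm, d$coef_col], arm01[perm])
            sub <- fit$p < p_thr & abs(fit$delta_beta) >= effect_thr
            if (!any(sub)) n_empty <- n_empty + 1L
            if (sum(sub & in_set) >= n_obs) count <- count + 1L
        }
        if (n_empty > B / 2)
            warning("subthreshold selection empty in most permutations")
        list(set_name = set_name, set_size = length(ids),
             n_subthreshold_total = length(sub_obs), n_overlap = n_obs,
             permutation_p = (1 + count) / (B + 1), B = B)
    })
}

# Exact OLS via Frisch-Waugh-Lovell for repeated refits where only the
# exposure column changes: Y and the exposure are residualized on the
# fixed covariates, so each permutation costs two matrix-vector products.
.fwl_setup <- function(Y, X, coef_col) {
    Z <- X[, -coef_col, drop = FALSE]
    A <- chol2inv(qr.R(qr(Z)))
    W <- Y %*% Z
    Ystar <- Y - (W %*% A) %*% t(Z)
    list(Y = Y, Z = Z, A = A, Ystar = Ystar,
         rss0 = rowSums(Ystar * Ystar), df = ncol(Y) - ncol(X))
}

.fwl_stats <- function(fwl, e, arm01) {
    estar <- e - drop(fwl$Z %*% (fwl$A %*% crossprod(fwl$Z, e)))
    s2x <- sum(estar * estar)
    coef <- drop(fwl$Ystar %*% estar) / s2x
    rss <- pmax(fwl$rss0 - coef^2 * s2x, 0)
    se <- sqrt(rss / fwl$df / s2x)
    tt <- coef / se
    n1 <- sum(arm01 == 1)
    n0 <- sum(arm01 == 0)
    v <- ifelse(arm01 == 1, 1 / n1, -1 / n0)
    list(estimate = coef, se = se, t = tt,
         p = 2 * stats::pt(-abs(tt), fwl$df),
         delta_beta = drop(fwl$Y %*% v))
}
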