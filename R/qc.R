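#' Sample-level QC: sex mismatches and outlying arrays
#'
#' Sex is predicted by a deterministic 2-means split of the per-sample
#' chrY-like summary signal (centers initialised at the signal extremes;
#' the higher-signal cluster is called male); samples whose predicted sex
#' disagrees with the reported sex are removed. Arrays whose array-wide
#' median beta deviates from the cohort median of medians by more than
#' \code{k_iqr} IQRs are removed as outliers.
#'
#' @param me a \linkS4class{MethylationExperiment}; \code{colData} must
#'   contain \code{sex} and \code{y_signal} (or pass \code{sex_signal}).
#' @param sex_signal optional data.frame with \code{x_signal},
#'   \code{y_signal} per sample (rownames = sample ids).
#' @param k_iqr IQR multiplier for the array-outlier rule.
#' @return list with the filtered experiment (\code{methyl}) and a
#'   \code{report} data.frame (sample_id, reason).
#' @export
filterSamples <- function(me, sex_signal = NULL, k_iqr = 3) {
    cd <- covariates(me)
    ys <- if (!is.null(sex_signal)) sex_signal[colnames(me), "y_signal"]
          else cd$y_signal
    if (is.null(ys)) stop("sex signal unavailable")
    pred <- .two_means_split(ys)   # TRUE = high-signal cluster (male)
    reported_m <- cd$sex == "M"
    mismatch <- pred != reported_m

    med <- apply(betas(me), 2L, stats::median, na.rm = TRUE)
    centre <- stats::median(med)
    iqr <- .iqr7(med)
    outlier <- abs(med - centre) > k_iqr * iqr

    report <- data.frame(
        sample_id = c(colnames(me)[mismatch],
                      colnames(me)[outlier & !mismatch]),
        reason = c(rep("sex_mismatch", sum(mismatch)),
                   rep("array_outlier", sum(outlier & !mismatch))),
        stringsAsFactors = FALSE)
    keep <- !(mismatch | outlier)
    if (!any(keep)) stop("all samples excluded by sample QC")
    list(methyl = me[, keep], report = report)
}

# deterministic 1-d 2-means (Lloyd iterations from the extreme values)
.two_means_split <- function(x) {
    c1 <- min(x); c2 <- max(x)
    if (c1 == c2) return(rep(FALSE, length(x)))
    for (i in 1:100) {
        hi <- abs(x - c2) < abs(x - c1)
        n1 <- mean(x[!hi]); n2 <- mean(x[hi])
        if (isTRUE(all.equal(c(c1, c2), c(n1, n2)))) break
        c1 <- n1; c2 <- n2
    }
    abs(x - c2) < abs(x - c1)
}

#' Probe-level QC filtering
#'
#' Removes probes failing detection (detection p above
#' \code{detection_p_max} in more than \code{max_fail_frac} of samples),
#' bead count (below \code{bead_min} in more than \code{max_fail_frac}),
#' and probes flagged as sex-chromosome or ambiguously mapping in the
#' annotation.
#'
#' @param me a \linkS4class{MethylationExperiment}.
#' @param detection_p_max,bead_min,max_fail_frac rule thresholds.
#' @return list with filtered \code{methyl} and a \code{report}
#'   data.frame (probe_id, reason); reasons are assigned in the order
#'   detection, beads, sex_chromosome, ambiguous (first matching reason).
#' @export
filterProbes <- function(me, detection_p_max = 0.01, bead_min = 3,
                         max_fail_frac = 0.05) {
    np <- nrow(me)
    reason <- rep(NA_character_, np)
    if ("detection_p" %in% assayNames(me)) {
        fail <- rowMeans(assay(me, "detection_p") > detection_p_max,
                         na.rm = TRUE) > max_fail_frac
        reason[fail] <- "detection"
    }
    if ("bead_count" %in% assayNames(me)) {
        fail <- rowMeans(assay(me, "bead_count") < bead_min,
                         na.rm = TRUE) > max_fail_frac
        reason[is.na(reason) & fail] <- "beads"
    }
    ann <- probeAnnotation(me)
    sexchr <- ann$sex_chromosome |
        ann$chrom %in% c("chrX", "chrY", "X", "Y")
    reason[is.na(reason) & sexchr] <- "sex_chromosome"
    reason[is.na(reason) & ann$ambiguous_mapping] <- "ambiguous"
    report <- data.frame(probe_id = rownames(me)[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
    keep <- is.na(reason)
    if (!any(keep)) warning("all probes excluded by probe QC")
    list(methyl = me[keep, ], report = report)
}

#' Pyrosequencing panel QC
#'
#' A panel value is excluded iff it lies more than \code{k_iqr} IQRs
#' (type-7 quantiles) from its CpG's median \emph{and} carries a technical
#' flag -- both conditions are required. Assay precision is reported as
#' CV\% = 100 * SD / mean over the positive-control replicates of each
#' assay.
#'
#' @param panel long data.frame: region, probe, sample, value, flag.
#' @param controls optional data.frame (region, replicate, value) of
#'   positive-control replicates.
#' @param k_iqr IQR multiplier (default 3).
#' @return list with the filtered \code{panel} (excluded rows dropped),
#'   \code{excluded} rows, and a per-assay \code{cv} data.frame.
#' @export
pyroQC <- function(panel, controls = NULL, k_iqr = 3) {
    stopifnot(all(c("probe", "value", "flag") %in% names(panel)))
    drop <- rep(FALSE, nrow(panel))
    for (pr in unique(panel$probe)) {
        sel <- which(panel$probe == pr)
        v <- panel$value[sel]
        if (sum(!is.na(v)) < 4L) {
            warning("fewer than 4 values for CpG '", pr,
                    "'; IQR undefined, skipped")
            next
        }
        med <- stats::median(v, na.rm = TRUE)
        iqr <- .iqr7(v)
        far <- !is.na(v) & abs(v - med) > k_iqr * iqr
        drop[sel] <- far & panel$flag[sel]
    }
    cv <- NULL
    if (!is.null(controls)) {
        cv <- do.call(rbind, lapply(split(controls, controls$region),
            function(d) data.frame(
                region = d$region[1L],
                cv_percent = 100 * stats::sd(d$value) / mean(d$value),
                n_replicates = nrow(d), stringsAsFactors = FALSE)))
        rownames(cv) <- NULL
    }
    list(panel = panel[!drop, , drop = FALSE],
         excluded = panel[drop, , drop = FALSE], cv = cv)
}
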