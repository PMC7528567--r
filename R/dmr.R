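#' Correlation of association signal by genomic distance
#'
#' Converts p-values to z-scores (signed by the effect estimate when one
#' is supplied, unsigned otherwise), then computes the Pearson correlation
#' of z between site pairs binned by genomic distance. Correlations are
#' clipped to \eqn{[0,1]}; distances beyond \code{max_lag} are treated as
#' uncorrelated.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}, \code{p} and an
#'   optional \code{effect} column, position-sorted within chromosome.
#' @param max_lag maximum pair distance considered (bp).
#' @param bin_width distance bin width (bp); the first bin starts at 0.
#' @return object of class \code{dmrAcf}: data.frame with bin bounds,
#'   correlation and pair count per bin.
#' @export
estimateAutocorrelation <- function(sites, max_lag = 1000, bin_width = 100) {
    .stop_if_not_sorted(sites$chrom, sites$pos)
    if (nrow(sites) < 1000)
        warning("fewer than 1000 sites; autocorrelation estimate unstable")
    z <- stats::qnorm(1 - .clamp_p(sites$p) / 2)
    if (!is.null(sites$effect)) z <- z * sign(sites$effect)
    d_all <- numeric(0); z1 <- numeric(0); z2 <- numeric(0)
    for (ch in unique(sites$chrom)) {
        sel <- which(sites$chrom == ch)
        pos <- sites$pos[sel]
        zz <- z[sel]
        n <- length(sel)
        k <- 1L
        repeat {
            if (k >= n) break
            i <- seq_len(n - k)
            d <- pos[i + k] - pos[i]
            keep <- d <= max_lag
            if (!any(keep)) break
            d_all <- c(d_all, d[keep])
            z1 <- c(z1, zz[i][keep])
            z2 <- c(z2, zz[i + k][keep])
            k <- k + 1L
        }
    }
    n_bins <- ceiling(max_lag / bin_width)
    # bins are (0, w], (w, 2w], ...; zero distance joins the first bin
    bin <- pmax(1L, ceiling(d_all / bin_width))
    out <- data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width,
                      bin_end = pmin(seq_len(n_bins) * bin_width,
                                     max_lag),
                      cor = NA_real_, n_pairs = 0L)
    for (b in seq_len(nrow(out))) {
        sel <- bin == b
        out$n_pairs[b] <- sum(sel)
        if (sum(sel) >= 3)
            out$cor[b] <- min(1, max(0, stats::cor(z1[sel], z2[sel])))
    }
    structure(out, class = c("dmrAcf", "data.frame"), max_lag = max_lag)
}

# correlation at a given distance from a dmrAcf table
.acf_at <- function(acf, d) {
    ml <- attr(acf, "max_lag")
    w <- acf$bin_end[1L] - acf$bin_start[1L]
    out <- numeric(length(d))
    inside <- d <= ml
    if (any(inside)) {
        b <- pmin(nrow(acf), pmax(1L, ceiling(d[inside] / w)))
        r <- acf$cor[b]
        r[is.na(r)] <- 0
        out[inside] <- r
    }
    out[d == 0] <- 1
    out
}

#' Stouffer-Liptak combination of correlated p-values
#'
#' \eqn{z_i = \Phi^{-1}(1 - p_i)}; combined
#' \eqn{z = \sum z_i / \sqrt{1^T C 1}}; combined p is the upper normal
#' tail. A non-positive-semidefinite correlation matrix is repaired to the
#' nearest PSD matrix (eigenvalue clipping, logged via message); p-values
#' of 0 are clamped at 1e-300.
#'
#' @param p numeric p-values.
#' @param corr correlation matrix (defaults to identity).
#' @return combined p-value.
#' @export
stoufferLiptak <- function(p, corr = diag(length(p))) {
    if (length(p) == 1L) return(p)
    if (any(p == 0)) message("p-value of 0 clamped at 1e-300")
    p <- .clamp_p(p)
    corr <- as.matrix(corr)
    if (!isSymmetric(unname(corr), tol = 1e-8))
        stop("correlation matrix must be symmetric")
    ev <- eigen(corr, symmetric = TRUE)
    if (min(ev$values) < -1e-8) {
        message("correlation matrix repaired to nearest PSD (min eigenvalue ",
                format(min(ev$values), digits = 3), ")")
        vals <- pmax(ev$values, 1e-8)
        corr <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    }
    z <- stats::qnorm(1 - p)
    denom <- sqrt(sum(corr))
    stats::pnorm(sum(z) / denom, lower.tail = FALSE)
}

#' Scan-based region caller
#'
#' Seeds at sites with \code{p < seed_p}; seeds within \code{max_gap} bp of
#' each other are clustered, and every site inside the seed span becomes a
#' region member (members are contiguous in position order). The regional
#' p combines member p-values by \code{\link{stoufferLiptak}} with
#' correlations taken from the distance-binned autocorrelation estimate;
#' the adjusted p applies a Sidak correction,
#' \eqn{1 - (1 - p)^{(\mathrm{scanned\ bases}) / (\mathrm{region\ length})}}.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}, \code{p},
#'   optional \code{probe_id} and \code{effect}, sorted within chromosome.
#' @param acf a \code{dmrAcf} from \code{\link{estimateAutocorrelation}};
#'   \code{NULL} means independence.
#' @param seed_p seeding threshold.
#' @param max_gap maximum gap between clustered seeds (bp).
#' @param min_cpgs minimum member count.
#' @return \code{GRanges} of regions with mcols: n_cpgs, probe_ids,
#'   min_p, region_p_raw, region_p_adj, method, direction_consistent.
#' @export
scanRegions <- function(sites, acf = NULL, seed_p = 0.05, max_gap = 500,
                        min_cpgs = 3) {
    .stop_if_not_sorted(sites$chrom, sites$pos)
    if (is.null(sites$probe_id))
        sites$probe_id <- sprintf("site_%d", seq_len(nrow(sites)))
    scanned <- sum(vapply(split(sites$pos, sites$chrom),
                          function(p) max(p) - min(p) + 1, numeric(1)))
    regions <- list()
    for (ch in unique(sites$chrom)) {
        s <- sites[sites$chrom == ch, , drop = FALSE]
        seeds <- which(s$p < seed_p)
        if (length(seeds) == 0) next
        gap_break <- c(TRUE, diff(s$pos[seeds]) > max_gap)
        cl <- cumsum(gap_break)
        for (g in unique(cl)) {
            sd_idx <- seeds[cl == g]
            memb <- which(s$pos >= s$pos[min(sd_idx)] &
                          s$pos <= s$pos[max(sd_idx)])
            if (length(memb) < min_cpgs) next
            pos <- s$pos[memb]
            pv <- s$p[memb]
            C <- outer(pos, pos, function(a, b) {
                d <- abs(a - b)
                if (is.null(acf)) as.numeric(d == 0) else .acf_at(acf, d)
            })
            diag(C) <- 1
            praw <- stoufferLiptak(pv, C)
            len <- max(pos) - min(pos) + 1
            padj <- -expm1(max(1, scanned / len) *
                           log1p(-.clamp_p(praw)))
            dirc <- if (!is.null(s$effect))
                all(sign(s$effect[memb]) == sign(s$effect[memb][1L]))
                else NA
            regions[[length(regions) + 1L]] <- list(
                chrom = ch, start = min(pos), end = max(pos),
                probe_ids = s$probe_id[memb], n_cpgs = length(memb),
                min_p = min(pv), region_p_raw = praw,
                region_p_adj = padj, direction_consistent = dirc)
        }
    }
    .regions_granges(regions, "scan")
}

.regions_granges <- function(regions, method) {
    if (length(regions) == 0) {
        gr <- GRanges()
        S4Vectors::mcols(gr) <- DataFrame(
            n_cpgs = integer(0), probe_ids = IRanges::CharacterList(),
            min_p = numeric(0), region_p_raw = numeric(0),
            region_p_adj = numeric(0), method = character(0),
            direction_consistent = logical(0))
        return(gr)
    }
    gr <- GRanges(vapply(regions, `[[`, character(1), "chrom"),
                  IRanges(vapply(regions, `[[`, numeric(1), "start"),
                          vapply(regions, `[[`, numeric(1), "end")))
    gr$n_cpgs <- vapply(regions, `[[`, numeric(1), "n_cpgs")
    gr$probe_ids <- IRanges::CharacterList(lapply(regions, `[[`,
                                                  "probe_ids"))
    gr$min_p <- vapply(regions, `[[`, numeric(1), "min_p")
    gr$region_p_raw <- vapply(regions, `[[`, numeric(1), "region_p_raw")
    gr$region_p_adj <- vapply(regions, `[[`, numeric(1), "region_p_adj")
    gr$method <- method
    gr$direction_consistent <- vapply(regions, function(r)
        as.logical(r$direction_consistent), logical(1))
    gr[order(gr$region_p_raw)]
}

#' Kernel-smoothing region caller
#'
#' Squared per-site t statistics are smoothed along position with a
#' Gaussian kernel (SD = \code{bandwidth}/2); each smoothed statistic is
#' referred to a scaled chi-square by Satterthwaite moment matching, sites
#' significant after BH < \code{fdr} on the smoothed p are grouped within
#' \code{bandwidth} bp into regions, and regions are combined by
#' unweighted Stouffer over member raw p with BH across regions.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}, \code{p},
#'   \code{t}, optional \code{probe_id} and \code{effect}, sorted within
#'   chromosome.
#' @param bandwidth kernel bandwidth lambda in bp.
#' @param min_cpgs minimum member count.
#' @param fdr BH threshold on smoothed site p.
#' @return \code{GRanges} of regions (same mcols as
#'   \code{\link{scanRegions}}; region_p_adj is the BH value).
#' @export
kernelRegions <- function(sites, bandwidth = 1000, min_cpgs = 3,
                          fdr = 0.05) {
    .stop_if_not_sorted(sites$chrom, sites$pos)
    if (is.null(sites$probe_id))
        sites$probe_id <- sprintf("site_%d", seq_len(nrow(sites)))
    sigma <- bandwidth / 2
    p_smooth <- rep(NA_real_, nrow(sites))
    for (ch in unique(sites$chrom)) {
        sel <- which(sites$chrom == ch)
        pos <- sites$pos[sel]
        t2 <- sites$t[sel]^2
        n <- length(sel)
        for (ii in seq_len(n)) {
            lo <- pos[ii] - 3 * sigma
            hi <- pos[ii] + 3 * sigma
            w_idx <- which(pos >= lo & pos <= hi)
            w <- exp(-(pos[w_idx] - pos[ii])^2 / (2 * sigma^2))
            w <- w / sum(w)
            S <- sum(w * t2[w_idx])
            f <- sum(w^2)
            df <- 1 / f
            p_smooth[sel[ii]] <- stats::pchisq(S / f, df,
                                               lower.tail = FALSE)
        }
    }
    sig <- which(bhFdr(p_smooth) < fdr)
    regions <- list()
    for (ch in unique(sites$chrom)) {
        s_sig <- sig[sites$chrom[sig] == ch]
        if (length(s_sig) == 0) next
        pos <- sites$pos[s_sig]
        cl <- cumsum(c(TRUE, diff(pos) > bandwidth))
        for (g in unique(cl)) {
            memb <- s_sig[cl == g]
            if (length(memb) < min_cpgs) next
            pv <- .clamp_p(sites$p[memb])
            z <- stats::qnorm(1 - pv)
            praw <- stats::pnorm(sum(z) / sqrt(length(z)),
                                 lower.tail = FALSE)
            dirc <- if (!is.null(sites$effect))
                all(sign(sites$effect[memb]) ==
                    sign(sites$effect[memb][1L])) else NA
            regions[[length(regions) + 1L]] <- list(
                chrom = ch, start = min(sites$pos[memb]),
                end = max(sites$pos[memb]),
                probe_ids = sites$probe_id[memb],
                n_cpgs = length(memb), min_p = min(sites$p[memb]),
                region_p_raw = praw, region_p_adj = NA_real_,
                direction_consistent = dirc)
        }
    }
    gr <- .regions_granges(regions, "kernel")
    if (length(gr) > 0) gr$region_p_adj <- bhFdr(gr$region_p_raw)
    gr
}

#' Agreement between two region callers
#'
#' Interval-overlap join (>= 1 bp) between the scan and kernel region
#' sets; regions found by both methods gain a consensus flag.
#'
#' @param regions_scan,regions_kernel \code{GRanges} from the two callers.
#' @return data.frame: method, rank (by regional p within method), chrom,
#'   start, end, n_cpgs, min_p, region_p_raw, region_p_adj, found_by_both.
#' @export
consensusRegions <- function(regions_scan, regions_kernel) {
    as_df <- function(gr, method) {
        if (length(gr) == 0)
            return(data.frame(method = character(0), rank = integer(0),
                              chrom = character(0), start = integer(0),
                              end = integer(0), n_cpgs = integer(0),
                              min_p = numeric(0), region_p_raw = numeric(0),
                              region_p_adj = numeric(0),
                              found_by_both = logical(0)))
        data.frame(method = method,
                   rank = rank(gr$region_p_raw, ties.method = "first"),
                   chrom = as.character(seqnames(gr)), start = start(gr),
                   end = end(gr), n_cpgs = gr$n_cpgs, min_p = gr$min_p,
                   region_p_raw = gr$region_p_raw,
                   region_p_adj = gr$region_p_adj,
                   found_by_both = FALSE, stringsAsFactors = FALSE)
    }
    ds <- as_df(regions_scan, "scan")
    dk <- as_df(regions_kernel, "kernel")
    if (nrow(ds) > 0 && nrow(dk) > 0) {
        ov <- findOverlaps(regions_scan, regions_kernel, minoverlap = 1L)
        ds$found_by_both[unique(S4Vectors::queryHits(ov))] <- TRUE
        dk$found_by_both[unique(S4Vectors::subjectHits(ov))] <- TRUE
    }
    out <- rbind(ds, dk)
    out[order(out$method, out$rank), , drop = FALSE]
}
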