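#' Specification of a synthetic trial cohort
#'
#' Describes the statistical structure of a simulated randomized
#' micronutrient-trial methylation cohort: per-arm sample sizes with sex
#' composition, probe layout on two synthetic chromosomes, intervention
#' effects at designated CpGs and regions, hypervariable (metastable-
#' epiallele-like) and intermediate-methylation (imprinted-like) probe
#' classes, cell-composition and batch structure, and cis-mQTL effects.
#'
#' @param n_probes total number of probes.
#' @param sex_imbalance list with per-arm male/female counts, e.g.
#'   \code{list(intervention = c(M = 64, F = 74), control = c(M = 93, F = 58))}.
#' @param n_true_dmps number of stand-alone true DMPs (outside regions).
#' @param true_effect_range beta-difference range for stand-alone DMPs
#'   (intervention minus control; negative = hypomethylation).
#' @param dmr_specs list of regions, each \code{list(n_cpgs, effect,
#'   spacing)}; spacing is the intra-region inter-CpG gap in bp.
#' @param n_me_probes,n_icr_probes sizes of the hypervariable and
#'   intermediate-methylation probe classes.
#' @param cell_alpha Dirichlet concentration for cell fractions.
#' @param cell_sd SD of per-probe cell-composition loadings (beta scale).
#' @param batch_levels number of array batches (plates).
#' @param batch_sd SD of per-probe batch offsets (beta scale).
#' @param noise_sd per-sample noise SD on the logit scale; 0 gives
#'   deterministic per-probe betas.
#' @param mqtl_specs list of \code{list(snp_id, targets, slope, maf)};
#'   \code{targets} may be \code{"dmr1"}, \code{"dmr2"}, ... or explicit
#'   probe ids. Slope is the beta increase per alt allele.
#' @param probe_gap inter-CpG gap (bp) outside regions.
#' @param season include a wet/dry season-of-conception covariate.
#' @param cohort cohort label.
#' @param detect_fail_rate,bead_fail_rate Bernoulli rates of failing
#'   detection-p / bead-count cells.
#' @param seed RNG seed stored with the spec.
#' @return object of class \code{SimulationSpec}.
#' @export
simulationSpec <- function(n_probes = 2000,
                           sex_imbalance = list(
                               intervention = c(M = 64, F = 74),
                               control = c(M = 93, F = 58)),
                           n_true_dmps = 0,
                           true_effect_range = c(-0.050, -0.025),
                           dmr_specs = list(),
                           n_me_probes = 0,
                           n_icr_probes = 0,
                           cell_alpha = c(CD4T = 12, CD8T = 9, NK = 6,
                                          Bcell = 6, Mono = 6, Gran = 27),
                           cell_sd = 0.02,
                           batch_levels = 4,
                           batch_sd = 0.004,
                           noise_sd = 0.2,
                           mqtl_specs = list(),
                           probe_gap = 5000,
                           season = TRUE,
                           cohort = "gambian",
                           detect_fail_rate = 0.002,
                           bead_fail_rate = 0.001,
                           seed = NULL) {
    spec <- list(n_probes = n_probes, sex_imbalance = sex_imbalance,
                 n_true_dmps = n_true_dmps,
                 true_effect_range = true_effect_range,
                 dmr_specs = dmr_specs, n_me_probes = n_me_probes,
                 n_icr_probes = n_icr_probes, cell_alpha = cell_alpha,
                 cell_sd = cell_sd, batch_levels = batch_levels,
                 batch_sd = batch_sd, noise_sd = noise_sd,
                 mqtl_specs = mqtl_specs, probe_gap = probe_gap,
                 season = season, cohort = cohort,
                 detect_fail_rate = detect_fail_rate,
                 bead_fail_rate = bead_fail_rate, seed = seed)
    spec$n_samples <- sum(unlist(sex_imbalance))
    n_region_cpgs <- sum(vapply(dmr_specs, function(d) d$n_cpgs, numeric(1)))
    if (n_true_dmps + n_me_probes + n_icr_probes + n_region_cpgs > n_probes)
        stop("infeasible spec: designated probe classes exceed n_probes")
    class(spec) <- "SimulationSpec"
    spec
}

#' Gambian-like cohort preset
#'
#' 289 children (intervention 64 M / 74 F, control 93 M / 58 F), 20,000
#' probes, six true DMPs with beta decreases of 0.025-0.050 in the
#' intervention arm (four of them inside a 10-CpG region, effect -0.03),
#' a second 4-CpG region, hypervariable and intermediate-methylation probe
#' classes (2.5% of probes each), season-of-conception covariate, and one cis-mQTL (slope 0.03
#' per alt allele, MAF 0.3) acting on the main region.
#' @param n_probes scaled probe count.
#' @param seed RNG seed.
#' @export
gambianCohortSpec <- function(n_probes = 20000, seed = NULL) {
    simulationSpec(
        n_probes = n_probes,
        sex_imbalance = list(intervention = c(M = 64, F = 74),
                             control = c(M = 93, F = 58)),
        n_true_dmps = 2,
        true_effect_range = c(-0.050, -0.025),
        dmr_specs = list(list(n_cpgs = 10, effect = -0.03, spacing = 150),
                         list(n_cpgs = 4, effect = -0.02, spacing = 200)),
        n_me_probes = round(0.025 * n_probes),
        n_icr_probes = round(0.025 * n_probes),
        mqtl_specs = list(list(snp_id = "snp_dmr1", targets = "dmr1",
                               slope = 0.03, maf = 0.3)),
        season = TRUE, cohort = "gambian", seed = seed)
}

#' Indian-like cohort preset
#'
#' 686 children (intervention 168 M / 153 F, control 209 M / 156 F) with
#' near-zero intervention effects, no regions, no season covariate.
#' @param n_probes scaled probe count.
#' @param seed RNG seed.
#' @export
indianCohortSpec <- function(n_probes = 20000, seed = NULL) {
    simulationSpec(
        n_probes = n_probes,
        sex_imbalance = list(intervention = c(M = 168, F = 153),
                             control = c(M = 209, F = 156)),
        n_true_dmps = 0, dmr_specs = list(),
        n_me_probes = round(0.025 * n_probes),
        n_icr_probes = round(0.025 * n_probes),
        season = FALSE, cohort = "indian", seed = seed)
}

.rdirichlet <- function(n, alpha) {
    x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                nrow = n, byrow = TRUE)
    sw <- x / rowSums(x)
    colnames(sw) <- names(alpha)
    sw
}

.simulate_covariates <- function(spec) {
    arms <- c(rep("intervention", sum(spec$sex_imbalance$intervention)),
              rep("control", sum(spec$sex_imbalance$control)))
    sexes <- c(rep(c("M", "F"), spec$sex_imbalance$intervention),
               rep(c("M", "F"), spec$sex_imbalance$control))
    n <- length(arms)
    age <- if (spec$cohort == "indian") stats::runif(n, 5.5, 6.1) else
        stats::runif(n, 8.5, 9.3)
    cells <- .rdirichlet(n, spec$cell_alpha)
    cov <- data.frame(
        sample_id = sprintf("S%04d", seq_len(n)),
        arm = factor(arms, levels = c("control", "intervention")),
        sex = factor(sexes, levels = c("F", "M")),
        age = age,
        batch = factor(sprintf("plate%d",
                               1L + (seq_len(n) - 1L) %% spec$batch_levels)),
        maternal_bmi = stats::rnorm(n, 20.8, 2.3),
        compliance = stats::rbeta(n, 20, 3),
        cohort = spec$cohort,
        stringsAsFactors = FALSE)
    cov <- cbind(cov, as.data.frame(cells))
    if (spec$season)
        cov$season <- factor(sample(c("dry", "wet"), n, replace = TRUE))
    # summary intensity signals used for sex QC (chrY-like channel)
    cov$y_signal <- ifelse(cov$sex == "M", stats::rnorm(n, 1.0, 0.04),
                           stats::rnorm(n, 0.12, 0.04))
    cov$x_signal <- ifelse(cov$sex == "M", stats::rnorm(n, 0.5, 0.04),
                           stats::rnorm(n, 1.0, 0.04))
    rownames(cov) <- cov$sample_id
    cov
}

# probe layout: two synthetic chromosomes, dense CpG runs at region specs
.simulate_annotation <- function(spec) {
    np <- spec$n_probes
    probe_id <- sprintf("cg%07d", seq_len(np))
    chrom <- rep(c("chr1", "chr2"), c(ceiling(np / 2), floor(np / 2)))
    gaps <- rep(spec$probe_gap, np)
    role <- rep("background", np)
    region_id <- rep(NA_character_, np)
    # place each region on chr1, well separated
    if (length(spec$dmr_specs) > 0) {
        chr1_cap <- ceiling(np / 2)
        offset <- 10L  # start index on chr1
        for (r in seq_along(spec$dmr_specs)) {
            d <- spec$dmr_specs[[r]]
            idx <- offset + seq_len(d$n_cpgs) - 1L
            if (max(idx) > chr1_cap)
                stop("infeasible spec: regions exceed chromosome capacity")
            sp <- if (is.null(d$spacing)) 150 else d$spacing
            gaps[idx[-1L]] <- sp
            role[idx] <- "dmr"
            region_id[idx] <- sprintf("dmr%d", r)
            offset <- offset + d$n_cpgs + 30L
        }
    }
    pos <- integer(np)
    for (ch in unique(chrom)) {
        sel <- chrom == ch
        g <- gaps[sel]
        g[1L] <- 1000L
        pos[sel] <- cumsum(g)
    }
    data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
               gene = ifelse(is.na(region_id), NA_character_, region_id),
               role = role, region_id = region_id,
               stringsAsFactors = FALSE)
}

#' Simulate a trial methylation cohort
#'
#' Betas are generated as an inverse-logit of per-probe baselines plus
#' logit-scale individual noise (keeping values in \eqn{[0,1]} with
#' realistic heteroscedasticity); intervention, cell-composition and batch
#' shifts are then added on the beta scale and clamped. Hypervariable
#' probes are drawn from a two-component mixture with per-sample component
#' assignment; intermediate-methylation probes sit near beta 0.5 with low
#' variance.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list with \code{methyl} (a
#'   \linkS4class{MethylationExperiment} carrying covariates, annotation
#'   and detection/bead assays) and \code{truth} (a \code{TruthLedger}
#'   list: per-probe effects and set memberships, per-region spans).
#' @export
simulateCohort <- function(spec) {
    stopifnot(inherits(spec, "SimulationSpec"))
    .with_seed(spec$seed, {
        cov <- .simulate_covariates(spec)
        ann <- .simulate_annotation(spec)
        n <- nrow(cov)
        np <- spec$n_probes

        free <- which(ann$role == "background")
        dmp_idx <- utils::head(free, spec$n_true_dmps)
        free <- setdiff(free, dmp_idx)
        me_idx <- sample(free, spec$n_me_probes)
        free <- setdiff(free, me_idx)
        icr_idx <- sample(free, spec$n_icr_probes)
        dmr_idx <- which(ann$role == "dmr")

        # per-probe logit baselines
        comp <- sample(1:3, np, replace = TRUE, prob = c(0.35, 0.45, 0.20))
        mu <- c(-2.2, 2.2, 0)[comp] + stats::rnorm(np, 0, c(0.7, 0.7, 0.9)[comp])
        mu[icr_idx] <- stats::rnorm(length(icr_idx), 0, 0.15)
        mu[c(dmp_idx, dmr_idx)] <- stats::rnorm(
            length(dmp_idx) + length(dmr_idx), 0, 0.45)

        effect <- rep(0, np)
        if (length(dmp_idx) > 0)
            effect[dmp_idx] <- stats::runif(length(dmp_idx),
                                            min(spec$true_effect_range),
                                            max(spec$true_effect_range))
        for (r in seq_along(spec$dmr_specs)) {
            idx <- which(ann$region_id %in% sprintf("dmr%d", r))
            effect[idx] <- spec$dmr_specs[[r]]$effect
        }
        exp_beta <- stats::plogis(mu) + effect
        if (any(exp_beta < 0 | exp_beta > 1))
            stop("infeasible spec: expected beta outside [0,1]")

        # logit-scale individual noise, heteroscedastic per probe
        h <- exp(stats::rnorm(np, 0, 0.2))
        if (spec$noise_sd > 0) {
            # mu and the per-probe scale recycle down the columns
            B <- (spec$noise_sd * h) * matrix(stats::rnorm(np * n), np, n)
            B <- B + mu
        } else {
            B <- matrix(mu, np, n)
        }
        if (spec$n_me_probes > 0) {
            # two-component hypervariable probes
            pi_me <- stats::runif(length(me_idx), 0.3, 0.7)
            hi <- matrix(stats::rbinom(length(me_idx) * n, 1L,
                                       rep(pi_me, n)), ncol = n)
            mu_lo <- stats::qlogis(0.25)
            mu_hi <- stats::qlogis(0.75)
            B[me_idx, ] <- B[me_idx, ] - mu[me_idx] +
                ifelse(hi == 1L, mu_hi, mu_lo)
        }
        B <- stats::plogis(B)

        arm01 <- as.numeric(cov$arm == "intervention")
        if (any(effect != 0)) B <- B + outer(effect, arm01)
        if (spec$cell_sd > 0) {
            f <- as.matrix(cov[, names(spec$cell_alpha)])
            f <- sweep(f, 2L, colMeans(f))
            L <- matrix(stats::rnorm(np * ncol(f), 0, spec$cell_sd),
                        np, ncol(f))
            B <- B + L %*% t(f)
        }
        if (spec$batch_sd > 0) {
            bl <- levels(cov$batch)
            off <- matrix(stats::rnorm(np * length(bl), 0, spec$batch_sd),
                          np, length(bl))
            B <- B + off[, as.integer(cov$batch)]
        }
        n_clamped <- sum(B < 0) + sum(B > 1)
        if (n_clamped > 0) {
            message("clamped ", n_clamped, " beta value(s) into [0,1]")
            B <- .clamp01(B)
        }
        dimnames(B) <- list(ann$probe_id, cov$sample_id)

        det <- beads <- NULL
        if (spec$detect_fail_rate > 0) {
            det <- matrix(stats::rbeta(np * n, 0.5, 2000), np, n,
                          dimnames = dimnames(B))
            fail <- matrix(stats::runif(np * n) < spec$detect_fail_rate,
                           np, n)
            det[fail] <- stats::runif(sum(fail), 0.02, 0.5)
        }
        if (spec$bead_fail_rate > 0) {
            beads <- matrix(10L + stats::rpois(np * n, 4), np, n,
                            dimnames = dimnames(B))
            bfail <- matrix(stats::runif(np * n) < spec$bead_fail_rate,
                            np, n)
            beads[bfail] <- sample(1:2, sum(bfail), replace = TRUE)
        }

        me <- MethylationExperiment(
            B, annotation = ann[c("probe_id", "chrom", "pos", "gene")],
            covariates = cov, detection_p = det, bead_count = beads)
        metadata(me)$n_clamped <- n_clamped

        probes <- data.frame(
            probe_id = ann$probe_id, chrom = ann$chrom, pos = ann$pos,
            is_true_dmp = effect != 0, true_effect = effect,
            is_me = seq_len(np) %in% me_idx,
            is_icr = seq_len(np) %in% icr_idx,
            region_id = ann$region_id, stringsAsFactors = FALSE)
        regions <- do.call(rbind, lapply(seq_along(spec$dmr_specs),
            function(r) {
                idx <- which(ann$region_id %in% sprintf("dmr%d", r))
                data.frame(region_id = sprintf("dmr%d", r),
                           chrom = ann$chrom[idx[1L]],
                           start = min(ann$pos[idx]), end = max(ann$pos[idx]),
                           n_cpgs = length(idx),
                           effect = spec$dmr_specs[[r]]$effect,
                           probe_ids = paste(ann$probe_id[idx],
                                             collapse = ","),
                           stringsAsFactors = FALSE)
            }))
        truth <- structure(list(probes = probes, regions = regions,
                                mqtl = NULL, spec = spec),
                           class = "TruthLedger")
        list(methyl = me, truth = truth)
    })
}

#' Simulate genotypes with cis-mQTL effects
#'
#' Hardy-Weinberg genotypes at the stated MAFs, independent of trial arm
#' (randomization). Each mQTL spec adds \code{slope * dosage} to its target
#' CpG betas (clamped to \eqn{[0,1]}). Additional null SNPs with random
#' MAF are generated for screening.
#'
#' @param spec the \code{\link{simulationSpec}} used for the cohort.
#' @param cohort result of \code{\link{simulateCohort}} (list with
#'   \code{methyl} and \code{truth}).
#' @param n_null_snps extra SNPs with no methylation effect.
#' @param seed RNG seed.
#' @return list with updated \code{methyl}, \code{genotypes}
#'   (a \linkS4class{GenotypeExperiment}) and \code{truth} (mQTL entries
#'   appended).
#' @export
simulateGenotypes <- function(spec, cohort, n_null_snps = 50, seed = NULL) {
    me <- cohort$methyl
    truth <- cohort$truth
    n <- ncol(me)
    .with_seed(seed, {
        specs <- spec$mqtl_specs
        for (s in specs)
            if (s$maf <= 0 || s$maf > 0.5)
                stop("MAF must be in (0, 0.5]")
        snp_ids <- c(vapply(specs, `[[`, character(1), "snp_id"),
                     sprintf("snp_null%03d", seq_len(n_null_snps)))
        mafs <- c(vapply(specs, `[[`, numeric(1), "maf"),
                  stats::runif(n_null_snps, 0.05, 0.5))
        dos <- matrix(stats::rbinom(length(snp_ids) * n, 2L,
                                    rep(mafs, n)), ncol = n,
                      dimnames = list(snp_ids, colnames(me)))
        B <- betas(me)
        ledger <- NULL
        for (s in specs) {
            targets <- s$targets
            if (length(targets) == 1L && grepl("^dmr", targets)) {
                tp <- truth$probes
                targets <- tp$probe_id[!is.na(tp$region_id) &
                                       tp$region_id == s$targets]
            }
            if (!all(targets %in% rownames(B)))
                stop("mqtl spec references unknown probes")
            B[targets, ] <- B[targets, ] +
                outer(rep(s$slope, length(targets)), dos[s$snp_id, ])
            ledger <- rbind(ledger,
                data.frame(snp_id = s$snp_id, probe_id = targets,
                           slope = s$slope, maf = s$maf,
                           stringsAsFactors = FALSE))
        }
        B <- .clamp01(B)
        assay(me, "beta") <- B
        ann <- probeAnnotation(me)
        snp_pos <- sample(seq(1000, max(ann$pos), by = 997),
                          length(snp_ids))
        snp_info <- data.frame(snp_id = snp_ids, chrom = "chr1",
                               pos = snp_pos, ref = "A", alt = "G",
                               stringsAsFactors = FALSE)
        ge <- GenotypeExperiment(dos, snp_info)
        truth$mqtl <- ledger
        list(methyl = me, genotypes = ge, truth = truth)
    })
}

#' Simulate a pyrosequencing candidate-locus panel
#'
#' Generates percent-methylation values for a set of candidate regions
#' (genes) with correlated CpGs within each region, a same-sample
#' duplicate-platform replicate correlated at \code{rho_tech}, a
#' second-tissue replicate correlated at \code{rho_tissue} (systemic
#' interindividual variation shared across tissues), per-assay positive
#' control replicates, and a small fraction of values perturbed beyond
#' 3 IQR from the per-CpG median and flagged, to exercise panel QC.
#'
#' @param n_regions number of candidate regions.
#' @param cpgs_per_region CpGs per region (>= 2).
#' @param n_samples samples assayed.
#' @param rho_within latent within-region CpG correlation, in \eqn{[0,1)}.
#' @param rho_tech,rho_tissue latent correlation with the platform and
#'   second-tissue replicates, in \eqn{[0,1)}.
#' @param effects optional per-region intervention effect on the percent
#'   scale (length \code{n_regions}; negative = lower in intervention arm).
#' @param outlier_frac fraction of panel cells perturbed and flagged.
#' @param n_control_reps positive-control replicates per assay.
#' @param seed RNG seed.
#' @return list with \code{panel}, \code{tech}, \code{tissue} (long
#'   data.frames: region, probe, sample, value, flag), \code{controls},
#'   \code{covariates} and \code{truth}.
#' @export
simulateCandidatePanel <- function(n_regions = 10, cpgs_per_region = 4,
                                   n_samples = 92, rho_within = 0.5,
                                   rho_tech = 0.85, rho_tissue = 0.45,
                                   effects = NULL, outlier_frac = 0.02,
                                   n_control_reps = 4, seed = NULL) {
    if (cpgs_per_region < 2) stop("per-region CpG count must be >= 2")
    for (r in c(rho_within, rho_tech, rho_tissue))
        if (r < 0 || r >= 1) stop("correlation parameters must be in [0,1)")
    if (is.null(effects)) effects <- rep(0, n_regions)
    stopifnot(length(effects) == n_regions)
    .with_seed(seed, {
        samples <- sprintf("P%03d", seq_len(n_samples))
        arm <- factor(sample(rep(c("control", "intervention"),
                                 length.out = n_samples)),
                      levels = c("control", "intervention"))
        cov <- data.frame(
            sample_id = samples, arm = arm,
            sex = factor(sample(c("F", "M"), n_samples, replace = TRUE)),
            age = stats::runif(n_samples, 8.5, 9.3),
            plate = factor(sprintf("plate%d",
                                   1L + (seq_len(n_samples) - 1L) %% 2L)),
            cell_gran = stats::rbeta(n_samples, 45, 55),
            season = factor(sample(c("dry", "wet"), n_samples,
                                   replace = TRUE)),
            stringsAsFactors = FALSE)
        rownames(cov) <- samples
        rows <- list(); t_rows <- list(); s_rows <- list()
        sigma_l <- 0.5
        for (r in seq_len(n_regions)) {
            region <- sprintf("gene%02d", r)
            mu_r <- stats::runif(1, -1.2, 1.2)
            u <- stats::rnorm(n_samples)          # region-level latent
            for (cpg in seq_len(cpgs_per_region)) {
                probe <- sprintf("%s_cpg%d", region, cpg)
                mu_c <- mu_r + stats::rnorm(1, 0, 0.2)
                z <- sqrt(rho_within) * u +
                    sqrt(1 - rho_within) * stats::rnorm(n_samples)
                z_t <- rho_tech * z +
                    sqrt(1 - rho_tech^2) * stats::rnorm(n_samples)
                z_s <- rho_tissue * z +
                    sqrt(1 - rho_tissue^2) * stats::rnorm(n_samples)
                eff <- effects[r] * (arm == "intervention")
                val <- function(zz) pmin(100, pmax(0,
                    100 * stats::plogis(mu_c + sigma_l * zz) + eff))
                rows[[length(rows) + 1L]] <- data.frame(
                    region = region, probe = probe, sample = samples,
                    value = val(z), flag = FALSE, stringsAsFactors = FALSE)
                t_rows[[length(t_rows) + 1L]] <- data.frame(
                    region = region, probe = probe, sample = samples,
                    value = val(z_t), flag = FALSE, stringsAsFactors = FALSE)
                s_rows[[length(s_rows) + 1L]] <- data.frame(
                    region = region, probe = probe, sample = samples,
                    value = val(z_s), flag = FALSE, stringsAsFactors = FALSE)
            }
        }
        panel <- do.call(rbind, rows)
        tech <- do.call(rbind, t_rows)
        tissue <- do.call(rbind, s_rows)
        # inject flagged outliers: > 3 IQR from the per-CpG median
        n_out <- floor(outlier_frac * nrow(panel))
        if (n_out > 0) {
            out_idx <- sample(nrow(panel), n_out)
            for (i in out_idx) {
                v <- panel$value[panel$probe == panel$probe[i]]
                med <- stats::median(v)
                iqr <- .iqr7(v)
                shift <- 4 * max(iqr, 1)
                panel$value[i] <- if (med <= 50) med + shift else med - shift
                panel$flag[i] <- TRUE
            }
        }
        controls <- do.call(rbind, lapply(seq_len(n_regions), function(r) {
            cv <- stats::runif(1, 0.02, 0.05)
            data.frame(region = sprintf("gene%02d", r),
                       replicate = seq_len(n_control_reps),
                       value = stats::rnorm(n_control_reps, 50, 50 * cv),
                       stringsAsFactors = FALSE)
        }))
        list(panel = panel, tech = tech, tissue = tissue,
             controls = controls, covariates = cov,
             truth = data.frame(region = sprintf("gene%02d",
                                                 seq_len(n_regions)),
                                effect = effects))
    })
}
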