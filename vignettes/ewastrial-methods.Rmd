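---
title: "Models and methods in ewastrial"
author: "ewastrial maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ewastrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ewastrial` analyses DNA-methylation outcomes of randomized nutritional
intervention trials measured on Illumina-style beta-value arrays. The
question throughout is whether a maternal micronutrient intervention,
randomized before conception, shifts methylation in the children — at
single CpGs, across short genomic regions, at targeted candidate loci
assayed off-array, and jointly across biologically motivated CpG sets
such as metastable epialleles (MEs, loci whose methylation is set
stochastically in the early embryo and is systemic across tissues) and
imprinting control regions (ICRs, parent-of-origin regulated loci near
50% methylation). Genetic confounding and moderation are addressed with
a cis-mQTL screen and genotype-by-intervention models; robustness of any
hit is probed with post hoc sensitivity analyses.

Because participant-level trial data of this kind are not publicly
deposited, the package carries a first-class synthetic-cohort generator
whose defaults emulate the data structure such a trial produces. All
calibration and power claims in the test suite are statements about
those synthetic conditions, not about any particular real cohort.

# Site-level model

For each CpG $j$ the beta value (methylation fraction, in $[0,1]$) is
regressed by ordinary least squares on the exposure plus adjustment
covariates:

$$\beta_{ij} = \alpha_j + \theta_j \cdot \mathrm{arm}_i + \gamma_j^T z_i
  + \varepsilon_{ij},$$

with $z_i$ typically sex, age, batch (plate), season of conception and
cell-type fractions (one type left out as the reference because the
fractions sum to one). The reported statistic is the two-sided $t$-test
on $\hat\theta_j$; multiplicity is controlled by Benjamini–Hochberg at
5% FDR. Betas are analysed untransformed so that effects are directly
interpretable as methylation differences; a logit (M-value-like) mode
exists but is off by default. Optional empirical-Bayes variance
moderation (via `limma::squeezeVar`) is likewise off by default: the
published FDR columns that the acceptance checks reconstruct follow from
plain BH on the raw OLS p-values, and moderation is kept only as a
fidelity option. `bhFdr()` accepts a total test count `m_total` larger
than the vector length so that a printed top list can be adjusted
against the full array size (about $8 \times 10^5$ probes).

The unadjusted effect descriptor `deltaBeta()` is
mean(intervention) − mean(control); negative values mean lower
methylation in the intervention arm, matching the sign convention of the
reported tables.

# Region-level models

Neighbouring CpGs are correlated, so two deliberately different region
statistics are computed and cross-checked; agreement between them is the
reported evidence of a differentially methylated region (DMR).

**Scan method.** Site p-values are converted to z-scores (signed by the
effect estimate when available). Their correlation is estimated
empirically as a function of genomic distance in bins of 100 bp up to a
1000 bp lag (`estimateAutocorrelation`). Sites with $p <$ `seed_p`
(default 0.05) are clustered when consecutive seeds lie within
`max_gap` (default 500 bp); every site inside the seed span is a member,
so members are contiguous. The regional p combines member p-values by
Stouffer–Liptak, $z = \sum_i z_i / \sqrt{1^T C 1}$, with $C$ read off
the distance-binned correlation estimate; a correlation matrix that is
not positive semidefinite is repaired by eigenvalue clipping (logged).
The multiplicity adjustment is Šidák on scanned footprint:
$1 - (1 - p)^{L/\ell}$ where $L$ is the total scanned extent and $\ell$
the region length (computed via `log1p`/`expm1` so that astronomically
small p-values survive). `max_gap = 500` comfortably spans the largest
intra-region gap the method is expected to bridge (a few hundred bp in
dense promoter CpG runs) without merging probes at the background
spacing of several kb.

**Kernel method.** Squared site $t$ statistics are smoothed along
position with a Gaussian kernel (bandwidth $\lambda = 1000$ bp, kernel
SD $\lambda/2$). Each smoothed statistic is a weighted sum of
approximately $\chi^2_1$ variables and is referred to a scaled
chi-square by Satterthwaite moment matching
($f = \sum \tilde w^2$, $\mathrm{df} = 1/f$ for normalized weights).
Sites passing BH $< 0.05$ on the smoothed p are grouped within
$\lambda$; regions need `min_cpgs` (default 3) members, carry an
unweighted Stouffer combination of member raw p-values, and are
BH-adjusted across regions.

Region coordinates are 1-based inclusive (manifest convention); a
536-bp region spans end − start + 1 bases. BED export is 0-based
half-open. Effect-direction consistency is reported as a flag, not
enforced.

# Candidate loci

Off-array candidate regions assayed by pyrosequencing (percent
methylation) are analysed per CpG with Huber M-estimation
(`MASS::rlm`; tuning constant $c = 1.345$ for 95% Gaussian efficiency,
MAD scale with consistency factor 1.4826, IRLS convergence $10^{-8}$,
50 iterations), adjusting for plate, age, sex, cell counts and season
where available; p-values use the asymptotic normal on the robust SE.
Per-region significance combines the member p-values with the empirical
Brown method: each CpG's data row is standardized, transformed to
$w = -2\log$ of its right-tail empirical CDF value (with an $n+1$
denominator so $w$ stays finite), and the Fisher statistic
$\sum -2\ln p_i$ is referred to a scaled chi-square whose scale and df
come from the empirical covariances of the $w$ rows
(mean $= 2k$, var $= 4k + 2\sum_{i<j}\mathrm{cov}(w_i, w_j)$; a
non-positive variance estimate is floored at $4k$, reducing to Fisher).
Perfect duplication collapses to the shared p (effective df 2);
independence recovers Fisher. BH runs across the candidate regions.

Panel QC excludes a value only when it is both more than 3 IQRs
(type-7 quantiles — stated because the rule depends on the quantile
definition) from its CpG's median *and* carries a technical flag; assay
precision is summarised as CV% over positive-control replicates.

# Enrichment of subthreshold signals

Subthreshold CpGs are those with nominal $p < 0.05$ (strict) and
$|\Delta\beta| \ge 0.02$ (inclusive). Enrichment of a CpG set is
measured by the overlap count, with significance from sample
permutation: intervention labels are permuted across samples (covariates
stay attached to their samples), the covariate-adjusted EWAS is
re-fitted in full for every permutation — the conservative reading of
the procedure — and $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\}) /
(B + 1)$. A variance-matched control set (greedy nearest-variance 1:1
matching without replacement, processed in descending target variance)
distinguishes set-specific enrichment from the inherent variability of
hypervariable loci. $B$ defaults to 10,000 in production use; scaled
runs in the tests use $B$ of 100–1000, which bounds the smallest
achievable p at $1/(B+1)$.

The permutation statistic is integer-valued, and under a pure null the
subthreshold selection retains only a handful of CpGs even at
20,000-probe scale (the joint cut *p* < 0.05 and |Δβ| ≥ 0.02 is a
roughly 3.4-sigma event per probe at n ≈ 289). Ties between the
observed and permuted overlaps plus the +1 correction therefore make
the test strictly conservative under the null: its type-I error is
well below the nominal 0.05 — the desirable direction for an
enrichment claim, but a property to know when interpreting
non-significant results. The calibration experiment reports the
realised type-I rate at the 20,000-probe reference scale.

# mQTL and gene–environment models

Genotype QC drops SNPs with exact Hardy–Weinberg $p < 10^{-3}$
(conditional exact test summing configurations no more probable than the
observed heterozygote count), MAF $< 5\%$, or missingness $> 5\%$
(boundaries kept). The mQTL screen regresses each target CpG (region
members by default) on allelic dosage plus arm and covariates,
complete-case per pair, BH across pairs; positive slopes mean each alt
allele increases methylation. The G×E screen adds a dosage-by-arm term.
`modelCompare` fits G, E, G+E and G×E with
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ (constant omitted — only
differences matter) and adjusted $R^2$, selecting the AIC minimiser.

A selection property worth knowing: under a true additive G+E model the
interaction term improves AIC whenever its likelihood-ratio statistic
exceeds 2, which happens with probability
$P(\chi^2_1 > 2) \approx 0.157$ regardless of sample size or effect
strength. Best-by-AIC therefore picks G+E in about 84% of replicates,
not more — an intrinsic ceiling of this selection rule, visible in the
reported selection rate.

# Sensitivity analyses

**Balanced resampling.** For a CpG of interest, each resample draws
without replacement $\min(n_M, n_F)$ males and the same number of
females within each arm, refits the model, and the 2.5th/97.5th
percentiles of the resampled intervention coefficients form the CI.
Note a structural property of this construction: the minority sex in
each arm is exhausted by every resample, so it contributes no
resampling variation, and with mild imbalance the percentile interval
is narrower than the sampling variability of the estimate. The interval
is a robustness descriptor — "does the effect survive forcing sex
balance" — rather than a frequentist CI; its coverage of a true effect
approaches 95% only as the imbalance grows extreme. The coverage runs
use a strongly imbalanced cohort (110M/35F vs 40M/104F) chosen from
this variance argument, and the measured coverage (mid-80s percent) is
reported as is.

**Interaction and strata.** Exposure-by-modifier interactions
(season of conception, maternal BMI, compliance) use a t-test on the
single-df interaction or a joint F-test for multi-level modifiers, BH
across CpGs. Stratified fits compare strata by
$z = (b_1 - b_2)/\sqrt{SE_1^2 + SE_2^2}$.

**SNP-in-probe flags.** Without probe strand information the 50-bp
probe footprint is approximated by a symmetric ±50 bp window (inclusive
at the boundary) around the CpG; flagged as an approximation in the
output.

# The synthetic cohort generator

`simulateCohort()` generates betas as
$\mathrm{logit}^{-1}(\mu_j + \sigma h_j \epsilon_{ij})$ — per-probe
baseline $\mu_j$ from a three-component mixture (hypo-, hyper-, and
intermediate-methylated), logit-scale noise SD $\sigma = 0.2$ with a
lognormal per-probe dispersion multiplier $h_j$ (log-SD 0.2) — then adds
intervention, cell-composition, batch and mQTL shifts on the beta scale
and clamps to $[0,1]$ (clamps are counted and logged). The logit-scale
noise keeps values in range and produces the heteroscedasticity real
arrays show; $\sigma = 0.2$ puts per-probe beta SDs around 0.03–0.08,
matching the interquartile ranges such arrays report, and makes the
designed effect sizes produce top-hit p-values of realistic magnitude
at $n \approx 289$. Setting `noise_sd = 0` gives deterministic betas —
useful for construction oracles.

Hypervariable (ME-like) probes draw a per-sample component from a
two-state mixture (around beta 0.25 / 0.75); the shared-component
construction also drives the cross-tissue replicate of the candidate
panel, which is what makes systemic interindividual variation testable.
Intermediate (ICR-like) probes sit near beta 0.5 with low variance.
Genotypes are Hardy–Weinberg at the stated MAF and independent of arm
(randomization); mQTL targets gain slope × dosage before clamping.

The Gambian-like preset uses the per-arm sex counts 64M/74F
(intervention) and 93M/58F (control), $n = 289$; six true DMPs with
effects −0.025..−0.050; one 10-CpG region (150 bp spacing, effect
−0.03) and one 4-CpG region; ME/ICR classes at 2.5% of probes each
(the full-array class sizes scaled to the default 20,000-probe matrix);
and one cis-mQTL of slope 0.03 per allele at MAF 0.3. The Indian-like
preset has $n = 686$ (168/153, 209/156), no true effects and no season
covariate. The candidate-panel generator uses within-region latent
correlation 0.5, platform-replicate correlation 0.85 and cross-tissue
correlation 0.45, which put the Spearman concordances in the 0.8–0.9
and 0.36–0.50 bands at $n = 92$.

What the generator does *not* emulate: probe-level detection physics
(detection failures are Bernoulli draws), dye or normalization
artifacts, genomic correlation of baseline methylation outside the
designed regions, linkage disequilibrium between SNPs, and population
structure. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under these conditions; they do not
certify behaviour under artifacts the generator omits.

# Numerical choices and degenerate inputs

- p-values of exactly 0 are clamped at $10^{-300}$ before probit or log
  transforms (logged); the Šidák adjustment uses `log1p`/`expm1`.
- Non-PSD correlation matrices are repaired by eigenvalue clipping at
  $10^{-8}$ with a message.
- IQRs are type-7 throughout, stated wherever a 3×IQR rule depends on
  it.
- Sex prediction in sample QC is a deterministic 1-d 2-means (centers
  initialised at the extremes), because sex-chromosome probes are
  excluded from the analysis matrix and only summary intensities are
  available.
- BH with `m_total` > length(p) supports adjusting printed top lists;
  ties are handled by stable ordering.
- Single-CpG candidate regions pass their robust-fit p through
  unchanged; empty scan results are legal (empty `GRanges`).
- Constant-response model comparison reports $R^2 = 0$ and $-\infty$
  AIC without error.

# Problem sizes used by the tests and the acceptance script

Null BH calibration: 200 cohorts of 20,000 probes × 289 samples in the
test suite (100 in the acceptance script). Permutation type-I: 200
cohorts of 5,000 probes at B = 100 in the test suite (120 in the
script).
Effect recovery: 100 cohorts of 400 probes; mQTL recovery: 30 cohorts.
Region recovery: 100 cohorts of 1,000 probes.
Model selection: 200 replicates at n = 289.
Coverage: 150 cohorts, 1,000 resamples each.
Concordance: 30 panels at n = 92.
These sizes make the full suite run in well under half an hour on a
single core while keeping Monte-Carlo error small relative to every
asserted margin.

# Known limitations

- The scan and kernel callers are this package's own implementations of
  the two published approaches' ideas (autocorrelation-corrected
  combination with Šidák adjustment; kernel smoothing with
  Satterthwaite calibration), not byte-compatible reimplementations of
  any external tool.
- Surrogate-variable-style latent covariate estimation is out of scope;
  principal components of the beta matrix are the offered alternative.
- The balanced-resampling CI undercovers by construction (see above).
- Best-by-AIC model selection carries the ~16% interaction-overfit rate
  noted above.
- No imputation anywhere: missing betas are complete-case per probe,
  missing dosages complete-case per pair.
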