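---
title: "telomr: methods, modelling choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{telomr: methods, modelling choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomr)
```

# The problem

Leukocyte telomere length (LTL) is a blood-derived marker of cellular
aging that correlates observationally with a broad swath of traits and
diseases. Observational correlation conflates causation in either
direction with confounding; two-sample Mendelian randomization (MR)
uses genetic variants as instruments to separate these, and
multivariable MR (MVMR) quantifies how much of a trait's effect on an
outcome flows *through* LTL. telomr implements this entire chain, plus
the observational cohort arm, against either real summary-statistics
files or a synthetic world with known causal structure.

# Summary-statistics model and harmonization

A summary-statistics table carries, per variant: identifier, GRCh37
coordinates (1-based, autosomes only), effect/other allele, effect-allele
frequency, effect size (per-SD for continuous traits, log OR for binary),
its SE, p-value, and sample size. Harmonization against a reference
panel (1) drops variants absent from the panel, (2) drops palindromic
variants (A/T, G/C — strand is unresolvable across studies), (3)
recodes strand-flipped variants (alleles matching only after
complementation), and (4) flips `beta -> -beta`, `eaf -> 1 - eaf` where
effect and other allele are swapped relative to the panel. For
non-palindromic biallelic variants these four cases are mutually
exclusive, which makes the operation idempotent — a property test
asserts it. Variants matching under neither interpretation are dropped.

Effect standardization puts every trait on the explained-variance
scale: with z = beta/se, the standardized effect is
r = z/√(z² + n − 2), whose square is the variance a standardized trait
shares with the variant in a univariate regression, and whose SE is
1/√(z² + n − 2). This preserves z exactly and is the scale on which
Steiger comparisons are made. Difference traits (e.g. reproductive
lifespan = age at menopause − age at menarche) are built by
back-transforming both GWAS to the year scale with the phenotype SDs,
differencing, adding SEs in quadrature, and taking n as the smaller of
the two studies; p-values use the normal approximation to the
t-statistic, justified at GWAS sample sizes.

# Instrument selection

Clumping is greedy: candidates are variants at p < 5e-8 (and below the
index threshold p1 = 1e-4); the best remaining candidate becomes an
index and absorbs every variant with p < p2 = 0.01 within 250 kb at
r² ≥ 0.01. Only index variants are reported as instruments. Ties on p
break by position then identifier, so output is deterministic. Pairs
missing from the LD matrix count as unlinked, with a warning — this
mirrors reference-panel coverage gaps. A naive, separately-written
oracle transcription of this rule is compared against the
implementation on 100 random instances in the test suite.

Boundary semantics are taken literally from the published inequalities:
allele-frequency discordance removes at a difference **≥ 0.05**;
Steiger filtering removes at **Z ≤ −1.96**, where
Z = (atanh|r_exp| − atanh|r_out|)/√(1/(n_exp−3) + 1/(n_out−3));
candidate inclusion requires **p < 5e-8** strictly. The HBB mask
(chr11:5,246,696–5,248,301) exists because that gene is the technical
control in qPCR telomere measurement; the HLA mask
(chr6:25,000,000–37,000,000) removes the region's long-range LD. Both
are 1-based inclusive.

The multi-trait Steiger filter generalizes directionality filtering
into a pleiotropy filter: an instrument survives only if its Steiger
comparison against *every* trait in a panel stays above the threshold,
and instruments absent from any panel trait are excluded (the presence
requirement is why candidates must be harmonized across the panel
before clumping). Two bespoke clumping schemes feed MVMR: the
*two-phase* scheme for mediation (exposure instruments clumped alone,
then pooled with mediator candidates with exposure variants ranked
strictly first, so a correlated mediator candidate can never displace
an exposure instrument regardless of p) and the *minimum-rank* scheme
for multi-exposure MVMR (per-exposure p ranks, minimum across
exposures, greedy clumping in that order; ties by smaller minimum p,
then identifier).

# Estimators

IVW is the weighted zero-intercept regression with weights 1/se_out².
We default to the multiplicative random-effects variance — SE scaled by
√max(1, Q/df) — matching the common default of widely used MR software;
a fixed-effect flag is available, and with one instrument IVW reduces
exactly to the Wald ratio. MR-Egger adds an intercept after orienting
all exposure effects non-negative (without a fixed orientation the
intercept is not identifiable); its slope is the pleiotropy-adjusted
effect and its intercept the average directional pleiotropy, df = k − 2.
The weighted median takes the 50% point of the inverse-variance-weighted
empirical distribution of Wald ratios; the mode estimators take the
argmax of a kernel density of ratios with a MAD-based bandwidth
0.9·MAD·k^(−1/5) times a user factor — a deliberate, scale-robust analog
of the normal-reference rule. Median and mode SEs come from a seeded
parametric bootstrap (default 1000 draws); ratio SEs use the
first-order delta method se_out/|beta_exp| with a second-order option.
All p-values use the normal approximation — at GWAS instrument counts
and sample sizes the t correction is immaterial, and it keeps the two
directions symmetric.

Egger has one structural caveat the synthetic experiments surfaced:
with equal-magnitude instruments there is no spread in instrument
strength, the slope is unidentified, and the intercept absorbs the
slope offset. The estimator-recovery tests therefore use the
normally-distributed effect world for Egger; this is a property of the
model, not of the implementation.

# MVMR and mediation

MVMR is the weighted zero-intercept multiple regression of outcome
associations on the exposure-association matrix (weights 1/se_out²),
with the same multiplicative over-dispersion (df = k − p) and a hard
error naming collinear exposures on rank deficiency. Conditional
instrument strength for exposure j regresses its associations on the
other exposures' (weights 1/se_exp_j²) and converts the residual
chi-square Q_j with df = k − (p − 1) to F = max(0, (Q_j − df)/df); with
one exposure this reduces to the mean per-instrument F = mean(z²).
Values below ~10 flag weak-instrument bias.

Mediation through LTL computes: the total effect (IVW of exposure on
outcome over the exposure instruments), the direct effect and mediator
path from the two-exposure MVMR over the pooled two-phase instruments,
the indirect effect by *difference* (total − direct, an identity that
holds to machine precision by construction) and by *product*
(α̂_{E→M}·θ̂_M, delta-method SE √(α²se_θ² + θ²se_α²)). Steiger filters
apply exactly as published: exposure instruments against both mediator
and outcome, mediator instruments against the outcome.

The regression-dilution correction divides a slope by the reliability
ratio λ = var_signal/(var_signal + mean(se_exp²)) with
var_signal = max(var(beta_exp) − mean(se_exp²), ε); λ ∈ (0, 1], and a
floored signal variance is flagged rather than extrapolated. The cited
reference's exact estimator is not reproduced in the source material,
so this operationalization is validated by a bias-reduction property
test (corrected slopes are closer to truth than uncorrected over 200
replicates), not by value matching. Because the published methods are
ambiguous about whether the correction applies to one or both mediation
strategies, telomr applies it to the product-method factors only: the
difference method's defining identity would otherwise break. The
product-versus-difference consistency check is correspondingly run on
the uncorrected estimators.

The mediation proportion P_M = 100·α_indirect/α_total gets its 95% CI
from the 2.5th/97.5th percentiles of 10,000 simulated ratios with both
numerator and denominator drawn from their estimated normal sampling
distributions; the upper limit — and the point estimate — are capped at
100%. Negative ratios are reported uncapped with a sign flag (the
source is silent; masking the sign would hide pathology). A total
effect within 2 SE of zero flags the ratio distribution as unstable
rather than suppressing the result. The network constructor runs one
MVMR per ordered trait pair with all remaining traits as co-exposures
over minimum-rank instruments, keeping nominally significant edges and
tiering them at the strict threshold — a deterministic reading of an
"iterative" procedure that the source does not specify
algorithmically.

# The observational arm

LTL is residualized on age, age², genotyping array, sex, and the sex
interactions with each, then re-standardized; residual orthogonality to
every design column is asserted at |r| ≤ 1e-10. Traits (binary ones
included) are standardized before single-trait regressions, so slopes
are SD_LTL/SD_trait (age is reported per year). Outliers in continuous
traits are removed at mean ± 5 SD. Serum lipids of cholesterol-lowering
drug users are shifted by the average simvastatin effect (+1.6, +1.4,
+0.4, −0.1 mmol/L for TC, LDL, TG, HDL). Normal-approximation p-values
are used above n = 200, the exact t below.

Lasso stability selection fits 50 cross-validated Lasso regressions of
unadjusted LTL on the complete-case candidate matrix, re-randomizing
the 10-fold assignment each fit (the fold count is unstated in the
source; 10 is the community default), takes lambda by the one-SE rule,
and keeps traits selected in ≥ 95% of fits; explained variance comes
from a joint OLS refit. Candidates must have < 7% missingness by
default. The effective number of tests is the smallest k such that the
k largest eigenvalues of the trait correlation matrix capture 99.5% of
the total variance — our reading of the cited eigenvalue rule —
with negative eigenvalues from pairwise-complete estimation clipped at
zero.

The reproductive-phase model splits each woman's age into years before
first live birth, premenopausal years after first birth, and
postmenopausal years, plus parity and menopause indicators. The phase-1
origin is unstated in the source; we measure it from birth
(t1 = min(age, age at first birth)), letting the intercept absorb
pre-adult effects — the linear model is anyway acknowledged not to
capture the pre-18 change in decline rate. Exclusions follow the
published list (first child post-menopause, missing menopausal status
or age, missing childbirth information), plus any record implying a
negative duration.

# The synthetic world

`sim_config()` defaults *are* the package's stated world: a mediation
structure with α_EM = 0.5, θ_M = 0.3, θ_direct = 0.35 (total effect
0.5, P_M = 30% — the planted recovery target), 50 AR(1) LD blocks
(ρ = 0.5) of 4 variants, 20,000 samples per study, two-sample design
(overlap 0), exposure heritability 0.15 on its causal block leads so
instruments clear genome-wide significance, and no pleiotropy or
reverse causation unless requested. Cohort defaults mirror the
published cohort: ages uniform on [40, 70), 54% women, sex-specific age
slopes −0.025/−0.021 SD/year, female phase slopes
(−0.014, −0.017, −0.022) SD/year, mean age at first birth 26 and at
menopause 50, residual noise SD 1 (LTL is deliberately left
unstandardized so planted slopes are exact regression targets). Parity
and menopause indicator effects (−0.03, −0.02 SD) are unpublished;
modest negative values were chosen once as plausible and are recovered,
not asserted.

The analytic backend samples marginal estimates from their asymptotic
distribution per LD block, β̂ ~ N(Rβ, R/n), with cross-study noise
correlation equal to the sample-overlap fraction (the first-order
behavior of overlapping cohorts); the individual-level backend draws
standardized genotype dosages per block and regresses simulated
phenotypes variant by variant. A cross-agreement test holds the two
backends to the same IVW answer. Directional pleiotropy is planted
relative to the exposure-increasing allele — under the Egger
orientation convention a mean defined on arbitrary allele coding is not
directional at all.

What the synthetic world does **not** emulate: real MAF spectra and LD
from sequenced panels, liability-scale binary traits, assortative
mating or population stratification, winner's curse from discovery in
the same sample, or the actual 166-trait phenome. A green recovery test
establishes that the estimators and filters implement their
definitions correctly and are calibrated under the stated generative
model — not that the published effect estimates are reproduced; those
require restricted individual-level data and consortium GWAS downloads.

# Numerical choices

- Printed inequalities are enforced verbatim (≥ 0.05 removal,
  Z ≤ −1.96 removal, p < 5e-8 inclusion); boundary tests pin each.
- Generator p-values are floored at 1e-320 (extreme z underflows
  `pnorm` to 0, which would violate the p ∈ (0, 1] invariant).
- Clumping ties break by p, then position, then identifier; minimum-rank
  ties by minimum p, then identifier. Output is deterministic.
- All bootstraps and simulations take explicit seeds and restore the
  caller's RNG state; a fixed config reruns byte-identically.
- Standardization and the difference-trait p-values use the normal
  approximation (sample sizes ≫ 30 by construction); the observational
  arm switches to the exact t below n = 200.
- `effective_tests` symmetrizes its input and clips negative
  eigenvalues at zero with a warning rather than failing on
  pairwise-complete correlation matrices.

# Known limitations

- Binary outcomes are analyzed on the log(OR) scale with no
  liability-scale conversion, matching the published convention.
- MR-PRESSO and MR-APSS are external methods the published analysis
  calls and are out of scope here, as are genome-build conversion,
  multi-allelic variants, and chromosomes X/Y.
- The dilution-correction form and the network iteration order are
  package operationalizations of under-specified procedures; both are
  documented above and validated by property tests only.
- With very few instruments the mode estimators' bandwidth rule
  degenerates (MAD of ratios can be 0); the estimator then returns the
  common ratio, which is the correct degenerate answer.
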