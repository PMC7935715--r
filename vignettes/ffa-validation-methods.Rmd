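---
title: "Models and methods behind ffasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ffasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ffasim` is a desk-scale simulation and analysis toolkit for studying
fetal fraction amplification (FFA) in whole-genome-sequencing based
noninvasive prenatal screening (NIPS). It generates synthetic cell-free
DNA (cfDNA) cohorts with known latent truth, applies an in-silico analog
of molecular fragment-size selection, and pushes both protocol arms
through the same screening and performance-modelling machinery a clinical
pipeline would use. This vignette documents the models, the tunable
parameters, the numerical choices, and — importantly — what the synthetic
cohorts do and do not say about real patient data.

## The generative model

### Scaled genome

Real WGS-based NIPS counts fragments in bins of tens of kilobases across
the genome at tens of millions of reads per sample. To make thousands of
simulated samples cheap, `build_genome()` scales every GRCh38 chromosome
by `1/genome_scale` (default 1/1000) and partitions it into fixed-width
bins (default 50 scaled bp, i.e. 50 kb-equivalent; ~62,000 bins in
total). Relative chromosome sizes are preserved because they set the
number of bins per region and hence the counting variance of each
region's mean depth — the quantity that drives z-score behavior.
Coordinates are 0-based half-open; trailing partial bins are dropped.
The region table carries every whole chromosome (chr13/18/21 classed as
common aneuploidies, other autosomes as rare autosomal aneuploidies) and
named microdeletion intervals (defaults: a 3 MB-equivalent 22q11.2
interval and a 3 MB-equivalent 5p15 interval).

The production bin width and genome build of any particular clinical
pipeline are not modelled; the scaled genome is a declared stand-in whose
purpose is statistical shape, not coordinate fidelity.

### Two-compartment counts

Each sample is a mixture of maternal and fetal (placental) fragments.
For a sample with fetal fraction $\mathrm{FF}$, the expected count of bin
$i$ is

$$\lambda_i \;=\; N \cdot \frac{w_i}{\sum_j w_j}, \qquad
  w_i \;=\; \Big[\mathrm{FF}\,\tfrac{c^{f}_i}{2} +
  (1-\mathrm{FF})\,\tfrac{c^{m}_i}{2}\Big]\; t_i ,$$

where $c^f_i, c^m_i$ are fetal and maternal copy numbers (maternal fixed
at 46,XX; fetal set by the karyotype: trisomy 3, deletion 1, and the
sex-chromosome configurations for XX/XY/MX/TX/XXY/XYY), $N$ is the
per-sample depth and $t_i$ is a planted depth tilt described below.
Counts are Poisson per (bin, compartment); a negative-binomial option
(`overdispersion > 0`) exists because production data are overdispersed,
but the default is the simplest law consistent with the z-score
machinery. Immediate consequences used throughout the tests: a disomic
bin has expected depth ratio 1, chrY in a male pregnancy has ratio
$\mathrm{FF}/2$, a trisomic chromosome $1+\mathrm{FF}/2$, a fetal
deletion $1-\mathrm{FF}/2$.

Two realism terms are added:

* **chrY mapping background.** Real pipelines see a small, library-specific
  chrY signal in female-fetus pregnancies from mis-mapped reads. Each
  library draws a relative chrY floor
  $\varepsilon \sim \mathrm{LogNormal}(\log 0.002,\, 0.3)$ added to the
  maternal compartment on chrY. Without it the female
  $\mathrm{FF}_{chrY}$ distribution would be a point mass at zero and the
  sex-call model (normal fit to female values) would be degenerate.
  `estimate_ff_chry()` accepts a `background` to subtract; the screening
  pipeline estimates it from pooled XX controls.
* **FF-correlated autosomal tilt.** The depth-based FF regression needs a
  genuine autosomal signal to learn. The generator multiplies bin
  expectations by $t_i = 1 + \gamma\,\mathrm{FF}\, s_i$ with a fixed
  mean-zero signature $s_i \sim N(0, 0.15^2)$ (seeded independently of the
  cohort, autosomes only) and $\gamma = 6$. Two deliberate choices here:
  the amplitude is large enough (roughly a GC-wave-sized ±10% modulation
  at typical FF) that a ridge with ~60k features can learn it from ~100
  training samples, and the signature is **projected orthogonal to every
  screened region**, so region mean ratios — and therefore z-scores — are
  provably unaffected by the planted signal. The real autosomal FF
  signature (fragment-start and coverage biases) is unpublished; this
  surrogate exists to enable parameter-recovery tests of the regression,
  nothing more.

### FF, BMI and karyotypes

BMI is lognormal ($\log\mathrm{BMI} \sim N(\log 26.5, 0.22^2)$) and FF
follows

$$\log \mathrm{FF} = a - b\,\mathrm{BMI} + \epsilon,\qquad
  \epsilon \sim N(0, \sigma^2),$$

clipped to $[0.005, 0.5]$, with defaults $a = -1.6348$, $b = 0.0252$,
$\sigma = 0.478$. These were fixed once, by a grid search anchored at a
median FF of 10% at the mean BMI, against two published operating
characteristics of standard-protocol screening: ~3.7% of samples below
the 4% low-FF threshold overall and ~16% below it among patients with
BMI ≥ 40. The lognormal-with-linear-log-mean family is one of many
consistent with those two rates; nothing downstream depends on the exact
family.

Karyotypes are drawn from configurable class frequencies. Positive
samples have their FF floored at `positive_ff_min` (default 0.03): a
validation cohort sources its positives from previously screened
repository samples, which are by construction detectable and FF-biased —
the exact bias the two-phase ROC model is designed to undo. Each batch
additionally carries no-template controls (NTC; expected count
`ntc_rate * depth`, contamination only) and pooled XX / XY controls
(euploid, aggregate FF = `pooled_ff`, default 0.10 — the pooled-control
FF of real assays is not published). Multiple gestations are excluded.

### What the generator does *not* emulate

Maternal CNVs, confined placental mosaicism, vanishing twins, GC waves
and their correction, mappability structure, PCR duplication, and
batch-level depth drift. Tests that pass on these cohorts demonstrate
the internal consistency and statistical calibration of the machinery —
estimator unbiasedness, null calibration, gain laws, model recovery —
not clinical performance on real plasma.

## In-silico size selection

Fragment lengths are a two-component mixture: fetal
$N(143, 18^2)$ and maternal $N(167, 20^2)$, truncated to positive
lengths. At low FF the pre-selection mean is ~165 nt. The published
means (165 pre-selection, 140 post-selection) are the only hard numbers
available; the component SDs are literature-typical defaults and
overridable. Selection retains a fragment of length $\ell$ with
probability $R(\ell)$ — a hard cutoff $\mathbf{1}[\ell \le L]$ by
default (it makes the gain oracle closed-form), or a logistic window,
since gel elution is not a step function. Per-compartment retention
probabilities are

$$r_c = \int R(\ell)\, f_c(\ell)\, d\ell,$$

and `solve_cutoff_for_target_mean()` bisects on $L$ (monotonicity of the
conditional retained mean is asserted first) until
$E[\ell \mid \text{retained}] = 140 \pm 0.1$ nt. The fetal fraction then
transforms as

$$\mathrm{FF}' = \frac{\mathrm{FF}\, r_f}
  {\mathrm{FF}\, r_f + (1-\mathrm{FF})\, r_m},$$

with gain $\mathrm{FF}'/\mathrm{FF}$ strictly decreasing in FF,
approaching $r_f/r_m$ as $\mathrm{FF} \to 0$ — low-FF samples benefit
most. At the defaults $r_f/r_m \approx 3$, so cohort-level mean gains
come out near 2.5× with the largest gains at low FF.

`apply_size_selection()` thins each compartment binomially and, with
`reamplify = TRUE`, re-amplifies to the target depth by multinomial
resampling. For paired protocol comparisons,
`simulate_paired_cohorts()` re-draws each sample's library independently
at `depth * library_oversample` (default 20×) molecules before thinning:
cfDNA libraries are molecule-rich relative to sequenced reads, so
selection changes the *composition*, not the effective counting depth,
and the two arms are compared like-for-like. Thinning the sequenced
reads themselves would roughly double post-selection counting variance
and understate the z-score benefit.

`bioinformatic_weighting()` implements the downstream alternative —
weighting each sequenced fragment by a function of its length — and with
an indicator weight reproduces hard molecular selection without
re-amplification.

## Fetal fraction estimators

`normalize_depth()` divides each bin's depth by a 1%-trimmed mean of the
sample's autosomal per-bin depth. A trimmed mean (rather than the
median) keeps robustness to isolated outlier bins while remaining
continuous: at desk-scale depth the per-bin counts are small integers and
a median normalizer is discrete, which biases every ratio
multiplicatively by up to several percent (on chrY, whose per-bin
expectation is below 1 at default depth, a median summary would simply
be zero). Region summaries are means for the same reason.

Three estimators:

* $\mathrm{FF}_{chrY} = 2 \times$ mean chrY ratio (optionally background-
  corrected), delta-method standard error from the implied count total.
* $\mathrm{FF}_{positive} = 2\,|\text{mean region ratio} - 1|$ for a
  sample known (or hypothesized) to be aneuploid in that region, with the
  observed sign checked against the gain/loss hypothesis.
* A SeqFF-style ridge regression of $\mathrm{FF}_{chrY}$ labels on
  autosomal bin ratios, trained on ≥50 male-fetus euploid samples
  (`glmnet`, $\alpha = 0$, default $\lambda = 0.1$ chosen by held-out
  performance on synthetic cohorts at the default tilt). Once trained it
  applies to either fetal sex; the production regressions of clinical
  pipelines are unpublished, so this is a declared stand-in with the
  same interface.

## Screening

`build_reference()` computes per-region mean/SD of the mean depth ratio
over ≥10 euploid reference samples; `region_z()` standardizes, flipping
the sign for loss-type regions so more positive always means more
evidence; `call_regions()` thresholds at per-class cutoffs (default 4.0
for every class — published figures show a single cutoff line without
printing the value; the tie at exactly the threshold calls positive).
Euploid z-scores are standard normal by construction, which the tests
verify by Kolmogorov–Smirnov and by the empirical false-positive rate at
z = 3 against $1 - \Phi(3)$.

Sex and sex-chromosome aneuploidies use the two-dimensional plane
(chrX deviation $d_X = 2(1 - \text{mean chrX ratio})$,
$f_Y = \mathrm{FF}_{chrY}$), where the six hypotheses sit at
XX $(0,0)$, XY $(\mathrm{FF},\mathrm{FF})$, MX $(\mathrm{FF},0)$,
TX $(-\mathrm{FF},0)$, XXY $(0,\mathrm{FF})$, XYY
$(\mathrm{FF},2\mathrm{FF})$. A sample is assigned to the nearest
hypothesis within a tolerance band
$\tau = \max(0.35\,\mathrm{FF}, 0.01)$ (max-norm); ambiguity or no match
yields a no-call. The baseline FF must come from an instrument
independent of $d_X$ and $f_Y$ (the regression, by default trained
on-the-fly from the cohort's own male euploids) — using the observed
deviations themselves would place the MX/TX hypotheses exactly on the
noise. With fewer than 50 male euploid training samples the pipeline
falls back to a gated heuristic: chrY carries the male-side hypotheses
and a female-side SCA call requires $|d_X|$ to clear three tolerance
floors. At the default desk-scale depth (5×10⁵ fragments) the chrX
counting noise is a visible fraction of FF, so borderline SCA samples
no-call or miscall more often than a production assay would; the
calibration tests therefore fix FF = 0.12 where the geometry is clean.

## The two-phase ROC model

Validation cohorts contain few, FF-biased positives, so sensitivity
cannot be read off the confusion table. The model's training phase
fits, by MCMC, how positive z-scores scale with FF and depth:

$$z \sim N\!\big(\beta\, \mathrm{FF} \sqrt{N/N_0},\ \sigma_z\big),
 \qquad \beta \sim \mathrm{HalfNormal}(200),\quad
 \sigma_z \sim 1 + \mathrm{HalfNormal}(2).$$

The form follows from the Poisson z-statistic (signal ∝ FF, noise ∝
$1/\sqrt{N}$) and is the minimal faithful choice; $\sigma_z \ge 1$
because a positive cannot be less noisy than the standard-normal null.
The sampler is a self-contained component-wise adaptive random-walk
Metropolis–Hastings (per-parameter scales tuned during burn-in toward
~30% acceptance; $\sigma_z$ proposals reflect at the boundary, which
preserves detailed balance), 4 chains × (2000 burn-in + 8000 kept) by
default, with split-chain potential scale reduction required < 1.05.
Within a single region z and $\mathrm{FF}_{positive}$ derive from the
same ratio, so $\sigma_z$ concentrates near its boundary — the
component-wise reflected sampler was adopted precisely because a joint
fixed-shape proposal mixes poorly there.

The simulation phase draws mock positives from the posterior and from
*population* FF and depth distributions (undoing the cohort bias), mock
negatives from the standard normal null, and sweeps thresholds to give
sensitivity/specificity with percentile intervals over posterior draws.
Sensitivities at the calling threshold land in the high-90s-to-100%
range for whole chromosomes and somewhat lower for 3 MB-equivalent
microdeletions, with FFA dominating the standard arm at every
specificity — the mechanism, not any published cohort's numbers, is the
reproduction target, because those numbers encode an unavailable
clinical cohort's FF and depth distributions. SCAs are excluded from
the ROC model (they rely on two regions jointly); they use plain
confusion-matrix metrics.

## The sex-call model

Per protocol arm, a normal is fitted to female $\mathrm{FF}_{chrY}$
(plain moments; no truncation — mass below zero is part of the model
error, as the female values are raw and may be negative after
normalization noise) and a beta (maximum likelihood, method-of-moments
start) to male values clipped into $(0,1)$ by machine epsilon. With
equal sex priors the expected miscall rate at threshold $y$ is

$$\mathrm{rate}(y) = \tfrac12\big(1 - \Phi\big(\tfrac{y-\mu_F}{\sigma_F}\big)\big)
 + \tfrac12 I_y(a, b),$$

minimized over a $10^4$-point grid refined by golden-section search
(ties toward smaller $y$; the tests check the optimizer against a
$10^6$-point brute force). `compare_protocols()` reports the ratio of
optimized rates across arms with a parametric-bootstrap interval; a zero
FFA-arm rate is reported as a bound at the numeric floor rather than
infinity. Because FFA shifts the male beta away from the female normal,
the fold reduction is large but seed-dependent (hundreds at the default
conditions) — a mechanism statement, not a cohort estimate.

## Problem sizes and numerical choices

The test suite and the acceptance script choose sizes that keep every
experiment within seconds to a few minutes on one CPU: cohorts of
80–250 samples, 5×10⁵ fragments per sample for estimator calibration
(where per-bin counts of ~8 match the information content the estimators
are designed for), and 2.5×10⁷ fragments (~400 per bin,
production-like) for the paired FFA-dominance and microdeletion
conversion experiments, where the interesting contrast lives near the
calling threshold. Monte Carlo assertions use 3–4 standard-error bands;
exact assertions (ROC recounts, confusion metrics, round-trips) use
equality. Reduced MCMC chain lengths (4 × (500 + 1500)) are used in
recovery tests; the 95% credible interval at n = 40 positives has ~93%
frequentist coverage (a small-sample effect, not a sampler artifact),
consistent with the ≥18/20 coverage the tests require.

## Known limitations

* Poisson counts understate real overdispersion; the negative-binomial
  switch exists but no published dispersion estimate anchors it.
* The planted regression signature is a surrogate; regression quality on
  real data cannot be inferred from its recovery here.
* The 2D SCA caller is noisy at desk-scale depth (see above).
* Gain figures saturate at $r_f/r_m \approx 3$ under the default length
  mixture; assays whose true retention curves differ will scale
  differently.
* The ROC model pools regions within a class under equal weights by
  default; incidence weighting is available but no published weighting
  rule exists to match.
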