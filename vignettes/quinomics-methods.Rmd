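---
title: "Methods: differential multiomics of a carbon-source shift"
author: "quinomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential multiomics of a carbon-source shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quinomics)
```

# Scope and model of the experiment

quinomics implements the statistical core of a two-condition bacterial
multiomics comparison: untargeted LC/MS metabolomics with six biological
replicates in the reference condition (A, succinate in the bundled study
configuration) against four in the perturbed condition (B, quinate), each
injected twice as analytical replicates, alongside duplicate-library
RNA-seq counts for roughly 3,300 genes. Raw spectra, peak picking and read
mapping are upstream of the package: the inputs are a feature table of
peak areas per injection, a compound library, nucleotide calibration
series and a gene count table.

The package ships a synthetic-data generator that reproduces the
statistical structure of this design so that every stage of the pipeline
is testable end to end without instrument data. The generator is a model
of the experiment, not of the instrument: what the tests demonstrate is
that the statistical machinery behaves as specified *under that model*
(see "What the simulations do and do not show").

# The pipeline, stage by stage

## Feature curation

Blank (culture-medium) subtraction drops any feature whose mean blank
area reaches half its mean sample area (closed threshold, configurable);
the drop list is retained for audit, because curation steps in this kind
of study are otherwise invisible to a reader of the final tables.

Redundant ion signals — isotopologues, adducts, dimers and in-source
fragments of one metabolite — are collapsed into feature groups. Two
features are linked when they co-elute (default window 10 s), their m/z
pair is explained by one neutral mass under two electrospray ion-species
rules within 10 ppm (default rule set: `[M+H]+`, `[M+Na]+`, `[M+NH4]+`,
`[M+K]+`, `[2M+H]+`; `[M-H]-`, `[M+Cl]-`, `[2M-H]-`) or by the isotope
spacing 1.003355 Da with the lighter peak more intense, and their
intensity profiles agree. Transitive closure forms the groups; each group
is represented downstream by its most intense member ion and its inferred
neutral mass.

Two numerical choices matter here:

* **Correlation scale.** Intensity noise is multiplicative, so profile
  correlation is computed on log intensities. It is also computed on
  *within-condition residuals*: two different metabolites that both
  respond to the carbon source correlate strongly through the condition
  means alone, and centering each condition removes exactly that
  confounder while preserving the replicate-level covariation that ions
  of a single metabolite share.
* **Two floors.** For pairs already explained by a mass rule the
  correlation gate only needs to veto clearly unrelated profiles; its
  floor is 0.3. Pairs with no mass explanation can join a group only on
  correlation evidence (putative in-source fragments) and face a strict
  0.9 floor. Undefined correlations (constant profiles, fewer than three
  complete pairs) do not block a mass-explained link — a constant profile
  carries no evidence against co-origin, and in the zero-noise limit all
  profiles are constant.

Grouping is order-invariant (features are sorted before the union-find
pass) and ties in species assignment are broken deterministically
(cluster explaining most members, then the one containing the
representative, then smallest neutral mass).

## Replicate quality control

The relative standard deviation (sample standard deviation over mean,
percent) is computed between analytical replicates per biological
replicate, and between injection-averaged biological replicates per
condition. RSDs are undefined — reported as missing, never as zero —
for fewer than two values or a zero mean. A biological RSD at or above
40 % (closed bound) flags the group for manual review; flags annotate
only, mirroring the manual-verification practice of this kind of study,
and nothing is dropped automatically. Biological RSD is computed after
injection averaging; whether the original workflow averaged first is not
documented, so the package fixes the order and states it.

## Differential abundance with Fieller intervals

For each group the point estimate is the ratio of detected-replicate
means, condition B over A. Zeros are treated as "not detected",
indistinguishable from missing cells, because absence calls in the source
workflow do not separate the two.

The confidence interval for the ratio of two means with unequal variances
inverts the t statistic for $\bar x - \rho \bar y$ (Fieller's method):

$$(\bar y^2 - t^2 s_y^2/n_y)\,\rho^2 - 2\bar x \bar y\,\rho +
  (\bar x^2 - t^2 s_x^2/n_x) \le 0,$$

with the Welch–Satterthwaite degrees of freedom evaluated at the point
estimate (plug-in). When the leading coefficient is non-positive the
denominator mean is not bounded away from zero at the confidence level
and the set is unbounded; infinite bounds are reported rather than
silently truncated. The plug-in convention makes the interval a
closed-form quadratic; the test suite quantifies its deviation from a
fully local-df inversion (median relative bound difference below 15 % in
the 6-vs-4 design) and verifies the closed form against an independent
numeric inversion to 1e-6.

The significance test is a two-sided Welch t-test on untransformed
intensities (a log-scale option exists via `test_scale = "log"`; which
scale the original analysis used is not documented). Classification uses
the study's rule: *increased* requires a ratio of at least 3 with
p < 0.05, *decreased* a ratio of at most 1/3 with p < 0.05. A condition
with no detections against at least three detected replicates on the
other side yields an *exclusive* call (the infinite fold-change
convention); fewer than three guards against single-replicate artifacts
and yields *unevaluable*. No multiple-testing correction is applied to
metabolites by default — the rule is a raw-p threshold — with
Benjamini–Hochberg available behind `multiple_testing_method = "BH"`.

## Identification

Matching is on the group's inferred neutral mass, not raw m/z, against
library monoisotopic masses (derived from elemental formulas when the
mass column is absent), with a strict bound: candidates require a ppm
error *below* 10. MSI confidence levels are assigned as level 1
(authentic standard available and retention time within 30 s of the
reference — the tolerance is a package default, configurable), level 2
(mass-only putative match) and level 4 (no candidate). Level 3 is not
modelled. Groups lacking adduct evidence fall back to the principal
species assumption (`[M+H]+` or `[M-H]-` by mode) for neutral-mass
inference.

## Energy charge

AMP, ADP and ATP are quantified against unweighted ordinary
least-squares calibration lines (a 1/x weighting is available for
heteroscedastic areas); inverse predictions outside the calibrated range
are flagged, and negative predictions are clamped to zero with a flag.
The default calibration levels are the study's: 0.1–10 µM in seven
levels for AMP and ADP, 2–20 µM in five for ATP. The adenylate energy
charge,

$$\mathrm{AEC} = \frac{[\mathrm{ATP}] + 0.5\,[\mathrm{ADP}]}
  {[\mathrm{ATP}] + [\mathrm{ADP}] + [\mathrm{AMP}]},$$

is computed per biological replicate and summarised per condition as
mean ± sample sd. It is scale-invariant and bounded in [0, 1]; an
all-zero pool is undefined, not zero. Isotope-labelled matrix-effect
correction is out of scope; a constant correction factor can be applied
upstream of the areas.

## Multivariate overview

The injection-averaged group matrix (samples × groups) is mean-centered
and Pareto-scaled — divided by the square root of the column standard
deviation, damping the dominance of intense features without erasing
magnitude. The phrase "reduced and scaled to Pareto variance" in the
upstream workflow's description is ambiguous between this and full
autoscaling; both are implemented (`pareto_mode = "auto"`), Pareto is
the default. Constant columns become zeros and are flagged; missing
values are mean-imputed per column (flagged) because the exclusives
would otherwise eject whole samples. PCA is a singular value
decomposition with a deterministic sign convention (largest-magnitude
loading positive per component).

## Transcript classification

Counts are normalized with median-of-ratios size factors: for genes with
nonzero counts in every replicate, the median ratio of the count to the
gene's geometric mean, rescaled by the median factor so unperturbed
replicates sit at 1. The per-gene test is deliberately a *surrogate*,
not a negative-binomial shrinkage analysis: a Welch t-test on log2
normalized counts with Benjamini–Hochberg adjustment. The module's
contract is the normalization formula and the threshold rule — up at
fold ≥ 3 with padj < 0.05, down at fold ≤ 1/3 — with the test
pluggable. Normalized means get a pseudocount of 0.5 before the ratio.
With only two replicates per condition (the study design) the surrogate
is underpowered; simulation-based checks therefore use three or more
replicates, and the high-signal recovery checks condition on genes with
base mean ≥ 200 counts, below which truly down-regulated genes land at
single-digit counts that a t-test cannot resolve.

Functional-class summaries and a regulator-neighborhood report (genes
whose span lies within a window of a candidate regulator, with fold and
label) complete the module.

# The synthetic-data generator

`simulate_metabolome()` draws, per metabolite, a neutral mass (uniform,
principal ions spanning m/z 62–955), a retention time, one ion mode, and
a mean intensity (lognormal around 10^6 arbitrary units). Defaults
encode the study conditions: 451 metabolites, 227 of them differential
with true folds of 3–30 (log-uniform, random direction), 28 of the
differential set exclusive to condition B; 6 vs 4 biological replicates,
2 injections each. Noise is multiplicative lognormal, parameterized by
CV: biological 25 % per condition and analytical 10 % by default —
chosen once inside the study's reported sub-40 % biological-RSD envelope
and typical published analytical reproducibility for this instrument
class. Each metabolite emits its principal ion plus, with configured
probabilities, an M+1 isotopologue (+1.003355 Da, relative intensity
0.1–0.3), one extra adduct and a proton-bound dimer, sharing the
metabolite's retention time up to 1 s jitter and 2 s drift, with 2 ppm
Gaussian m/z error. Exclusive metabolites are all-missing in the other
condition. The ground truth (per-metabolite means, ratios, member ions
with species labels, library identity) is always emitted alongside the
data; tests never re-derive truth from data.

`simulate_counts()` draws negative-binomial counts with recorded
lognormal library-size factors; `simulate_calibration()` generates
calibration lines at the study's concentration levels;
`simulate_aec_scenario()` builds a self-consistent nucleotide
quantification input from target energy charges (defaults 0.84 vs 0.66,
a healthy against a perturbed adenylate pool).

## What the simulations do and do not show

The generator emulates the *design*: replication structure,
detection-exclusive metabolites, redundancy of ion signals, lognormal
intensity noise, NB count noise. It does not model chromatographic peak
shapes, retention-time alignment errors across runs, ionization
suppression, censoring at the detection limit (absence is
all-or-nothing per condition), in-source fragments (which have no mass
rule and are only reachable through the correlation gate), multi-charge
species, or metabolites visible in both ion modes. Passing tests
therefore certify the statistical contracts — interval coverage,
threshold exactness, recovery of a known partition — under a clean
model of the design, and say nothing about peak picking or alignment
quality on real spectra.

# Problem sizes and numerical conventions

Simulation-based checks run at the study scale (451 metabolites, ~1,000
ions, 20 injections; 1,500–2,000 genes) or smaller, which keeps the full
suite under a minute of compute; coverage of the Fieller interval is
estimated from 2,000 simulated experiments, giving a binomial standard
error of about 0.5 points at the 95 % level. All retention times are
seconds internally; minutes in source files are converted at the
boundary. All randomness flows from explicit integer seeds; the same
seed reproduces every output byte-identically. Degenerate inputs follow
fixed conventions rather than erroring mid-pipeline where a value can be
defined: zero-variance groups collapse the Fieller interval to a point,
identical constant groups test at p = 1 and distinct constant groups at
the p → 0 limit, undefined RSDs and correlations are missing values with
documented non-blocking semantics.

# Known limitations

* The Fieller plug-in df is an approximation; its discrepancy from the
  local-df inversion is bounded in the test suite but grows for very
  uncertain denominators.
* The transcript surrogate is not DESeq and should not be used for real
  two-replicate designs without that caveat; it exists to exercise the
  classification rule.
* Exclusivity is all-or-nothing per condition; left-censored imputation
  is explicitly out of scope.
* The identification module ranks by mass accuracy only; retention-time
  and spectral evidence enter solely through the MSI level.
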