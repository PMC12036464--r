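---
title: "An nCounter workflow for heterogeneous FFPE samples: models, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An nCounter workflow for heterogeneous FFPE samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncountr)
```

`ncountr` implements an end-to-end expression workflow for NanoString
nCounter count data from formalin-fixed paraffin-embedded (FFPE) tissue.
This vignette is the package's own account of the science: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
design decisions taken where the design was genuinely open.

## The data and the container

An nCounter lane reports one integer count per probe. A codeset mixes five
probe classes: endogenous genes (the biology), housekeeping genes (assumed
stably expressed; normalization anchors), synthetic positive spikes at known
concentrations (128 down to 0.125 fM; lane-efficiency calibrators), negative
probes against sequence absent from biology (background estimators), and —
the distinctive ingredient of this workflow — a small panel of *biological
positive controls*: endogenous genes with universal expression in the target
tissue (for colon: `MUC5AC`, `TFF1`, `CDH1`, `CDX2`, `CTNNB1`, `ITLN1`,
`B2M`, `MUC2`, `OLFM4`, `PIGR`, `SELENBP1`). These genes are ordinary
biology in every analysis — several are themselves differentially expressed
across lesion types — but they additionally drive a QC flag, which is why
the container tracks them as a class overlay (`BIO_POSITIVE`) rather than a
separate count stream.

`experiment()` bundles a counts matrix (probes × samples) with probe
annotation and sample metadata; probe rows are canonicalized alphabetically
(C-locale) so that downstream linear algebra never depends on input order.

## Quality control

QC precedes normalization, so every statistic below is computed on raw
counts.

**Background.** Each sample's background threshold is the arithmetic mean of
its negative-control counts. A probe counting *strictly below* this
threshold is treated as undetected; a tie counts as detected. The strict
inequality is the retention-friendly reading — with discrete counts a probe
sitting exactly at background carries no evidence of absence.

**Technical flags.** Imaging (counted/attempted fields of view < 0.75),
binding density outside 0.1–2.25 spots/µm², and limit of detection (the
0.5 fM spike not exceeding mean + 2 SD of the negatives). The workflow names
these checks; the numeric cutoffs are the platform's published guideline
values, and all are exposed in `qc_config()`.

**PCA outliers.** Samples are projected onto the first two principal
components of centered `log2(count + 1)` over all biological probes. A
sample is an outlier if its score on PC1 *or* PC2 falls outside
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` of that axis, quartiles by linear
interpolation (type 7, the most common convention; fixed for
reproducibility). The fence rule replaces the visual confirmation step of
interactive workflows with a deterministic criterion. Outliers are computed
once, not iteratively after removal — iteration would change the exclusion
counts and the single pass matches the workflow this package implements.
Whether PCA runs before or after technical-flag removal is configurable
(`pca_after_technical`, default `TRUE`, the stage order of the reference
workflow).

**The missingness flag.** The conventional codeset-wide rule — flag when
> 30% of endogenous *and* ≥ 20% of housekeeping genes fall below background
— discards biologically silent samples along with degraded ones. The
workflow's alternative flags a sample only when **4 or more of the 11**
tissue positive-control genes fall below its background threshold. Because
the panel has 11 genes, the count rule (≥ 4) and the fraction rule (> 30%)
coincide for every possible count, and the package asserts that equivalence
in its tests. The conjunction in the standard rule follows its verbatim
definition; an OR variant is available (`std_rule = "or"`) for sensitivity
analysis. The standard flag is always reported alongside for comparison but
does not drive exclusion.

`run_qc()` applies, in order: technical flags → PCA outliers (on technically
passing samples) → the 11-gene flag, recording each sample's first
triggering reason and all flags.

## Normalization

Three strategies, deliberately kept behind one result type:

* **nSolver-style scaling.** Per sample: positive factor
  `f_i = mean_j(p_j)/p_i` with `p_i` the geometric mean of the positive
  spikes; counts scaled by `f_i`; the scaled negative-control mean
  subtracted (floored at 0.5 counts); housekeeping factor
  `g_i = mean_j(h_j)/h_i` on the geometric means of the scaled,
  background-subtracted housekeeping counts; output
  `log2` of the fully adjusted counts. Background subtraction uses the plain
  negative mean — not mean + 2 SD — so that "background" means the same
  thing in every module. The method is invariant to global per-sample
  scaling of raw counts.
* **RUVg-style factor analysis.** On `Y = log2(count + 1)` (samples ×
  biological probes), the housekeeping columns are centered and decomposed
  by SVD; `W` is the first `k` left singular vectors scaled by their
  singular values, `alpha` the least-squares loadings of all probes on `W`.
  Housekeeping genes are the control set; the spike-ins are *not* used as
  RUV controls, and spike probes are excluded from the normalized output
  (they are controls, not biology). `k` defaults to 1 — the smallest model,
  sufficient for the dominant lane/batch shift — and is exposed for
  sensitivity runs. Sign convention: each `W` column's largest-magnitude
  entry is positive, making results reproducible across LAPACK builds.
  Differential expression uses `W` as design covariates rather than the
  subtracted matrix `Y − W·alpha`, the standard recommendation in the RUV
  literature (the subtracted matrix underestimates residual variance);
  the subtracted matrix is retained for visualization and correlation
  outputs.
* **NB size factors.** For the joint count model
  `E[Y_ig] = lambda_i + c_i d_i mu_ig`: `c_i` is the geometric mean of the
  positive spikes (rescaled so the geometric mean of `c` over samples is
  exactly 1), `lambda_i` the negative-control mean, and `d_i` the geometric
  mean of `(hk − lambda_i)/c_i` (floored at 0.5, rescaled to geometric mean
  1). Dividing by `c_i` before the housekeeping geometric mean is what makes
  the pair consistent with the model: scaling a sample's every count by `t`
  scales `c_i d_i` by `t`, not `t²`.

Zeros are floored at 0.5 counts before any geometric mean or log — the
standard count floor, preventing −∞ while perturbing real counts (≥ 1) not
at all. The log base is 2 with pseudocount 1 throughout. None of the three
methods uses random numbers.

## Differential expression

**Moderated linear model.** Gene-wise ordinary least squares on log2
expression against a shared design (intercept, group indicators vs. a stated
referent, optional covariates, optional `W` columns), followed by
empirical-Bayes variance moderation under
`s2_g ~ s0² · chi²_{d0} / d0`: the prior `(d0, s0²)` is estimated by moment
matching on `log s2_g` (digamma/trigamma inversion), and the moderated
variance `s̃²_g = (d0 s0² + d_g s2_g)/(d0 + d_g)` feeds a t statistic on
`d0 + d_g` degrees of freedom. `d0 = ∞` (all variances equal) is handled as
the normal limit; `d0 = 0` reduces to the ordinary t-test; both limits are
asserted numerically in the tests, and the whole path is cross-checked
against an independent implementation of moderated statistics.

**Negative-binomial GLM.** The joint count engine background-corrects
(`Y − lambda`, floored at 0, rounded) and fits a log-link NB GLM with offset
`log(c_i d_i)` per gene. Treating the background as a subtracted offset is a
deliberate simplification of a full Poisson-convolution likelihood: the
convolution is not identified by anything this package needs, while the
simplification preserves the three-factor normalization and the NB
empirical-Bayes structure. Per-gene dispersions are estimated by maximum
likelihood and shrunk on the log scale toward the across-gene mean with
weight `w = n0/(n0 + n)`, `n0 = 10` by default — a few hundred genes is too
few to support a mean–dispersion trend, so the shrinkage target is global.
When the dispersion ML diverges toward the Poisson boundary (underdispersed
counts), the boundary is accepted if a Poisson fit shows no overdispersion;
genes whose fit genuinely fails are reported as `NA`, counted, and excluded
from the multiple-testing denominator rather than silently dropped. Each
group coefficient is tested by a likelihood-ratio test (full vs. the model
without that column, 1 df) at the shrunk dispersion. As the dispersion
approaches zero the engine reproduces Poisson regression, asserted against a
Poisson GLM oracle.

Contrasts are single-coefficient tests within the multi-group model (e.g.
SSL vs. TA and TV vs. TA inside one three-group fit), two-sided throughout.
Covariate adjustment (lesion size, age, sex) is supported but defaults off —
in the reference analysis it did not materially change results, so
unadjusted models are the primary presentation. Multiple testing uses
Benjamini–Hochberg at q < 0.05, with the denominator equal to the number of
tested genes.

## Evaluation

`deg_overlap()` computes exact membership counts for every non-empty subset
of methods on the common gene universe; `logfc_correlation()` the pairwise
Pearson r of fold changes. `type_i_simulation()` estimates empirical Type I
error: permute the group labels uniformly at random, re-run normalization
and DE from scratch, record the fraction of tested genes with unadjusted
p < α (both contrasts pooled — under the permutation null every gene in
every contrast is null), and average over replicates. Counting uses
unadjusted p, matching the definition of a per-test error rate. Permutation
is unrestricted across samples by default (`stratify = "cartridge"` is
available); the scaling normalizations do not use labels, but recomputation
per replicate keeps the protocol uniform with the label-dependent joint
model. One master seed spawns recorded per-replicate child seeds, so any
replicate can be audited in isolation and identical seeds are
bit-reproducible.

## The synthetic generator

`simulate_experiment()` draws: negatives ~ Poisson(λ0 = 10); positive spikes
~ Poisson(κ·conc·s_i) with gain κ such that the 128 fM spike sits near
20,000 counts at s = 1; and each biological probe as Poisson(λ0) background
plus an NB signal with mean `s_i · b_c · 2^(μ_g + Δ_g + shift)` and
dispersion φ_g ∈ [0.05, 0.15]. Baseline log2 means are uniform on [5, 10]
for endogenous genes, [6, 9] for housekeeping, [6, 7.5] for the biological
positive-control panel (well expressed, but not so high that degradation
cannot silence them).

Three generator choices deserve explanation:

* **Bounded technical variation.** Lane efficiency (`log2 s_i ~ U(±0.8)`)
  and cartridge batch effects (`log2 b_c ~ U(±0.7)`) are uniform, not
  Gaussian. Lane-to-lane efficiency on this platform varies within a limited
  range, and bounded noise has a second virtue: interquartile-range fences
  never exclude a clean sample by tail luck, so QC outcomes are determined
  by planted anomalies. Passing QC tests therefore demonstrates the flag
  logic, *not* robustness to heavy-tailed technical noise — real cohorts can
  produce borderline samples that this generator will not.
* **Latent composition axes.** Two bounded latent axes (scores `U(±1)`,
  Gaussian gene loadings, sd 0.7 log2) act on endogenous genes only,
  emulating bounded biological composition variation (epithelial vs. immune
  content). They give the clean cohort the strong PC1/PC2 structure real
  lesion cohorts show; without them, the only high-variance direction is the
  global lane shift and any planted degradation signature would surface as
  PC2 and be caught by the fences instead of by the missingness flag.
  Housekeeping genes carry no composition loading (that is what makes them
  housekeeping), and the positive-control panel carries none either (chosen
  for universal expression).
* **Degradation as thinning.** A degraded sample's counts are binomially
  thinned: strongly (2^−5.5) on the degradation-sensitive panel — by default
  the 11 positive-control genes, standing in for fragmentation-sensitive
  transcripts — and mildly (2^−0.3) elsewhere. Thinning the observed count
  (signal plus that probe's background) reflects lost capture; spike-ins are
  never attenuated, encoding the FFPE premise that degradation destroys
  endogenous RNA while technical controls still pass. Real degradation is
  broader and length-dependent; the concentrated default is the
  configuration under which the missingness flag is the *only* detector of
  the planted degradation, which is exactly what the QC tests need to
  demonstrate. The attenuation default (−5.5 log2) is the weakest value that
  pushes the whole panel decisively below a λ0 = 10 background across the
  panel's baseline range.

`null_experiment()` strips all planted structure, making group labels
exchangeable by construction — the Type I simulation on its output targets α
exactly. `paper_like_cohort()` is the reference preset: 100 samples
(25 SSL / 27 TV / 48 TA) on 10 cartridges via a stratified round-robin, 2
planted outliers (+5 log2) and 11 degraded samples allocated 4/3/6 with the
outliers across SSL/TV/TA, planted mucin-program analogs (over-expressed in
SSL, including `TFF1`, `MUC5AC`, `MUC2`, `CDH1`), WNT-program analogs
(under-expressed in SSL, including `ITLN1`, `OLFM4`, `SELENBP1`), and
under-expression only in TV vs. TA.

What the generator does **not** emulate: gene–gene correlation beyond the
composition axes, length-dependent degradation profiles, wet-lab purity
metrics (260/280, DV200), replicate and universal-reference lanes in the
analysis presets, or heavy-tailed technical noise. Tests passing on this
generator show the algorithms implement their definitions and are calibrated
under exchangeability; they do not certify behavior on any real cohort.

## Numerical choices and degenerate inputs

Quartiles are type 7 everywhere. Zero-variance PCA axes produce no fence
violations (all scores equal). `ruvg_fit()` reports the attainable rank when
`k` exceeds the control block's rank; identical samples give rank 0 and an
error. Samples whose positive spikes are all zero, or whose housekeeping
counts all sit at the background floor, are named in a non-normalizable
error rather than silently scaled. NB fits cap `theta` at 1e8 and floor
dispersions at 1e-8; q-values are floored at the smallest positive double
before `−log10` in volcano tables. All geometric means floor their inputs at
0.5 counts.

## Problem sizes

The test suite and acceptance script run at the sizes the package documents
as its reference conditions: Type I calibration on an 87-sample null cohort
(group proportions 22/23/42) with 200 replicates in the tests and 1000 — the
reference protocol's replication count — in the acceptance script; QC on the
100-sample preset; parameter-recovery checks at 500 genes (variance prior),
40 samples per group (NB fold-change recovery), and 30 samples (RUVg batch
removal). The full suite runs in about half a minute on one CPU.

## Known limitations

* The NB engine's background treatment is subtractive, not a convolution
  likelihood; with backgrounds near signal level its fold changes are
  approximations.
* The moderated model assumes a common residual-variance hierarchy across
  genes; no mean–variance trend is fitted.
* `W` is estimated from 15 housekeeping genes; with `k` large relative to
  that panel the loadings are noisy, and the package errors rather than
  extrapolating beyond the attainable rank.
* Type I calibration is demonstrated under an exchangeable synthetic null;
  cartridge-confounded designs should use stratified permutation
  (`stratify = "cartridge"`), and calibration on real data depends on the
  design actually being exchangeable under the null.
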