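---
title: "Models and methods in affwm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in affwm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(affwm)
```

This vignette documents the statistical models behind the two analysis
arms, the tunable parameters with their defaults and rationale, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## 1. The behavioral arm

### Effect sizes

The unit of analysis is a standardized mean difference between an
affective and a neutral condition of a working-memory task,
$d = (\bar m_{aff} - \bar m_{neut})/s_{pooled}$, corrected for the
small-sample upward bias of the pooled-SD denominator by Hedges' factor
$J = 1 - 3/(4\,df - 1)$, so $g = J\,d$. The sampling variance is the
standard large-sample form
$v = (n_1+n_2)/(n_1 n_2) + g^2 / (2(n_1+n_2))$ for two independent
groups, and $v = 2(1-r)/n + g^2/(2n)$ for paired (within-subject)
designs standardized on the raw-score metric (average condition SD).

Sign convention: $d > 0$ always means a *larger* outcome value under
affective material — better accuracy for accuracy outcomes, slower
responding for response times. Interpreting the direction is a labeling
concern, never a computation concern, so a single convention is applied
to both outcomes.

Choices made where the design was open:

* Both independent-groups and paired formulas are implemented; the
  default is independent, the common convention when primary reports do
  not state the within-subject correlation. When a paired design is
  requested without a correlation, $r = 0.5$ is assumed — the neutral
  midpoint — and recorded in the output record.
* A variance floor of $10^{-8}$ keeps inverse-variance weights finite in
  degenerate paired configurations ($r \to 1$, $g \to 0$).
* Effect sizes from test statistics (t, F) or correlations are out of
  scope; the table reader accepts either per-condition summaries or
  precomputed $(d, v)$ pairs.

### The multilevel model

Effects (level 1) are nested in studies (level 2):
$$y_i = x_i'\beta + u_{study(i)} + e_i, \qquad
  e_i \sim N(0, v_i)\ \text{known}, \qquad u_j \sim N(0, \sigma^2).$$

The single variance component makes profile optimization robust, so
$\sigma^2$ is estimated by bounded one-dimensional maximization of the
restricted log-likelihood (REML, the default; ML is exposed for model
comparison). The search interval $[0, \max(1, 10\,\mathrm{var}(y))]$ is
split into five subintervals each searched by Brent's method
(`optimize`, tolerance $10^{-8}$), and the boundary value $\sigma^2 = 0$
is always compared explicitly; at the boundary the fit reduces exactly
to fixed-effect GLS. All per-$\sigma^2$ quantities use the rank-one
Woodbury identity on the per-study blocks
$V_j = \mathrm{diag}(v) + \sigma^2 \mathbf{1}\mathbf{1}'$, so a fit is
$O(k p^2)$ rather than $O(k^3)$.

Inference is Wald/normal for coefficients and chi-square for the omnibus
moderator statistic $Q_M$ (all non-intercept columns jointly), matching
the $z$, CI and $Q_M(df)$ quantities conventionally reported; no
Knapp–Hartung adjustment is applied. Cochran's $Q$ is computed at the
fixed-effect fit with $df = k - p$. Age correlations are plain Pearson
$r$ with Fisher-z intervals, unweighted by default (a precision-weighted
variant sits behind a flag), because the corresponding reported
quantities are plain $r(df)$. No multiplicity correction is applied
across moderator models; reports carry the number of tests run.

### Publication-bias diagnostics

Two diagnostics are provided:

* `egger_multilevel()` — the regression test adapted to nested data: the
  multilevel model is refit with $\sqrt{v_i}$ as an additional
  moderator and the Wald $z$ of that slope is reported. A marginal
  (non-nested, 1/v-weighted) variant is available via
  `method = "marginal"`; the multilevel form is primary.
* `rank_correlation_bias()` — a rank-correlation approximation for
  multilevel data: the model is refit with $v_i$ as a moderator, and
  Kendall's $\tau$ between the marginal residuals and $v_i$ is tested
  with the normal approximation. Including $v$ as a moderator first
  removes the deterministic variance–effect association so the rank test
  sees only the residual one. The exact construction of this test is
  under-determined in the literature it approximates; the implemented
  reading is recorded here and in the result's `method` field.

## 2. The imaging arm (MKDA)

Each study contrast contributes a *binary* indicator map: voxels whose
center lies within 10 mm (Euclidean) of any reported peak, intersected
with the gray-matter mask. Multiple nearby peaks union rather than add,
which caps any one contrast's contribution at 1 and prevents
peak-dense studies from dominating. Contrast maps combine into
$$P(v) = \frac{\sum_c \sqrt{N_c}\, I_c(v)}{\sum_c \sqrt{N_c}} \in [0,1],$$
the weighted proportion of contrasts activating each voxel. Only the
$\sqrt N$ weighting is implemented; fixed/random-effects study weighting
variants of MKDA are deliberately out of scope.

Talairach-space coordinates are converted to MNI with the
branch-consistent inverse of Brett's piecewise linear transform (the
$z \ge 0$ and $z < 0$ branches as published); the foci reader converts
and audits such rows.

### Monte Carlo null and thresholds

The null preserves the number of contrasts, the number of coordinates
within each contrast and the $\sqrt N$ weights, but redraws every focus
uniformly over mask voxel centers (independently, with replacement).
Voxel-level null densities are pooled across voxels and iterations (a
stationary null — the mask is homogeneous under uniform placement);
the per-iteration *maximum* suprathreshold cluster size yields the
cluster-extent distribution, i.e. maximum-statistic FWER control.

Thresholds are defined on the empirical distributions without
interpolation: the voxel threshold is the smallest observed density $t$
with $\Pr(\text{null} \ge t) \le p$ (default $p = .01$), and the extent
threshold the smallest integer $k$ with
$\Pr(\max\text{-cluster} \ge k) \le \alpha_{FWER}$ (default $.05$).
Using order statistics rather than interpolated quantiles keeps the
in-sample guarantee exact under the atoms that a discrete weighted sum
produces (most voxels have density exactly 0).

Open points decided here:

* Null foci are placed at voxel centers, not continuous mm positions —
  the natural discretization once densities live on the grid; flagged
  because the alternative is defensible too.
* Contrasts from the same study stay separate in the null: the contrast,
  not the study, is the exchangeable unit.
* Clusters use 26-connectivity; ordering and tie-breaks are
  deterministic (size descending, then lexicographic peak coordinate),
  so identical seeds give byte-identical cluster tables.
* Difference maps ($P_A - P_B$) are tested by permuting condition labels
  over contrasts, each contrast keeping its foci and weight; each tail
  gets its own voxel and extent thresholds from the permutation null.
  The choice of a label-permutation null is recorded in the output.
* When the pooled null is degenerate (e.g. identical condition sets make
  every permuted difference zero), the threshold is set to $+\infty$
  with a warning and no clusters are reported, rather than erroring out
  of a batch run.

Memory note: the pooled voxel null is capped (default $2\times 10^6$
samples) by pooling a per-iteration random subsample of masked voxels —
an unbiased sample of the same pooled distribution.

### Grids

The default analysis grid is 2 mm isotropic over the MNI bounding box
$x \in [-90, 90]$, $y \in [-126, 90]$, $z \in [-72, 108]$. Tests and the
acceptance script use a 4 mm grid with a synthetic ellipsoid "brain"
mask (`gen_mask()`, semi-axes 70/85/70 mm, ~27,000 voxels), which keeps
a 1,000-iteration null under a minute while preserving every geometric
property the engine relies on. When no mask is supplied the ellipsoid
default is used, so the engine is fully testable offline.

## 3. The synthetic-data generators

`gen_behavioral_dataset()` draws study intercepts
$u_j \sim N(0, \sigma^2)$, builds per-effect true effects
$\mu + x'\beta + u_j$ with randomly assigned moderators, and observes
$d \sim N(\text{true}, v)$ with $v$ uniform on `v_range` (default
$[0.02, 0.2]$, i.e. per-group n of roughly 10–100). The emitted
study-summary table is reverse-engineered (neutral mean/SD fixed,
affective mean solved from the uncorrected $d$, group size solved from
the target variance) so that recomputing effect sizes from the summaries
reproduces each record's $g$ exactly — the two behavioral modules
round-trip bit-for-bit. Default truth: $\mu = 0.2$,
$\sigma^2 = 0.04$, $\beta_{valence} = 0.14$ — a small positive grand
mean, moderate heterogeneity and a moderator effect on the scale such
meta-analyses report.

The optional selection model censors direction-consistently: an effect
publishes with certainty when significantly positive (one-sided
$z > 1.96$), otherwise with probability $\pi_0$ (default 0.3). This
one-parameter rule produces the classic small-study asymmetry the Egger
tests are built to detect; power grows with censoring strength and with
the spread of standard errors in the corpus.

`gen_foci_dataset()` plants activation clusters (per-contrast activation
probability, isotropic normal dispersion around a center, rejection
truncation to the mask) over uniform Poisson background foci, with
per-contrast sample sizes uniform over `N_range` (default 10–40).

What the generators do **not** emulate: realistic neuroanatomy or
atlas-shaped gray matter; empirically calibrated covariate
distributions; correlated outcomes within a study (multivariate
meta-analysis is out of scope); non-normal effect-size sampling
distributions. Passing tests therefore demonstrate the *statistical
machinery* — estimator consistency, calibration of the thresholds, FWER
control under the stated null — not robustness to the messiness of real
corpora.

## 4. Verification at a glance

The test suite checks, among others: exact closed forms (Hedges $J$, SMD
variances, $\sqrt N$ weighting, the Brett transform); equivalence of the
REML optimizer with a dense grid search of the restricted likelihood;
agreement with an independent multilevel meta-analysis implementation on
identical input; type-I error of $Q$ and the Egger test; 95% CI coverage
of planted truth over replicate corpora; realized MKDA family-wise error
and voxel-level calibration against independently simulated null
datasets; planted-cluster recovery through the full pipeline; and
bit-reproducibility under fixed seeds. Problem sizes used by the checks:
corpora of 200 studies × 2 effects (coverage), 2,000 replicates
(type-I), a 4 mm ellipsoid grid with 20 contrasts × 5–15 foci, a
1,000-iteration threshold null and 500 independent evaluation datasets
(FWER/calibration).

## 5. Known limitations

* One variance component only: no multivariate or correlated-effects
  structure, no three-level nesting.
* Wald inference can be anticonservative for very small $k$; the
  degenerate single-effect fit is flagged rather than adjusted.
* MKDA maps are voxelwise proportions, not model-based effect sizes; no
  ALE/SDM kernels, no atlas labeling, no surface rendering.
* Oblique or anisotropic NIfTI masks are rejected rather than resampled.
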