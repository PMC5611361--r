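---
title: "Methods: leaf-stem allometry and the xylem efficiency-strength trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf-stem allometry and the xylem efficiency-strength trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twigscale)
```

## The scientific problem

Across tree species, larger leaves sit on thicker twigs (Corner's rules), and
whether that scaling is isometric (log-log slope 1) or allometric is
informative about biomass allocation strategy. One functional explanation
runs through the stem's xylem: supplying a large leaf area demands wide
vessels and high hydraulic conductivity per sapwood area, while mechanical
safety demands dense wood and a high modulus of elasticity -- and the two are
in tension, because lumen space and fiber matrix compete for the same
cross-section. `twigscale` implements the complete analysis workflow for
testing these ideas on a multi-species twig survey (the motivating system is
a 28-species *Ficus* common garden, 3 individuals per species, 3-5 twigs per
individual), plus a synthetic-data generator with known ground truth so every
stage can be validated end to end.

## Trait derivation

**Hydraulics.** Vessels are near-elliptical; the diameter of the circular
conduit with the same Poiseuille resistance is
$D = \left[\frac{32 (ab)^3}{a^2+b^2}\right]^{1/4}$, with $a \ge b$ the
**semi**-axes. We adopt the semi-axis reading because only it satisfies the
circular limit $a=b=r \Rightarrow D=2r$; image-analysis exports that report
full axis lengths are ingested with `full_axes = TRUE`. The hydraulically
weighted diameter is the fourth-power mean $D_h = (\tfrac{1}{n}\sum
D^4)^{1/4}$, vessel density VD is count per analyzed xylem area, the lumen
fraction is VF $= \overline{\pi a b} \cdot$ VD, and the theoretical specific
conductivity follows Hagen-Poiseuille:
$K_{theo} = \frac{\pi \rho}{128\,\mu\,A_s}\sum D^4$ (kg m$^{-1}$ MPa$^{-1}$
s$^{-1}$), with $\rho = 998.2$ kg m$^{-3}$ and $\mu = 1.002\times10^{-9}$
MPa s at 20 °C. The $\pi\rho$ numerator is the standard form of the law; a
numerator in which the viscosity appears both above and below the fraction
would cancel and cannot be what any source intends. When a vessel set comes
from a sub-sampled window rather than the whole section, the window area is
the correct normalizer: vessel density in the window stands for density in
the sapwood, so the window-normalized sum equals the sapwood-normalized sum
in expectation.

**Density and water content.** WD $=$ DW$/V$ (g cm$^{-3}$) and SWC
$= 100\,(FW-DW)/(SW-DW)$, which is bounded by [0, 100] whenever the masses
obey $SW \ge FW \ge DW$; violations are rejected, and $SW = DW$ (no
saturable pore space) is a hard error rather than an NaN.

**Bending.** A midspan-loaded beam gives $\delta = F L^3/(48\,EI)$, so the
least-squares slope $s$ of deflection on load yields $EI = L^3/(48 s)$ and
MOE $= EI/I$ with $I = \pi d^4/64$ for a solid circular section (bark and
pith removed). Span-to-diameter ratios below 25 warn (shear contamination)
and below 20 are rejected. Linearity thresholds -- warn below $r^2 = 0.95$,
reject below $0.8$ -- are this package's own choices; no published value
governs them.

**Twig architecture.** SLA $=$ TLA/LeM (converted once to m$^2$ kg$^{-1}$),
per-leaf quantities divide by leaf count, and leafing intensity LI is leaves
per gram of stem dry mass. Species means are **two-stage**: twigs are
averaged per individual, individuals per species. With unbalanced twig
counts this differs from a pooled mean, and tests pin the two-stage order.
Missing species-trait cells propagate by pairwise deletion in the
correlation and SMA stages.

## Allometry

Pairs of log10 species means are fit by standardized major axis:
$\hat\beta = \mathrm{sign}(r)\, s_y/s_x$, symmetric in the axes. The 95% CI
is $\hat\beta(\sqrt{B+1} \pm \sqrt{B})$, $B = F_{0.95;1,n-2}(1-r^2)/(n-2)$.
The test of $H_0: \beta = b_0$ (isometry when $b_0 = \pm 1$) uses the
correlation between residual scores $y - b_0 x$ and fitted-axis scores
$y + b_0 x$, referred to $t_{n-2}$ -- the standard SMA statistic; the source
analyses do not name theirs, and this is the assumption we document. Data
lying on the hypothesized line up to floating-point rounding return $p = 1$
with a degeneracy flag instead of amplifying rounding noise. The
common-slope test minimizes $-\sum_i n_i \log(1 - r_i(b)^2)$ over $b$ by
Brent/golden-section search on the sign-consistent bracket
$[\min|\hat\beta_i|/3,\; 3\max|\hat\beta_i|]$ and refers the minimized
statistic to $\chi^2_{k-1}$; groups with mixed correlation signs are
rejected with advice to analyze the signs separately. Negative size-LI
relationships are tested against $b_0 = -1$. Two-sided tests at
$\alpha = 0.05$, no multiple-testing correction -- matching the conventions
of the reference analysis. OLS is available only as a labeled diagnostic.

## Phylogenetic contrasts

Contrasts use Felsenstein's pruning pass on a validated tree (rooted,
strictly binary, positive branch lengths; polytomies are an error that
names `ape::multi2di`, not something we silently resolve). Contrast
correlations go through the origin with $n-1$ df (one df for the forced
origin) -- standard PIC practice; the reference analysis does not state its
df. Contrast direction follows input tree order; every exported statistic is
invariant to joint sign flips, and tests assert this. Contrasts are computed
on log10 traits, the scale on which the Brownian model is assumed. The
package's own recursion is tested against `ape::pic` as an independent
oracle; branch lengths are taken as given (unit vs substitution lengths is
the user's modeling decision).

## Multivariate structure

The MFA centers and scales each trait (correlation-style scaling -- the
traits' units are heterogeneous, so covariance scaling would be
meaningless), divides each group block (11 stem/petiole vs 13 leaf traits by
default) by $\sqrt{\lambda_1}$ of that block so no group dominates, and runs
one global SVD. A single group therefore reduces exactly to PCA, and
duplicating a group leaves axis percentages unchanged -- both are tests. For
contrast matrices, `center = FALSE` respects their through-origin mean-zero
construction. Nested variance components come from method-of-moments on the
species / individual / twig mean squares, with harmonic-mean group sizes for
unbalanced designs and negative estimates truncated to zero before
renormalizing (the classical convention).

## The synthetic world

The generator is a stated world, not a tuning dial:

* **Tree**: Yule pure-birth, the simplest branch-length model, rescaled to
  root-to-tip depth 1 so BM rates read per total depth.
* **Species means**: multivariate Brownian motion of log10 traits; defaults
  give roughly one order of magnitude of spread in the size traits, root
  states at field-plausible values (e.g. stem area ~8 mm$^2$, $D_h$ ~40 um,
  WD ~0.5 g cm$^{-3}$, MOE ~3.2 GPa).
* **Imposed structure**: for an exponent pair $(y, x, \beta, r^2)$ we set
  $y = \mathrm{root}_y + \beta\sqrt{r^2}\,(x - \mathrm{root}_x) +
  \varepsilon$ with $\mathrm{sd}(\varepsilon) = |\beta|\,\sigma_x
  \sqrt{1-r^2}$, recycling the trait's own BM deviate as $\varepsilon$ so
  residuals stay phylogenetically structured. This construction makes the
  *population SMA slope* exactly $\beta$ and the population $R^2$ exactly
  $r^2$. The naive alternative ($y = \beta x + \varepsilon$) would put the
  population SMA slope at $\beta / \sqrt{r^2}$ and no estimator could
  "recover" $\beta$ from it. Trade-off entries $(a, b, r)$ reuse the same
  machinery with $\beta = \mathrm{sign}(r)\,\sigma_a/\sigma_b$, preserving
  trait $a$'s marginal variance. Chained pairs use the already-adjusted
  upstream trait.
* **Derived consistency**: the vessel system is over-determined given
  $\{D_h, K_{theo}, A\}$, so $D_h$ and $K_{theo}$ are the free traits (the
  trade-off axis targets $K_{theo}$ directly) and VD and VF follow from the
  Hagen-Poiseuille law. The species leaf count is an integer, and LI is
  re-derived as count/SM so the zero-noise round trip is exact for every
  derived twig trait. SWC is clamped at 98% (its formula bound is 100%,
  which unbounded BM on log scale would cross).
* **Noise**: multiplicative log-normal, individual level (sd 0.05 log10)
  then twig level (sd 0.08), matching the nested design and keeping
  within-species variation under ~20%. Within-species $D_h$ noise is scaled
  down 4-fold because per-twig conductivity follows the fourth-power law --
  unscaled diameter noise would be amplified 4x into density and
  conductivity, which is not how real stems vary. Within-stem vessel
  diameters are log-normal (cv 0.25) rescaled so the fourth-power mean is
  exact; aspect ratios uniform in [1.05, 1.5]. The within-species
  distributional form is an assumption of this package, not an assertion
  about any field system.
* **Determinism**: one integer seed, one documented stream order (tree,
  species traits, then species-by-species noise); identical configs give
  bit-identical tables.

What the generator does **not** emulate: measurement rounding and detection
limits, missing data, non-Brownian (e.g. Ornstein-Uhlenbeck) trait
evolution, within-crown light gradients, or correlated individual noise
across traits. A green test therefore establishes that the estimators
recover the stated world's parameters -- not that any particular field
dataset satisfies the model.

## Validation design and numerical notes

* CI-calibration and type-I-error suites simulate **independent** species
  (the star-phylogeny limit), because that is the regime where SMA's iid
  sampling theory is exact. On Yule trees the same estimators remain
  essentially unbiased for the slope, but phylogenetic correlation widens
  the sampling spread and the iid CI under-covers (roughly 70% at n = 28
  under the default rates) -- which is precisely the motivation for the PIC
  stage. `sma_recovery_experiment()` exposes both regimes.
* Slope-recovery experiments (the acceptance targets) run 500 replicates at
  n = 28 and recover generative exponents to well within ±0.03.
* Variance-component recovery is validated on traits whose species-level
  share dominates (the regime the nested design targets); traits whose
  species share sits near the noise floor (e.g. WD under the default rates)
  carry method-of-moments uncertainty larger than ±5 percentage points at
  27 species df.
* The manifest hash covers the scientific configuration only (not output
  paths), so reruns are byte-identical.
* Ellipse/diameter, conductivity and contrast computations are tested
  against independent oracles (numerical root-finding, longhand SI
  arithmetic, a separate recursion, `ape::pic`) at tolerances of 1e-9 to
  1e-12.

## Known limitations

* No measured (as opposed to theoretical) conductivity, vulnerability
  curves, or embolism modeling; $K_{theo}$ is an upper-bound porosity index.
* No common-intercept or slope-shift SMA tests; no phylogenetic signal
  statistics or PGLS.
* Config files are JSON (no YAML parser among the package's dependencies).
* Petiole area is treated as cross-sectional (mm$^2$); leaf anatomy traits
  (LT, UET, PT, SP, LET, SS, SD) are pass-through measured columns, never
  derived.
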