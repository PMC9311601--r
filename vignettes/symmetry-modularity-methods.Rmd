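---
title: "Methods: object-symmetry decomposition and modularity inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-symmetry decomposition and modularity inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symmod)
```

`symmod` implements a complete landmark-based analysis of bilateral
asymmetry and modularity for 2D structures with *object symmetry* — a single
structure (here the dorsal cephalothorax of a decapod crustacean, digitized
as 33 landmarks) whose left and right halves mirror each other across an
internal axis. This vignette records the statistical model behind each
stage, the conventions and tunable parameters, the design choices made where
the methodology was genuinely open, and what the synthetic-data generator
does and does not establish about real data.

## Superimposition and the symmetry decomposition

Configurations are superimposed by generalized Procrustes analysis: each
`K x 2` configuration is centered, scaled to unit centroid size
(`CS = sqrt(sum of squared landmark distances from the centroid)`), and
rotated to minimize the summed squared distance to an iteratively updated
consensus. Conventions:

* **Rotation only.** Fitting rotations are constrained to determinant +1.
  Reflection is never absorbed into the fit, because reflection is exactly
  the quantity under study: it is applied explicitly by `reflect_relabel()`
  (mirror across the symmetry axis, then swap left/right labels).
* **Convergence.** Iteration stops when the consensus moves by less than
  `1e-10` (root summed squared difference) or at 100 iterations; the
  objective trace is retained and is non-increasing.
* **Axis convention.** After convergence the consensus is rotated so the
  best-fit line through the midline landmarks is the x-axis, with the
  anterior reference landmark at positive x. The source methodology never
  states an axis convention; fixing one makes the anterior-posterior
  profile and the sign of the asymmetry descriptor well defined.
* **Exact symmetrization.** With object symmetry the alignment set is
  closed under `reflect_relabel()`, so the converged consensus is symmetric
  up to the tolerance; it is then symmetrized exactly and the copies are
  re-aligned once. This makes the downstream algebra exact to machine
  precision instead of exact to the GPA tolerance.

`decompose_symmetry()` aligns all `n x r` digitized copies jointly with
their reflected-relabeled counterparts (`2 n r` configurations). For an
aligned copy `A`, the components are

* symmetric: `(A + RR(A)) / 2` — an exact fixed point of `RR`;
* asymmetric: `(A - RR(A)) / 2` — exactly sign-flipping under `RR`,

so `A = sym + asym` and `RR(A) = sym - asym` hold exactly. The asymmetric
component is the *half*-difference; conventions that use the full
difference differ by a factor 2, which cancels in every ratio, test
statistic and correlation reported here. Specimen-level components average
the replicates; replicate-level copies are retained for the error term of
the ANOVA.

## Procrustes ANOVA with restricted residual randomization

The two-sex, two-replicate design with object-symmetry doubling gives
`2 x n x r` observations (each replicate plus its reflected copy). The
distance-based ANOVA uses the sequential decomposition of the model

```
shape ~ sex + side + sex:side
```

where `side` distinguishes original from reflected copies. Sums of squares
are summed squared Procrustes distances (totals decompose exactly); each
reported term has `nlevels(sex) - 1 = 1` df, and with 103 specimens x 2
replicates the residual has `412 - 4 = 408` df. The `side` main effect
carries directional asymmetry pooled over sexes; `sex:side` carries the
sexual divergence of directional asymmetry together with the sex effect on
individual asymmetry; the residual absorbs individual variation,
fluctuating asymmetry and digitization error.

P-values use randomization of reduced-model residuals (RRPP) with the
`(count + 1) / (B + 1)` estimator and B = 1000 by default — but the
residuals are permuted over each term's *exchangeable units*, not free
rows. The four copies of one specimen share its individual shape and are
strongly mutually correlated; permuting rows freely treats them as
independent and inflates the type-I error of the sex term to ~0.8 in null
simulations. `symmod` therefore permutes whole-specimen blocks for the
`sex` and `sex:side` terms and swaps the side labels within each digitized
copy for the `side` term. Under this scheme the sex term's empirical
type-I error sits at the nominal level (the acceptance suite verifies
0.01-0.10 at alpha = 0.05 over 200 null simulations).

## The triangle-area left-right asymmetry profile

For each bilateral pair the descriptor compares the areas of the right
triangles spanned by the anterior midline reference landmark and each side
landmark, with legs parallel and perpendicular to the symmetry axis:
`A_side = |x_side - x_ref| |y_side - y_ref| / 2`, and

```
LR = 100 (A_R - A_L) / ((A_L + A_R) / 2)
```

negative when the left-side area is larger (asymmetry "skewed to the
left"). Choices worth recording:

* **Triangle construction.** "The right triangle formed by the reference
  landmark and the side landmark" admits several readings; the
  axis-parallel-legs construction is the only one that is right-angled by
  construction for every landmark, and is implemented. The descriptor is
  scale-free (a ratio of areas), so it is invariant to uniform rescaling of
  the input.
* **Input coordinates.** The profile is computed on `grand mean +
  per-specimen asymmetric component`. Raw asymmetric deviations are
  near-zero displacement fields on which triangle areas are degenerate;
  adding the deviation to the consensus isolates each specimen's asymmetry
  while excluding its symmetric individual variation. A perfectly
  symmetric specimen scores exactly 0 on every pair. With
  `component = "fa"` the sex-mean asymmetry is removed first, giving the
  fluctuating-asymmetry profile.
* **Z-test.** The one-sample test of `LR = 0` per pair uses
  `z = mean / (sd / sqrt(n))` with the *sample* standard deviation; the
  classical z-test wants a known sigma that the design does not provide,
  and a fixed `sigma` argument is available. Zero-variance pairs are
  flagged degenerate (`p = 0` for nonzero mean, `p = 1` otherwise).
* **Between-sex comparison.** With 55 females and 48 males a literally
  paired test does not exist; a Welch two-sample t per pair is used
  (`var_equal = TRUE` gives the pooled variant). The comparison of the two
  bootstrap Mantel-r distributions *is* paired, by iteration index.

## Mantel correlation of module-wise asymmetry

Per sex, the specimen x specimen Euclidean distance matrices over each
developmental module's asymmetric coordinates are correlated (Pearson, on
the lower triangles). Significance comes from 999 joint row/column
permutations of one matrix; the distribution used for the between-sex
comparison comes from 5000 bootstrap iterations, each recomputing both
matrices and r on a random 90% subsample of specimens drawn without
replacement. Subsampling (the convention of the ecodist implementation this
mirrors) avoids the exact-duplicate specimens that with-replacement
resampling would inject as zero distances into both matrices.

## Covariance-ratio modularity

For two modules, with `S` the sample covariance matrix of the coordinate
columns (both coordinates of a landmark always travel with it),

```
CR = sqrt( sum_b s_ij^2 / sqrt( sum_w1 s_ij^2 * sum_w2 s_ij^2 ) )
```

where the numerator sums squared between-module covariances and the
denominators squared off-diagonal within-module covariances; for more than
two modules CR is the mean over module pairs. CR near 0 means weak
between-module covariation relative to within-module covariation — strong
modularity. Because diagonal blocks exclude their diagonal while the
rectangular block does not, equal covariances everywhere give
`CR = sqrt(n_b / sqrt(n_w1 n_w2))`, slightly above 1; CR is a ratio of
sums, not of means, matching the published statistic.

**Effect size.** The null distribution reassigns landmarks to modules at
random, preserving module sizes; `Z = (CR_obs - mean_null) / sd_null`. The
*distribution* of Z (whose mean and 95% CI the modular-signal table
reports) comes from re-standardizing CR_obs against bootstrap resamples of
the permutation set, one Z per resample — an RRPP-style account of the
uncertainty of the standardization itself. Negative Z_CR indicates modular
signal; on non-modular data |Z_CR| <= 1.96 for ~95% of datasets.

**Pairwise comparison.** For two hypotheses fitted on the same data the
signal difference is `|Z12| = |mean(Z1) - mean(Z2)|`, and the overlap
p-value, with distributions ordered so `mean(Z_lo) <= mean(Z_hi)`, is
`min(1, 2 min(P(Z_lo >= mean Z_hi), P(Z_hi <= mean Z_lo)))`. The
literature gives the "overlap ratio" no formula; this symmetrized
exceedance is isolated in one function so an alternative can be swapped
in. Letter groups are maximal cliques of the non-significant pairs
(compact letter display): letters can overlap, and two models share a
letter only if their difference is non-significant — a transitive-closure
grouping would merge models whose difference is significant whenever a
chain of similar models connects them.

**Modularity test.** The hypothesized partition's CR is compared with CR
values of 10,000 random partitions with the same module sizes;
`p = (#{CR_arb <= CR_obs} + 1) / (rounds + 1)`. CR depends on the
partition only through its set structure, so shuffling landmarks *within*
modules leaves it exactly invariant — the "observed distribution" of such
shuffles is a constant, and the default test uses the observed CR
directly. `observed = "bootstrap"` resamples specimens to display the
sampling spread of the observed CR alongside the arbitrary-partition
distribution, as in the usual graphical presentation of this test; the
p-value then uses that distribution's mean, which is nearly identical but
carries a small upward small-sample bias, so the point form remains the
default. The test operates on the symmetric-component residuals after
multivariate regression on centroid size (raw size by default; the
methodology leaves raw-vs-log open, so `log_size = TRUE` is a switch).

## Likelihood/AICc covariation-model selection

The landmark-level correlation is the congruence coefficient between
coordinate blocks: `phi_ab = (cov(xa, xb) + cov(ya, yb)) /
sqrt((var(xa) + var(ya))(var(xb) + var(yb)))`. Each covariation model
assigns every unordered landmark pair to a parameter group (within module
m, between modules m and m'); the group estimate is the inverse Fisher
transform of the mean Fisher z, and the log-likelihood treats each pair's
z as normal with mean `z(rho_group)` and variance `1 / (n_eff - 3)`. Then
`AICc = -2 logL + 2k + 2k(k + 1) / (N - k - 1)` with k the number of
correlation parameters and N the number of correlations (the EMMLi
convention; `aicc_n = "neff"` switches to the specimen count), and
posterior weights are proportional to `exp(-delta/2)`.

The registry expands each modularity hypothesis into the standard
variants: shared vs module-specific within-correlation crossed with shared
vs pair-specific between-correlation, deduplicated by pair-grouping
signature (for a 2-module hypothesis the two between choices coincide, so
it contributes 2 variants, not 4). The shipped seven hypotheses — uniform,
developmental, gonadic, agonistic, and three anatomical subdivisions —
expand to 1 + 3x2 + 3x4 = 19 variants. The detailed variant list of the
original 19-model comparison is not published; the registry is a
reconstruction that pins the count and the expansion rule, and is marked
as such.

A caution specific to bilateral data: in object-symmetric coordinates the
y-deviations of the two sides mirror each other, so the congruence between
landmarks on *opposite* sides is attenuated toward zero regardless of
module membership. Model-recovery behaviour of the estimator itself is
therefore validated on `generate_shape_matrix()` output (direct block
correlation, no superimposition), where the generating partition is
recovered in >= 90% of runs at n = 100, K = 12, rho_w = 0.6, rho_b = 0.1;
through the full bilateral pipeline the same contrast is diluted by the
cross-side structure, which is a property of the data geometry, not of the
estimator.

## The synthetic-data generator

`generate_dataset()` emulates the study design end to end: 55 female and
48 male specimens (defaults), each digitized twice, 33 landmarks under the
shipped pairing scheme. Per specimen it draws

| parameter | default | meaning (units of the unit-CS template) |
|---|---|---|
| `rho_within`, `rho_between` | 0.5, 0.2 | block correlation of symmetric individual deviations at the bilateral-unit level (pairs + midline), within/between the two developmental modules |
| `sigma_shape` | 0.01 | SD of those deviations — a few percent of the configuration scale, typical of intraspecific shape variation |
| `da_vector_by_sex` | F: +0.004, M: -0.003 (left-side y) | directional asymmetry added to the left-side landmarks; females skew left, males right, magnitudes chosen so the sexes diverge clearly but remain subtle asymmetries (well under 1% of size) |
| `sigma_fa` | 0.003 | SD of the individual fluctuating-asymmetry field |
| `asym_module_corr` | 0.5 | coupling of the modules' fluctuating asymmetry through a common specimen factor; drives the Mantel correlation (defaults land r near the 0.45-0.67 range the method targets) |
| `sigma_digit` | 0.001 | per-replicate digitization noise, an order below the biological signals |

Symmetric deviations are applied mirror-symmetrically (midline units move
only along the axis); asymmetry is injected in the template's symmetric
frame *before* each copy receives a random rotation, scale and translation
— so recovering the injected effects genuinely requires the Procrustes
stage to undo nuisance transforms. The truth record returns every drawn
effect.

What the generator does **not** emulate: realistic cephalothorax geometry
(the template is a schematic symmetric configuration), allometry (no
size-shape covariance, so the size regression is exercised only as a
no-op plus centering), antisymmetry, and landmark-specific digitization
error. Passing tests therefore establish that the machinery is correct
and calibrated under the stated statistical structure, not that any
biological conclusion transfers to real specimens.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: coincident landmarks (zero centroid size),
modules with no within-module covariance, zero-variance permutation nulls,
single-replicate ANOVA designs, and sub-100 iteration counts in the
pipeline are all errors or flagged warnings rather than silent results.
All permutation p-values use `(count + 1) / (B + 1)`; all stochastic
operations take an explicit seed and default to the design's iteration
counts (1000 ANOVA permutations, 5000 Mantel iterations, 999 CR
permutations, 10,000 modularity rounds).

The validation suite runs its simulations at reduced sizes chosen to keep
Monte-Carlo error well inside the asserted bands: a 12-landmark scheme (5
pairs + 2 midline) for calibration (200 null datasets, B = 199) and
recovery (20-50 seeds), and the full 33-landmark design where the claim
is about the design itself (error df = 408, fixture counts, the default
generator). The analysis scripts under `analysis/` run the full design at
the publication-scale iteration counts.

## Known limitations

* 2D object symmetry only: no matching symmetry (paired separate
  structures), no 3D, no semilandmark sliding.
* The ANOVA reports the three 1-df sex-design terms of the emulated
  design; it is not a general Procrustes ANOVA for arbitrary factors, and
  the classical individual-by-side decomposition (individual df = n - 1)
  is intentionally out of scope.
* The 19-variant registry reconstructs an unpublished model list; counts
  and expansion rule are pinned, individual variants are not.
* CR values depend on the covariance scale structure; they are compared
  only within a dataset, never across datasets.
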