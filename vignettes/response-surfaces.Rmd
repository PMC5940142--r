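---
title: "Methods: response-surface QTL mapping and surface-shape modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface QTL mapping and surface-shape modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfqtl)
```

## The phenotype is a surface

When drought and nitrogen limitation act together, growth cannot be
summarised by one number per genotype: the response is a surface
$z(x_w, x_n)$ over the two stress axes. `surfqtl` works throughout in
*recentred* coordinates — water percentage minus 50 and nitrogen
percentage minus 7.5 — so the design levels $\{8, 20, 50, 80, 92\}$ and
$\{0, 2.5, 7.5, 12.5, 15\}$ land exactly on $\{-42, \dots, 42\}$ and
$\{-7.5, \dots, 7.5\}$, and the design centre is the origin. The
evaluation plane is the rectangle $[-42, 42] \times [-7.5, 7.5]$,
discretised with step 0.5 into a $169 \times 31$ grid (`eval_grid()`).
Peaks are reported as *grid* maxima, not analytic optima: the reference
peak table is grid-quantised (the analytic B73 optimum is (28.70, 4.59)
but the tabulated peak is (28.5, 4.5)), and `find_peak()` therefore scans
nodes exhaustively, breaking ties towards smaller $x_w$ then smaller
$x_n$.

## The quadratic mixed model and the marker scan

Growth (difference in height, cm) for line $i$ at stress combination
$(x_w, x_n)$ is modelled as

$$
z = \mu + \alpha_i + \beta_1 x_w + \beta_2 x_n + \beta_3 x_w^2 +
    \beta_4 x_n^2 + \beta_5 x_w x_n + \varepsilon,
$$

with $\alpha \sim N(0, \sigma^2_{line} K)$ for an allele-sharing kinship
matrix $K$ and $\varepsilon \sim N(0, \sigma^2_{resid})$ i.i.d. The model
is *statistically* linear but represents a curved (elliptic or
hyperbolic) surface; the $\beta_5$ term carries the water-by-nitrogen
interaction hypothesis.

Key estimation choices:

* **Variance components once, not per marker.** REML estimates
  $(\sigma^2_{line}, \sigma^2_{resid})$ on the all-inclusive
  (single-surface) model only; every marker model reuses them. This keeps
  the residual sums of squares comparable across nested models — the scan
  compares RSS directly — and avoids the instability of re-estimating two
  variance components on each allele split at the study's population
  size.
* **Low-rank REML.** The covariance $V = \sigma^2_{line} Z K Z^\top +
  \sigma^2_{resid} I$ has a rank-$q$ structured part ($q$ = number of
  lines), so whitening, determinants and generalised least squares are
  computed from the thin SVD of $Z\,\mathrm{chol}(K)^\top$ and a
  one-dimensional profile-REML search on the variance ratio. This is
  exact, transparent, and fast enough to rerun inside replicated
  simulation tests. When $\sigma^2_{line} = 0$ the fit reduces exactly to
  ordinary least squares (asserted against an `lm()` oracle in the
  tests).
* **Marker models share the whitening.** At each marker, lines with a
  missing call are dropped *for that marker only*, the all-inclusive RSS
  is recomputed on the reduced records, and one 12-column GLS estimates a
  six-coefficient surface per allele group under the same covariance.
  Fitting both groups jointly under the shared whitening (rather than two
  independent fits) is what the "same covariance" requirement means once
  kinship correlates lines across groups, and it makes the nesting
  $RSS_1 \le RSS_0$ exact.
* **F test.** $F = ((RSS_0 - RSS_1)/6) / (RSS_1/(n - 12))$ with p-values
  from $F_{6, n-12}$: the marker model adds one full coefficient set
  (6 parameters). The reference analysis does not print its degrees of
  freedom; this nesting-based choice is the natural one and is what the
  calibration tests validate. Markers whose minor allele class has fewer
  than 10 observations are skipped and flagged (threshold configurable).
* **Smoothing and multiplicity.** Raw p-values are combined over sliding
  windows of (default) 5 map-adjacent markers with the Simes rule
  $\min_k w\,p_{(k)}/k$, truncated at chromosome ends and never spanning
  chromosomes. The window size is a documented default (the reference
  analysis cites a smoothing procedure without its window); it is an
  argument everywhere it matters. Smoothed values are then adjusted by
  Benjamini–Hochberg FDR and by the Sidak experiment-wise threshold
  $1 - (1-\alpha)^{1/m}$, and maximal runs of adjacent significant
  markers become QTL intervals.

A limitation worth stating plainly: the random effect is a line
*intercept*. A causal locus changes a line's whole surface, which an
intercept cannot absorb, so a very large allele contrast elsewhere in the
genome inflates the evidence at weakly correlated unlinked markers. The
calibration guarantees in the test suite are for the global null; with a
planted locus the scan is guaranteed to rank the causal region first at
the tested effect sizes, not to stay silent elsewhere.

## Kinship

Relatedness is estimated as identity-in-state: the proportion of markers,
non-missing in both lines, carrying the same allele, with unit diagonal.
The scan only needs a *relative* covariance scale, and this estimator is
transparent and dependency-free. Two numerical safeguards: a ridge
(default $10^{-6}$) keeps the matrix invertible, and — because
pairwise-complete estimation under missing calls can produce small
negative eigenvalues — the spectrum is clipped at zero before the ridge
is applied. With complete data the clip is a no-op.

## The synthetic experiment

The generator reproduces the statistical structure the analysis assumes,
at the study's stated conditions; its defaults *are* those conditions.

* **Population**: 89 fully homozygous recombinant inbred lines from a
  biparental cross. Alleles follow a two-state Markov chain along each
  chromosome with Haldane recombination fractions
  $r = (1 - e^{-2d/100})/2$ on map distances multiplied by an expansion
  factor (default 4) — intermated populations have expanded effective
  maps, and a scalar factor reproduces the marker autocorrelation that
  matters downstream without simulating intermating generations
  explicitly. The default map (10 chromosomes × 20 markers × 120 cM) is a
  package choice at the scale of the real marker set.
* **Design**: a face-centered two-stress layout. The reference experiment
  states five levels per stress, nine combinations, and replicate counts
  of 4 or 8 with heavier central replication, but not the identity of the
  nine points; the default places the four extreme corners and four
  mid-level "face" points at $n = 4$ and the centre at $n = 8$, spanning
  all five levels of each factor. This allocation is an assumption and is
  fully configurable. Every line receives every combination at its
  replicate count (the reading of the replicate semantics that supports
  per-allele surface fits); the variance-recovery checks use one
  replicate per combination, i.e. 89 × 9 records.
* **Phenotypes**: growth = baseline + causal allele surfaces
  (producing functions per allele) + kinship-structured line effect +
  Gaussian noise; initial height $N(15, 2^2)$ cm and final = initial +
  growth. Defaults: baseline 25 cm (the scale of the reference fits'
  lumped constants), $\sigma_{line} = 2$ cm, $\sigma_{resid} = 3$ cm —
  seedling-growth measurement noise of a few centimetres. Lines missing a
  call at a causal marker receive the average of the two allele effects.
* **Reproducibility**: every stochastic operation takes one integer seed;
  identical seeds give byte-identical outputs end to end.

What the generator does *not* emulate: greenhouse spatial structure,
segregation distortion, heterozygosity, genotyping error, epistasis, and
non-Gaussian measurement error. Passing tests therefore demonstrate
correctness of the machinery under the model's own assumptions, not
robustness of the scan to violations of them.

## The producing function and its estimation

The shape model is the sum of an elliptical paraboloid and a plane:

$$ z = c\,(a x_w^2 + b x_n^2) + d x_w + e x_n , $$

with no constant term (the surface is pinned to zero at the origin). $c$
scales and flips the paraboloid — $c < 0$ gives the convex-upward domes,
$c > 0$ the Mo17-type trough — while $a, b$ weight the two inputs and
$d, e$ tilt the plane. Only the products $ca$ and $cb$ are identifiable
from data, so `fit_producing()` presets $c \in \{-1, +1\}$ to match the
surface's convexity and reports $a, b$ jointly interpretable with that
preset. Estimation is ordinary least squares on the basis
$(c x_w^2, c x_n^2, x_w, x_n)$ via QR; the scalar error $s$ is the square
root of the objective at the solution and the constraint-violation
residual norm is identically zero for this unconstrained problem (both
are reported, mirroring the two norms of constrained linear solvers).
Exact recovery of model-class surfaces to $10^{-8}$ on any full-rank mesh
of at least four points is asserted against a normal-equations oracle.

### Meshes

Two mesh flavours discretise a surface:

* **Absolute mesh** (for parameter estimation): rays from the peak at
  fixed angles (default $0, \pm15, \pm30, \pm45$ degrees) about the
  surface's *local axis* — the slow-curvature Hessian eigenvector for
  elliptic surfaces, the asymptote bisector for hyperbolic ones —
  intersected with contours at fractional depths (default
  $\{0.05, 0.15, 0.30, 0.50\}$ of the peak-to-ray-end drop), each
  crossing located by bisection to $|\Delta z| < 10^{-6}$ (far below
  phenotype noise). The reference analysis never prints its contour
  levels or angles, so these defaults concentrate points in the central,
  best-determined region and are exposed as arguments; consequences are
  discussed under Limitations. Each ray is oriented towards the longer
  clipped segment so it runs into the plane interior; rays pinned at a
  corner may have zero length and are flagged.
* **Relative mesh** (for shape comparison): ten points at uniform
  fractions $k/10$ of each clipped ray segment, along six rays of fixed
  slopes $\{0, 0.05, 0.099, 0.175, 0.32, 0.75\}$ extending leftwards and
  downward from dome-type peaks; trough-type surfaces negate the slopes
  and extend rightwards. Uniform spacing is the simplest reading of
  "equal relative distances"; 6 rays × 10 points give the 60-point
  descriptor, with 9 bands per ray.

## Shape similarity

Three scores compare an experimental surface (e) with a simulated model
surface (s) at corresponding relative mesh points:

* $\rho$ — Euclidean displacement in $(x_w, x_n, z)$, signed by the
  direction of the $z$ difference (positive when the simulation sits at
  or above the experiment). The sign labels direction; it never zeroes
  the magnitude of a purely planar displacement.
* $\theta$ — the angle subtended at the *evaluation-plane origin* between
  the projected point positions, counter-clockwise positive. Measuring at
  the origin is the convention under which peak shifts and differing ray
  lengths legitimately show up as apparent rotation; rays drawn from each
  surface's own peak would make the score identically zero.
* $\delta z_r$ — per band, the difference of discrete $z$ gradients, each
  normalised by its surface's planar step and full grid amplitude
  $|z_{max} - z_{min}|$, so the score reflects bending, not scale;
  negative values mean the simulation descends more steeply.

`compare_all()` assembles the scores for every admitted pair into
matrices whose columns form concentric rings around the peaks (position 1
of all rays, then position 2, ...), with each experimental surface's
model sibling first. Model surfaces are excluded, with a logged reason,
when their analytic critical point falls outside the evaluation plane
inflated by 10%, or when their relative mesh collapses entirely (a peak
pinned on an outward edge) — principled versions of the displacement
exclusions applied in the reference analysis. The concatenated descriptor
has $60 + 60 + 54 = 174$ entries under the defaults.

## Problem sizes in the test suite

The replicated statistical checks run at the study's population scale
(89 lines, the default design) with a reduced marker panel: 200 null
scans of a 2 × 10-marker genome for the uniformity and family-wise-error
checks, 20 seeds for scan power, and 20 seeds at 89 × 9 records for
variance-component recovery. These sizes give the binomial/KS assertions
comfortable resolution while keeping the suite quick to rerun during
development.

## Known limitations

* The exact published producing-function estimates (parameter values and
  $s$) depend on unprinted mesh contours and angles and are therefore not
  a reproduction target; the package instead guarantees exact recovery on
  model-class surfaces and reports its own fits of the reference surfaces
  descriptively. Because the model has no intercept, fits to surfaces
  with a large constant offset necessarily absorb the offset into the
  plane/paraboloid terms, and parameter signs are sensitive to the mesh.
* Reproducing the original study's mapped loci requires its genotype and
  phenotype files, which are not bundled; the end-to-end integration
  check runs the identical pipeline on the synthetic emulation instead.
  Scan outcomes on real data are additionally sensitive to the smoothing
  window and covariance parameterisation, which is why both are exposed
  rather than fixed.
* No composite-interval mapping, no epistasis scan, and no nonlinear
  (five-parameter) optimisation of the producing function: linear-fit
  estimates make poor starting points for such an optimisation, and that
  extension is left open here as it is in the reference analysis.
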