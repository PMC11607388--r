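---
title: "A two-dimensional model of cortical sensory integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-dimensional model of cortical sensory integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensoangle)
```

## The model

Sensory information enters the cortex through the primary visual (V1),
somatosensory (areas 1, 2, 3a, 3b) and auditory (A1) cortices and becomes
progressively more abstract and multimodal as it ascends toward
association cortex. `sensoangle` summarizes where every cortical location
sits in that process with two numbers derived from its BOLD time series.

**Sensory parameters.** The mean time series of the three primary parcels,
$t_V$, $t_S$, $t_A$, are used as regressors for every vertex series $Y$
under a non-negativity constraint:

$$Y = \beta_V t_V + \beta_S t_S + \beta_A t_A + \varepsilon,
\qquad \beta_V, \beta_S, \beta_A \ge 0.$$

The constraint encodes the assumption that a vertex *receives* primary
sensory signal in some proportion; anticorrelation is treated as absence
of drive, not negative drive. The fit is the Lawson–Hanson active-set
solution (`pracma::lsqnonneg`) applied independently per vertex in a
fixed vertex order, so results are bit-reproducible.

**Sensory angle.** The coefficient triple is mapped to a point on the
unit circle by the hue transformation of color science, treating
$(\beta_V, \beta_S, \beta_A)$ as an RGB triple: with
$\Delta = C_{max} - C_{min}$,

$$\theta = \begin{cases}
0^\circ & \Delta = 0 \\
0^\circ + 60^\circ (\beta_S - \beta_A)/\Delta & C_{max} = \beta_V \\
120^\circ + 60^\circ (\beta_A - \beta_V)/\Delta & C_{max} = \beta_S \\
240^\circ + 60^\circ (\beta_V - \beta_S)/\Delta & C_{max} = \beta_A
\end{cases}$$

reduced mod 360 into $[0^\circ, 360^\circ)$. Visual, somatosensory, and
auditory dominance anchor at 0°, 120° and 240°; intermediate angles
express integrative mixtures. Negative raw values (possible in the first
branch) wrap; exact ties at the maximum between non-adjacent channels are
broken in branch order (V, S, A), while ties between hue-adjacent
channels give the same angle from either applicable branch, so the
mapping is continuous.

**Sensory magnitude.** For each vertex the proportion of variance
explained by the primary signals is

$$SS_{total} = \sum (Y - \bar Y)^2,\quad
  SS_{exp} = \sum (Y_{pred} - \bar Y)^2,\quad
  R^2 = SS_{exp}/SS_{total},$$

where $\bar Y$ is by default the *globally averaged time series* (the
across-vertex mean signal at each timepoint). A configuration switch
(`ybar = "temporal_mean"`) substitutes the per-series temporal mean,
which makes $R^2$ the classical coefficient of determination; the
default follows the global-mean convention and both are recorded in the
fit object. The $R^2$ values are ranked (average ranks on ties) and the
ranks rescaled onto $[0, 1]$ as $(rank - 1)/(n - 1)$. High magnitude
marks primary cortex; low magnitude marks transmodal cortex, so the
magnitude map is a rank-based proxy for position in the cortical
hierarchy. Vertices with $SS_{total} = 0$ or a raw ratio above 1 (beyond
a $10^{-10}$ numerical guard) are flagged, excluded from the ranking, and
emitted as `NA`.

For display, angle and magnitude map to color as HSV hue and saturation
with fixed brightness 0.86 (`color_encode()`), the hexcone model.

## Preprocessing assumptions

The pipeline expects surface-sampled, denoised data (e.g. the standard
minimal-preprocessing outputs). In scope here: discarding rest-interval
volumes of movie runs plus the 10 volumes after each rest block
(hemodynamic lag; `lag_volumes` is tunable, in volumes), per-series
standardization, and run concatenation — in that fixed order, so means
and SDs are computed on retained volumes only. The SD convention is the
population SD (divide by $N$); "subtract the mean, divide by the
standard deviation" does not by itself distinguish $N$ from $N-1$, so
the choice is exposed as `sd_method` and recorded. Geodesic smoothing is an out-of-scope external step: the
functions accept pre-smoothed input. Rest masks are user-supplied per
run; nothing is auto-detected.

## Reliability and comparison statistics

Angle maps are compared with a **circular correlation**; magnitude maps
with Spearman rank correlation. The package default is the Fisher–Lee
T-linear coefficient,

$$r = \frac{\sum_{i<j} \sin(a_i - a_j)\,\sin(b_i - b_j)}
  {\sqrt{\sum_{i<j} \sin^2(a_i - a_j)\sum_{i<j} \sin^2(b_i - b_j)}},$$

computed through $O(n)$ trigonometric identities. The more common
Jammalamadaka–SenGupta estimator (available via
`method = "jammalamadaka"`) centers each vector on its sample circular
mean; for sensory-angle maps that mean is degenerate, because the angle
distribution concentrates near three anchors 120° apart and the sample
resultant nearly vanishes, leaving the centering direction arbitrary.
In simulation this produced coefficient swings of more than 0.5 between
statistically equivalent session pairs whose vertexwise angular
agreement was a few degrees. The Fisher–Lee form involves no circular
mean and is stable in exactly this regime, which is why it is the
default; the choice is recorded in CLI provenance output.

The dissimilarity between two angles (between states, or between
corresponding vertices of the two hemispheres) is the **angular
variance** $V = 1 - \lVert(e^{i\theta_1} + e^{i\theta_2})/2\rVert \in
[0, 1]$, with the signed wrapped difference kept alongside for direction
display. Cluster-mean sensory parameters are compared across states with
classical paired t tests.

## Cluster-based sign-flip inference

Group-level localization uses a 95th-percentile threshold (linear
interpolation, strict exceedance) on the group-mean difference map,
connected components under shared-triangle-edge adjacency as clusters
(extent = vertex count; hemispheres clustered separately), and a
sign-flip permutation null: in each of 5000 permutations (500 in the
package's own scaled-down experiments) every subject's whole map is
multiplied by an independent fair coin, the permuted group mean is
re-thresholded at its own 95th percentile, and the maximum cluster size
recorded. Cluster $p$-values use the add-one rule
$p = (1 + \#\{null \ge observed\})/(1 + n_{perm})$ with inclusive
comparison, so the smallest attainable $p$ is $1/(n_{perm}+1)$; the
95th percentile of the null maximum sizes is reported as the
cluster-size threshold. The identity permutation is not forced into the
null, and the permutation RNG is seeded, so results are reproducible
and independent of any parallel execution order.

For angle contrasts the flipped quantity is the per-subject angular
variance map, which is non-negative; the test is therefore conservative
by construction and only has power when the background of the $V$ map
carries variability comparable to the effect (see the generator notes
below — this is a property of the published procedure itself, which we
reproduce literally rather than repair).

## The synthetic-data generator

`make_sphere_mesh()` builds icospheres ($10 \cdot 4^s + 2$ vertices)
as mirrored left/right pairs with index correspondence, and
`make_parcellation()` places three 120°-separated geodesic caps as V1,
A1, and a four-quadrant somatosensory strip (areas 1/2/3a/3b), leaving
the rest as association cortex. Ground-truth mixing weights decay with
squared geodesic distance from each cap center
(`baseline + exp(-d^2/(2*lambda^2))`, baseline 0.1, decay length 0.7
rad), which reproduces the qualitative gradients of primary-sensory
association. Latent primary signals are standardized AR(1) series
(autocorrelation 0.3, giving split-half sessions realistic serial
structure) with equicorrelation 0.3 imposed by a Cholesky square root —
a moderate collinearity regime (VIF = 1.5 at correlation 0.5 is verified
separately as the closed-form case).

Each dataset is $Y_v = \beta_v^\top t + \varepsilon$ with a single
global noise SD equal to `noise_level` (default 0.5) times the
root-mean signal SD, then standardized. Subject identity is an
elementwise lognormal jitter of the weights (sdlog 0.1) persistent
across states and sessions; each subject-state additionally receives a
hue-rotation field with SD 20° (`angle_noise_sd`), modeling the
scan-level variability of functional topography that real individual
angle maps exhibit. That last term matters twice: it brings the
group-level same-state split-half reliability of synthetic angle maps
into the empirically reported range (circular correlations around
0.9–0.97), and it gives individual angular-variance maps a non-trivial
background, without which the sign-flip cluster test cannot reject at
all (a noiseless-background patch dominates every permutation's top 5%
and the null maximum cluster equals the observed one). The 20° default
was fixed from the reliability calibration, not from any downstream
test outcome.

Between-state contrasts are emulated by rotating hue inside designated
patches while preserving chroma and baseline, so magnitudes stay put
while angles move — matching the empirical observation that magnitude is
state-stable and angle state-dependent. The default movie-vs-rest
analogue (`between_state_scenario()`) rotates the three
nearest-primary-cap association sectors heterogeneously (+100°, −80°,
−85°), following the reported directions and sizes of state-dependent
cluster shifts; a homogeneous rotation would barely move the circular
correlation, which is rotation-invariant.

The closed-form truth for the explained-variance ratio
(`true_r_squared()`) is derived under the same global-mean reference
convention the pipeline uses; it neglects $O(1/n_{vertices})$
mean-series noise terms, which the long-run simulation test makes
visible at small vertex counts.

What the generator does *not* emulate: hemodynamic convolution,
physiological noise spectra, motion, spatial autocorrelation of the
noise, realistic parcel geometry, and model mismatch (every synthetic
vertex truly is a non-negative mixture of the three signals). Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to their
violation in real data.

## Problem sizes and numerical choices

The package's own validation experiments use icospheres of 162 and 642
vertices, 300–900 timepoints, 10–20 subjects, and 500 permutations —
sizes chosen so the full suite runs on a laptop in minutes while keeping
Monte-Carlo error small relative to the tested margins. Specific
choices worth knowing:

* Vertex indices are 1-based internally (the natural R convention; a
  single internal convention is what prevents off-by-one cluster
  errors), converted at the GIFTI/CIFTI boundary where files are
  0-based.
* Percentiles use R's default linear-interpolation quantile (type 7).
* The non-negative fit flags rank-deficient predictor matrices but
  still returns the active-set solution.
* Circular means are declared undefined below a resultant length of
  1e-12 and emitted as `NA`.
* An exact fit can produce $R^2$ marginally above 1 in floating point;
  ratios above $1 + 10^{-10}$ are flagged, smaller excursions clipped.
* Angle values of exactly 360 after wrapping are mapped to 0 to keep
  the $[0, 360)$ contract.
* `write_scalar_map()` validates the angular domain for maps named
  `"angle"`, because a 360.0 written to disk would silently alias 0.

## Known limitations

The hue transform is three-channel by construction; more than three
sensory systems would need a different embedding. The hexagonal
decoding stage takes the term-by-ROI z-matrix as an input — the
meta-analytic database query that produces it is outside the package.
The "weight of each ROI based on its z-values" aggregation for a term's
hierarchical magnitude is implemented as the z-weighted mean of
hierarchical weights normalized by the count of surviving ROIs,
mirroring the angle aggregation; this is the module's main interpretive
choice and is deliberately symmetric with the angle formula. Left/right
correspondence relies on the symmetric-mesh convention that identically
indexed vertices correspond; no resampling is performed.
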