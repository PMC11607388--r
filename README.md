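# sensoangle

Two-dimensional mapping of sensory integration on the cortical surface.

Cortical processing is organized along a hierarchy from primary sensory
areas to transmodal association cortex, and most locations mix input
from more than one sensory system. `sensoangle` characterizes every
vertex of a surface-sampled fMRI dataset with two numbers:

* **Sensory angle** θ ∈ [0°, 360°): the mean time series of the primary
  visual (V1), somatosensory (areas 1/2/3a/3b) and auditory (A1)
  parcels are fit to each vertex series by non-negative least squares,

  Y = β_V t_V + β_S t_S + β_A t_A + ε,  β ≥ 0,

  and the coefficient triple is converted to an angle by the
  color-science hue transformation, with visual, somatosensory and
  auditory dominance anchored at 0°, 120° and 240°. The angle expresses
  the *proportional contributions* of the three systems and is
  state-dependent.

* **Sensory magnitude** r ∈ [0, 1]: the proportion of each vertex's
  variance explained by the primary signals
  (R² = SS_exp / SS_total, reference series = global mean signal),
  rank-rescaled across vertices. Magnitude decreases along the
  unimodal-to-transmodal hierarchy and is highly stable across states.

Around this core the package provides surface I/O (tab-separated,
GIFTI, CIFTI-2 dense formats, with mesh adjacency from shared triangle
edges), the in-scope preprocessing steps (rest-volume trimming with
hemodynamic lag, standardization, run concatenation, test/retest
session splitting), reliability statistics (Fisher–Lee circular
correlation for angles, Spearman for magnitudes), between-state and
between-hemisphere comparison (angular variance, paired t tests,
sign-flip cluster-based permutation inference on the mesh),
meta-analytic hexagonal decoding of functional topic terms, and a
synthetic-data generator with closed-form ground truth that makes the
whole pipeline testable without any external download.

## Worked example

Simulate a small synthetic cortex (162-vertex icosphere, three primary
caps), fit the model, and inspect the two dimensions:

```r
library(sensoangle)

mesh  <- make_sphere_mesh(2)$left
parc  <- make_parcellation(mesh)
truth <- synthetic_truth(mesh, parc, noise_level = 0.5)
data  <- generate_dataset(mesh, parc, truth, n_subjects = 1,
                          n_timepoints = 600, seed = 42)

fit <- build_sensory_map(data[[1]]$state1, parc)
print(fit)
#> <sensory_fit> 162 vertices; ybar = global_mean
#>   VIF: t_V=2.31 t_S=2.67 t_A=2.08
#>   angle range: [0.0, 359.7] deg
```

A vertex inside the V1 cap sits near the visual anchor with high
magnitude; an association vertex sits at an integrative angle with low
magnitude:

```r
#> V1 vertex 42:    angle 357.2 deg, magnitude 0.944, R2 0.588
#> assoc vertex 2:  angle  61.3 deg, magnitude 0.398, R2 0.246
#> median |angle error| vs ground truth: 6.0 deg
```

The VIF line reports predictor collinearity; the angle error compares
the recovered angles with the generator's known mixing weights.
`color_encode(fit)` turns the map into RGB (hue = angle, saturation =
magnitude, brightness 0.86) for surface rendering.

Decoding places functional topic terms in the hexagonal coordinate
space from a term-by-30-ROI z-value matrix:

```r
z <- matrix(0, 2, 30, dimnames = list(c("visual_perception", "speech"), NULL))
z["visual_perception", c(25, 26)] <- c(5, 3)
z["speech",            c(23, 29)] <- c(6, 4)
project_terms(z)
#>                                term     D   m    M     x      y
#> visual_perception visual_perception  13.8 3.6 3.21  3.12  0.768
#> speech                       speech 240.0 3.9 3.38 -1.69 -2.925
```

`speech`, loading only auditory-dominant ROIs, lands exactly on the
auditory anchor (D = 240°); a mostly-visual term lands near 0°. M is
the hexagon-corrected radius (M = m·√(3/4)/cos(D mod 30°), branch by
d = ⌊D/30⌋ mod 2).

A thin CLI wrapping these functions is installed at
`system.file("cli", "sensoangle", package = "sensoangle")` with
`simulate`, `fit`, `compare-states` and `decode` subcommands.

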