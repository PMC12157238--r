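# gojivision

Recognition and localization of wolfberry (goji berry) fruits and branches
from RGB-D images, for harvesting-robot vision systems.

Wolfberries are small, tender fruits picked at close range (20–30 cm) under
uncontrolled field lighting. `gojivision` implements a classical,
training-free vision pipeline for this setting:

- **Fruit segmentation by chroma-feature fusion.** Two
  illumination-robust feature images are extracted from the RGB frame: the
  a\* plane of a chromaticity-normalized Lab representation (green ↔ red
  axis) and the I plane of YIQ (orange ↔ cyan axis). Both are rescaled to
  \[0, 255\] and fused coefficient-by-coefficient through a 3-level
  orthogonal wavelet transform — detail (high-frequency) coefficients by
  the maximum-absolute-value rule, approximation (low-frequency) planes by
  the weighted average *C<sub>f</sub> = α C<sub>a</sub> + β C<sub>I</sub>*
  with α = β = 0.5. The fused image has a bimodal gray histogram; it is
  binarized at the valley between the two modes, cleaned by morphological
  opening and a 100-pixel connected-component area filter, and each
  surviving component is localized by its first moment (centroid)
  *X = Σx/N, Y = Σy/N* over member pixels.
- **Branch segmentation by K-means in Lab space.** Pixels are clustered
  (K = 8, Lloyd's algorithm) on (L\*, a\*, b\*); the clustered image is
  rendered at one gray level per cluster, the dark cluster group is
  selected, and the *longest* region — largest bounding-rectangle height —
  is refined by median filtering (window 3) and a 2×2 morphological
  opening. The gripping point for the robot end effector is the region's
  centroid if it lies on the branch, otherwise the branch pixel nearest to
  it.
- **3D localization.** With a depth map and pinhole intrinsics, pixel
  targets back-project to camera coordinates via *Z = d·s*,
  *X = (x−c<sub>x</sub>)Z/f<sub>x</sub>*, *Y = (y−c<sub>y</sub>)Z/f<sub>y</sub>*.
- **Synthetic orchard scenes.** A seeded generator renders
  ground-truthed scenes (red elliptical fruits, mottled green foliage, an
  elongated grey-brown branch, illumination gradients, occlusion patches,
  impulse noise, matching depth maps), so every stage is testable without
  field data.

## Worked example

```r
library(gojivision)
intr <- camera_intrinsics(600, 600, 319.5, 239.5)  # fx, fy, cx, cy

# --- fruits -------------------------------------------------------------
scene  <- generate_scene(scene_spec(branch = FALSE, seed = 42))  # 640 x 480
fruits <- segment_fruits(scene$rgb, depth = scene$depth, intrinsics = intr)
fruits
#> <fruit_segmentation> 5 fruit(s), threshold 156 (valley), channel fused
#> # A tibble: 5 x 12
#>   centroid_x centroid_y  area  xmin  xmax  ymin  ymax depth        X       Y
#> 1       79.2      429.    215    70    88   422   436  222. -0.0888   0.0700
#> 2      193.       293.    554   182   205   279   307  227. -0.0477   0.0204
#> 3      326.        59.1   605   312   339    46    72  211.  0.00219 -0.0633
#> 4      452.       366.    469   440   465   356   377  234.  0.0518   0.0495
#> 5      549.       162.    504   535   562   151   173  267.  0.102   -0.0344
```

All five ground-truth fruits are recovered; centroids land within a
fraction of a pixel of the generator's recorded first moments (compare
`scene$truth$fruit_centroids`), and `X`, `Y`, `Z` are camera-frame meters
read through the depth map (fruits sit at the 200–300 mm working
distance). `threshold 156 (valley)` says the binarization threshold was
found at the histogram valley rather than by the variance-split fallback.

```r
# --- branch -------------------------------------------------------------
orchard <- generate_scene(scene_spec(seed = 42))     # foliage + fruits + branch
branch  <- segment_branch(orchard$rgb, depth = orchard$depth, intrinsics = intr)
branch
#> <branch_segmentation> region 4323 px (height 480), grip (300, 240)
orchard$truth$branch_mask[branch$grip_point$y + 1, branch$grip_point$x + 1]
#> [1] TRUE
```

The selected region spans the full image height (the branch), and the
gripping point lies on the true branch mask. Results are tidyverse-ready:
`tidy()` returns the detections/grip tibble, `glance()` a one-row summary,
`autoplot()` a ggplot of the mask with markers.

A command-line interface wrapping the same functions lives at
`inst/cli/gojivision.R` (`segment-fruits`, `locate-branch`, `synth`,
`eval`; exit codes 0 ok / 2 bad input / 3 nothing found).

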