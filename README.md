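# muellermap

Pixel-wise analysis of multispectral Mueller-matrix images of biological
tissue, built around the workflow used to characterize fresh brain
specimens: reconstruct Mueller matrices from polarimetric intensity frames,
screen them for physical realizability, decompose them three ways, map
polarimetric purity and anisotropy, and classify grey versus white matter
from the decomposition parameters. A synthetic multispectral brain phantom
generator makes the entire pipeline runnable and testable without any
measured data.

## Who this is for

Researchers working with Mueller-matrix imaging polarimetry of scattering
tissue (neurosurgical guidance, tissue characterization, polarimetric
microscopy) who need a tested, scriptable implementation of the standard
analysis chain, and methods developers who want a reproducible synthetic
testbed with known ground truth.

## The core quantities

A Mueller matrix $M$ (4×4, real) is the complete linear polarization
transfer description of a sample; it is measured through
$\bar M = \mathrm{PSA}\, M\, \mathrm{PSG}$, where the PSG/PSA matrices
describe the generator and analyzer optics, and reconstructed per pixel by
least squares. Physically realizable matrices must have a positive
semi-definite coherency matrix $H(M)$ and satisfy passivity
($M_{00}(1 + \lVert\vec D\rVert) \le 1$, likewise for polarizance) — the
ensemble criterion, applied per pixel at tolerance $10^{-5}$.

From each valid pixel the package derives:

* **Indices of polarimetric purity** $P_1 \le P_2 \le P_3$ and the degree
  of purity $P_\Delta$, from the coherency eigenvalues; **anisotropy
  coefficients** $\alpha_L$, $\alpha_C$ with
  $P_\alpha = \sqrt{\alpha_L^2 + \alpha_C^2} \le P_\Delta \le 1$.
* **Forward polar (Lu–Chipman) decomposition** $M = M_\Delta M_R M_D$:
  depolarization $\Delta \in [0,1]$, retardance $R \in [0,\pi]$,
  diattenuation $D \in [0,1]$, and the linear-retardance axis
  $\theta \in (-\pi/2, \pi/2]$.
* **Symmetric decomposition**
  $M = M_{D2} M_{R2} M_{\Delta d} M_{R1}^{\mathsf T} M_{D1}$ with all
  depolarization confined to a diagonal depolarizer and a
  gauge-invariant total retarder.
* **Differential decomposition** $L = \ln M = L_m + L_u$: six mean
  spectroscopic properties from the G-antisymmetric part and the
  fluctuation variances/covariances from the G-symmetric part.
* **GM/WM classification**: class-balanced, leave-one-specimen-out
  cross-validated k-nearest neighbors on $[\Delta, R, D]$ per wavelength,
  with permutation feature importance and sequential floating feature
  selection, plus Mann–Whitney separability tests.

## Worked example

Decompose a known composed medium and map a synthetic phantom:

```r
library(muellermap)

m <- mm_depolarizer(0.55) %*%
  mm_linear_retarder(0.9, 25 * pi / 180) %*%
  mm_linear_diattenuator(0.15, 25 * pi / 180)
lu_chipman(m)
#> <polar_result> Delta = 0.4500, R = 0.9000 rad, D = 0.1500,
#>                theta = 0.4363 rad, residual = 1.12e-16
```

The decomposition recovers exactly the depolarization (1 − 0.55), the
retardance, the diattenuation, and the 25° axis (0.4363 rad) used to
compose the medium, with a reconstruction residual at machine precision.

```r
cfg <- phantom_config(size = 48, seed = 7)
ph  <- generate_phantom(cfg, specimen = 1, region = 1)
img <- screen_image(ph$images[[1]])      # 450 nm cube, realizability mask
img
#> <mueller_image> 48 x 48 pixels @ 450 nm (specimen 1, region 1); 100.0% valid

maps <- polar_maps(img)
dplyr::filter(summarize_regions(maps, ph$labels), quantity == "Delta")
#> # A tibble: 3 x 8
#>   label  wavelength quantity     n  mean median   q25   q75
#> 1 GM            450 Delta     1227 0.601  0.603 0.514 0.689
#> 2 WM            450 Delta      621 0.867  0.869 0.821 0.915
#> 3 vessel        450 Delta       88 0.812  0.818 0.732 0.892
```

Grey matter depolarizes markedly less than white matter at 450 nm (median
0.60 vs 0.87 here), which is the separation the classification stage
exploits. `autoplot(maps)` renders the parameter maps;
`run_pipeline(phantom_config())` executes the full simulate → screen →
decompose → summarize → classify chain and returns tidy per-fold
cross-validation reports (`tidy()`, `glance()`).

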