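---
title: "Methods: multispectral Mueller-matrix analysis of brain tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral Mueller-matrix analysis of brain tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellermap)
```

# The measurement model

A Mueller-matrix imaging polarimeter illuminates the sample through a
polarization state generator (PSG) and analyzes the backscattered light
through a polarization state analyzer (PSA). For analyzer row $a$ and
generator state $g$ the recorded intensity at a pixel is

$$\bar M_{ag} = \mathrm{PSA}_{a\cdot}\, M \,\mathrm{PSG}_{\cdot g},$$

so the measured intensity matrix is $\bar M = \mathrm{PSA}\, M\,
\mathrm{PSG}$. The built-in ideal instrument emulates a
division-of-focal-plane camera: the PSG is a fixed linear polarizer followed
by a quarter-wave plate at four orientations ($\pm 15.1^\circ, \pm
51.7^\circ$, the condition-number-optimal set for a rotating quarter-wave
generator — the instrument description fixes the *count* of states but not
their angles, so the package documents this choice as a constant), and the
PSA has eight rows: four micropolarizer orientations
($0/45/90/135^\circ$) with a retractable quarter-wave slider out and then
in. That yields $4 \times 2 \times 4 = 32$ frames per Mueller measurement;
six spectral filters and twenty measured regions give $3840$ frames and
$120$ Mueller matrices, which `plan_acquisition()` reproduces as plain
arithmetic. Reconstruction inverts the model per pixel as
$M = \mathrm{PSA}^{+} \bar M\, \mathrm{PSG}^{-1}$; with eight analyzer rows
this is the least-squares solution over all 32 frames (the protocol does not
state how the redundant rows are weighted, so uniform least squares is
used), and for a square four-row analyzer it reduces to the direct two-sided
inversion.

Conventions fixed package-wide: Stokes components $(I, Q, U, V)$ with $Q$ =
horizontal $-$ vertical; angles in radians; element axes measured from the
horizontal fast axis and folded into $(-\pi/2, \pi/2]$; "$(i,j)$" element
references are 0-based.

# Physical realizability

Measured matrices are screened pixel-wise by the ensemble criterion before
any further analysis. The coherency matrix

$$H(M) = \tfrac14 \sum_{ij} M_{ij}\, \sigma_i \otimes \sigma_j^{*}$$

(Pauli basis $\sigma_0 = I$, $\sigma_1 = \mathrm{diag}(1,-1)$, $\sigma_2$
real off-diagonal, $\sigma_3$ imaginary off-diagonal; conjugation of the
second factor makes the identity matrix map to a rank-one projector) must be
positive semi-definite, and the forward and reverse passivity conditions
$M_{00}(1 + \lVert\vec D\rVert) \le 1$ and
$M_{00}(1 + \lVert\vec P\rVert) \le 1$ must hold. The default tolerance is
$10^{-5}$. Two numerical choices deserve note:

* the eigenvalue tolerance is applied *relative to* $\mathrm{trace}(H)$,
  because matrices arrive at arbitrary intensity scale and an absolute
  $10^{-5}$ would be meaningless for a matrix scaled by $10^{-3}$;
* passivity needs the unnormalized $M_{00}$. Synthetic cubes store
  normalized matrices, so the screen uses the stored per-pixel `m00` plane
  when present and otherwise a configurable reflectance scale (default 0.4,
  comfortably inside the passive range for diffusely backscattering
  tissue).

Pixels that fail are excluded — maps show `NA` and no statistic ever
includes them. Failing pixels are not projected back onto the physical cone;
exclusion matches how measured artifacts (specular reflections, sample
edges) are handled.

# Purity and anisotropy

With the coherency eigenvalues sorted as
$\hat\lambda_0 \ge \dots \ge \hat\lambda_3$ (trace-normalized), the indices
of polarimetric purity are $P_1 = \hat\lambda_0 - \hat\lambda_1$,
$P_2 = \hat\lambda_0 + \hat\lambda_1 - 2\hat\lambda_2$, and
$P_3 = 1 - 4\hat\lambda_3$, combined into the degree of polarimetric purity
$P_\Delta = \sqrt{\tfrac13(2P_1^2 + \tfrac23 P_2^2 + \tfrac13 P_3^2)}$.
The $P_3$ form is the standard one consistent with the ordering chain
$0 \le P_1 \le P_2 \le P_3 \le 1$ and with both limits (all ones for a pure
matrix, all zeros for the ideal depolarizer); printed variants that violate
the chain are typographical.

The anisotropy coefficients read the complementary vectors $\vec k$,
$\vec r$, $\vec q$ off the lower-right $3\times3$ block and combine them
with the diattenuation and polarizance vectors:

$$\alpha_L = \frac{(D_1{+}P_1)^2 + (r_1{-}q_1)^2 + (D_2{+}P_2)^2 +
(r_2{-}q_2)^2}{\Sigma}, \qquad
\alpha_C = \frac{(D_3{+}P_3)^2 + (r_3{-}q_3)^2}{\Sigma},$$

with $\Sigma = 3(1 - \lVert\vec k\rVert^2) + 2\vec D^{\mathsf T}\vec P -
2\vec r^{\mathsf T}\vec q$ and
$P_\alpha = \sqrt{\alpha_L^2 + \alpha_C^2}$. The quantities in the
numerators are squared magnitudes of the G-antisymmetric (anisotropic)
content of $m$; writing $2A^2$ for their total, $\Sigma$ obeys the identity
$\Sigma = 3(1 - P_\Delta^2) + 2A^2$. Two consequences pin this form down as
the correct one among typographically plausible variants: every pure
anisotropic element saturates exactly ($\alpha_L = 1$ for a polarizer or
any linear retarder at any axis, $\alpha_C = 1$ for a rotator), and the
chain $P_\alpha \le P_\Delta \le 1$ is a theorem for every physically
realizable matrix (it reduces to $2A^2 \le 3P_\Delta(1+P_\Delta)$, which
follows from $A^2 \le 3P_\Delta^2$). Variants that take square roots of the
numerator terms individually lose rotation invariance and break the chain;
the test suite checks the chain on 10,000 random physical matrices.

# Three decompositions

**Forward polar (Lu–Chipman).** $m = M_\Delta M_R M_D$ with the
diattenuator built from the first row, the depolarizer block taken as the
signed symmetric square root of $m'm'^{\mathsf T}$ (sign branch from
$\det m'$; degenerate eigenvalues resolved by a deterministic
symmetric eigendecomposition with descending-eigenvalue order), and
$M_R = M_\Delta^{-1} m'$. Scalars: $\Delta = 1 - |\mathrm{tr}(M_\Delta) -
1|/3$, $R = \arccos(\mathrm{tr}(M_R)/2 - 1)$, $D = \lVert\vec D\rVert$.
Diattenuations within $10^{-9}$ of 1 are clipped and flagged rather than
inverted. The retarder is further split as $M_R = M_{LR} M_\psi$ (linear
retarder times rotator), choosing the rotation that symmetrizes the
upper-left $2\times2$ of the linear retarder's block, and the linear
retardance axis is the quadrant-correct estimate
$\theta = \tfrac12\,\mathrm{atan2}(M_{LR}(3,1) - M_{LR}(1,3),\,
M_{LR}(2,3) - M_{LR}(3,2))$ folded into $(-\pi/2, \pi/2]$ (a bare
arctangent would lose the quadrant). The axis is undefined — flagged, not
guessed — when the retardance is within $10^{-6}$ of $0$ or $\pi$.

**Symmetric.** $m = M_{D2} M_{R2} M_{\Delta d} M_{R1}^{\mathsf T} M_{D1}$
confines all depolarization to a diagonal depolarizer. The two
diattenuation vectors come from the eigenvector of the largest eigenvalue
of $M^{\mathsf T}GMG$ and $MGM^{\mathsf T}G$, scaled to first component 1;
when the leading eigenspace is degenerate (pure retarders: every vector is
an eigenvector) the projection of $(1,0,0,0)$ onto that eigenspace is used,
which correctly returns zero diattenuation. The stripped matrix is factored
by SVD; both singular frames are forced to proper rotations
(determinant $+1$), pushing any reflection into the sign of $d_3$. The
total retarder is the gauge-invariant product $M_R = M_{R2}
M_{R1}^{\mathsf T}$ — the retarder content of $m$ in its own factor order
with the depolarizer removed — which reproduces a pure retarder input
exactly and is unchanged by any common rotation inserted into the SVD
frames. Inputs whose $N = GM^{\mathsf T}GM$ is defective or has negative or
complex eigenvalues are flagged and mapped to `NA` with a logged count.

**Differential.** $L = \ln m$ is taken as the principal real logarithm via
the complex eigendecomposition; eigenvalues on the closed negative real
axis (possible when retardance near $\pi$ combines with strong
depolarization) have no principal logarithm and such pixels are excluded
and counted rather than branch-shifted — any branch choice would offset
retardance entries by multiples of $2\pi$. All quantities are per single
traversal ($z = 1$). The split $L = L_m + L_u$ into G-antisymmetric and
G-symmetric parts uses $G = \mathrm{diag}(1,-1,-1,-1)$. Six mean
spectroscopic properties (LDH, LD45, CD, LBH, LB45, CB) are read off the
fixed $L_m$ template with the printed signs. The fluctuation statistics
come from the identity $L_u = \tfrac12\langle \Delta L^2\rangle$ for a
zero-mean Gaussian G-antisymmetric perturbation of the six elementary
properties: carrying the template layout through the square gives the fixed
linear map

* $|\Delta L_H|^2 = L_{u,00} + L_{u,11} - L_{u,22} - L_{u,33}$,
* $|\Delta L_{45}|^2 = L_{u,00} - L_{u,11} + L_{u,22} - L_{u,33}$,
* $|\Delta C|^2 = L_{u,00} - L_{u,11} - L_{u,22} + L_{u,33}$,

with complex covariances from the off-diagonal pairs
($2L_{u,12} + 2iL_{u,03}$ and cyclic). The mapping is pinned by an
independent Monte-Carlo oracle: averaging $10^5$ matrix exponentials of a
randomly perturbed generator recovers a configured variance of $0.2$ to
well within 5%. Applicability of the differential model is the positive
semi-definiteness of the $3\times3$ Hermitian fluctuation covariance
assembled from these quantities — an exact reparameterization (10 degrees
of freedom on both sides) of the G-symmetric part once the isotropic
absorption entry $L_{u,00}$ is set aside. Per-wavelength summaries
aggregate the twelve quantities over the realizability mask with the mean
(the aggregation the summary tables of the measured study are most
consistent with; the median is available as an option).

# The synthetic phantom

The phantom generator defines the study conditions under which the whole
pipeline is exercised; no measured data is required. Each region is a
square image (64 px sides at study scale) with a branching white-matter
core (thresholded smooth Gaussian random field), a grey-matter ribbon
around it, two thin sinusoidal vessels, and a 2 px background border. Per
pixel and wavelength the ground-truth matrix is composed as
$M = M_\Delta(1{-}\Delta)\, M_R(R, \theta)\, M_D(D, \theta)$ — the same
order as the forward polar model, so the polar decomposition is an exact
inverse of the noiseless phantom (recovery to $10^{-6}$ is a test). The
other decompositions are validated on these phantoms through reconstruction
residuals, without assuming exactness.

Class parameter curves follow the reported tissue trends at the six
wavelengths (450, 500, 550, 590, 650, 680 nm):

* grey-matter depolarization rising 0.60 → 0.88 across the range,
  white matter 0.88 → 0.945, both with a multiplicative dip at 550 nm (9%
  for GM, 2% for WM, the hemoglobin-related feature imposed
  phenomenologically);
* median retardance 0.16 → 0.32 rad (GM) and 0.42 → 0.72 rad (WM);
* diattenuation below 0.04 everywhere with GM about half of WM
  (0.012/0.024 at 450 nm, decaying slightly to the red).

Within-class pixel spread emulates the reported distribution widths: the
depolarization SD is 0.13 for GM, 0.07 for WM (GM boxes are visibly
broader), retardance SD 0.28 rad and diattenuation SD 0.012 (heavily
overlapping between classes), all growing by a factor 1.3 from the bluest
to the reddest filter to emulate the noisier red acquisitions. Pixel noise
is drawn independently per wavelength. Specimen effects are multiplicative
log-normal factors (SD 0.08) per class and property, shared across
wavelengths within a specimen — this is what makes leave-one-specimen-out
folds genuinely harder than random splits and produces fold-to-fold
accuracy spreads of a few percent, as in the measured study. Parameters are
clamped to their physical ranges after jitter; the resulting point mass at
the depolarization ceiling is why the KNN distance computation applies a
deterministic $10^{-8}$ tie-breaking dither (see below).

What the phantom does *not* model: anatomically faithful geometry, optical
photon transport, the oblique detection geometry, wavelength-correlated
noise, and spatial noise correlations. Passing tests therefore demonstrate
the correctness of the algorithms and the qualitative reproduction of the
class structure, not quantitative agreement with any particular measured
specimen.

A frame-level corruption stage emulates the artifacts that fail the screen
in measured data: additive Gaussian intensity noise and specular patches
saturated at three times the maximum intensity, which reconstruct into
passivity-violating matrices and are removed by the ensemble criterion at
elevated rates.

# Classification protocol

One row per labeled pixel with features $\Delta(\lambda), R(\lambda),
D(\lambda)$ at six wavelengths (18 features, header grammar
`<property>_<wavelength>`). The dataset is balanced once, globally, by
randomly removing rows until every (specimen × class) cell has the minimum
cell count. Cross-validation always leaves one specimen out per fold (never
random splits), giving a 5/6 ≈ 83% training fraction for six specimens.

KNN uses Euclidean distance on z-scored features, with the scaler fitted on
each fold's training split: depolarization in $[0,1]$ and retardance in
radians are incommensurate without standardization (the protocol leaves
scaling unstated; it is switchable). Neighbor counts follow the reported
sweep: $K_n = 50$ (single-wavelength), 8 (all features), 48 (selected
features). A deterministic dither of $10^{-8}$ (far below any data scale)
is added to the z-scored features before the distance computation purely to
break exact ties, which the KNN backend otherwise refuses when clipped
values pile up.

Permutation importance shuffles one feature at a time in the evaluation
split, $s = 10$ repetitions per feature and fold, and reports the mean
accuracy decrease. Sequential floating selection runs fold-wise with the
held-out specimen's accuracy as the objective, both forward and backward,
under the simplification that an excluded feature is never revisited. On
the phantom study these reproduce the reported qualitative pattern:
depolarization features dominate importance by a factor of 3–5, the
single-wavelength accuracy decays from the blue to the red end, the
all-wavelength model beats every single-wavelength model, and forward
selection at $N = 3$ picks short-wavelength depolarization features in most
folds (the third feature is fold-unstable, exactly as in the measured
study). Class separability is additionally checked with the two-sided
Mann–Whitney rank-sum test (normal approximation with tie correction).

# Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as follows:
decomposition round trips on 1,000 seeded composed matrices per method
(residual thresholds $10^{-8}$, $10^{-8}$, $10^{-9}$); purity and
realizability invariants on 10,000 random physical matrices; axis recovery
on a $1^\circ \times 3$-retardance grid; fluctuation recovery with $10^5$
Monte-Carlo draws; and an end-to-end study of six 64×64 specimens over
twenty regions and six wavelengths, capped at 400 pixels per
(specimen × class) cell for the classification stages. These sizes keep the
full run in minutes on a single core while leaving every statistical check
far from its decision boundary.

Other numerical conventions collected in one place: retarder composition
residuals are Frobenius norms; eigenvalues in $[-10^{-9}, 0)$ are clipped
to zero before purity computation; the differential round-trip oracle uses
an independently implemented matrix exponential; degenerate depolarizer
eigenvalues are ordered descending with deterministic eigenvector sign
(first nonzero component positive); TIFF serialization affine-maps signed
Mueller elements into $[0,1]$ with the scale recorded in the JSON sidecar,
because TIFF pages cannot carry signed values portably.

# Known limitations

* The reverse polar decomposition is not implemented (out of scope by
  design).
* Non-diagonalizable (Minkowski-type) matrices are excluded from the
  symmetric decomposition rather than handled by the normal-form theory.
* The eigenvalue calibration of a real instrument is not modeled; PSA/PSG
  are either the built-in ideal model or user-supplied matrices.
* Differential-domain pixels whose principal logarithm does not exist are
  excluded; media genuinely requiring a non-principal branch are outside
  the model.
* Phantom realism is qualitative: trends, overlaps, and fold structure are
  emulated, per-pixel optics are not.
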