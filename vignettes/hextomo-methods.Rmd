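---
title: "Dynamic tomography with a six-plane neural field: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic tomography with a six-plane neural field: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hextomo)
```

## The problem

Time-resolved X-ray tomography (tomoscopy) reconstructs one 3D volume per
half-rotation of the sample: each time point requires radiographs spanning
0--180 degrees, so the rotation speed caps the temporal resolution. This
package implements the alternative of assigning each time point only a
narrow contiguous angular *wedge* (much less than 180 degrees) and solving
for all time points jointly in 4D, sharing structure across space and time.
The temporal-resolution gain over a conventional scan is the ratio

$$\mathrm{TE} = \frac{180^\circ}{\Delta\theta},$$

so 18-degree wedges give a 10-fold enhancement, 3 degrees gives 60-fold, and
0.9 degrees gives 200-fold (`temporalEnhancement()`).

The price is a severely ill-posed limited-angle problem at each time point,
which the joint 4D representation and its regularization must compensate.

## The scene model

The time-evolving complex refractive index is written
$n(\mathbf{x}, t) = 1 - \delta(\mathbf{x}, t) + i\beta(\mathbf{x}, t)$:
$\delta$ (the decrement) drives phase contrast, $\beta$ drives absorption.
The field over normalized spacetime $[-1,1]^3 \times [-1,1]$ is factorized
into **six 2D feature planes**, one per coordinate pair --- three spatial
(xy, xz, yz) and three spatiotemporal (zt, yt, xt). A query point is
projected onto each plane, a feature vector of length $F$ is bilinearly
interpolated from each, and the six vectors are fused into a descriptor that
a small multilayer perceptron (ReLU hidden layers) decodes into $\delta$
(and optionally $\beta$). Storage therefore grows as
$O(N^2 F + N T F)$ in the plane resolutions $N, T$ and channel count $F$,
instead of $O(N^3 T)$ for a dense 4D voxel grid --- the parameter audit in
the test suite asserts exactly this count.

Two fusion rules are provided (`fusionMode`):

* `"concat"` (default): the six vectors are concatenated into a $6F$
  descriptor. This is the most direct reading of the fused-descriptor
  design and is what all defaults use.
* `"paired-product"`: elementwise products of the paired planes
  (xy·zt, xz·yt, yz·xt) are concatenated into a $3F$ descriptor. This is
  the multiplicative low-rank form used by the hexplane/tensor-factorization
  lineage of visible-light scene models, exposed so the two couplings can be
  compared on equal terms.

On the relationship between the per-axis low-rank counts of a CP-style
tensor factorization and a single per-plane channel count: we treat the
feature dimension $F$ as the shared rank of all three paired-plane terms
($R_1 = R_2 = R_3 = F$), which the concatenation + MLP then mixes. No
per-plane nonlinearity is applied before fusion.

Defaults (`newSceneConfig()`) follow the reference configuration for
dynamic synchrotron data: plane grids of 64 along every axis, $F = 48$,
and an MLP of 3 hidden layers with 64 neurons. Desk-scale experiments in
the tests use smaller scenes (grids of 32, $F = 8$, 2 x 32 MLP).

**Output activation.** A softplus is applied to each output channel so that
$\delta, \beta \ge 0$, which is physically correct at hard-X-ray energies;
a raw linear output is available (`activation = "linear"`) for analyses
that need signed fields (e.g. the linearity tests). The activation choice
is a design decision of this package.

**Initialization.** Plane features are drawn uniform on
$(-0.1, 0.1)/\sqrt{F}$; MLP weights use uniform fan-in scaling; biases are
zero. A single integer seed drives everything, and two scenes built with
equal seeds are bitwise identical.

## The forward model

Under the projection approximation (weak scattering), the exit wave after
traversing the object accumulates the line integral of $\delta - i\beta$
along the beam; for a unit-intensity incident wave the transmitted
intensity is $\exp(-2k\int\beta\,dz)$ and the phase shift is
$-k\int\delta\,dz$, with $k = 2\pi/\lambda$. The package's native rendering
and training currency is the **line-integral domain**; conversions to
intensity and phase are explicit, invertible operators
(`intensityFromLineIntegrals()`, `lineIntegralsFromIntensity()`,
`phaseFromLineIntegrals()`), so preprocessing decisions stay visible.

Geometry is parallel-beam: the rotation axis is the volume z-axis, mapped
to detector rows; detector columns map to the rotated lateral axis;
$\theta = 0$ sends rays along $+y$ and rotation is counter-clockwise about
$+z$. A radiograph is rendered by marching each detector pixel's ray
through the normalized cube: the chord is split into $n$ equal
sub-intervals with one sample each (midpoint rule for deterministic
rendering, stratified jitter during training) and quadrature weight
chord$/n$, so weights always sum to the chord length. The default $n$
equals the spatial plane resolution; the sample count and distribution
are this package's choices. Points outside the cube contribute zero
(vacuum); bilinear interpolation clamps at plane edges for points on the
boundary.

A second, independent projector (`projectVolume()`) computes line integrals
of an explicit voxel grid by dense trilinear sampling at fixed fine steps.
It serves as the reference for the scene renderer (the two agree to about
$10^{-5}$ relative once the same boundary convention is selected via
`boundary = "clamp"`) and as the simulator that turns phantoms into
virtual acquisitions. Its default `boundary = "zero"` treats the outside
of the grid as vacuum, which is exact for compact phantoms.

## Acquisition scheduling

`buildSchedule()` assigns time point $i$ (0-based) the half-open unwrapped
window $[\,i\Delta\theta,\ (i{+}1)\Delta\theta)$ (plus a start offset).
Two extraction modes carve wedge datasets out of continuous-rotation
stacks (`extractWedges()`):

* **streaming** (default): consecutive frames, no rotation skipping ---
  every acquired frame is used. This models the native wedge acquisition.
* **per-rotation**: time point $i$ is drawn from rotation
  $\lfloor i\Delta\theta/360\rfloor + 1$, selecting frames whose angle
  modulo 360 falls in the window. This emulates benchmarking against
  repeated full-rotation tomoscopy data, where each wedge must come from a
  distinct rotation; full 360-degree rotations avoid the image flip
  required when splicing 180-degree ranges.

Both modes are pure selections: pixels are untouched and only time stamps
are rewritten (all frames of a wedge share its index and the wedge's
normalized mid-time, linearly scaled to $[-1, 1]$). Window membership uses
half-open intervals with a $10^{-9}$-degree tolerance so that frames
landing exactly on wedge boundaries are assigned uniquely despite angle
rounding. When $360/\Delta\theta$ is an integer, the same viewing angle
recurs every that-many time steps (`revisitPeriod()`), and the windows of
one period tile the full circle.

## Training

The scene is fitted by minimizing

$$L = \frac{1}{|R|}\sum_{r\in R}\|I(r) - \hat I(r)\|^2
      + \lambda_\mathrm{reg} L_\mathrm{reg}$$

over random ray batches $R$: the mean squared difference between rendered
and measured line-integral pixels, plus total-variation and L1 penalties on
the six feature planes. TV is the mean squared forward difference over both
plane axes and all channels (averaged over planes); L1 is the mean absolute
feature value; `tvWeight`/`l1Weight` split them (equal by default), and
$\lambda_\mathrm{reg} = 10^{-4}$ by default. TV enforces spatio-temporal
continuity, L1 sparsity; both act on the planes only, never the MLP.

One "epoch" is **one optimizer step on one random ray batch**: a frame is
drawn uniformly, a without-replacement batch of its detector rays is
rendered with stratified jitter, and Adam updates all parameters (planes at
$2\times10^{-2}$, MLP at $10^{-3}$, cosine-decayed to a tenth over the
run). The reference run length is 50,000 such steps. The optimizer, rates,
batch size (256 rays) and $\lambda_\mathrm{reg}$ are this package's
choices, all exposed in `newTrainConfig()`. Runs are deterministic given
the configuration seed (a dedicated generator, single-threaded); a
non-finite loss aborts immediately with the failing iteration. Gradients
are analytic (hand-derived backpropagation through the quadrature, MLP and
bilinear interpolation, implemented in compiled code) and are verified
against central finite differences to $10^{-3}$ relative in the tests.

When the scene has one output channel the loss compares $\delta$ line
integrals; beta-domain stacks train the second channel of a two-channel
scene. A single-channel configuration matches data whose preprocessing
retrieves only the phase component.

## Preprocessing

* **Flat-field correction**: $(raw - dark)/(flat - dark)$, clipped below at
  $10^{-9}$ so later logarithms stay finite; non-positive denominators are
  an error that reports the pixel count.
* **Single-distance phase retrieval** for a homogeneous object
  (transport-of-intensity): the transmission is filtered in Fourier space
  by $1/\bigl(1 + R\,(\delta/\beta)\,\tfrac{\lambda}{4\pi}\,|2\pi f|^2\bigr)$
  with $f$ in cycles per length derived from the pixel size, then
  log-transformed to a thickness map via $\mu = 4\pi\beta/\lambda$ (the
  returned map is thickness-proportional; only $\delta/\beta$ enters the
  filter). At $R = 0$ the filter collapses to 1 and the output is exactly
  $-\ln(I)/\mu$ --- the closed-form limit covered in the tests. Symmetric
  padding to the next power of two suppresses FFT wrap-around
  (`pad = FALSE` restores exact cyclic shift-invariance). Exact constant
  conventions for this filter vary across implementations; ours is the one
  documented here and pinned by the $R \to 0$ test.
* **Radon-sum normalization**: for parallel-beam data the pixel sum of
  every projection of a contained object is constant within a time point;
  each frame is rescaled to its group's mean sum (idempotent; factors
  returned for audit).
* **Half-to-full-rotation rebinning**: pairs of 0--180 degree blocks are
  concatenated into 0--360 degree blocks, halving the time points and
  doubling the projections per block while preserving every frame.

## Evaluation

**FSC.** The Fourier shell correlation of two volumes is
$\mathrm{Re}\sum F_A\bar F_B / \sqrt{\sum|F_A|^2\sum|F_B|^2}$ per spherical
shell (width one frequency bin; non-cubic volumes are zero-padded to
cubes; full-sphere voxel counts). The resolution is the reciprocal of the
first downward crossing of the half-bit information threshold

$$T(n_r) = \frac{0.2071 + 1.9102/\sqrt{n_r}}{1.2071 + 0.9102/\sqrt{n_r}},$$

located by linear interpolation between neighbouring shells; a curve that
never crosses is Nyquist-limited and reported as 2 voxels, and the
estimate is never reported below 2. Numerical rule: the DC shell is
excluded from the crossing scan --- it holds a single voxel, where
$T(1) = 1$ exactly and self-correlation is exactly 1, so floating-point
jitter there would otherwise fabricate near-zero crossing frequencies.
Sustained-crossing variants of the rule are deliberately not used.

A caveat the dynamic experiments make visible: limited-angle
reconstructions concentrate spectral power inside the sampled wedge, where
they correlate well with the truth, so their shell correlations are biased
upward (roughly the square root of the in-wedge power fraction). A wedge
FBP volume can therefore fail to cross the half-bit threshold at all on
noiseless data, saturating the comparison at the 2-voxel floor; FSC-based
baselines should be read with this in mind.

**PSNR / SSIM / NRMSE** are computed per time point against the ground
truth's value range (PSNR capped at 100 dB for exact matches; SSIM with a
uniform 7-voxel window, standard constants, valid-region mean; NRMSE
normalized by the truth's range) and aggregated as mean ± sd over time.

**FBP baseline.** A slice-wise parallel-beam filtered back projection
(ramp filter $|f|$ via zero-padded FFTs, linear interpolation, $\pi/n$
angular weighting) provides the conventional per-time-point
reconstruction. It is a surrogate for Fourier-regridding reconstructors,
not a clone of any. Spans under 180 degrees warn about limited-angle
artifacts rather than erroring, since single-wedge baselines are exactly
the comparison of interest.

**Segmentation.** `moltenVolume()` counts voxels above (or below) a
threshold times the voxel volume --- sufficient for piecewise-constant
phantoms, where the configured contrast levels make thresholding exact.

## Synthetic phantoms

`makePhantom()` builds piecewise-constant 4D ground truth:

* **merging_droplets** emulates a binary-droplet coalescence: two metaball
  bodies (smooth-minimum union of signed distances, sharpness 16) approach
  linearly until deeply overlapped at `mergeFraction` of the sequence, then
  the implicit surface blends toward the volume-equivalent sphere. The
  smooth union produces a neck through coalescence; the equivalent-sphere
  endpoint conserves the combined volume by construction (within
  voxelization, asserted at 5% in the tests). Defaults --- 75 time points,
  128 voxels per axis, radii 0.25/0.20, initial separation 1.0 --- mirror
  the simulated droplet protocol this generator stands in for. It is an
  analytic morphological surrogate, not a Navier--Stokes Cahn--Hilliard
  solution: interface dynamics, internal flow and asymmetric necking are
  not modeled, so passing tests demonstrate recovery of topology and
  morphology, not fluid physics.
* **melt_pool** emulates a laser-melting experiment: a static substrate
  slab plus an ellipsoidal molten region of different contrast translating
  linearly just below the surface. No thermal physics is modeled.
* **static_ball** is the self-consistency target.

`simulateTomoscopy()` rotates the source continuously (frame $j$ at
$j\cdot360/P$ degrees) and maps phantom time onto frames by zero-order
hold --- the object is static within each time point's frame span, matching
the staticity assumed within a wedge. A linear-interpolation motion mode
(`motion = "linear"`) is provided, off by default, to stress-test
intra-wedge motion. Optional Gaussian (line-integral domain) or Poisson
(intensity domain, given dose) noise is seeded and reproducible. The
phantom and its acquisition are deterministic given the specification.

## Problem sizes and run times

The bundled experiments are deliberately desk-scale so that the full suite
runs on one CPU core in minutes: a 32-cube static ball fitted from 90
angles over 180 degrees (3,000 steps) reaches a rendered-projection NRMSE
under 0.05 and a volume FSC resolution at the 2-voxel floor; an 8-time-point
32-cube droplet sequence acquired as 18-degree streaming wedges (10x
enhancement, 20 frames per wedge, 5,000 steps) recovers the 2-to-1
component transition at the correct time index with per-time FSC
resolution at or near the floor, against wedge-FBP baselines ranging from
about 4 voxels to worse than 30. These sizes and thresholds are the
package's own testing choices; they demonstrate the mechanism, not
published large-scale figures.

## Known limitations

* Parallel-beam geometry only; no cone/fan beam, no Fresnel propagation or
  multi-slice wave optics beyond the projection approximation, no detector
  blur.
* No coarse-to-fine plane upsampling during training (a config hook for it
  would be a natural extension; the current schedule trains fixed-size
  planes).
* FSC-based resolution comparison against limited-angle baselines
  saturates, as discussed above.
* The phantoms are morphological surrogates; no fluid or thermal physics.
* Ring artifacts, beam hardening and detector distortions are out of scope
  of the preprocessing chain.
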