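# hextomo

Self-supervised 4D reconstruction for time-resolved X-ray tomography from
narrow angular wedges.

## The problem

Time-resolved tomography (tomoscopy) reconstructs one 3D volume per
0–180° scan, so temporal resolution is capped by how fast the sample can
spin — and spinning faster introduces centrifugal forces and makes in-situ
sample environments impractical. `hextomo` instead assigns each time point
only a narrow contiguous angular wedge Δθ ≪ 180° and solves all time
points jointly, sharing information across space and time. The temporal
enhancement over a conventional scan is

```
TE = 180° / Δθ
```

(18° wedges → 10×, 3° → 60×, 0.9° → 200×). The package is aimed at
synchrotron and lab-CT practitioners studying fast processes — coalescing
droplets, melt pools in laser powder-bed fusion, solidification — and at
methods developers who need a complete, testable wedge-reconstruction
stack on synthetic ground truth.

## The model

The time-evolving refractive index `n(x,t) = 1 − δ(x,t) + iβ(x,t)` is
represented by a **hexplane neural field**: six learned 2D feature planes
over the coordinate pairs (xy, zt, xz, yt, yz, xt), bilinearly
interpolated at each query point, fused into a descriptor and decoded by a
small MLP into δ (and optionally β). Storage scales as `O(N²F + NTF)`
rather than `O(N³T)` for a dense 4D grid. Radiographs are rendered under
the projection approximation — each detector pixel integrates the decoded
field along its parallel-beam ray — and the scene is fitted by minimizing

```
L = (1/|R|) Σ_r ‖I(r) − Î(r)‖² + λ_reg · (TV + L1 on the six planes)
```

over random ray batches with Adam, with analytic gradients implemented in
compiled code (verified against finite differences in the tests).

Around that core the package provides: the wedge scheduler and extraction
from continuous-rotation stacks (streaming and per-rotation modes),
radiograph preprocessing (flat field, single-distance transport-of-
intensity phase retrieval, Radon-sum normalization, 180°→360° rebinning),
a filtered-back-projection baseline, Fourier shell correlation with the
half-bit resolution criterion, PSNR/SSIM/NRMSE scoring, deterministic 4D
phantoms with a virtual tomoscopy simulator, TIFF/CSV/JSON interchange,
and an end-to-end pipeline driver with a hashed manifest.

## Worked example

An 8-time-point droplet-coalescence phantom on a 32³ grid, acquired as
18° streaming wedges (10× temporal enhancement, 20 frames per wedge), then
reconstructed from scratch:

```r
library(hextomo)

sch <- buildSchedule(nTimepoints = 8, wedgeDeg = 18, framesPerRotation = 400)
sch
#> AcquisitionSchedule: 8 wedges of 18 deg (TE 10x), 400 frames/rev
#>   total unwrapped coverage 144 deg

spec    <- newPhantomSpec("merging_droplets", gridSize = 32, nTimepoints = 8)
phantom <- makePhantom(spec)
stack   <- simulateTomoscopy(phantom, framesPerRotation = 400, rotations = 0.4)
wedges  <- extractWedges(stack, sch, mode = "streaming")
wedges
#> ProjectionSet: 160 frames of 32 x 32 (delta_line_integral), 8 time point(s),
#>   theta 0..143.1 deg

scene <- initScene(newSceneConfig(spatialGrid = 32, temporalGrid = 8,
                                  featureDim = 8, mlpLayers = 2,
                                  mlpWidth = 32, seed = 1))
fitted <- fitScene(scene, wedges,
                   newTrainConfig(iterations = 2000, seed = 1, logEvery = 500))
tail(trainHistory(fitted), 1)
#>   iteration    data_loss  reg_loss   total_loss elapsed_s
#> 5      2000 0.0001632960 0.3119239 0.0001944884  52.73447

recon <- reconstructSeries(fitted, 32, sort(unique(wedges@time)))
fsc(volumeAt(recon, 8), volumeAt(phantom, 8))
#> FSCCurve: 17 shells, crossing 0.3665 cycles/voxel, resolution 2.73 voxels

attr(imageMetrics(recon, phantom), "summary")
#>   metric        mean         sd
#> 1   psnr 27.22594775 2.05872664
#> 2   ssim  0.90652587 0.03581305
#> 3  nrmse  0.04464217 0.01116925
```

Reading the numbers: the rendered-vs-measured mean squared error falls to
~1.6·10⁻⁴ after 2,000 steps; the final-frame reconstruction correlates
with the ground truth out to 0.37 cycles/voxel, i.e. a 2.7-voxel
resolution from an 18° wedge (the Nyquist floor is 2 voxels); mean NRMSE
over the 8 time points is ~4%. Longer runs (the tests use 5,000 steps)
push every time point to the 2-voxel floor and recover the droplets'
2→1 component merge at the correct time index. A conventional FBP given
only the same single wedge reaches 4–30+ voxels depending on wedge
orientation.

The same experiment runs from a config file:

```sh
Rscript inst/scripts/hextomo.R pipeline \
    --config inst/extdata/droplet_fixture.yaml --out runs/droplet
```

which writes every intermediate (phantom, stacks, schedule, checkpoint,
volumes, metric tables) plus `manifest.json` with MD5 hashes;
deterministic stages reproduce identical manifests across runs.

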