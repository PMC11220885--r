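---
title: "Methods: predicted-model-aided SPI reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicted-model-aided SPI reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In X-ray free-electron-laser single-particle imaging (SPI), identical
particles are delivered into the beam one at a time at unknown random
orientations, and each femtosecond pulse records one noisy snapshot
diffraction pattern — a curved Ewald-sphere section through the particle's
continuous 3D diffraction intensity. Reconstruction requires (i) recovering
the orientation of every snapshot so the patterns can be merged into a 3D
intensity, and (ii) solving the phase problem to turn the merged amplitudes
into an electron-density map. Both steps are classically initialized at
random and can stall in local minima, especially with few patterns, weak
signal, or a missing low-resolution region behind the beam stop.

`spirecon` implements the predicted-model (PM)-aided variant of this
pipeline: an externally predicted atomic structure seeds the orientation
search (as a reference Fourier volume) and the phase retrieval (as a set of
starting phases). The package also contains the full simulation and
evaluation machinery needed to study the approach end to end without any
external data.

# Conventions

* Scattering vectors are crystallographic: $|q| = 2\sin\theta/\lambda$
  (no $2\pi$), resolution $d = 1/|q|$ in ångström. A pixel at transverse
  offset $\rho$ on a flat detector at distance $D$ maps to
  $\mathbf q = (\hat{\mathbf s}-\hat{\mathbf z})/\lambda$ with
  $\hat{\mathbf s}$ the unit sample-to-pixel vector. This reproduces the
  reference geometries' printed edge resolutions (6.6 Å at 0.5 m and
  13.1 Å at 1 m for a 512-pixel, 300 µm, 1 Å setup).
* Orientations are intrinsic $z\!-\!x'\!-\!z''$ Euler triplets,
  $R = R_z(\alpha) R_x(\beta) R_z(\gamma)$, with
  $\alpha,\gamma \in [0,2\pi)$ and $\beta \in [0,\pi]$. A pattern at
  orientation $R$ samples the intensity volume on the *forward-rotated*
  Ewald sphere, $I(\mathbf q_{\text{pix}}) \propto |F(R\,\mathbf
  q_{\text{pix}})|^2$. In this composition the third angle $\gamma$ acts
  directly on the detector azimuth, so an in-plane rotation of the particle
  is exactly a circular shift of the pattern's polar representation — the
  property the FFT-based in-plane search relies on.
* Reciprocal volumes are cubic and centered (origin at voxel
  $\mathrm{dim}/2+1$), with voxel pitch
  $\Delta q = (\text{binned center-pixel pitch})/2$, i.e. a linear
  oversampling of 2, and side $2\times$ the binned detector — a 512²
  detector binned 2× yields a 512³ volume. Real-space maps implied by such
  a volume have pitch $1/(\mathrm{dim}\,\Delta q)$.

# Simulation

Atoms are isotropic 3D Gaussians of width $\sigma = 1$ Å whose integrated
weight is the element's electron count; the analytic transform
$F(\mathbf q) = e^{-2\pi^2\sigma^2 q^2}\sum_j w_j e^{-2\pi i \mathbf
q\cdot \mathbf r_j}$ is evaluated by exact direct summation in compiled
code (for the phantom models used here, with at most a few hundred atoms,
direct summation is both exact and faster than any gridded approximation,
so no non-uniform FFT is needed). Per-pixel expected photon counts are
$J r_e^2\, \Omega\, |F|^2$ with fluence $J$ from a uniform focal disc,
$r_e = 2.818\times10^{-5}$ Å, and flat-detector solid angle $\Omega = A
\cos^3 2\theta / D^2$. Poisson noise is sampled per pattern from a stream
derived from (master seed, pattern index), so any subset of a dataset is
reproducible. A centred square beam stop can be masked, and preprocessing
bins patterns 2×2 (sums, with mask propagation).

Binned counts are divided by $J r_e^2 \Omega$ before matching and merging.
The ring-wise normalization below makes orientation matching invariant to
this calibration; its purpose is to put the merged volume on the $|F|^2$
scale so that phased maps are directly comparable with the model transform.

# Orientation determination by correlation maximization

The slice normal $(\alpha, \beta)$ is searched exhaustively on a
quasi-uniform grid: $\beta$ rings spaced $\Delta\beta$ (default 0.1 rad),
each carrying $\max(1, \text{round}(2\pi \sin\beta/\Delta\beta))$ equally
spaced $\alpha$ values (rounding chosen; the sampling rule only fixes the
product $\Delta\alpha \sin\beta \approx \Delta\beta$), and a single
direction per pole. $\gamma$ is never gridded: patterns and reference
slices are resampled onto concentric rings $I(r,\theta)$ (1-binned-pixel
radial spacing, $n_\theta$ a power of two $\ge 2\pi r_{\max}$), each ring
is z-scored to zero mean and unit variance so the bright low-resolution
rings cannot dominate, and the ring-averaged Pearson correlation
$C(\gamma)$ is evaluated for all $n_\theta$ in-plane rotations at once by
1D FFTs (cross-correlation theorem). Rings below $r_{\min}$ (beam-stop
radius + 2) and above $r_{\max}$ (0.85 × Nyquist) are excluded: the
innermost rings are both overwhelmingly bright and most distorted by
gridding, the outermost have the worst signal-to-noise.

Each iteration assigns every pattern the global maximizer over (grid
direction × $\gamma$), then re-merges all patterns into a new intensity
volume: every measured binned pixel deposits its calibrated value at
$R\,\mathbf q$ on the 8 surrounding voxels with trilinear weights, and
voxels are weighted means (zero-weight voxels are flagged missing). The
loop stops when the mean best correlation changes by less than `tol`
(default $10^{-3}$), then one refinement pass re-assigns each pattern on a
local cap (radius $3\Delta\beta$) sampled at 0.02 rad with parabolic
sub-bin interpolation of $\gamma$; a full-grid refinement would cost ~25×
more for no measurable gain on the phantom panels. The PM-aided variant
starts the loop from $|F|^2$ of the predicted model's reference volume; the
classical variant starts from smoothed, Friedel-symmetrized positive noise.

Two properties observed on the noise-free phantom panels mirror the
behaviour this algorithm is known for: with a true-model reference, ≥95 %
of patterns land within $2\Delta\beta$ of their true orientation in a
single pass and the median deviation after refinement is below 2°; and the
PM-aided start reaches its correlation plateau in fewer iterations than the
random start (which, at only 500 patterns, plateaus at a lower correlation
with largely wrong orientations — the small-dataset failure mode of the
randomly initialized method).

# Phase retrieval

Amplitudes are the square root of the merged intensity. The real-space
constraint is a fixed, centred cubic support sized from the particle extent
(margin 1.2; no shrink-wrap) plus positivity inside it. Missing voxels
(beam-stop cube and unfilled grid points) float freely in both modulus and
phase. ER projects the violating set to zero; HIO damps it with feedback
$\beta_{fb} = 0.9$ (the standard Fienup value; a constant is used — a
relaxation schedule would be an alternative reading of "slowly pushed to
zero"). Defaults follow the two-regime logic: random starting phases get
1000 HIO + 100 ER (exploration), prior phases from the predicted model get
1100 ER only, because HIO's feedback can kick an already-good iterate out
of its basin. Random initial phases are drawn Friedel-consistently (phases
of the transform of white real noise). With prior phases the missing
region is seeded with the predicted model's complex values; for a monomeric
reference the voxel-to-voxel phase mapping is exact by construction, while
for partial (e.g. single-subunit) references the reconstructed volume frame
may not match the reference frame — the package surfaces this as a caveat
rather than auto-correcting it.

Phased maps are compared to ground truth only after removing the trivial
ambiguities of the phase problem (translation and inversion): alignment
searches the 48 cube symmetries (which contain the inversion) × integer
translations via FFT cross-correlation, and success is an aligned overall
Pearson correlation above 0.5. A band-limited fine map at 1 Å spacing is
produced by extracting the support cube, zero-padding its spectrum and
inverse transforming (total density conserved).

# Evaluation metrics

Per-1-voxel-shell curves: CC shell (Pearson of intensities, missing voxels
excluded pairwise), FSC (complex correlation of maps; 0.5 threshold against
truth, 0.143 between half-maps), PRTF (magnitude of the across-run mean
unit phasor, 1/e threshold), plus per-pattern geodesic angular deviations
(1° histogram) and per-pattern CC maps over the $(\alpha,\beta)$ grid.
Resolution read-outs take the first downward threshold crossing from low
$q$ with linear interpolation; curves that never cross report the band
limit flagged as such. A half-map protocol splits a dataset randomly,
reconstructs each half independently and aligns the two maps before the
FSC.

# The phantom fixtures and what they do (not) show

All tests run on synthetic "proteins": seeded atom clouds (blob / chain /
two-lobe styles) rescaled exactly to a target radius of gyration, with
carbon weights throughout — element diversity adds nothing to the
algorithms under test. The "predicted" model is emulated by perturbing the
truth: smooth correlated jitter rescaled exactly to a target RMSD (default
6 Å, about a fifth of the phantom Rg — the same order, relative to size, as
the ~9.4 Å discrepancy reported for real predicted structures of large
proteins), or a rigid domain shift of half the atoms emulating a
mis-assembled multimer.

The desk tiers fix the study conditions: `tiny` (32² detector, 50
noiseless patterns), `small` (64² detector, 500 Poisson patterns),
`medium` (128² detector, 2000 patterns). The shared geometry (1 Å
wavelength, 500 µm pixels at 0.128 m) gives a 256 Å real-space field of
view — oversampling ≈ 2.8 for the 30 Å-Rg phantom — and a binned-pattern
edge at 4 Å (8 Å for tiny). The default pulse energy (5 × 10¹⁵ photons
into a 0.1 µm focus) is chosen so a pattern carries ≈ 2300 photons,
matching the photon budget of the reference experiments; phantoms carry
~10³ electrons versus ~10⁵ for a 470 kDa protein, which is why the pulse
energy is correspondingly larger. The fluence sweep used in testing runs
at 1, 1/4 and 1/16 of this budget, bracketing the transition from accurate
orientation recovery to failure.

What passing these panels does *not* show: behaviour under detector
artefacts (gain, readout noise, panel gaps), background scattering, sample
heterogeneity, hit finding, or conformational mixtures — none of which are
simulated; nor near-atomic resolution, since the phantoms are low-resolution
objects by construction.

# Numerical choices and known limitations

* Trilinear gather/scatter everywhere (slices, polar resampling via
  bilinear, merging). Hard-assignment merging with trilinear deposition
  smooths sharp low-$q$ structure toward shell means; on the 32³ `tiny`
  grid this gridding bias visibly caps the attainable map correlation
  (~0.7 against a truth map, although phasing exact amplitudes on the same
  grid reaches 0.999). The effect shrinks with grid size and is part of
  why the quantitative end-to-end panels run on the 64³ `small` tier.
* The in-plane correlation zeroes invalid polar samples after z-scoring
  and divides by the count of mutually valid rings; this slightly biases
  absolute correlation values when many samples are masked but leaves the
  argmax (the assigned orientation) essentially untouched.
* Ties in the orientation search break to the first grid entry; $\gamma$
  is reported at FFT-bin resolution ($2\pi/n_\theta$) during coarse passes
  and parabolic sub-bin resolution during refinement.
* The CC map of a matched pattern shows, besides the true peak, a
  comparable peak at the antipodal direction: at weak Ewald curvature a
  pattern nearly equals its Friedel mate, so both hemispheres explain it.
  Diagnostics that quantify peak contrast must exclude both caps.
* Merging applies no per-pattern intensity scaling (simulated fluence is
  constant); real-data scale factors are out of scope.
* The 4-voxel beam stop ↔ 167 nm correspondence quoted for the reference
  512³ setup is not reproducible from the published geometry under the
  conventions above (our 512³ volume implies 1/Δq ≈ 154 nm full period);
  the package documents its own convention rather than matching that
  number.

# Problem sizes used in the shipped checks

The automated checks run, on one CPU in roughly ten minutes: the 500-pattern
noise-free `small` reconstruction (0.1 rad grid, 0.02 rad refinement), the
same dataset with Poisson noise for the PM-vs-random comparison (0.2 rad
grid), 150-pattern single-pass sweeps at three fluences, a 10-seed 32³
phase-retrieval panel (500 HIO + 100 ER), and a beam-stop ladder
(0–12 voxels) at 5 random seeds per size. The ladder runs on amplitudes
carrying 60 % multiplicative intensity noise, emulating the voxel-level
error of a merged Fourier volume: with clean, exactly supported amplitudes
random-phase HIO completes even a 14-voxel missing cube, so only the noisy
panel discriminates the two phase initializations (prior phases survive the
full ladder; random starts fail at 12 voxels). These sizes were chosen as
the smallest at which each qualitative effect is stable across seeds.
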