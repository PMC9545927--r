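---
title: "Methods: real-time spiral phase-contrast flow reconstruction and monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time spiral phase-contrast flow reconstruction and monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`rtflow` implements, at desk scale, a low-latency pipeline for beat-to-beat
cardiac-output monitoring from real-time phase-contrast MR (PCMR): a
variable-density golden-angle spiral acquisition model, gridding
reconstruction with deep artifact suppression, automatic aortic
segmentation, and flow quantification, driven end to end by a synthetic
pulsatile-flow phantom rather than scanner data.

The physical model is standard one-sided PC velocity encoding: each frame
is acquired twice, flow-compensated (`comp`) and flow-encoded (`enc`), and
through-plane velocity maps to the phase difference,
$v = \mathrm{VENC}\cdot\Delta\phi/\pi$, with VENC = 200 cm/s. Velocities
beyond VENC wrap, and all phase arithmetic in the package is wrap-safe.

# Trajectory design and audit

The spiral arm solves the pitch equation
$dr/d\theta = R(\rho)/(2\pi\,\mathrm{FOV})$, where $\rho = r/k_\max$ and
$R(\rho)$ is the per-arm acceleration profile: 26 inside the central 20% of
k-space, 65 beyond 90% of $k_\max$, linear in between (density ratio 2.5).
The ODE is integrated with fixed-step RK4 in $\theta$ (step $2\pi/8192$)
and the path resampled at 2048 points uniform in arc length; the
samples-per-readout and golden-angle variant are not fixed by the protocol,
so both are configurable (default increment $2\pi/\varphi \approx
222.5^\circ$; the $137.5^\circ$ convention is available as an argument).
Three arms form one 35 ms frame; frame $f$ uses global arms $3f..3f+2$, so
the schedule is deterministic and stateless.

With this profile the whole arm makes only about 2.45 turns (the outer
plateau spans ~0.15 turn), so no complete turn lies inside either plateau
and the literal distance to the next turn mixes plateau and transition
pitches. The audit therefore measures the *local* turn spacing
$2\pi\,r'(\theta)\cdot\mathrm{FOV}$ at crossings of fixed-azimuth rays --
the quantity the printed per-arm factors (26x/65x) describe -- and averages
it per plateau. Per-frame values divide by the interleave count, giving
8.67/21.67 against the published 8.7/21.7. The audit's "outer" band is the
plateau beyond $0.9\,k_\max$; the main text calls this the "outer 10%"
while the supplement says "outermost 20%", and we resolve the discrepancy
in favour of the plateau region actually prescribed to the designer.

# Gridding and density compensation

The nonuniform Fourier operators are Kaiser-Bessel gridding transforms
(oversampling 2, kernel width 8, Beatty shape parameter), unnormalized,
with DC at the grid centre. Forward and adjoint share one kernel and a real
deapodization, so they are exact adjoints by construction; accuracy against
brute-force DFT summation is ~1e-7 relative, tested at 1e-6.

Two density-compensation estimators are provided. The iterative
sampling-density fixed point (10 iterations, width-4 kernel) matches the
approach cited for the original pipeline and is correct whenever the
convolution kernel can sense the local sampling density -- it reproduces
the $|k|$ ramp for an azimuthally sampled uniform spiral to within 10%.
For *this* protocol, however, the inter-turn gaps are 26-65 grid cells
wide, far beyond the kernel, and the iteration only equalizes the
along-readout density. The pipeline therefore defaults to analytic local
cell areas (along-arm spacing times the smaller of the azimuthal spacing
near DC and the radial inter-turn pitch), rescaled once so the adjoint has
unit gain on an internal smooth reference.

A consequence worth stating plainly: at 8.7-fold (centre) to 21.7-fold
(periphery) undersampling, more than 85% of the k-space integral is
unobserved, and *no* density weighting makes the plain adjoint an accurate
reconstruction. A centred-Gaussian round trip through the printed
single-frame trajectory leaves ~50-60% relative L2 residual (the package
tracks 0.65 as a regression bound), while fully sampled controls pass at
2-5% -- which is precisely why the protocol needs deep artifact
suppression, and why the aliased images are usable as network input but
not as quantitative maps.

# Synthetic phantom

The phantom is a circular vessel (default radius 15 mm, wall 2 mm) with a
parabolic through-plane profile $v(r,t) = 2\bar v(t)(1-(r/R)^2)$ inside
static background ellipses with zero velocity. The waveform is a systolic
half-sinusoid over the first 35% of the cycle plus a 5% diastolic offset;
the per-beat peak is scaled so the integral matches the configured stroke
volume. Beat-to-beat variation uses lognormal RR jitter ($\sigma = 0.03$),
sinusoidal respiratory SV modulation (5%) and translation (2 px peak at a
4 s period), values chosen once as typical of resting physiology. Heart
rate follows a piecewise-linear 40 s rest / 80 s exercise / 60 s recovery
ramp, 68 to 94 bpm by default, mirroring the published cohort means as
parameters (not targets). Vessel-rim pixels are included by centre-in-circle
without subpixel weighting; the parabolic profile makes flow insensitive
to one-pixel rim errors because rim velocities vanish. Ground-truth flow is
defined as the mask-summed discretized velocity, so truth is self-consistent
to machine precision, and the discretized-vs-analytic flow agreement
($\pi R^2 v_\mathrm{peak}/2$, within 5% for $R \ge 7$ px) is tested.

Complex per-coil noise is applied where coils exist -- at k-space
simulation -- with the noise level carried in the phantom config; the
ground truth itself stays noise-free.

What the phantom does *not* emulate: in-plane flow, turbulence, off-
resonance, T1/T2 contrast, anatomical variability, or coil-array physics
beyond smooth Gaussian-lobe sensitivities. Passing the recovery tests shows
the pipeline's machinery is correct and well-calibrated on data whose
statistics it controls; it does not certify in-vivo accuracy.

# Training data and networks

Training pairs are made by sampling clean complex frames along the
prescribed trajectory and gridding back (synthetic corruption), then
cutting 24-frame blocks, centre-cropped and normalized by the corrupted
member's 99th-percentile magnitude with channels clipped to $[-1, 1]$.
Augmentations apply one transform to both members: flips, rotations
(multiples of 90 degrees, to avoid interpolating complex data), circular
time roll, a random second-order polynomial phase offset bounded by
$\pi/2$, and -- with probability 0.5 -- a sinusoidal translational drift
up to 4 px. In this package augmentation acts on already-corrupted pairs;
the alternative order (motion before undersampling) is noted as a
modelling refinement, not implemented as the default. Augmentation is
applied freshly per epoch during suppression training
(`train_suppressor(augment = TRUE)`), and it is load-bearing at desk
scale: without it the tiny network overfits its ~20 blocks and, on
held-out data, biases the phase difference toward zero -- the raw gridded
phase difference is nearly unbiased (static-background aliasing is
coherent between the two encodings and cancels in the subtraction), so an
overfitted denoiser that regresses toward the majority zero-phase
background *under-estimates* velocities by 20-30%. With per-epoch
augmentation the held-out stroke-volume bias collapses to a few percent.

For the end-to-end study, training corruption is generated through the
same path the pipeline sees at inference -- multi-coil sampling, gridding
with estimated coil maps, coil combination -- rather than the single-coil
synthetic undersampling used to emulate clinically stored training data;
the latter remains the corruption operator of the data-generation module
and is tested in its own right. Matching the corruption path removes a
train/test distribution gap that otherwise costs both restoration quality
and velocity fidelity.

Both networks are 2D+time U-Nets built on an in-package engine (im2col +
BLAS convolution with analytic backprop; no external deep-learning
framework): leaky-ReLU 3x3x3 convolutions, 2x average pooling, nearest
upsampling, concatenated skips fused by 1x1x1 convolutions, Adam at
learning rate 1e-3, batch = one block. The artifact-suppression net has a
global residual connection and a zero-initialized head, so it starts as
the identity. Its loss is the complex-SSIM form
$L = 1 - \tfrac12[\mathrm{SSIM}(\tfrac{\Re y + 1}2, \tfrac{\Re\hat y+1}2)
+ \mathrm{SSIM}(\tfrac{\Im y+1}2, \tfrac{\Im\hat y+1}2)]$, SSIM averaged
over 2D frames with an 11x11 Gaussian window ($\sigma = 1.5$, $K_1 = 0.01$,
$K_2 = 0.03$, data range 1, valid interior); the analytic gradient is
verified against finite differences. The segmentation net sees the
combined phase-contrast block with CLAHE-equalized magnitude (clip limit
0.02, 8x8 tiles) recombined with the subtracted phase, and trains on
BCE + soft Dice (the default among the three loss options). The published
architecture search is represented by a reduced successive-halving search
(keep one third per round) rather than a full Hyperband at scale.

# Streaming, latency, and quantification

The stream is processed in 24-frame blocks every 18 frames, keeping each
block's central 18 frames; the first and last blocks also keep their edge
frames so every frame is kept exactly once (the mid-stream convention only
specifies central-frame retention; dropping edges would lose beats at the
ends). Frame duration uses the printed 35.0 ms rather than 6 x TR =
34.8 ms; the two differ in the source and we follow the printed temporal
resolution. The latency model reproduces the published arithmetic exactly
-- 622.2 ms for the central kept frame and 902.2 ms for the first kept
frame ($13\times35 + 16.2 + 151$ and $21\times35 + 16.2 + 151$) -- and
models initialization as a queue drained at the per-step processing rate
(442.6 ms of work per 630 ms of acquisition). The published 26 s catch-up
time is not reproduced numerically; its queueing semantics are
under-specified and the model makes the backlog drain at the stated rates.

Flow is quantified as mask-summed velocity times pixel area
(cm/s x mm^2 x 0.01 = mL/s). Peaks are local maxima with a minimum
spacing of 60000/220 ms and prominence at least 20% of the running median
peak height (scale-invariant); beats span peak to peak, which conserves
total volume exactly; SV is the trapezoidal integral, HR = 60000/RR,
CO = SV x HR / 1000. The 5-beat running median is display-only.

The optional compressed-sensing oracle minimizes
$\|Fx - y\|^2 + \lambda\,\mathrm{TV}_t(x)$ with $\lambda = 5\times10^{-4}$
on unit-normalized data, using Charbonnier-smoothed TV and monotone
FISTA (momentum restart plus step backtracking), because the exact
temporal-TV prox has no closed form and a monotone objective trace is part
of the solver's contract.

# Desk-scale study conditions

The end-to-end tests run on one CPU with problem sizes chosen for that
budget: 96 x 96 phantom grid at the protocol's 2.1 mm voxel
(FOV 201.6 mm), 24-frame blocks, 3 coils, 24 training blocks from four
phantoms spanning 65-90 bpm and 70-90 mL, tiny U-Nets (2 scales,
8 filters, 1 block per scale), 8 augmented epochs for suppression and 12
for segmentation, and a 10.5 s held-out acquisition reconstructed at a
64 x 64 crop. Training blocks use a 48 x 48 crop (the networks are fully
convolutional, so they apply unchanged to the 64 x 64 inference crop).
The suppression training length was selected once on a separate
validation phantom -- mirroring the original train/validation/test
split -- by stroke-volume bias against the validation ground truth
(+1.7%, -2.3%, -3.8% at 8/12/16 epochs; 8 chosen), never on the held-out
test phantom. The segmentation network trains on both clean and
suppressor-restored phase-contrast blocks with the same mask labels:
clean blocks match the original design (labels were drawn on stored
images), restored blocks match the distribution the network sees when
deployed; with restored-only or clean-only training the tiny segmenter
over-segments the smeared restored vessel by ~30% in area, which inflates
stroke volume by capturing positively-smeared rim flux. The default
specification (3 scales, 16 filters, 2 blocks per scale) is config-
overridable and not exercised by the tests. Recovery criteria on held-out
phantoms: magnitude-SSIM improvement of at least 0.05 over the aliased
input, mask Dice at least 0.8, and mean per-beat SV and pipeline CO within
10% of ground truth. The published in-vivo agreement statistics and
in-silico test-set metrics require the original patient data and are out
of scope by design.

# Known limitations

* The adjoint-gridded input images are aliasing-dominated by design; all
  quantitative claims are made after suppression and segmentation.
* The concomitant-field correction is a subtractive low-order polynomial
  phase model, not a physical computation from gradient waveforms.
* Coil-map estimation is a smoothed temporal-average/RSS scheme; it is
  validated by simulation recovery, not against a named algorithm.
* The training engine is CPU-bound R/C++; it is sized for the tests and
  for method study, not for training at clinical scale.
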