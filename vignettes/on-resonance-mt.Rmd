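---
title: "On-resonance MT imaging with non-balanced SSFP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-resonance MT imaging with non-balanced SSFP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulfmt)
```

## The problem

Magnetization transfer ratio (MTR) imaging is a semi-quantitative,
myelin-sensitive contrast built from two images with different amounts of
bound-pool saturation. The classical route — an off-resonance saturation
prepulse on a spoiled gradient-echo readout — is awkward on ultra-low-field
(~64 mT) point-of-care scanners. An alternative exploits the fact that the
imaging pulses of a steady-state free precession (SSFP) sequence
saturate the macromolecular pool *on resonance*: varying the RF energy
deposited per TR (through the flip angle, or the pulse width at fixed flip
angle) modulates MT weighting without any prepulse, and the direct
saturation of the free pool is matched between the two acquisitions, so
their ratio isolates the MT effect. At ultra-low field there is no
practical SAR constraint, so flip angles up to 420° are usable.

This package simulates that experiment end to end: a two-pool steady-state
signal model for spoiled (non-balanced) SSFP, digital phantoms emulating
multi-vial bench experiments, and the complete MTR analysis chain (sweeps,
symmetry analysis, flip-angle-pair selection, MTR maps, ROI statistics,
Bland–Altman agreement, bias-corrected scan–rescan CoV).

## Signal model

### Two pools

A material is described by a free water pool (longitudinal/transverse
relaxation times $T_1^f$, $T_2^f$, in ms) and a macromolecular bound pool
holding a fraction $f \in [0,1)$ of the total equilibrium magnetization,
with longitudinal relaxation $T_1^b$ and a very short transverse lifetime
$T_2^b$ (microseconds — the bound pool is never directly observed, it only
absorbs RF). Exchange follows detailed balance with fundamental rate $k$
(s$^{-1}$): forward rate $k_f = k f$, reverse $k_b = k(1-f)$, so that the
equilibrium split $M_0^f = (1-f)\,PD$, $M_0^b = f\,PD$ is a fixed point.
`bound_fraction = 0` selects an exact single-pool code path.

### Bound-pool saturation by the imaging pulse

A rectangular (hard) pulse of flip angle $\alpha$ and width $\tau$ has mean
amplitude $\omega_1 = \alpha_\mathrm{rad}/\tau$ and saturates the bound
pool at rate $W = \pi\,\omega_1^2\,G(0)$, where $G(0)$ is the absorption
lineshape at zero offset. Over one pulse the bound longitudinal
magnetization is multiplied by $e^{-W\tau}$. Because $W \propto \alpha^2$,
sweeping the flip angle sweeps the deposited MT saturation quadratically —
this is the handle the method turns; at fixed $\alpha$, $W\tau \propto
1/\tau$, which is why longer pulses give *less* saturation in the
pulse-width sweep.

The Gaussian lineshape is finite on resonance, $G(0) = T_2^b/\sqrt{2\pi}$,
and is the default. The super-Lorentzian — the usual choice for
semi-solids at high field — diverges at zero offset; when selected, the
package evaluates it at a configurable cutoff offset (default 1 kHz), the
standard regularization in quantitative MT. The lineshape of the materials
modelled here is not established at 64 mT, which is why the well-posed
Gaussian is the default rather than the super-Lorentzian.

### EPG with exchange

The free pool is propagated with the extended phase graph (EPG)
formalism: transverse configuration states $F_k$ and longitudinal states
$Z_k$, $k = 0 \ldots K-1$. One TR consists of

1. bound-pool saturation ($Z^b \to e^{-W\tau} Z^b$) and an instantaneous
   RF mixing of each $(F_k, F_{-k}^*, Z_k)$ triple by the standard unitary
   rotation operator (the bound pool has no transverse magnetization and
   is not rotated);
2. relaxation and exchange over the TR: transverse decay
   $e^{-TR/T_2^f}$, and the longitudinal pair $(Z_k, Z^b_k)$ propagated by
   the exact matrix exponential of the two-pool Bloch–McConnell equations —
   with thermal recovery feeding only order $k=0$ (recovery is spatially
   uniform);
3. an ideal spoiler shifting every transverse order up by one,
   $F_k \to F_{k+1}$.

The FID observable (FISP / SSFP-FID) is $|F_0|$ right after the pulse; the
echo observable (PSIF / SSFP-Echo) is the refocusing pathway $|F_{-1}|$
just before the next pulse. The bound-pool longitudinal states are kept
*per configuration order*: exchange couples each free $Z_k$ to a bound
$Z^b_k$ and the return flow is several percent of the echo signal for
white-matter-like parameters, which a scalar bound pool would miss — the
package's isochromat validation (below) is sensitive to exactly this.

Design choices, made once:

* **Pulse model.** The hard pulse is instantaneous for the free pool
  (rotation at the pulse center, no free-pool relaxation bookkeeping
  during $\tau$; the free interval spans the full TR). The pulse width
  enters only through the bound-pool saturation factor. Consequence: a
  single-pool signal is exactly independent of pulse width, which is the
  control behaviour the pulse-width experiment relies on.
* **Spoiling.** Ideal gradient spoiling, one configuration order per TR,
  no diffusion damping. `n_epg_states` defaults to $K = 40$; truncation
  error can be probed by doubling $K$ (configuration amplitudes pass one
  RF mixing and one $T_2$ decay per order, so they fall off geometrically).
* **Convergence.** Fixed-point iteration from thermal equilibrium at a
  relative tolerance of 1e-10 on both signals, capped at 10,000
  iterations with an explicit solver-failure condition. Because the
  iteration contracts slowly for long-$T_1$ materials ($TR \approx 12$ ms
  versus $T_1$ of seconds), the stopping rule extrapolates the geometric
  tail — successive changes $d_n$ with ratio $r$ imply a remaining error
  $\approx d_n r/(1-r)$ — rather than testing $d_n$ itself, which would
  stop too early. The steady state is independent of the initial state
  (tested to 1e-9 from random states).
* **B1 error.** A transmit scale $s$ multiplies the nominal flip angle in
  both the rotation and the saturation amplitude, so a B1 error is an
  exact relabelling of the flip-angle axis: features pinned to effective
  angles (the 180° null, the symmetry axis) appear at nominal $180°/s$.
* **Units.** Degrees, ms and µs at all interfaces; radians and seconds
  internally. Angles above 360° are allowed (sweeps run to 420°).

### Isochromat oracle

`isochromat_oracle()` brute-forces the same steady state with $N$ spins
uniformly spanning $2\pi$ of spoiler dephasing per TR, full two-pool
longitudinal dynamics per spin, and complex-mean readout. It shares the
pulse model deliberately: it validates the configuration-state
bookkeeping (dephasing, spoiling, exchange across orders) by direct
ensemble summation, and agrees with the EPG engine to well below 1e-3
relative at $N = 2000$ (in practice to machine precision once $N$ exceeds
the retained configuration orders).

## What the simulated experiments show

```{r sweeps, eval = FALSE}
water <- tissue_presets("water")
cond  <- tissue_presets("conditioner_like")
grid  <- default_flip_angles()            # 1, 10, ..., 420 (43 angles)
cw <- flip_angle_sweep(grid, default_protocol(), water)
cc <- flip_angle_sweep(grid, default_protocol(), cond)
find_symmetry_point(cw)                   # 180
asymmetry_index(cc, 180, 120)             # > 0: MT depresses the 300 side
choose_flip_angle_pair(cw, cc)
```

* A single-pool (no bound pool) PSIF response is mirror-symmetric about
  180° and nulls there; this holds for *any* $T_1$/$T_2$, which is what
  the relaxometry-array phantom (14 single-pool vials spanning wide
  relaxation ranges) demonstrates: every vial has MTR $\approx 0$ at a
  symmetric pair such as 60°/300°, so relaxation differences alone cannot
  masquerade as MT contrast.
* A bound pool breaks the symmetry — saturation grows quadratically with
  flip angle, depressing the high-angle side — and the asymmetry index and
  MTR grow monotonically with the bound fraction.
* The flip-angle pair is chosen on the no-MT reference curve: pairs
  mirrored about the symmetry axis with matched, near-maximal reference
  signal; among those, the pair maximizing predicted MTR on the MT curve.
  An exhaustive enumeration oracle reproduces the selection on any grid.

## Digital phantoms and the analysis chain

Phantoms are defined as labelled geometric compartments (cylinders,
spheres, boxes) rasterized by voxel-center membership — no partial-volume
mixing, so compartment means are exact and testable. The default six-vial
MT phantom (2 water, 2 dairy-cream-like, 2 hair-conditioner-like) fills
the acquisition geometry: 180 × 220 × 200 mm FOV at 2 × 2 × 5 mm voxels
(90 × 110 × 40 grid), RL × AP × FH axis order, TR 12.03 ms, 220 µs pulses,
18 kHz bandwidth.

Acquisition simulation multiplies the per-compartment steady-state signal
(computed once per unique tissue) by smooth complex coil sensitivities
(Gaussian lobes around the perimeter, strictly positive
root-sum-of-squares) and adds i.i.d. complex Gaussian noise per channel in
the image domain — equivalent to k-space noise for this noise model and
free of any reconstruction machinery, which is out of scope. Magnitudes
are combined by root-sum-of-squares, so background noise follows a
central-chi law with $2 n_\mathrm{coils}$ degrees of freedom (checked
against the analytic mean). All randomness flows through one seeded
generator; identical seed and configuration give bit-identical volumes,
and a provenance sidecar (JSON) echoes everything needed to reproduce a
run.

The MTR map is $(MT_\mathrm{low} - MT_\mathrm{high})/MT_\mathrm{low}
\times 100\%$, computed only where $MT_\mathrm{low}$ exceeds a validity
threshold (default: 5 × estimated background noise sd, reflecting that the
high-flip-angle image sits near the noise floor at ultra-low field);
invalid voxels are `NA`, never zero, and values are not clipped. ROI
statistics use the $n-1$ sample sd and report explicit missing entries
for empty ROIs. Histograms default to 1-point bins on $[-20, 60]$,
widened so counts are always conserved. Scan–rescan CoV uses the
two-value sample sd and mean times the small-sample correction
$1 + 1/(4 \cdot 2) = 1.125$, in percent; Bland–Altman reports the mean
difference and $\pm 1.96$ sd limits.

A plain non-local means filter (patch-SSD weights, box-filtered,
exact identity on constants and at zero smoothing) is available but *off*
by default in quantitative checks: patch averaging can leave MTR maps
patchy, and the package's claims are about the raw statistic.

## Parameter presets and what they are not

The two-pool parameters of water, CSF-like, white-matter-like, cream-like
and conditioner-like materials at 64 mT are not established measured
values; the shipped YAML presets are literature-informed estimates chosen
once for plausibility (tissue $T_1$ shortens substantially at ultra-low
field; conditioner has a larger bound fraction than cream; water has
none). Simulations reproduce the *structure* of the bench experiments —
symmetry, asymmetry ordering, null location, MTR ordering conditioner >
cream > water — not any particular printed in vivo value, and no such
value is claimed. Quantities that depend on undeposited scanner data
(white-matter MTR and its scan–rescan CoV in volunteers, MS comparisons)
are outside what a desk-scale simulation can reproduce.

What the generator also does not emulate: $B_0$ inhomogeneity and
off-resonance banding, geometric distortion from low readout bandwidth,
compressed-sensing reconstruction artifacts, motion, flow, and
partial-volume mixing. Passing tests therefore validate the signal model,
the statistics and the pipeline plumbing — not robustness to those
real-world effects.

## Problem sizes used in the checks

The routine checks run sweeps of 35–43 angles on single tissues (seconds),
one full-FOV noise-free six-vial phantom at two flip angles, the 14-vial
relaxometry array, and small (24 × 24 × 4) noisy phantoms for the
reproducibility chain; the isochromat validation uses 2000 isochromats on
a 3 × 3 tissue/flip-angle grid and a 1°-resolution null search over
1°–359°. These sizes were chosen so the whole suite exercises every claim
in a few minutes on one CPU while keeping every tolerance at the level the
physics supports (1e-3 for EPG-vs-oracle, 1e-6 for mirror symmetry,
exact arithmetic for the closed-form statistics).

## Known limitations

* The saturation factor uses the mean-amplitude hard-pulse rate
  $W = \pi \omega_1^2 G(0)$; shaped pulses would need the time-resolved
  $\omega_1(t)$ integral.
* On-resonance super-Lorentzian evaluation is cutoff-regularized; results
  with that lineshape depend (weakly) on the chosen cutoff.
* The echo is sampled immediately before the next pulse; an explicit TE
  within the TR is not modelled.
* No quantitative MT inversion (estimating $f$, $k$ from data) is
  provided — the package predicts signals and analyses MTR, it does not
  fit the two-pool model.
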