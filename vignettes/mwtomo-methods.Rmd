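---
title: "Methods: forward modelling, acquisition emulation, and DBIM inversion in mwtomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward modelling, acquisition emulation, and DBIM inversion in mwtomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mwtomo` implements the full computational chain of an antenna-ring
microwave tomography system: dispersive-media modelling, a 2-D FDTD
forward solver with an analytic validation oracle, a multistatic
acquisition emulator with empty-tank calibration, and the distorted Born
iterative method (DBIM) with TwIST and CGLS linear solvers and frequency
hopping. This vignette documents the models, the numerical choices, and
the design decisions that were genuinely open, so that results produced
with the package can be interpreted — and challenged — precisely.

## The physical setup

The system emulated here is a cylindrical imaging tank (inner tank 100 mm,
outer tank 200 mm diameter) filled with a lossy immersion liquid —
90% glycerine–water by default — surrounded by a ring of 8 antennas at
130 mm diameter acting as vertical line transceivers. Cylindrical targets
(16 mm diameter by default) emulate dielectric discontinuities.
Reconstruction is restricted to a ring 10 mm inside the antenna circle
(120 mm by default) to keep antenna-adjacent artifacts out of the image.
All user-facing lengths are millimeters (JSON configs); everything
internal is SI meters.

## Dispersive media

Every material is a single-pole Debye medium,

$$\epsilon(\omega) = \epsilon_\infty + \frac{\Delta\epsilon}{1 + j\omega\tau}
  - j\frac{\sigma_s}{\omega\epsilon_0},$$

with the package-wide sign convention $e^{+j\omega t}$, so passive media
have $\epsilon = \epsilon' - j\epsilon''$ with $\epsilon'' \ge 0$.

The shipped material library anchors each liquid exactly to its measured
complex permittivity at 1.2 GHz (90% glycerine–water
$\epsilon' = 14.2$, $\epsilon'' = 13.3$; water $78.6/4.8$; salt–water
10 mg/mL $77.5/30.5$): $\epsilon_\infty$ and $\tau$ are plausible
assumptions (35 ps for the glycerine mixture, 8.3 ps for the water-based
liquids, near literature relaxation times), and $\Delta\epsilon$,
$\sigma_s$ are then solved so the 1.2 GHz anchor is reproduced to machine
precision. Only the anchor values are measurements; the dispersion shape
away from 1.2 GHz is a documented modelling assumption. Users with their
own dielectric-probe data can bypass the library entirely via
`dispersion_table()` + `fit_debye()`.

`fit_debye()` is a bounded Levenberg–Marquardt fit on the stacked real and
imaginary residuals with a deterministic multi-start over
$\tau \in \{10, 20, 50, 100\}$ ps — the Debye fit has well-known local
minima in $\tau$, and a fixed start list keeps the fit reproducible.
A caveat established with a Monte-Carlo oracle during development: under
1% multiplicative measurement noise the *curve* is recovered to better
than 2%, but the raw parameters (especially the
$\epsilon_\infty$–$\Delta\epsilon$–$\tau$ split) can individually wander
by 10–15% because they are weakly identifiable. Parameter values from
noisy fits should be interpreted through the curve they imply, not as
physical constants.

## Forward solver

The forward model is a 2-D TM-polarized ($E_z$, $H_x$, $H_y$) FDTD solver
on a uniform Yee grid:

* **Dispersion** enters through the auxiliary-differential-equation (ADE)
  method with one polarization-current variable per cell — the discrete
  update reproduces the single-pole Debye law exactly in the
  small-$\omega\Delta t$ limit and is second-order accurate.
* **Boundaries** are a 10-cell convolutional PML (polynomial grading
  $m = 3$, $\sigma_{\max} = 0.8\,(m+1)/(\eta_0\Delta x)$, $\kappa = 1$,
  linearly graded $\alpha$). The physical tank's absorber and metal
  shield are *not* modelled; the PML stands in for "no reflections".
* **Antennas** are soft additive line-current sources at the nearest grid
  node; probes read $E_z$ at the antenna nodes. The source enters
  Ampère's law at half-integer time steps, and its spectrum is DFTed at
  exactly those times, so FDTD fields can be compared to analytic
  line-source fields *absolutely* (amplitude and phase), not just in
  shape. This is what makes the Born kernel constant checkable.
* **Excitation** is a Gaussian-modulated sine (center 2 GHz, width
  0.30 ns), keeping the spectral amplitude at the 0.5/3.5 GHz band edges
  above 10% of peak.
* **Steady state**: a running DFT accumulates over the whole simulation;
  the run extends until the peak trailing field drops below $10^{-5}$ of
  its running maximum (checked every 128 steps). Lossy immersion liquids
  converge in a few thousand steps. Non-converged runs carry a warning
  flag; a Courant violation is caught by a field blow-up guard and raised
  as an error.
* **Time step** is 0.9 of the 2-D stability bound
  $\Delta x/(c\sqrt{2})$; grids must resolve the shortest background
  wavelength with at least 10 cells (warned otherwise).
* **PEC targets** are realized by zeroed update coefficients, which pins
  $E_z = 0$ for all time at masked cells.

Validation is against the classical eigenfunction series for a line
source near a circular cylinder (Bessel/Hankel expansion with
$H_n^{(2)}$ outgoing waves). Because the background is lossy, the series
needs integer-order Bessel functions of *complex* argument; these are
implemented in the package (power series for $J_n$ via Miller's downward
recurrence with sum normalization, the log-form series for $Y_0$, $Y_1$
plus upward recurrence) and are themselves tested against base R on the
real axis and the Wronskian identity in the complex plane. Measured
agreement on the 8-probe ring: 0.3–1.1% for the homogeneous line-source
field and 1.4–1.8% for the scattered field of a 16 mm cylinder on the
1 mm grid (12–16% on the 2 mm grid, dominated by staircase rasterization
of the disk — the error is resolution-limited, as it should be).

Received signal strength is reported as
$20\log_{10}(|E_z(\mathrm{rx})|/|E_z^{\mathrm{ref}}|)$ with the reference
taken one cell from the source in the homogeneous background. Absolute
port-calibrated S-parameter levels of a physical VNA include antenna and
cable factors a 2-D line-source model cannot express; only relative
comparisons (shapes, with/without-target differences) are meaningful,
and only those are asserted anywhere.

## Acquisition emulation and calibration

`simulate_dataset()` emulates the measurement campaign as a complete
tx × rx sweep: $n(n-1)$ transmission entries per frequency (280 for
8 antennas × 5 frequencies). Monostatic entries are excluded throughout —
reflection data is dominated by unmodelled antenna internals. Receiver
noise is complex circular Gaussian with RMS set by a dB noise floor
(−100 dB emulating the reference VNA setting) on the dataset's own dB
scale, deterministic under a fixed seed.

Calibration follows the standard empty-tank procedure in its
multiplicative per-channel form: for each (freq, tx, rx),

$$E^{\mathrm{cal}}_{\mathrm{tot}} =
  \frac{M_{\mathrm{target}}}{M_{\mathrm{empty}}}\, S_{\mathrm{empty}},
  \qquad
  E^{\mathrm{cal}}_{\mathrm{scat}} = E^{\mathrm{cal}}_{\mathrm{tot}} - S_{\mathrm{empty}},$$

where $M$ are measured and $S$ simulated (model-frame) data. The ratio
form cancels any per-channel complex port factor — the property that
makes an empty-tank reference meaningful — and this invariance is tested
to $10^{-12}$. Entries whose empty-tank magnitude falls below a floor
threshold are flagged and excluded rather than divided.

## DBIM inversion

The nonlinear inverse problem is solved by repeated linearization about
the current background estimate. At each iteration, all $n$ antennas are
simulated on the current background (each run provides both the incident
field and, by reciprocity, the receiver Green's function), and the Born
kernel

$$J_{(m,n),k} = \frac{j\omega\epsilon_0\,\Delta A}{\hat I(\omega)}
  E^{(m)}(r_k)\, E^{(n)}(r_k)$$

maps the complex contrast
$\delta\chi_k = \delta\epsilon'_k - j\,\delta\sigma_k/(\omega\epsilon_0)$
to the probe-field perturbation. The $1/\hat I(\omega)$ factor removes
the excitation spectrum that would otherwise be counted twice; its
correctness (constant, sign, and DFT phase conventions together) is
pinned by a finite-difference test that agrees to $10^{-4}$.

**Unknowns.** Two real unknowns per voxel — $\delta\epsilon'$ and
$\delta\sigma$ at the working frequency — assembled as a real
block system from the complex Born equation. Updated maps are converted
back to per-voxel Debye parameters holding $\epsilon_\infty$ and $\tau$
at background values: the reconstruction at the working frequency is
exact under this conversion, and the Debye form gives the forward solver
a physical wideband extrapolation between hops. The reference never
states which Debye parameters its implementation frees; this choice is
ours and documented here.

**Linear solvers.** TwIST iterates
$x_{t+1} = (1-\alpha)x_{t-1} + (\alpha-\beta)x_t +
\beta\,\Gamma_\lambda\!\left(x_t + A^T(y - Ax_t)\right)$ with
soft-threshold denoiser $\Gamma_\lambda$, after scaling $A$ to unit
spectral norm (power iteration, deterministic start). The two-step
parameters default to the standard rule driven by `lam1` ($10^{-4}$).
A monotone safeguard falls back to a plain IST step whenever the
two-step update would raise the objective. $\lambda$ defaults to
$10^{-3}\max|A^Ty|$: with data at a −100 dB noise floor the dominant
error is discretization, not noise, so regularization is kept light;
heavier shrinkage visibly biases the recovered disk into a too-small,
too-high blob (a ~40% centroid overshoot at
$\lambda = 10^{-2}\max|A^Ty|$ in the development experiments). CGLS is
the classical conjugate gradient on the normal equations; its iteration
cap (default 15) is the regularization knob.

**Outer loop.** Frequency hopping over 1.2, 1.5, 1.8, 2.1, 2.4 GHz with
20 iterations per hop; each hop warm-starts from the previous maps, the
first from the homogeneous immersion background of known properties.
Within an iteration the linear solve always starts from a zero update.
Two stabilizations are built in:

* a **monotone outer step**: if an update would increase the data
  residual, it is halved (up to 3 times) before being accepted — the
  plain distorted-Born step overshoots at strong contrast, and without
  this guard the iteration can run away to phantom solutions;
* optional **Jacobian column normalization** (`col_normalize`, off by
  default): it counteracts the tendency of strong-contrast solutions to
  concentrate in the high-$|E|^2$ voxels next to the antennas, at the
  price of amplifying artifacts in the low-sensitivity ring center on
  moderate scenes.

Recovered $\epsilon'$ is clamped to $[1, 90]$ and $\sigma \ge 0$.
Final maps are reported as complex permittivity at a report frequency
(default: the first hop, 1.2 GHz).

## What the synthetic-data generator does and does not emulate

Synthetic measurements are produced by the same FDTD physics on a
**finer grid** (1 mm) than the inversion (2 mm), with −100 dB receiver
noise — so recovery experiments are free of the inverse crime in
discretization, but *not* in physics: data and model share the 2-D
line-source world. Real measurements add 3-D propagation, antenna
dispersion, cable coupling and drift, which empty-tank calibration only
partially removes. Passing recovery tests therefore demonstrate the
correctness of the inversion chain, not field performance on hardware
data.

This distinction matters quantitatively at high frequency and strong
contrast. A 16 mm water cylinder in 90% glycerine–water is a ~6:1
$\epsilon'$ contrast carrying ~3.7 rad of extra phase at 2.2 GHz — beyond
the single-frequency linearization's basin of attraction when the data
contain the full 2-D scattering physics. In our experiments,
single-frequency 2.2 GHz imaging of two such water targets produces
displaced or phantom maxima with every solver setting tried, while at
1.0 GHz both solvers image both water targets (with the overestimated
amplitudes characteristic of low-frequency single-hop inversion), and at
2.2 GHz two *moderate*-contrast targets (≤ 2:1, ~0.8 rad) are resolved
cleanly by both solvers, top-two maxima within 2 mm of truth. The
two-target validation experiment therefore uses the moderate-contrast
pair; the frequency-hopping schedule exists precisely because
single-frequency high-contrast inversion is unreliable.

## Problem sizes and determinism

The validation experiments run at the sizes used throughout this
vignette: 2 mm inversion grids (≈ 130×130 cells with PML; 2813 ring
voxels for the 120 mm ring), 1 mm data grids (≈ 250×250), 8 antennas,
5-frequency hopping with 20 iterations per hop. A full single-target
recovery takes a few minutes on one core; all randomness (noise draws,
randomized reciprocity scenes) flows from explicit seeds, and repeated
runs are bit-identical.

## Known limitations

* 2-D scalar model: no antenna height effects, no 3-D spreading, no
  tank-wall (acrylic) layer — the background is homogeneous immersion
  liquid out to the PML.
* The material library's dispersion away from the 1.2 GHz anchors is
  assumed, not measured; supply measured tables via `fit_debye()` when
  they exist.
* Single-pole Debye only; media needing two poles or Cole–Cole laws are
  out of scope.
* $\lambda$, TwIST relaxation parameters, and the CGLS iteration cap are
  exposed configuration with documented defaults; no automatic
  L-curve/discrepancy machinery beyond the default rule.
* Touchstone/VNA file import is not implemented; external data enter
  through the documented CSV format.
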