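---
title: "Simulating arterial pulse waves across the adult age range: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating arterial pulse waves across the adult age range: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsesim)
```

pulsesim simulates arterial pressure, flow, luminal-area and
photoplethysmogram (PPG) pulse waves for virtual adults aged 25–75 yr, and
extracts the pulse wave indexes used in clinical practice. This vignette
explains the model, its assumptions and tunable parameters, the numerical
choices, what the synthetic networks emulate (and do not), and the design
decisions taken where the design was genuinely open.

## The 1D model

Blood flow in each arterial segment is described by the cross-sectionally
averaged 1D equations for an incompressible Newtonian fluid
(density $\rho = 1060\,$kg/m$^3$, viscosity $\mu = 2.5\,$mPa·s, laminar
flow with a parabolic velocity profile):

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\alpha \frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x P = -\,8\pi\frac{\mu}{\rho}\frac{Q}{A},$$

with momentum correction $\alpha = 4/3$ (a flat-profile alternative,
$\alpha = 1$ with friction coefficient $22\pi$, is available through
`solver_options(friction_model = "flat")`). Segments are thin Voigt-type
viscoelastic tubes of constant length with linearly tapered diameter:

$$P = P_d + \frac{\beta}{A_d}\left(\sqrt{A} - \sqrt{A_d}\right)
      + \frac{\Gamma}{A_d^{3/2}}\,\partial_t A,
  \qquad \beta = \tfrac{4}{3}\sqrt{\pi}\,Eh,$$

where $A_d$ is the luminal area at the diastolic reference pressure
$P_d$. The elastic part is built so the linearised wave speed at
$A = A_d$ equals the theoretical diastolic speed
$c_d = \sqrt{2Eh/(3\rho R_d)}$ exactly (`tube_law_pressure()` /
`wave_speed()`).

Wall stiffness follows the empirical law
$Eh = R_d\,[k_1 \exp(k_2 R_d) + k_3]$ shared by all segments of a network;
wall viscosity follows $\Gamma = b_1/(2R_d) + b_0$ with
$b_1 = 150\,$g·cm/s and $b_0 = 600\,$g/s, which produces realistic
hysteresis in peripheral pressure–area loops (asserted by a test, not a
formula). The literature quotes $k_1$–$k_3$ in CGS;
`stiffness_constants_si()` converts them once at the config boundary and
everything internal is SI (pressures externally in mmHg, conversion fixed
at 133.322 Pa/mmHg).

Each terminal segment ends in a three-element (RCR) windkessel
representing its vascular bed; a prescribed periodic flow waveform at the
aortic root represents ventricular ejection; junctions conserve mass and
total pressure $P + \tfrac{1}{2}\rho u^2$ with no energy-loss model. The
PPG at a peripheral site is the blood volume stored in the terminal
windkessel (optionally the integrated luminal volume of a segment),
normalised to $[0, 1]$ per cycle.

## Numerics

The interior of each segment is advanced with the explicit two-step
MacCormack scheme (predictor forward / corrector backward differences),
which is conservative in mass with the numerical flux
$\hat F_{i+1/2} = (Q_{i+1} + Q^p_i)/2$. Boundary nodes are closed with
half-cell finite-volume continuity against that same flux, coupled
directly to the physical condition: the prescribed inflow at the root, a
monotone scalar equation for the windkessel outlets, and a small Newton
system (mass + total-pressure continuity, analytic Jacobian) at
junctions. Closing the boundaries in flux form rather than with
characteristic extrapolation makes global mass conservation exact by
construction — important on strongly tapered aortic segments, where
characteristic closures showed a systematic per-cycle volume bias.

The viscoelastic pressure term is applied by operator splitting as a
diffusion in $Q$, solved implicitly (one tridiagonal solve per segment per
step), so the time step is limited only by the advective CFL condition
(safety factor 0.5 by default, with margin for systolic pressurisation).
Node spacing is at most `dx_max` (default 7 mm, at least 3 nodes per
segment): this resolves the taper of the short proximal aortic segments;
halving it changes aortic systolic pressure by well under 0.5 mmHg.
Each simulation runs whole cardiac cycles until the relative
L$_\infty$ change of the aortic-root pressure between consecutive cycles
(normalised by its pulse range) falls below `periodicity_tol`
(default $10^{-3}$, at most `max_cycles` = 20), then records one further
cycle, resampled to 500 Hz. Non-convergence flags the result and warns; a
non-positive area aborts with a diagnostic. Degenerate inputs (flat
signals, zero aortic pulse pressure, missing fiducial points) raise
errors or yield `NA` rather than fabricated values.

## Aging model and calibration

Model inputs are prescribed per age from per-decade anchor tables shipped
as CSV (`aging_tables()`): cardiac parameters (HR, SV, LVET, PFT, RFV),
pressures (MAP, DBP), geometry (proximal aortic length; ascending,
descending-thoracic and abdominal aortic and carotid diameters), PWV
targets (aortic, arm, leg; with asymmetric SDs capturing the positive
skew of PWV) and total peripheral compliance. HR is interpolated with a
shape-preserving cubic, the MAP mean with a natural spline (SDs
linearly), everything else linearly; decade anchors are reproduced
exactly. Six parameters are flagged as the varied factors (HR, SV, LVET,
diameter, PWV, MAP); a virtual population enumerates all $3^6 = 729$
combinations of $\{-1, 0, +1\}$ SD offsets per age. Two couplings are
applied: the LVET mean is shifted by $-0.926$ ms per beat/min and
$+1.08$ ms per ml of the subject's HR/SV deviations before LVET's own
offset (the regression can also be applied in absolute form via
`lvet_mode`), and the PWV targets are evaluated at the subject's MAP
(multiplicative 1 %/mmHg about the age mean — the magnitude implied by
population reference tables of PWV by age and BP category).

Two calibrations make each subject self-consistent:

* **Stiffness.** `calibrate_stiffness()` fits $(k_1, k_2, k_3)$ so the
  theoretical wave speed matches the subject's aortic/arm/leg targets at
  representative path radii; an exact three-anchor solve is used when the
  targets are exponential-shaped in radius, otherwise a deterministic
  positivity-constrained weighted least squares (aorta weighted most,
  since the peripheral targets are derived quantities). A fixed-point
  refinement then matches the *path-integrated* transit times
  $L/\!\int dx/c_d(x)$ to the targets.
* **Vascular beds.** `calibrate_resistances()` solves one scaling factor
  so the tree of conduit (Poiseuille) resistances in series with the
  windkessels equals $(\mathrm{MAP} - P_\mathrm{out})/\mathrm{CO}$
  ($P_\mathrm{out} = 0$, i.e. venous pressure neglected, configurable).
  Bed totals follow baseline flow fractions; within a bed, outlet
  resistance is inversely proportional to the luminal area of the feeding
  branch. $R_1$ is matched to the terminal characteristic impedance
  (capped at 90% of the outlet total) to avoid spurious outlet
  reflections; compliances are distributed for equal bed time constants
  and sum to the prescribed total.

The tabulated peripheral compliance values are stored verbatim in their
printed units and converted with $10^{-10}$ m$^3$/Pa per displayed unit.
This interpretation — one power of ten below the printed column header —
is the one consistent with realistic pulse pressures and diastolic decay
constants on this network; taking the header literally would imply a
peripheral compliance an order of magnitude above the total arterial
compliance of a healthy adult.

The BP plausibility filter compares a subject's aortic and brachial
SBP/DBP/MAP/PP and PP amplification to age-specific healthy reference
intervals mean ± 2.575 SD (99% coverage). The interval is closed: a value
exactly on the boundary is plausible. All nine quantities are treated
identically.

## The inflow waveform

`generate_inflow()` time-warps an archetype single-cycle shape — a
raised-cosine systolic lobe, a brief reverse lobe, zero diastolic flow —
so the peak falls at PFT and the end-systolic zero crossing at LVET,
scales the reverse lobe to the reverse flow volume and the forward lobe
so the net integral equals stroke volume. Shape characteristics not
pinned by these parameters are held fixed across subjects and ages.
`measure_inflow_features()` inverts the construction; round-tripping
recovers every parameter to within one sample or 0.5%.

## The fixture networks

The full-anatomy geometry that a production study would transcribe is
accepted through the documented JSON schema (`load_network()` /
`save_network()`; a 7-segment example ships in `inst/extdata`). All
bundled analyses run on the deterministic 13-segment reduced network
(`make_fixture_network("reduced")`): the aorta in four tapering segments
from root to iliac bifurcation, a large visceral bed off the distal
thoracic aorta (55% of resting cardiac output — it stands in for the
celiac/renal/mesenteric beds a pruned network lacks), a
subclavian–brachial–radial arm with an ulnar branch, an
iliac–femoral–tibial leg plus the contralateral iliac, and a
carotid–temporal head path. Measurement sites include the aortic root,
carotid, brachial, radial, femoral, ankle and iliac bifurcation, with
windkessel-volume PPGs at finger, toe and temporal sites. Ages rescale
the proximal aortic length and the aortic/carotid diameters by their
age-specific anchors.

What the reduced network does *not* emulate: the distributed reflection
sites of ~100 further segments. Its pulse pressure amplification
(1.28 at 25 yr falling to 1.14 at 75) and carotid augmentation index
(11% rising to 42%) reproduce the directions but compress the in vivo
dynamic range (about 1.62 to 1.19 and 2% to 42% respectively), and the
windkessel PPG is smoother than a measured finger PPG, so PPG index
values (RI, SI, AGI$_{mod}$) are best interpreted through their trends.
One consequence is a known limitation: baseline PP amplification is flat
(±0.001) between ages 45 and 55, where the aging inputs themselves are
nearly flat (HR 77→77 beats/min, MAP 96.3→96.2 mmHg), so the "strictly
decreasing with age" property holds everywhere except that single pair.
Passing tests on this network therefore demonstrate the mechanics of the
pipeline and the directional physiology, not quantitative agreement of
every cohort statistic with in vivo data.

## Index extraction

`find_fiducials()` analyses each wave and its Savitzky–Golay first and
second derivatives (polynomial order 3, window 9 samples at 500 Hz,
scaled with the sampling rate, circular padding). The foot is located by
intersecting tangents (the horizontal through the pre-upstroke minimum
crossed with the tangent at the steepest upstroke); alternatives such as
the minimum itself are deliberately not used because the intersecting
tangent is the robust standard for foot-to-foot transit times. P1/P2 are
the early and late systolic peaks when both are distinct local maxima;
on single-peaked waves the missing shoulder is recovered from the slope
signal (a slope dip on the rising limb for stiff, late-peaked waves; a
slope bulge on the falling limb for young, early-peaked waves). The
dicrotic notch falls back to the strongest late-systolic inflection and
the diastolic peak to the decay-limb slope shoulder when the wave does
not reverse — but never on a featureless monotone decay, so absent
features stay absent. The a–e waves are alternating extrema of the
second derivative starting from the dominant early acceleration maximum.

Derived indexes follow their standard definitions: SBP/DBP/MAP/PP from
extrema and time average; PP$_\mathrm{amp}$ = brachial PP / aortic PP;
AP = P(P2) − P(P1), AIx = 100·AP/PP, Tr = t(P1) − t(foot) on the carotid
wave; RI = diastolic/systolic peak amplitude, SI = height / peak-to-peak
delay (the model carries no height; 1.75 m is used throughout, so SI is
proportional to the reciprocal delay) and AGI$_{mod}$ = (b − c − d − e)/a
on the finger PPG; PTTs by foot-to-foot with PWV = path length / PTT,
path lengths measured along the tree between sites.

## Case studies

*PP amplification decomposition* reports, besides PP$_b$/PP$_a$, the
early (P1-referenced) and late (P2-referenced) systolic components
PP$_b$/(P1$_a$ − DBP$_a$) and PP$_b$/(P2$_a$ − DBP$_a$).

*PPG surrogates of aortic stiffness*: `correlate_index_with_pwv()` gives
the squared Pearson correlation of an index with the foot-to-foot aortic
PWV over the plausible subjects, and `sensitivity_index()` the percent
change per +1 SD one-at-a-time parameter move (forward difference, per
its definition; not centred).

*Pulse contour cardiac output*: two algorithms on the radial pressure
wave, CO ∝ RMS and CO ∝ PP/[T·(SBP + DBP)], each calibrated on the
age-matched baseline. The RMS is taken over the raw pressure by default:
the mean-pressure level is what lets the algorithm track CO when the
vasculature is unchanged, and only this convention reproduces the
characteristic error pattern (near-zero RMS error under CO changes,
~8% under MAP changes; the pulsatile-RMS convention is available via
`mean_subtract`). The assessment varies one parameter at a time: HR or SV
(±1 SD) with the vascular beds held at their age-baseline calibration so
MAP responds passively — an acute cardiac perturbation — or MAP (±1 SD)
implemented through the resistances at fixed CO. Database-grid subjects,
by contrast, always control MAP as its own factor. Errors are mean
absolute percentage errors against the reference CO = HR×SV, overall and
per subgroup; the calibrated algorithm is exact on its own calibration
point by construction.

## Problem sizes used by the bundled tests and script

The test-suite and the acceptance script simulate the six baseline
subjects, the 42 single-parameter case-study runs and a handful of
idealised tubes at the default resolution (7 mm spacing, CFL 0.5,
periodicity $10^{-3}$); a full 729-subject-per-age database is supported
by the same functions (`run_database()`) and is simply a larger loop over
the identical per-subject pipeline.
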