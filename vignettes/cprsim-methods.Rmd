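---
title: "Modelling mechanical chest compression and its hemodynamic effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mechanical chest compression and its hemodynamic effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprsim)
```

cprsim simulates the complete chain from a pneumatic CPR device's control
input to the blood flow it produces in an arrested patient: a
valve-controlled cylinder under PID depth control, a spring–damper model
of the sternum, and a 14-compartment lumped-parameter circulation driven
by the chest-wall velocity. This vignette records the models, their
assumptions, the numerical choices, and the design decisions a maintainer
would want to know about.

## The pneumatic actuator

The compression head is a double-acting cylinder. Supply air passes
through a voltage-controlled electro-pneumatic regulator whose spool is a
first-order lag, \(\dot x_v = (k_v u - x_v)/\tau_v\); the effective
throttle area is \(A_0 = x_v w\). Mass flow through the throttle follows
the standard compressible-orifice law
\[
Q_m = c_0\,\eta_2\,A_0\,\frac{p_u}{\sqrt{RT}}\,f_1(p_d/p_u),
\qquad
f_1(r) = \begin{cases} 1 & r \le r_c\\[2pt]
\dfrac{\eta_1}{\eta_2}\sqrt{r^{2/k} - r^{(k+1)/k}} & r > r_c,
\end{cases}
\]
with \(\eta_1 = \sqrt{2k/(k-1)}\),
\(\eta_2 = \sqrt{k}\,(2/(k+1))^{(k+1)/(2(k-1))}\) and the critical ratio
\(r_c = (2/(k+1))^{k/(k-1)}\) (0.528 for air). Using the analytic
\(r_c\) rather than the rounded 0.528 makes \(f_1\) exactly continuous
at the sonic/subsonic transition — below it the flow is choked and
independent of downstream pressure, a property the test suite checks to
machine precision.

Both chambers evolve adiabatically (charge and discharge are fast), so
\(V\,dP = kRT\,dM - kP\,dV\) per chamber, with the discharging chamber's
gas temperature at the isentropic value \(T = T_s (P/P_s)^{(k-1)/k}\).
The piston obeys
\(M_W \ddot X = a_0 P_1 A_1 - P_2 A_2 - F\), where the load
\(F = \pm F_1 + F_2 - F_3 + P_a(A_1-A_2)\) combines Coulomb friction
(sign with the motion; capped static friction at rest), the sternal
reaction \(F_2\), the gravity component \(F_3\) and the ambient-pressure
imbalance across the rod. The working-area coefficient is derated to
\(a_0 = 0.8\) at the retracted stop, and the piston starts to move only
once the net thrust beats static friction.

The 5-port directional valve is treated as commutating instantaneously
at the instruction edges: during the compression phase chamber 1 is fed
through the regulator and chamber 2 blows down through the valve exhaust;
at the edge the roles swap and the regulator is driven wide open, so
retraction always happens at full throttle. The two exhaust paths (one
per chamber) have separate effective areas `A_exh1`/`A_exh2`, because a
real 5-port valve vents each chamber through its own port and silencer;
these two areas are what set the decompression and compression speeds
independently.

**Control.** Depth is closed-loop PID on the piston displacement with
output saturation to \([0, u_{\max}]\) and conditional-integration
anti-windup; the derivative memory is reset at each instruction rise to
avoid a derivative kick. The shipped gains (kp = 1000 V/m, ki = 100
V/(m s), kd = 18 V s/m) were tuned so that sub-maximal commands settle
with less than 2 mm overshoot while a 50 mm command (which saturates the
controller) traverses the stroke at full speed.

**Chest model.** The thorax is a linear spring–damper,
\(F_2 = k_1 X + m\dot X\) with the measured adult constants
k1 = 7028.9 N/m and m = 438.1 N s/m ("m" is a damper despite the
symbol; its printed units are N s/m). The same expression, with its
natural sign, returns stored elastic energy to the piston during
decompression; the spring contributes nothing above the resting chest
position.

**Shipped configuration.** Appendix-level constants for the physical
prototype are not available, so `inst/extdata/actuator_default.yaml`
documents a concrete 50 mm-stroke, 40 mm-bore cylinder fed at 0.45 MPa
absolute whose closed-loop trajectory reproduces the reference
trapezoid-like waveform: steady-cycle event times
(start-compress 0.009 s, fully-compressed 0.217 s, start-decompress
0.309 s, fully-decompressed 0.472 s) under the standard instruction,
within 20 ms of the published timing of the device the model describes.
All tests and the acceptance script read this file rather than
hard-coding constants.

## Compression waveforms

`instruction_signal()` builds the square-wave command (depth for
`duty_cycle` of each period). `manual_waveform()` builds the surrogate
for human compressions: a half-sine displacement hump sampled at 50
points per cycle, with an independent uniform perturbation on
\([-1, 1]\) mm added to each of the 25 downstroke points. The release
half-cycle is left noiseless — the perturbation is specified for the
downstroke only, and mirroring the clean half-sine is the most
conservative completion. The noise distribution is uniform because only
a "±1 mm random value" is specified; the generator takes the
half-width as a parameter so other choices are one argument away.
Batches derive per-set seeds deterministically from one master seed, so
a 10-waveform "study arm" is bit-reproducible.

`waveform_velocity()` differentiates by central differences (one-sided
at the ends); at the 1 kHz-equivalent sampling used throughout, the
velocity of a pure half-sine matches its analytic derivative to better
than 1% RMS, and re-integrating the velocity returns the displacement
within 0.1 mm per cycle.

## The circulation model

The vasculature is a closed loop of 14 compliant compartments connected
by Ohmic resistances, with ideal-diode valves at the four cardiac
stations and in the jugular vein. Each compartment stores volume on a
linear compliance, \(C = \Delta V/\Delta P\); flows follow
\(Q = (P_{\text{from}} - P_{\text{to}})/R\) (positive downstream — the
sign convention is normalised so that forward gradients give forward
flow), and pressures evolve as \(\dot P = (Q_{in} - Q_{out})/C\).
Topology, resistances, compliances, arrest baselines and source
constants are data in `inst/extdata/circulation_default.yaml`, not code.

Chest motion enters through two pressure sources. The mediastinal
source integrates \(\dot P_M = E(\dot X + \dot x_2)/d_0\) — effectively
\(P_M \propto X\) plus a correction from the vessel-expansion speed
\(\dot x_2\), computed by default as the rate of intrathoracic vascular
volume change divided by an effective area (a switch sets
\(\dot x_2 \equiv 0\)). The alveolar source integrates
\(\dot P_{lung} = (\dot X A_L - (P_{lung}-P_{mouth})/R_{airway})/C_{lung}\):
a compression inflow term against an airway leak. \(P_M\) is applied as
an additive external pressure to the compartments flagged
`intrathoracic`; \(P_{lung}\) to the lung vascular bed only (alveolar
pressure replaces, rather than adds to, the mediastinal pressure there).
Because the integrated state of each compartment is the transmural
pressure of its compliance, external pressure offsets move no volume by
themselves and total blood volume is conserved to machine precision — a
property the suite audits every run.

**Why two compartments are pressure-shielded.** An external pressure
applied uniformly to a set of connected compartments cancels out of
every internal pressure gradient: a uniformly squeezed thoracic block
can push blood out of the thorax but can never raise the aortic pressure
above the venous side by more than the peripheral circuit allows, and no
realistic parameter set then reproduces the observed aortic pressures or
coronary perfusion pressure. The shipped topology therefore treats the
stiff thoracic aorta and the deep pulmonary-vein reservoir as shielded
from the mediastinal squeeze (their `intrathoracic` flag is off). The
mitral and aortic valves then gate a two-stage pump: during
decompression the left heart fills from the shielded reservoir; during
compression the squeeze pressurises the left heart against the
unexposed aorta and ejects. This is the lumped-network expression of
the cardiac-pump component of CPR, and it is a topology-file choice,
not a code path.

**Shipped parameter values.** Compliances and peripheral resistances
are physiologic for an arrested adult (total arterial compliance
≈ 4.7 mL/mmHg, systemic resistance ≈ 24 mmHg min/L, mean circulatory
filling pressure ≈ 6–8 mmHg). Within those physiologic ranges the
constants were calibrated once so that the standard mechanical waveform
reproduces the published operating point of the device this model
describes — CO ≈ 1.22 L/min, CPP ≈ 31 mmHg, CF ≈ 0.32 L/min — and were
then frozen; the same file yields manual-waveform group statistics and
sweep optima consistent with the same source without further
adjustment.

## Numerics

Both integrators are fixed-step classical RK4, written in C++ (Rcpp):
the actuator at `dt = 5e-5` s (the chamber-pressure and velocity time
constants are a few milliseconds, so this resolves them by two orders
of magnitude; trajectories at `dt` and `dt/2` agree within 0.1 mm), the
circulation at `dt = 2e-4` s against RC time constants of 20 ms and
longer. Stroke limits are inelastic stops: the position is clamped and
the velocity zeroed on contact, with the force balance re-evaluated
every step so the piston can lift off again. Valve diodes clamp reverse
flow to zero inside the right-hand side; at these step sizes the
non-smoothness costs no observable accuracy (the two-compartment
reduction matches its closed-form exponential to 1e-6, and an adaptive
stiff solver agrees with the fixed-step trace to the same tolerance).

Event times ("start to compress", "fully compressed", and their
release counterparts) are defined by 0.5 mm threshold crossings of the
linearly interpolated trajectory — the threshold is a parameter —
because the reference timing table does not define them. Circulation
metrics are taken after a 10-cycle warm-up over 15 recorded cycles;
cycle-to-cycle pressure traces then agree within 0.5% RMS, and
averaging over 1 or 5 cycles changes CO by less than 0.5%. The
diastolic window for CPP is the decompression phase of the driving
waveform (there is no intrinsic heartbeat during CPR): the instruction
low phase for mechanical waveforms, the release half-cycle for manual
ones.

Internally the circulation integrates in mmHg–mL–s (the cardiovascular
convention); the user-facing surface is mmHg, L and min, with the
conversions (1 mmHg min/L = 0.06 mmHg s/mL; 1 mL/s = 0.06 L/min)
applied at the boundary. The actuator is SI throughout.

## What the synthetic data does and does not show

The manual-waveform generator emulates only the displacement profile of
human compressions (half-sine with bounded displacement noise). It does
not model rescuer fatigue, incomplete release, rate drift, or
force-depth coupling; consequently the spread it produces between
repeated compressions is narrower than between real rescuers —
displacement noise alone gives a CPP standard deviation an order of
magnitude below observed inter-operator variability, though group means
are reproduced. Passing the group-statistics tests therefore shows the
pipeline's central tendency is right, not that it captures human
variability.

Other known limitations: the model transmits the full mediastinal
squeeze to the right atrium, so simulated peak right-atrial pressure
(≈ 31 mmHg) exceeds the reference measurement (≈ 21 mmHg) even though
decompression-phase CPP is reproduced; CPP versus frequency declines
from the low end of the 90–150 press/min range rather than peaking just
inside it (CO and CF do peak in the interior, near 102 and 111
press/min); there is no baroreflex, gas exchange, nonlinear
pressure–volume behaviour, or viscoelastic thorax; and the
recorded-waveform comparisons that would exercise `load_waveform()` on
real sensor data cannot be reproduced because no recordings are
deposited — the simulated waveform stands in for the mechanical arm
throughout.

## Problem sizes

The shipped defaults balance fidelity against runtime: 3 actuator
cycles (the third is steady), 25 circulation cycles with 10 discarded,
10 manual waveforms per group, and sweep grids at 1 mm, 0.01 duty and
1 press/min over the validated ranges (20–50 mm, 0.2–0.8, 90–150
press/min). A full sweep of all three parameters completes in well
under a minute on one core.
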