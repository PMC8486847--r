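---
title: "Modelling a graphene bioFET molecular-communication receiver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a graphene bioFET molecular-communication receiver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofetmc)
```

## The system being modelled

A microfluidic channel carries short DNA strands (the "information
molecules") over a graphene field-effect transistor whose surface is
functionalised with complementary probe strands. Hybridisation of target to
probe deposits negative charge within the electrical double layer, gates the
graphene, and lowers the drain–source current — so concentration pulses at
the channel inlet become current dips at the transistor. On-off keying over
this physical link (bit-1 = a concentration pulse, bit-0 = buffer only)
turns the sensor into a molecular-communication receiver. This package
implements the full quantitative chain: channel hydraulics, gate
electrostatics, binding kinetics, pulse superposition, detection, parameter
inference, and seeded synthetic data for testing all of it.

## Transduction chain

Three capacitances in series set the gate coupling,

$$C_G = \left(\frac{1}{C_{Gr}} + \frac{1}{C_{Pt}} + \frac{1}{C_Q}\right)^{-1},$$

where the graphene electrical-double-layer term is a parallel-plate
capacitor of thickness the Debye length, $C_{Gr} = A\,\varepsilon_r
\varepsilon_0/\lambda_D$ with $\lambda_D \approx 0.3/\sqrt{I}$ nm for an
aqueous electrolyte of ionic strength $I$ (molar); the reference-electrode
term is negligible for a macroscopic electrode (passed as `Inf`); and the
quantum capacitance is $c_q A$. A tethered oligonucleotide's charge is
screened exponentially over the Debye length, $q = n\,q_e\,
e^{-r/\lambda_D}$ with $r$ the effective height of the charge centroid
(half the contour length for a vertically tethered single strand). One
bound molecule then contributes $Q = g_m q / C_G$ to the drain–source
current, and bound-receptor counts and current changes interconvert
exactly through $Q$.

Two conventions matter and are deliberate:

* **SI internally, bench units at the boundary.** Constructors accept
  micrometres, microlitres per minute and molar, convert once, and all
  arithmetic is done unrounded. The widely quoted flow velocity of
  220 µm/s for this geometry is a two-significant-figure rounding of the
  exact 222.22 µm/s; the package computes with the latter (the published
  Reynolds number 0.4839 is only reproducible from the unrounded value),
  and `reproduce_constants()` compares at tolerances that respect the
  original rounding.
* **Receptor-count domain internally.** The transconductance of an
  n-doping response is negative, so the current change, equilibrium
  response and transduction factor are all negative. All kinetics are
  computed on the positive bound-receptor count $N(t)$ and multiplied by
  the signed $Q$ only at the boundary, which removes sign gymnastics from
  every formula.

One worked value does not survive recomputation: the probe surface density
from the neutrality-point shift, $n = \Delta V_{CNP} C_G / (q A)$,
evaluates to roughly $2.4\times10^4\ \mu m^{-2}$ with the stack's own
inputs, an order of magnitude above the commonly quoted
$\sim 2\times10^3\ \mu m^{-2}$. The package implements and tests the
direct evaluation.

## Binding kinetics: three nested layers

**Equilibrium.** Single-site reversible binding gives the Langmuir
isotherm, occupancy $c/(c + K_D)$. With the fitted constants of the
reference device ($K_D = 730$ nM, saturation response $-1.393$ µA) the
predicted equilibrium response at 1 µM is $-0.805$ µA.

**Transients.** Step application of concentration $c$ relaxes
exponentially at the observed rate $k_{obs} = k^+ c + k^-$; removal decays
at $k^-$. The dissociation branch is implemented as
$\Delta I(t_d)\,e^{-k^-(t - t_d)}$, time-referenced to the buffer switch,
so the composite curve is continuous at $t_d$.

**Finite pulses with transport limitation.** When delivery of molecules to
the surface competes with binding, the surface-adjacent concentration
$c_s$ lags the bulk. Under the quasi-steady flux balance
$k_T^*(c_b - c_s) = dN/dt$ the binding ODE becomes

$$\frac{dN}{dt} = \frac{k_T^*\left[k^+ c_b (N_{max} - N) - k^- N\right]}
{k_T^* + k^+ (N_{max} - N)},$$

and this ODE has an exact closed-form solution in the principal branch of
the Lambert-W function, with pulse-shape constants

$$\alpha^* = \frac{k^+ c\, N_{eq}}{k^- N_{eq} + k_T^* c},\qquad
\beta^* = \frac{k^+ c + k^-}{1 + k^- N_{eq}/(k_T^* c)},\qquad
\gamma^* = N_{max} + k_T^*/k^+.$$

`pulse_response()` evaluates the closed form;
`ode_reference_response()` integrates the ODE with `deSolve` at
`rtol = 1e-10` and serves as the independent numerical oracle — the test
suite holds the two to within $10^{-5}$ relative error across a grid of
transport rates, concentrations and pulse widths, which is the strongest
kind of check available here since the fitted pulse-model parameters of
the original device were never tabulated. As $k_T^* \to \infty$ the model
collapses onto the pure kinetic transients (asserted numerically to
$10^{-3}$), and at the pulse arrival the identity $W_0(\alpha
e^{\alpha}) = \alpha$ makes the response exactly zero.

Numerical care: for $\alpha^* < 10^{-8}$ the association branch switches
to its analytic small-$\alpha$ limit $e^{\alpha-\beta\tau}$ (avoiding
0/0); Lambert-W arguments are guarded at the branch point $-1/e$ (the
dissociation argument is provably inside the domain because
$N_0 < \gamma^*$, so the guard only ever absorbs rounding); and the
association/dissociation branch assignment is half-open
($[t_a, t_d]$ / $(t_d,\infty)$), removing the need for an infinitesimal
step-function offset.

### The transport coefficient $k_T^*$

$k_T^*$ lumps channel geometry, flow and diffusion into one coefficient
with units of molecules·M⁻¹·s⁻¹ (fixed by dimensional analysis of
$\alpha^*$). Its value for the reference device was never published, so the
package treats it as a configuration parameter, recoverable from pulse
data by `fit_pulse_model()`. When nothing better is available,
`leveque_transport_rate()` supplies a laminar boundary-layer estimate
($k_c = 0.81(\dot\gamma D_0^2/L_s)^{1/3}$, wall shear rate $\dot\gamma =
6u/h$, converted to molecule-flux units). For the default device this
lands around $9\times10^{12}$, deep in the transport-fast regime — a
documented order-of-magnitude stand-in, not a measurement.

## Transmission and detection

`received_signal()` superposes shifted copies of the single-pulse response
for every transmitted bit-1 (the linear time-invariant approximation,
accurate while the receiver stays far from saturation); `mode = "ode"`
re-integrates the full multi-pulse schedule through the nonlinear ODE to
quantify the approximation error. Signals are normalised by the baseline
current, $\hat I = (I_{baseline} + \Delta I)/I_{baseline}$.

The decoder compares the current at the start and end of each bit
interval after a constant synchronisation delay: a drop decodes as bit-1
(binding lowers the current), an exact tie as bit-0. This depends only on
difference signs, so it is invariant to baseline offset and positive
rescaling — the property that lets it survive the heavy intersymbol
interference (slow dissociation, half-life $\ln 2/k^- \approx 512$ s)
that defeats fixed-threshold detection at short bit intervals.

One formula-versus-prose discrepancy is resolved in favour of the prose:
the printed decoding rule multiplies by the transmitted bit, which would
require the receiver to know the ground truth; the implemented rule is
$\hat s[i] = \mathbf{1}[r[i+1] - r[i] < 0]$.

Filtering interacts with decoding in a way worth spelling out. The
conventional 21-s moving mean is, offline, a *centred* window — and a
centred window is non-causal: at a decision instant that coincides with
the next pulse's onset it averages ~10 s of the future dip into the
present sample, which on a noiseless trace turns an exact-tie bit-0 into
a spurious bit-1. `moving_mean(..., align = "trailing")` provides the
causal variant any real-time receiver would use; the decoding pipeline
filters causally, and with it noiseless decisions are provably unchanged
by filtering. The centred default is kept for like-for-like offline
denoising.

## Inference

All three layers are fit by bounded Levenberg–Marquardt least squares
(`minpack.lm`), on response magnitudes so sign conventions stay out of
the optimiser. The isotherm fit multi-starts from five log-spaced $K_D$
guesses spanning the concentration range (the isotherm's residual surface
has a flat valley in $K_D$/saturation); the transient fit seeds $k^-$
from the late-time log-linear decay and $k_{obs}$ from the early-time
rise; the pulse-model fit optimises positive parameters on the log scale
and flags the weakly identified joint release of $k_T^*$ and $c_{avg}$.
Uncertainty, when requested (`n_boot`; 200 resamples is a reasonable
choice), comes from a residual bootstrap rather than asymptotic
covariance — the traces are short and autocorrelated.

## What the synthetic data emulate — and what they do not

The generators reproduce the three experiment types at their published
operating points: staircase sensing runs (50 nM → 10 µM, each
concentration held until the response settles to within 1% of its step
equilibrium), specificity runs (association to 1 µM, buffer switch at
1800 s), and 20-bit OOK transmissions (30-s pulses of 1 µM at bit
intervals of 60/120/360 s over a 31.25 µA baseline). Sampling is 1 s,
commensurate with the 21-s filter. The noise model is additive Gaussian
(default σ = 0.05 µA, chosen so the filtered traces show roughness around
0.15% of baseline, qualitatively matching the published recordings — no
noise figure was ever stated) plus optional linear drift. It deliberately
omits 1/f FET noise, temperature drift, nonspecific adsorption, steric
hindrance and inlet dispersion; consequently, passing tests demonstrate
the correctness of the pipeline's mathematics and its parameter recovery
under the stated statistical assumptions, not performance on real devices.
The measured 5% bit error rate and ~55 s propagation delay of the original
experiments live in untabulated recordings and are preserved here only as
context (the delay as the default synchronisation constant, the error
tally as the arithmetic 3/60).

Problem sizes are chosen for desk-scale reproducibility: recovery studies
use 100 replicates of 7-point isotherms, transient fits run on 3600-point
traces, and the ODE-versus-closed-form grid covers 24 parameter
combinations — the full suite runs in seconds.

## Worked reproduction

```{r constants}
reproduce_constants()
```

```{r isi}
run_isi_study(seed = 1, noise = NULL, k_t = 1e10)
```

## Known limitations

* The LTI superposition underestimates interaction between closely spaced
  pulses; `mode = "ode"` bounds that error but is itself still the lumped
  two-compartment model, not convection–diffusion–reaction PDE transport.
* $c_{avg}$ defaults to the inlet pulse concentration (plug flow); an
  attenuated effective concentration can be fitted but not predicted.
* The Lévêque default for $k_T^*$ assumes a developed laminar boundary
  layer over a small sensor; treat quantitative pulse-shape work as
  requiring a fitted $k_T^*$.
* Mismatched-control kinetics (single- and 7-base-pair mismatch strands)
  are carried in `device_defaults()` for specificity simulations, but
  their published rate/constant rows are internally consistent only to
  about three digits and are not used as numeric oracles.
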