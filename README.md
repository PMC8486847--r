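# biofetmc

Modelling, simulation and decoding for a microfluidic molecular-communication
link whose receiver is a DNA-functionalised **graphene field-effect
transistor (bioFET)**. Target DNA pulses flowed over the sensor hybridise
with surface probes, gate the graphene, and lower the drain–source current;
on-off keying of the inlet concentration turns the sensor into a chemical
data receiver. The package is aimed at biosensing and molecular-communication
researchers who want the full quantitative chain — device electrostatics,
binding kinetics, link simulation, detection and parameter inference — as
tested, reusable code.

## What it computes

* **Channel & screening constants** — hydraulic diameter `4A/P`, linear
  velocity `u = u_V/A`, Reynolds number `ρuD_H/μ`, Debye length
  `λ_D ≈ 0.3/√I` nm.
* **FET transduction** — series gate capacitance
  `C_G = (1/C_Gr + 1/C_Pt + 1/C_Q)⁻¹`, screened molecular charge
  `q = n q_e e^(−r/λ_D)`, per-molecule current factor `Q = g_m q / C_G`,
  and exact count↔current conversion.
* **Binding kinetics** — Langmuir isotherm `θ = c/(c+K_D)`, exponential
  association/dissociation transients, and the closed-form
  **Lambert-W finite-pulse response** of the transport-limited
  two-compartment model

  `N(t) = N_eq (1 − W₀[α* e^(α* − β*(t−t_a))]/α*)` (association), with an
  analogous W₀ expression for dissociation — verified against an
  independent `deSolve` ODE integration to 1e−5 relative error.
* **Transmission & detection** — LTI superposition of pulse responses over
  a bit sequence, baseline normalisation, 21-s moving-mean filtering
  (centred or causal), constant-delay synchronisation, difference-based
  decoding `ŝ[i] = 1[r[i+1] − r[i] < 0]`, and bit error rate.
* **Inference** — bounded multi-start least squares recovering
  `K_D`/saturation from isotherms, `k⁺`/`k⁻` from transients, and the
  transport coefficient from pulse shapes, with optional residual
  bootstrap intervals.
* **Synthetic data** — seeded generators for staircase sensing runs,
  association/dissociation specificity runs, and 20-bit OOK transmission
  traces, whose noise-free outputs coincide exactly with the forward
  models.

## Worked example

Recover hybridisation rates from a noisy synthetic specificity run, then
simulate and decode binary transmissions:

```r
library(biofetmc)

tr <- gen_specificity_trace(kinetic_rates(1814.9, 13.538e-4), 1e-6, -1.393,
                            t_d_s = 1800, duration_s = 3600, baseline_uA = 0,
                            noise = noise_model(0.03, seed = 42))
fit_transients(tr, 1800, 1e-6, n_boot = 200, seed = 42)
#> Nonlinear least-squares fit
#>   k_on         1838.53  [1801, 1884]
#>   k_off        0.00135099  [0.001343, 0.001359]
#>   delta_i_eq   -0.797345  [-0.7994, -0.7953]
#>   k_d          7.34818e-07
#>   residual norm 1.81122

run_isi_study(seed = 1, noise = noise_model(0.02, seed = 1), k_t = 1e10)
#>   bit_interval_s  ber ber_filtered isi_depth
#> 1             60 0.30         0.05 0.9884794
#> 2            120 0.10         0.05 0.9906635
#> 3            360 0.35         0.05 0.9936389
```

The fit recovers the generating rates (`k⁺ = 1814.9 M⁻¹s⁻¹`,
`k⁻ = 1.3538e-3 s⁻¹`) within ~1–2%, with `K_D = k⁻/k⁺ ≈ 735 nM` against
the generating 746 nM. In the transmission study, `ber` is the bit error
rate of difference detection on the raw noisy signal and `ber_filtered`
after causal 21-s filtering; `isi_depth` is the minimum of the normalised
signal — it rises toward 1 as the bit interval grows because slow
dissociation (half-life ≈ 512 s) leaves less residual interference between
bits. Noiseless runs decode error-free at every interval and the device
worked constants reproduce via `reproduce_constants()`:

```r
reproduce_constants()
#>               constant     computed  printed units rel_tol pass
#> 1                   Re   0.48388072   0.4839     -   0.001 TRUE
#> 2                    u 222.22222222 220.0000  um/s   0.020 TRUE
#> ...
#> 10    K_D = k_off/k_on   0.74593642   0.7460    uM   0.001 TRUE
```

A command-line wrapper exposes the same pipeline
(`Rscript inst/cli/biofetmc.R constants|simulate|fit|detect|isi-study ...`).

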