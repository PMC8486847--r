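# Shared fixtures: the measured hybridisation kinetics of the reference
# device and a pulse model assembled in the receptor-count/current chain
# used throughout the tests.

tdna_rates <- function() kinetic_rates(k_on = 1814.9, k_off = 13.538e-4)
ntdna1_rates <- function() kinetic_rates(k_on = 355.3, k_off = 12.454e-4)
ntdna2_rates <- function() kinetic_rates(k_on = 48.9, k_off = 13.110e-4)

# Pulse model at 1 uM with the fitted equilibrium response; k_t chosen per
# test (small values put the model in the transport-influenced regime).
make_model <- function(k_t = 1e9, c_avg = 1e-6, t_a = 0, t_d = 30,
                       q = -8.3e-7, rates = tdna_rates()) {
  eq <- -1.393 * langmuir_equilibrium(c_avg, 730e-9)
  pulse_model(rates, c_avg, k_t,
              response_scale(eq, -1.393, q), t_a = t_a, t_d = t_d)
}
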