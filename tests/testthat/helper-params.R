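# small, fast parameter sets used across tests; defaults elsewhere
quick_params <- function(duration = 1000, ...) {
  clutch_params(duration = duration, ...)
}

# a stiff, effectively elastic substrate: eta so large that no relaxation
# occurs within any test window
elastic_params <- function(...) {
  clutch_params(k_l = 10, k_a = 10, eta = 1e9, ...)
}
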