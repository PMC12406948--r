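# shared fixtures: default acquisition, packaged presets, small builders

test_config <- function(...) excitation_config(...)

test_presets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_presets()
    cache
  }
})

# spectrum object built directly from numbers (bypasses the analyzer)
make_spectrum <- function(A_n, phi_n, orders = seq(3L, by = 2L,
                                                   length.out = length(A_n)),
                          floors = rep(0, length(A_n)), id = "synthetic") {
  structure(list(orders = as.integer(orders), A_n = A_n, phi_n = phi_n,
                 noise_floor_n = floors, sample_id = id,
                 config = test_config()),
            class = "mps_spectrum")
}

# physical presets used as oracle-equivalence fixtures: spanning weak to
# strong relaxation lag at 25 kHz
oracle_fixture_presets <- function() {
  list(
    particle_preset("fix_small", "physical", d_med = 8e-9, sigma_d = 0.15,
                    M_s = 3.2e5, tau = 3e-7),
    particle_preset("fix_mid", "physical", d_med = 12e-9, sigma_d = 0.20,
                    M_s = 3.0e5, tau = 1e-6),
    particle_preset("fix_large", "physical", d_med = 16e-9, sigma_d = 0.25,
                    M_s = 2.8e5, tau = 3e-6))
}
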