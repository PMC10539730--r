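# Standard scenario builders shared across the test files.

benchtop_field <- function() field_config(12.09)
highfield_field <- function() field_config(138.36)

# benchtop single-cryptophane Z-scan scenario (1 T, weak rf, 3 s)
benchtop_system <- function(r2b = 1) {
  exchange_system(
    benchtop_field(),
    free_pool(delta_ppm = 196, r1 = 0.01, r2 = 20),
    bound_pool(f = 0.04, k_out = 50, delta_ppm = 52, r1 = 0.01, r2 = r2b)
  )
}

# high-field counterpart (11.7 T, strong rf, 1 s)
highfield_system <- function(r2b = 1) {
  exchange_system(
    highfield_field(),
    free_pool(delta_ppm = 196, r1 = 0.01, r2 = 50),
    bound_pool(f = 0.04, k_out = 50, delta_ppm = 52, r1 = 0.01, r2 = r2b)
  )
}

# two-cryptophane mixture at 1 T
mixture_system <- function() {
  exchange_system(
    benchtop_field(),
    free_pool(delta_ppm = 196, r1 = 0.1, r2 = 10),
    list(
      bound_pool(f = 0.037, k_out = 50, delta_ppm = 52, r1 = 0.01, r2 = 1),
      bound_pool(f = 0.025, k_out = 100, delta_ppm = 42, r1 = 0.01, r2 = 1)
    )
  )
}

# UFZ experiment on the mixture; rf carrier midway between the pools
mixture_ufz <- function(larmor = 12.09, g_sat = 0.021, g_acq = 0.084,
                        rf_ppm = 47, omega1 = 64.7, t_sat = 3,
                        n_positions = 512, noise_sigma = 0, seed = NULL,
                        off_scale = 1) {
  field <- field_config(larmor)
  sys <- exchange_system(
    field,
    free_pool(delta_ppm = 196, r1 = 0.1, r2 = 10),
    list(
      bound_pool(f = 0.037, k_out = 50, delta_ppm = 52, r1 = 0.01, r2 = 1),
      bound_pool(f = 0.025, k_out = 100, delta_ppm = 42, r1 = 0.01, r2 = 1)
    )
  )
  ufz_experiment(
    system = sys,
    sat = saturation_scheme(omega1, rf_ppm, t_sat),
    geometry = tube_geometry(0.0043),
    gradients = gradient_scheme(g_sat, g_acq),
    n_positions = n_positions,
    noise_sigma = noise_sigma,
    off_scale = off_scale,
    rng_seed = seed
  )
}

# single-pool UFZ experiment used by the recovery studies
recovery_ufz <- function(noise_sigma = 0, seed = NULL, f = 0.037,
                         k_out = 50, omega1 = 64.7) {
  field <- field_config(12.09)
  sys <- exchange_system(
    field,
    free_pool(delta_ppm = 196, r1 = 0.1, r2 = 10),
    bound_pool(f = f, k_out = k_out, delta_ppm = 52, r1 = 0.01, r2 = 1)
  )
  ufz_experiment(
    system = sys,
    sat = saturation_scheme(omega1, 52, 3),
    geometry = tube_geometry(0.0043),
    gradients = gradient_scheme(0.021, 0.084),
    n_positions = 512,
    noise_sigma = noise_sigma,
    rng_seed = seed
  )
}
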