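test_that("chemical-shift conversions are linear, invertible and correct", {
  f1 <- benchtop_field()
  f2 <- highfield_field()
  expect_identical(ppm_to_rad(f1, 0), 0)
  # hand arithmetic: 2*pi * 12.09 * 144
  expect_equal(ppm_to_rad(f1, 144), 10938.77, tolerance = 1e-6)
  expect_equal(ppm_to_rad(f2, 1), 869.342, tolerance = 1e-5)
  x <- c(-196, 0, 42, 52, 196)
  expect_equal(rad_to_ppm(f1, ppm_to_rad(f1, x)), x)
  expect_equal(hz_to_ppm(f2, ppm_to_hz(f2, x)), x)
  expect_equal(ppm_to_hz(f1, 1), 12.09)
})

test_that("rf amplitude converts between rad/s and microtesla", {
  f <- benchtop_field()
  expect_equal(b1_to_omega1(f, omega1_to_b1(f, 64.7)), 64.7)
  # with gamma-bar = 11.79 MHz/T, 64.7 rad/s is ~0.873 uT
  expect_equal(omega1_to_b1(f, 64.7), 0.8733, tolerance = 1e-3)
})

test_that("tilt angle covers the on-resonance, no-rf and generic cases", {
  expect_equal(tilt_angle(10, 0), pi / 2)
  expect_equal(tilt_angle(0, 123), 0)
  # arctan(64.7 / 1.0939e4), checked by hand
  expect_equal(tilt_angle(64.7, 10938.77), 5.915e-3, tolerance = 1e-3)
  expect_equal(tilt_angle(5, -100), tilt_angle(5, 100))
  expect_error(tilt_angle(0, 0), "undefined")
})

test_that("direct depolarization interpolates between R1A and R2A", {
  fp <- free_pool(196, r1 = 0.01, r2 = 20)
  expect_equal(lambda_direct(fp, 0, 500), 0.01)
  expect_equal(lambda_direct(fp, 30, 0), 20)
  # benchtop conditions: weak rf 144 ppm from free xenon barely tilts the
  # effective field, but R2A is large enough to cost ~3% signal over 3 s
  lam <- lambda_direct(fp, 64.7, ppm_to_rad(benchtop_field(), 144))
  expect_equal(lam, 0.0107, tolerance = 0.01)
  expect_equal(1 - exp(-3 * lam), 0.03, tolerance = 0.08)
  # bounded between the two relaxation rates for arbitrary inputs
  set.seed(42)
  for (i in 1:25) {
    w1 <- runif(1, 0, 1000)
    d <- runif(1, -1e5, 1e5)
    if (w1 == 0 && d == 0) next
    l <- lambda_direct(fp, w1, d)
    expect_gte(l, 0.01)
    expect_lte(l, 20)
  }
})

test_that("on-resonance CEST rate rises monotonically to f * k_out", {
  b <- bound_pool(f = 0.04, k_out = 50, delta_ppm = 52)
  expect_equal(lambda_on(b, 0), 0)
  # omega1 = k_out sits exactly at half the asymptote
  expect_equal(lambda_on(b, 50), 0.04 * 50 / 2)
  expect_equal(lambda_on(b, 1e6), 0.04 * 50, tolerance = 1e-6)
  w <- seq(0, 500, by = 10)
  expect_true(all(diff(lambda_on(b, w)) > 0))
  expect_true(all(lambda_on(b, w) <= 0.04 * 50))
})

test_that("dip width power-broadens from its 2*k_out floor", {
  b <- bound_pool(0.04, 50, 52)
  expect_equal(gamma_fwhm(b, 0), 100)
  b2 <- bound_pool(0.02, 100, 42)
  expect_equal(gamma_fwhm(b2, 92.4), 2 * sqrt(92.4^2 + 100^2),
               tolerance = 1e-12)
  expect_equal(gamma_fwhm(b2, 92.4), 272.3, tolerance = 1e-3)
  expect_true(all(gamma_fwhm(b, seq(0, 300, 25)) >= 2 * 50))
})

test_that("off-resonance CEST rate is a Lorentzian with the stated peak and width", {
  fld <- benchtop_field()
  b <- bound_pool(0.04, 50, 52)
  w1 <- 64.7
  expect_equal(lambda_cest(b, fld, w1, 52), lambda_on(b, w1))
  half_ppm <- rad_to_ppm(fld, gamma_fwhm(b, w1) / 2)
  expect_equal(lambda_cest(b, fld, w1, 52 + half_ppm),
               lambda_on(b, w1) / 2)
  expect_lt(lambda_cest(b, fld, w1, 52 + 100 * half_ppm),
            lambda_on(b, w1) / 1000)
  # symmetric about the bound-pool shift
  d <- seq(0.1, 20, by = 0.7)
  expect_equal(lambda_cest(b, fld, w1, 52 + d),
               lambda_cest(b, fld, w1, 52 - d))
})

test_that("CEST Lorentzian integrates to lambda_on * pi * Gamma / 2", {
  fld <- benchtop_field()
  b <- bound_pool(0.03, 80, 52)
  w1 <- 100
  # independent quadrature over the offset axis in rad/s
  integrand <- function(om) {
    lambda_cest(b, fld, w1, rad_to_ppm(fld, om))
  }
  area <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-10,
                           subdivisions = 2000L)$value
  expect_equal(area, lambda_on(b, w1) * pi * gamma_fwhm(b, w1) / 2,
               tolerance = 1e-6)
})

test_that("total rate sums direct and per-pool CEST terms", {
  sys1 <- benchtop_system()
  sat_on_b <- saturation_scheme(64.7, 52, 3)
  b <- sys1$bound[[1]]
  # simplified (far-off-resonance) mode: R1A + lambda_on exactly on the dip
  expect_equal(lambda_total(sys1, sat_on_b, simplified = TRUE),
               0.01 + lambda_on(b, 64.7))
  # no bound pools, no rf: pure R1A
  bare <- exchange_system(sys1$field, sys1$free, list())
  expect_equal(lambda_total(bare, saturation_scheme(0, 52, 3)), 0.01)
  # multi-pool additivity: mixture equals sum of single-pool CEST parts
  mix <- mixture_system()
  offs <- seq(30, 70, by = 1)
  sat <- saturation_scheme(80, offs, 3)
  singles <- lapply(mix$bound, function(bp) {
    exchange_system(mix$field, mix$free, list(bp))
  })
  lam_mix <- lambda_total(mix, sat)
  lam_sum <- lambda_total(singles[[1]], sat) +
    lambda_total(singles[[2]], sat) -
    lambda_direct(mix$free, 80, ppm_to_rad(mix$field, offs - 196))
  expect_equal(lam_mix, lam_sum, tolerance = 1e-12)
  # one pool reduces exactly to the single-pool expression
  expect_equal(lambda_total(singles[[1]], sat),
               lambda_direct(mix$free, 80, ppm_to_rad(mix$field, offs - 196)) +
                 lambda_cest(mix$bound[[1]], mix$field, 80, offs))
})

test_that("simplified form converges to the full form far off resonance", {
  # the convergence rate scales with R2A/R1A: tested on the mixture
  # relaxation values (R1A = 0.1, R2A = 10 /s)
  sys <- exchange_system(benchtop_field(), free_pool(196, 0.1, 10),
                         bound_pool(0.04, 50, 52))
  rel_err <- function(w1, ratio) {
    off_ppm <- 196 - rad_to_ppm(sys$field, ratio * w1)
    sat <- saturation_scheme(w1, off_ppm, 3)
    full <- lambda_total(sys, sat)
    abs(full - lambda_total(sys, sat, simplified = TRUE)) / full
  }
  # |w_i - w_A| >= 100 * omega1: difference below 1 percent
  for (w1 in c(10, 64.7, 100)) {
    expect_lt(rel_err(w1, 100), 0.01)
  }
  # ratio 1e3: relative error below 1e-3, and decreasing with distance
  errs <- vapply(c(100, 300, 1000, 3000), function(r) rel_err(10, r),
                 numeric(1))
  expect_lt(errs[3], 1e-3)
  expect_true(all(diff(errs) < 0))
})

test_that("population-weighted relaxation is exposed but off by default", {
  sys <- benchtop_system(r2b = 30)
  eff <- effective_relaxation(sys)
  expect_equal(eff$r1_eff, (1 - 0.04) * 0.01 + 0.04 * 0.01)
  expect_equal(eff$r2_eff, (1 - 0.04) * 20 + 0.04 * 30)
  sat <- saturation_scheme(64.7, 52, 3)
  expect_false(isTRUE(all.equal(
    lambda_total(sys, sat, weighted_relaxation = TRUE),
    lambda_total(sys, sat)
  )))
})

test_that("Z follows the exponential saturation law", {
  sys <- benchtop_system()
  expect_equal(z_value(sys, saturation_scheme(64.7, 52, 0)), 1)
  # lambda ~ 0.0107 for 3 s costs about 3% (direct term only)
  bare <- exchange_system(sys$field, sys$free, list())
  z3 <- z_value(bare, saturation_scheme(64.7, 52, 3))
  expect_gt(z3, 0.96)
  expect_lt(z3, 0.975)
  # doubling t_sat squares the normalized value
  z1 <- z_value(sys, saturation_scheme(64.7, 52, 1.3))
  z2 <- z_value(sys, saturation_scheme(64.7, 52, 2.6))
  expect_equal(z2, z1^2, tolerance = 1e-12)
})

test_that("Z is monotone non-increasing in omega1, t_sat and f", {
  fld <- benchtop_field()
  mk <- function(f) {
    exchange_system(fld, free_pool(196, 0.01, 20),
                    bound_pool(f, 50, 52))
  }
  for (off in c(52, 60, 45)) {
    z_w <- vapply(seq(0, 300, by = 20), function(w1) {
      z_value(mk(0.04), saturation_scheme(w1, off, 3))
    }, numeric(1))
    expect_true(all(diff(z_w) <= 1e-14))
    z_t <- vapply(seq(0, 8, by = 0.5), function(ts) {
      z_value(mk(0.04), saturation_scheme(64.7, off, ts))
    }, numeric(1))
    expect_true(all(diff(z_t) < 0))
    z_f <- vapply(seq(0.005, 0.1, by = 0.005), function(f) {
      z_value(mk(f), saturation_scheme(64.7, off, 3))
    }, numeric(1))
    expect_true(all(diff(z_f) < 0))
  }
})

test_that("Z spectrum shows the dip at the cage shift and a flat no-rf baseline", {
  sys <- benchtop_system()
  offs <- seq(30, 70, by = 0.25)
  zs <- z_spectrum(sys, 64.7, 3, offs)
  expect_named(zs, c("offset_ppm", "lambda", "z", "z_norm"))
  expect_equal(zs$offset_ppm[which.min(zs$z_norm)], 52)
  flat <- z_spectrum(sys, 0, 3, offs)
  expect_equal(flat$z_norm, rep(exp(-0.01 * 3), length(offs)))
})

test_that("at weak saturation the pool with the larger f/k_out dominates", {
  mix <- mixture_system()  # pool 1: f/k = 7.4e-4; pool 2: 2.5e-4
  offs <- seq(30, 70, by = 0.1)
  zs <- z_spectrum(mix, 15, 3, offs)
  z_at <- function(ppm) zs$z_norm[which.min(abs(zs$offset_ppm - ppm))]
  depth1 <- 1 - z_at(52)
  depth2 <- 1 - z_at(42)
  expect_gt(depth1, depth2)
})
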