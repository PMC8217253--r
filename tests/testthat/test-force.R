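# Force-ramp pipeline: calibration, contact point, force-distance
# conversion, steric fitting and force-volume aggregation.

ideal_reference <- function(slope_v_per_nm = 0.05, z0 = 60, noise = 0,
                            seed = 1) {
  set.seed(seed)
  z <- seq(0, 120, length.out = 400)
  v <- pmax(0, z - z0) * slope_v_per_nm + rnorm(length(z), 0, noise)
  force_ramp(z, v)
}

test_that("deflection sensitivity is the inverse contact slope", {
  expect_equal(deflection_sensitivity(ideal_reference(0.05)), 20,
               tolerance = 1e-6)
  expect_equal(deflection_sensitivity(ideal_reference(0.05, noise = 1e-3)),
               20, tolerance = 0.02)
  flat <- force_ramp(seq(0, 100, length.out = 200),
                     rnorm(200, 0, 1e-3))
  expect_error(deflection_sensitivity(flat), "linear|R\\^2")
})

test_that("Hertz contact point is recovered from a pure contact curve", {
  z <- seq(0, 120, length.out = 500)
  z0 <- 70; b <- 0.1; k <- 0.1
  delta <- pmax(z - z0, 0)             # nm of indentation (stiff-sample limit)
  f <- b * delta^1.5
  cp <- find_contact_hertz(z, f / k + delta * 0, spring_constant = k)
  # the fit sees deflection f/k, so indentation is (z - z0) - f/k; rebuild
  # a self-consistent curve instead: parametric inversion
  d_par <- seq(0, -20, length.out = 800)
  f_par <- b * (-d_par)^1.5
  z_par <- z0 - d_par + f_par / k
  z_grid <- seq(min(z_par) - 40, max(z_par), length.out = 600)
  defl <- approx(c(min(z_grid) - 1, z_par), c(0, f_par / k), xout = z_grid)$y
  cp <- find_contact_hertz(z_grid, defl, spring_constant = k)
  expect_false(cp$flagged)
  expect_equal(cp$z0, z0, tolerance = 1e-3)
  expect_equal(cp$hertz_prefactor, b, tolerance = 1e-3)
})

test_that("contact point survives a steric tail and detector noise", {
  fv <- gen_force_volume(12, grid = c(3, 3), noise = noise_spec(seed = 42),
                         z0_jitter = 0)
  sens <- deflection_sensitivity(fv$reference)
  z0s <- vapply(fv$ramps, function(r) {
    cp <- find_contact_hertz(r$piezo_z, r$signal * sens, 0.1)
    cp$z0
  }, numeric(1))
  expect_true(all(abs(z0s - 80) < 0.5))   # generator places contact at 80 nm
})

test_that("a flat force-free curve is flagged, not fitted", {
  set.seed(8)
  cp <- find_contact_hertz(seq(1, 100), rnorm(100, 0, 0.05), 0.1)
  expect_true(cp$flagged)
})

test_that("force-distance conversion honours its sign conventions", {
  lever <- cantilever(0.1, 25)
  z <- seq(0, 100, length.out = 50)
  # zero deflection: d_ts is the gap to the contact position
  fc <- to_force_distance(force_ramp(z, rep(0, 50)), lever, z0 = 80)
  expect_true(all(fc$force == 0))
  expect_equal(fc$d_ts, 80 - z)
  # hard wall: deflection tracks the piezo beyond contact, d_ts pinned at 0
  defl <- pmax(0, z - 80)
  fc2 <- to_force_distance(force_ramp(z, defl / 25), lever, z0 = 80)
  expect_equal(fc2$d_ts[z >= 80], rep(0, sum(z >= 80)), tolerance = 1e-10)
  expect_error(to_force_distance(force_ramp(z, rep(0, 50)),
                                 cantilever(0.1, NA), 80), "sensitivity")
})

test_that("reconstructed force-distance matches the generative law", {
  fv <- gen_force_volume(10, grid = c(2, 2),
                         noise = noise_spec(detector_sigma = 0, seed = 3),
                         z0_jitter = 0)
  sens <- deflection_sensitivity(fv$reference)
  lever <- cantilever(0.1, sens)
  r <- fv$ramps[[1]]
  cp <- find_contact_hertz(r$piezo_z, r$signal * sens, 0.1)
  fc <- to_force_distance(r, lever, cp$z0)
  sel <- fc$d_ts > 2 & fc$d_ts < 50
  expect_equal(fc$force[sel], 1 * exp(-fc$d_ts[sel] / 10), tolerance = 0.01)
})

test_that("exact exponentials are fitted exactly, tails and all", {
  sf <- fit_steric(steric_curve(10, 1))
  expect_false(sf$flagged)
  expect_equal(sf$lambda_exp, 10, tolerance = 1e-6)
  expect_equal(sf$f0, 1, tolerance = 1e-6)
})

test_that("median decay length is unbiased under detector noise", {
  lams <- vapply(1:200, function(i) {
    sf <- fit_steric(steric_curve(10, 1, noise_sd = 0.02, seed = 1000 + i))
    sf$lambda_exp
  }, numeric(1))
  expect_equal(stats::median(lams, na.rm = TRUE), 10, tolerance = 0.03)
})

test_that("curves without an exponential tail are flagged unfit", {
  # pure Hertz contact, zero force off contact
  d <- seq(0.2, 60, by = 0.25)
  flat <- structure(list(d_ts = d, force = rep(0, length(d)),
                         deflection_nm = rep(0, length(d))),
                    class = "force_curve")
  expect_true(fit_steric(flat)$flagged)
  set.seed(2)
  noisy <- structure(list(d_ts = d, force = rnorm(length(d), 0, 0.005),
                          deflection_nm = rnorm(length(d), 0, 0.05)),
                     class = "force_curve")
  expect_true(fit_steric(noisy)$flagged)
})

test_that("force-volume analysis recovers decay lengths across the range", {
  for (lam in c(3, 10, 25)) {
    fv <- gen_force_volume(lam, grid = c(6, 6),
                           noise = noise_spec(seed = 100 + lam))
    res <- analyze_volume(fv$ramps, cantilever(), reference_ramp = fv$reference,
                          grid_shape = c(6, 6))
    expect_equal(unname(res$summary["median"]), lam, tolerance = 0.05)
  }
})

test_that("results are invariant to piezo offset and detector gain", {
  fv <- gen_force_volume(8, grid = c(4, 4), noise = noise_spec(seed = 55))
  res0 <- analyze_volume(fv$ramps, cantilever(), reference_ramp = fv$reference)
  shift_gain <- function(r, dz, g) force_ramp(r$piezo_z + dz, r$signal * g)
  fv2 <- list(ramps = lapply(fv$ramps, shift_gain, dz = 37.5, g = 2.5),
              reference = shift_gain(fv$reference, 37.5, 2.5))
  res2 <- analyze_volume(fv2$ramps, cantilever(), reference_ramp = fv2$reference)
  expect_equal(res2$lambda, res0$lambda, tolerance = 1e-6)
})

test_that("aggregate-like ramps are excluded without biasing the rest", {
  fv <- gen_force_volume(10, grid = c(20, 20), noise = noise_spec(seed = 77),
                         aggregate_fraction = 0.05)
  res <- analyze_volume(fv$ramps, cantilever(), reference_ramp = fv$reference)
  frac <- res$n_excluded / res$n_total
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
  expect_equal(unname(res$summary["median"]), 10, tolerance = 0.05)
})

test_that("a single ramp yields a point-mass distribution", {
  fv <- gen_force_volume(10, grid = c(1, 1), noise = noise_spec(seed = 5))
  res <- analyze_volume(fv$ramps, cantilever(), reference_ramp = fv$reference)
  expect_length(res$lambda, 1)
  expect_equal(unname(res$summary["iqr"]), 0)
})

test_that("condition ratios are antisymmetric and cover the null", {
  a <- gen_force_volume(12, grid = c(5, 5), noise = noise_spec(seed = 61))
  b <- gen_force_volume(4, grid = c(5, 5), noise = noise_spec(seed = 62))
  ra <- analyze_volume(a$ramps, cantilever(), reference_ramp = a$reference)
  rb <- analyze_volume(b$ramps, cantilever(), reference_ramp = b$reference)
  self <- condition_ratio(ra, ra, n_boot = 50, seed = 1)
  expect_equal(self$fold_change, 1)
  ab <- condition_ratio(ra, rb, n_boot = 200, seed = 2)
  ba <- condition_ratio(rb, ra, n_boot = 200, seed = 2)
  expect_equal(ab$fold_change * ba$fold_change, 1, tolerance = 1e-12)
  expect_equal(ab$fold_change, 3, tolerance = 0.1)
  # equal generative lengths: interval straddles 1
  b2 <- gen_force_volume(12, grid = c(5, 5), noise = noise_spec(seed = 63))
  rb2 <- analyze_volume(b2$ramps, cantilever(), reference_ramp = b2$reference)
  eq <- condition_ratio(ra, rb2, n_boot = 500, seed = 3)
  expect_true(eq$ci[1] <= 1 && eq$ci[2] >= 1)
})
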