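# Co-refinement and posterior sampling. Heavier recovery runs live in the
# acceptance suite; here small problems exercise correctness contracts.

make_noise_free <- function(model, contrasts, q, weight_rel = 0.02) {
  lapply(contrasts, function(ct) {
    st <- stack_from_model(model, ct)
    r <- pmin(pellifilm:::reflectivity_smeared(st, q, 0.04) + 1e-7, 1)
    contrast_measurement(q, r, dr = weight_rel * r, dq_over_q = 0.04,
                         contrast = ct)
  })
}

test_that("a fit started at the generative truth stays at the truth", {
  truth <- scenario_truth("capb")$pellicle_before
  q <- default_q_grid(40)
  meas <- make_noise_free(truth, pbs_contrasts()[c("hPBS", "dPBS")], q)
  fit <- corefine(meas, truth, seed = 1,
                  control = list(popsize = 10, maxiter = 10))
  expect_true(fit$converged)
  expect_lt(fit$chi2, 1e-8)
  expect_equal(fit$model$outer$thickness, truth$outer$thickness,
               tolerance = 1e-4)
  expect_equal(fit$model$inner$hydration, truth$inner$hydration,
               tolerance = 1e-4)
})

test_that("noise-free co-refinement recovers a perturbed start within 1%", {
  truth <- scenario_truth("capb")$pellicle_before
  q <- default_q_grid(50)
  meas <- make_noise_free(truth, pbs_contrasts(), q)
  start <- pellicle_model(
    pellicle_layer(46 * 1.3, 0.557 * 0.75, roughness = 5),
    pellicle_layer(325 * 0.7, 0.999, roughness = 8),
    salivary_sld = truth$salivary_sld, surfactant_sld = truth$surfactant_sld)
  fit <- corefine(meas, start, seed = 3, fit_roughness = FALSE,
                  control = list(popsize = 24, maxiter = 80))
  expect_true(fit$converged)
  expect_equal(fit$model$inner$thickness, 46, tolerance = 0.01)
  expect_equal(fit$model$outer$thickness, 325, tolerance = 0.01)
  expect_equal(fit$model$inner$hydration, 0.557, tolerance = 0.01)
  expect_equal(fit$model$outer$hydration, 0.975, tolerance = 0.01)
})

test_that("co-refinement is deterministic given its seed", {
  truth <- scenario_truth("c12e5")$pellicle_before
  q <- default_q_grid(30)
  meas <- gen_nr(truth, pbs_contrasts()["dPBS"], q, noise_spec(seed = 7))
  f1 <- corefine(meas, truth, seed = 11, fit_roughness = FALSE,
                 control = list(popsize = 8, maxiter = 10))
  f2 <- corefine(meas, truth, seed = 11, fit_roughness = FALSE,
                 control = list(popsize = 8, maxiter = 10))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$chi2, f2$chi2)
})

test_that("ensemble sampler reproduces an analytic Gaussian posterior", {
  lp <- function(x) -0.5 * ((x[1] - 2) / 0.3)^2 - 0.5 * ((x[2] + 1) / 2)^2
  s <- pellifilm:::with_seed(5,
    pellifilm:::stretch_sampler(lp, c(2, -1), n_walkers = 20, n_steps = 600))
  expect_gt(s$acceptance, 0.1)
  expect_lt(s$acceptance, 0.9)
  expect_equal(stats::sd(s$chain[, 1]), 0.3, tolerance = 0.1)
  expect_equal(stats::sd(s$chain[, 2]), 2.0, tolerance = 0.1)
  expect_equal(stats::median(s$chain[, 1]), 2, tolerance = 0.05)
})

test_that("posterior intervals bracket the truth and shrink with noise", {
  truth <- scenario_truth("capb")$pellicle_before
  q <- default_q_grid(35)
  fit_at <- function(rel) {
    meas <- gen_nr(truth, pbs_contrasts()[c("hPBS", "dPBS")], q,
                   noise_spec(relative_sigma = rel, seed = 9))
    fit <- corefine(meas, truth, seed = 2, fit_roughness = FALSE,
                    control = list(popsize = 10, maxiter = 15))
    posterior_sample(fit, meas, seed = 4, n_walkers = 16, n_steps = 150)
  }
  iv_hi <- fit_at(0.02)
  iv_lo <- fit_at(0.004)
  expect_true(all(iv_hi$sigma > 0))
  row <- function(iv, p) iv[iv$parameter == p, ]
  r <- row(iv_hi, "outer_thickness")
  expect_gt(325, r$lower - 3 * r$sigma)
  expect_lt(325, r$upper + 3 * r$sigma)
  # tighter data give tighter credible intervals
  expect_lt(row(iv_lo, "outer_thickness")$sigma,
            row(iv_hi, "outer_thickness")$sigma)
  expect_lt(row(iv_lo, "inner_hydration")$sigma,
            row(iv_hi, "inner_hydration")$sigma)
})

test_that("posterior sampling refuses an unconverged fit", {
  fake <- structure(list(converged = FALSE), class = "nr_fit")
  expect_error(posterior_sample(fake, list()), "converged")
})

test_that("bare-block stage recovers the oxide within 2 Angstrom", {
  q <- default_q_grid(50)
  truth_ox <- 14
  meas <- lapply(pbs_contrasts()[c("hPBS", "dPBS")], function(ct) {
    st <- data.frame(name = c("Si", "SiO2", "solvent"),
                     thickness = c(NA, truth_ox, NA),
                     sld = c(2.07, 3.47, ct$solvent_sld),
                     roughness = c(0, 3, 4))
    r <- pellifilm:::reflectivity_smeared(st, q, 0.04) + 1e-7
    set.seed(21)
    robs <- pmin(pmax(r * (1 + 0.02 * rnorm(length(q))), 1e-9), 1)
    contrast_measurement(q, robs, 0.02 * r, 0.04, ct)
  })
  bare <- fit_bare_block(meas, seed = 6)
  expect_lt(abs(bare$oxide$thickness - truth_ox), 2)
})
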