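# Forward reflectivity model against closed forms and an independent
# Parratt recursion.

si_solvent <- function(solvent_sld, rough = 0)
  data.frame(name = c("Si", "solvent"), thickness = c(NA, NA),
             sld = c(2.07, solvent_sld), roughness = c(0, rough))

test_that("single sharp interface matches the closed-form Fresnel law", {
  q <- seq(0.006, 0.4, length.out = 200)
  r <- reflectivity(si_solvent(6.36), q)
  expect_equal(r, fresnel_step(q, 2.07, 6.36), tolerance = 1e-10)
})

test_that("matched solvent gives no reflectivity", {
  q <- seq(0.01, 0.3, length.out = 50)
  r <- reflectivity(si_solvent(2.07), q)
  expect_true(all(r < 1e-20))
})

test_that("total reflection plateau ends at the critical edge", {
  qc <- critical_edge(2.07, 6.36)
  expect_equal(qc, sqrt(16 * pi * (6.36 - 2.07) * 1e-6), tolerance = 1e-12)
  expect_equal(round(qc, 5), 0.01468)
  expect_equal(critical_edge(3, 3), 0)
  expect_equal(critical_edge(2.07, -0.56), 0)   # solvent below substrate
  q_below <- seq(0.005, qc * 0.999, length.out = 40)
  expect_true(all(reflectivity(si_solvent(6.36), q_below) > 1 - 1e-9))
  q_above <- seq(qc * 1.2, 0.3, length.out = 40)
  expect_true(all(reflectivity(si_solvent(6.36), q_above) < 1))
})

test_that("transfer-matrix result equals an independent Parratt recursion", {
  q <- exp(seq(log(0.006), log(0.45), length.out = 150))
  for (seed in 1:8) {
    st <- random_stack(5, seed)
    r1 <- reflectivity(st, q)
    r2 <- parratt_reflectivity(st, q)
    expect_lt(max(abs(r1 - r2) / pmax(r2, 1e-14)), 1e-8)
  }
})

test_that("roughness strictly damps reflectivity above the critical edge", {
  qc <- critical_edge(2.07, 6.36)
  q <- seq(qc * 1.5, 0.3, length.out = 60)
  r_sharp <- reflectivity(si_solvent(6.36, 0), q)
  r_rough <- reflectivity(si_solvent(6.36, 8), q)
  expect_true(all(r_rough < r_sharp))
})

test_that("reflectivity is invariant under subdividing a uniform slab", {
  q <- seq(0.01, 0.3, length.out = 80)
  one <- data.frame(name = c("Si", "L", "solvent"),
                    thickness = c(NA, 200, NA),
                    sld = c(2.07, 4.0, 6.36), roughness = c(0, 4, 6))
  two <- data.frame(name = c("Si", "La", "Lb", "solvent"),
                    thickness = c(NA, 120, 80, NA),
                    sld = c(2.07, 4.0, 4.0, 6.36), roughness = c(0, 4, 0, 6))
  expect_equal(reflectivity(one, q), reflectivity(two, q), tolerance = 1e-10)
})

test_that("smearing is the identity at zero resolution and for constants", {
  q <- seq(0.01, 0.3, length.out = 100)
  r <- reflectivity(si_solvent(6.36), q)
  expect_identical(smear(q, r, 0), r)
  expect_equal(smear(q, rep(0.5, 100), 0.04), rep(0.5, 100), tolerance = 1e-12)
})

test_that("smearing damps Kiessig fringes at every interior extremum", {
  q <- seq(0.015, 0.25, length.out = 600)
  st <- data.frame(name = c("Si", "film", "solvent"),
                   thickness = c(NA, 300, NA),
                   sld = c(2.07, 4.3, 6.36), roughness = c(0, 0, 0))
  r <- reflectivity(st, q)
  rs <- smear(q, r, 0.04)
  lr <- log(r)
  i <- 2:(length(q) - 1)
  maxima <- i[lr[i] > lr[i - 1] & lr[i] > lr[i + 1]]
  minima <- i[lr[i] < lr[i - 1] & lr[i] < lr[i + 1]]
  # drop extrema too close to the grid edges for the convolution window
  inner <- function(ix) ix[q[ix] > 0.03 & q[ix] < 0.22]
  expect_gt(length(inner(maxima)), 3)
  expect_true(all(rs[inner(maxima)] < r[inner(maxima)]))
  expect_true(all(rs[inner(minima)] > r[inner(minima)]))
})

test_that("layer SLD composes hydration and dry-material fractions", {
  lay <- pellicle_layer(117, 0.955, salivary_fraction = 0.92,
                        surfactant_fraction = 0.08)
  # independent hand arithmetic: phi*rho_s + (1-phi)*(f_sal*2.0 + f_surf*0.36)
  by_hand <- 0.955 * 6.36 + 0.045 * (0.92 * 2.0 + 0.08 * 0.36)
  expect_equal(layer_sld(lay, 6.36, 2.0, 0.36), by_hand, tolerance = 1e-12)
  # fully solvated layer shows only solvent
  wet <- pellicle_layer(100, 1.0, salivary_fraction = 0.5,
                        surfactant_fraction = 0.5)
  expect_equal(layer_sld(wet, 6.36, 2.0, 0.36), 6.36)
  # dry pure salivary layer
  dry <- pellicle_layer(100, 0)
  expect_equal(layer_sld(dry, 6.36, 2.0, 0.36), 2.0)
})

test_that("slab stacks are contrast-invariant in structure, not SLD", {
  m <- scenario_truth("capb")$pellicle_before
  s_d <- stack_from_model(m, pbs_contrasts()$dPBS)
  s_h <- stack_from_model(m, pbs_contrasts()$hPBS)
  expect_equal(s_d$thickness, s_h$thickness)
  expect_equal(s_d$roughness, s_h$roughness)
  expect_false(any(s_d$sld[3:5] == s_h$sld[3:5]))
  # dPBS stack: SLD strictly increasing from inner layer to solvent when
  # the dry material lies below the solvent
  expect_true(all(diff(s_d$sld[3:5]) > 0))
})

test_that("zero-thickness layers drop out of the stack", {
  m <- scenario_truth("capb")$pellicle_before
  m$outer$thickness <- 0
  st <- stack_from_model(m, pbs_contrasts()$dPBS)
  expect_equal(nrow(st), 4)   # Si, SiO2, inner, solvent
})

test_that("measurement container validates its physical ranges", {
  ct <- pbs_contrasts()$dPBS
  q <- seq(0.01, 0.3, length.out = 10)
  expect_error(contrast_measurement(rev(q), runif(10, 0, 1), rep(1e-3, 10),
                                    0.04, ct), "increasing")
  expect_error(contrast_measurement(q, rep(1.5, 10), rep(1e-3, 10), 0.04, ct),
               "reflectivity")
  expect_error(contrast_measurement(q, rep(0.5, 10), rep(0, 10), 0.04, ct),
               "dr")
})
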