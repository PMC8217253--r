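## Seeded synthetic-data generators for the four techniques. Every generator
## is a pure function of (truth, spec, seed): identical calls give identical
## data. Default truths are the published two-layer pellicle fits and the
## headline scenario contrasts (surfactant collapses / spares the outer
## layer; wet vs dry removal ordering).

#' Noise specification for the generators
#'
#' @param relative_sigma relative (multiplicative) reflectivity noise
#'   (default 2%, time-of-flight counting statistics).
#' @param background reflectivity background floor (default 1e-7).
#' @param detector_sigma force-ramp detector noise, nm of deflection
#'   equivalent (default 0.05).
#' @param trace_sigma QCM-D noise: `c(f = Hz, d = 1e-6 units)` on raw
#'   overtone signals.
#' @param seed integer seed; mandatory for any stochastic call.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(relative_sigma = 0.02, background = 1e-7,
                       detector_sigma = 0.05,
                       trace_sigma = c(f = 0.2, d = 0.05), seed = 1) {
  stopifnot(relative_sigma >= 0, background >= 0, detector_sigma >= 0,
            all(trace_sigma >= 0))
  structure(list(relative_sigma = relative_sigma, background = background,
                 detector_sigma = detector_sigma, trace_sigma = trace_sigma,
                 seed = seed), class = "noise_spec")
}

#' Scenario ground truths
#'
#' The generative truths of the three surfactant scenarios. The pellicle
#' models are the published two-layer fits (thickness, hydration, dry
#' surfactant fraction per layer); steric decay lengths give the CAPB
#' scenario a ~3-fold collapse and the C12E5 scenario none; QCM-D wet
#' masses give retentions of ~0.85 (C12E5), ~0.6 (CAPB) and ~0 (SDS).
#'
#' @param scenario `"capb"`, `"c12e5"` or `"sds"`.
#' @return a list: `pellicle_before`, `pellicle_after` (NULL for sds),
#'   `surfactant_sld`, `qcmd_masses` (per-step wet mass, mg m^-2),
#'   `ellipsometry` (dry masses before/after), `lambda_before`,
#'   `lambda_after` (nm), `f0` (nN), `hertz_prefactor` (nN nm^-3/2).
#' @export
scenario_truth <- function(scenario = c("capb", "c12e5", "sds")) {
  scenario <- match.arg(scenario)
  refs <- reference_slds()
  mk <- function(t_in, h_in, s_in, t_out, h_out, s_out, surf_sld)
    pellicle_model(
      pellicle_layer(t_in, h_in, salivary_fraction = 1 - s_in,
                     surfactant_fraction = s_in, roughness = 5),
      pellicle_layer(t_out, h_out, salivary_fraction = 1 - s_out,
                     surfactant_fraction = s_out, roughness = 8),
      surfactant_sld = surf_sld)
  if (scenario == "capb") {
    before <- mk(46, 0.557, 0, 325, 0.975, 0, refs$capb)
    after  <- mk(35, 0.544, 0.006, 117, 0.955, 0.08, refs$capb)
    list(scenario = scenario, pellicle_before = before, pellicle_after = after,
         surfactant_sld = refs$capb,
         qcmd_masses = c(baseline = 0, saliva = 22, rinse1 = 20,
                         surfactant = 24, rinse2 = 12),
         ellipsometry = c(before = 4.0, after = 3.4),
         lambda_before = 12, lambda_after = 4,
         f0 = 1, hertz_prefactor = 0.1)
  } else if (scenario == "c12e5") {
    before <- mk(46, 0.620, 0, 286, 0.971, 0, refs$d_c12e5)
    after  <- mk(45, 0.701, 0.08, 277, 0.980, 0.04, refs$d_c12e5)
    list(scenario = scenario, pellicle_before = before, pellicle_after = after,
         surfactant_sld = refs$d_c12e5,
         qcmd_masses = c(baseline = 0, saliva = 22, rinse1 = 20,
                         surfactant = 23, rinse2 = 17),
         ellipsometry = c(before = 4.0, after = 3.6),
         lambda_before = 12, lambda_after = 12,
         f0 = 1, hertz_prefactor = 0.1)
  } else {
    before <- mk(46, 0.60, 0, 300, 0.973, 0, 0.3)
    list(scenario = scenario, pellicle_before = before, pellicle_after = NULL,
         surfactant_sld = 0.3,
         qcmd_masses = c(baseline = 0, saliva = 22, rinse1 = 20,
                         surfactant = 5, rinse2 = 0.05),
         ellipsometry = c(before = 4.0, after = 0.05),
         lambda_before = 12, lambda_after = NA,
         f0 = 1, hertz_prefactor = 0.1)
  }
}

#' Default reflectometry q grid
#'
#' Logarithmic grid over the measured range 0.01-0.3 Angstrom^-1.
#' @param n number of points.
#' @return numeric vector of q values.
#' @export
default_q_grid <- function(n = 90) exp(seq(log(0.01), log(0.3), length.out = n))

#' Generate synthetic multi-contrast reflectivity
#'
#' Smears the model curve at each contrast, adds the background floor and
#' multiplicative Gaussian counting noise; the `dr` column is set to the
#' generating sigma.
#'
#' @param truth a [pellicle_model()] (or `NULL` plus `stack_fun` for other
#'   structures).
#' @param contrasts list of [contrast_definition()] objects.
#' @param q q grid (default [default_q_grid()]).
#' @param noise a [noise_spec()] (its `seed` drives the noise).
#' @param dq_over_q relative resolution (default 4%).
#' @return list of [contrast_measurement()] objects.
#' @export
gen_nr <- function(truth, contrasts, q = default_q_grid(),
                   noise = noise_spec(), dq_over_q = 0.04) {
  with_seed(noise$seed, {
    lapply(contrasts, function(ct) {
      st <- stack_from_model(truth, ct)
      r <- reflectivity_smeared(st, q, dq_over_q) + noise$background
      sigma <- pmax(noise$relative_sigma * r, 1e-12)
      r_obs <- r * (1 + noise$relative_sigma * stats::rnorm(length(q)))
      r_obs <- pmin(pmax(r_obs, noise$background / 10), 1)
      contrast_measurement(q, r_obs, dr = sigma, dq_over_q = dq_over_q,
                           contrast = ct)
    })
  })
}

#' Generate a stepwise QCM-D trace
#'
#' Per step the film relaxes exponentially (time constant `kinetics_tau`)
#' from its previous state to the step's target wet mass; overtone signals
#' come from the Voigt forward model plus Gaussian noise. Step annotations
#' are embedded in the trace.
#'
#' @param step_masses named vector of target wet areal masses per step
#'   (mg m^-2), in schedule order (e.g. baseline, saliva, rinse1,
#'   surfactant, rinse2).
#' @param durations step durations in seconds (recycled if length 1).
#' @param kinetics_tau relaxation time constant, s (default 300).
#' @param noise a [noise_spec()].
#' @param crystal,bulk sensor and liquid constants.
#' @param density,viscosity,shear_modulus film properties (density fixed at
#'   1080 kg m^-3 in the pellicle analyses).
#' @param dt sampling interval, s.
#' @param overtones overtone set.
#' @return a [qcmd_trace()].
#' @export
gen_qcmd <- function(step_masses, durations = 3600, kinetics_tau = 300,
                     noise = noise_spec(), crystal = quartz_crystal(),
                     bulk = bulk_liquid(), density = 1080,
                     viscosity = 3e-3, shear_modulus = 1e5, dt = 10,
                     overtones = c(3, 5, 7)) {
  n_steps <- length(step_masses)
  durations <- rep_len(durations, n_steps)
  starts <- cumsum(c(0, durations[-n_steps]))
  t_end <- sum(durations)
  time <- seq(0, t_end - dt, by = dt)
  # wet mass trajectory: exponential relaxation toward each step target
  mass <- numeric(length(time))
  m_prev <- step_masses[1]
  for (i in seq_len(n_steps)) {
    sel <- time >= starts[i] & time < starts[i] + durations[i]
    tt <- time[sel] - starts[i]
    m0 <- if (i == 1) step_masses[1] else mass_end
    mass[sel] <- step_masses[i] + (m0 - step_masses[i]) * exp(-tt / kinetics_tau)
    mass_end <- step_masses[i] + (m0 - step_masses[i]) *
      exp(-durations[i] / kinetics_tau)
  }
  h <- mass * 1e-6 / density                       # mg/m2 [=1e-6 kg/m2] -> m
  film <- viscoelastic_film(h, density, viscosity, shear_modulus)
  df <- dd <- matrix(0, length(time), length(overtones))
  for (k in seq_along(overtones)) {
    r <- voigt_response(film, bulk, crystal, overtones[k])
    df[, k] <- r$df
    dd[, k] <- r$dd
  }
  with_seed(noise$seed, {
    df <- df + stats::rnorm(length(df), 0, noise$trace_sigma["f"])
    dd <- dd + stats::rnorm(length(dd), 0, noise$trace_sigma["d"])
  })
  qcmd_trace(time, df, dd, overtones = overtones,
             steps = data.frame(label = names(step_masses), start = starts,
                                stringsAsFactors = FALSE))
}

## ground-truth total force (nN) at tip-sample distance d (nm):
## exponential steric tail off contact, offset Hertz in contact
fv_truth_force <- function(d, f0, lambda, hertz_b) {
  ifelse(d > 0,
         if (is.finite(lambda) && f0 > 0) f0 * exp(-d / lambda) else 0,
         (if (is.finite(lambda) && f0 > 0) f0 else 0) + hertz_b * (-d)^1.5)
}

## one synthetic approach ramp: parametric in d, interpolated to a uniform
## piezo grid, inverted through the cantilever model
gen_ramp <- function(z0, f0, lambda, hertz_b, k, sens, sigma_nm,
                     d_max = 60, delta_max = 16, n_points = 350) {
  d_par <- seq(d_max, -delta_max, length.out = 2000)
  f_par <- fv_truth_force(d_par, f0, lambda, hertz_b)
  defl_par <- f_par / k                          # nm
  z_par <- z0 - d_par + defl_par                 # piezo position
  z_grid <- seq(min(z_par), max(z_par), length.out = n_points)
  defl <- stats::approx(z_par, defl_par, xout = z_grid)$y
  signal <- (defl + stats::rnorm(n_points, 0, sigma_nm)) / sens
  force_ramp(z_grid, signal)
}

#' Generate a synthetic force-volume dataset
#'
#' Grid of approach ramps with exponential steric tails and offset-Hertz
#' contact, inverted through the cantilever model to (piezo, detector
#' signal) with detector noise and per-ramp contact-position jitter, plus a
#' rigid (hard-wall) reference ramp for calibration. An optional fraction
#' of "aggregate" ramps has no steric tail and a stiffer contact.
#'
#' @param lambda steric decay length, nm.
#' @param f0 exponential amplitude, nN.
#' @param hertz_prefactor Hertz prefactor B, nN nm^-3/2.
#' @param grid `c(rows, cols)` (default 64 x 64).
#' @param cantilever a [cantilever()]; its sensitivity field is the true
#'   generative sensitivity (default 25 nm/V when `NA`).
#' @param noise a [noise_spec()] (detector_sigma in nm equivalent).
#' @param z0_jitter SD of the per-ramp contact position, nm (default 2).
#' @param aggregate_fraction fraction of tail-free stiff ramps.
#' @return list `ramps` (list of [force_ramp()]), `reference`
#'   ([force_ramp()]), `grid_shape`, `truth` (the generative parameters).
#' @export
gen_force_volume <- function(lambda, f0 = 1, hertz_prefactor = 0.1,
                             grid = c(64, 64), cantilever = NULL,
                             noise = noise_spec(), z0_jitter = 2,
                             aggregate_fraction = 0) {
  if (is.null(cantilever)) cantilever <- pellifilm::cantilever()
  sens <- cantilever$deflection_sensitivity
  if (is.na(sens)) sens <- 25
  k <- cantilever$spring_constant
  n <- prod(grid)
  with_seed(noise$seed, {
    z0s <- 80 + stats::rnorm(n, 0, z0_jitter)
    is_agg <- stats::runif(n) < aggregate_fraction
    ramps <- lapply(seq_len(n), function(i) {
      if (is_agg[i])
        gen_ramp(z0s[i], 0, NA, hertz_prefactor * 5, k, sens,
                 noise$detector_sigma)
      else
        gen_ramp(z0s[i], f0, lambda, hertz_prefactor, k, sens,
                 noise$detector_sigma)
    })
    # rigid reference: hard wall, deflection follows piezo beyond contact
    z_ref <- seq(0, 120, length.out = 400)
    defl_ref <- pmax(0, z_ref - 70)
    ref <- force_ramp(z_ref, (defl_ref +
      stats::rnorm(length(z_ref), 0, noise$detector_sigma)) / sens)
    list(ramps = ramps, reference = ref, grid_shape = grid,
         truth = list(lambda = lambda, f0 = f0,
                      hertz_prefactor = hertz_prefactor, sensitivity = sens,
                      aggregate_fraction = aggregate_fraction))
  })
}

#' Generate a synthetic ellipsometry series
#'
#' Adds Gaussian noise to a ground-truth `(n_f, d_f)` film-growth series;
#' in raw mode, emits `(psi, delta)` via the forward model plus angular
#' noise.
#'
#' @param truth data frame `time`, `n_f`, `d_f` (nm).
#' @param noise a [noise_spec()].
#' @param sigma_n,sigma_d noise SDs on index and thickness (nm).
#' @param mode `"nf-df"` or `"psi-delta"`.
#' @param known an [optical_stack()] for raw mode.
#' @param sigma_angle angular noise SD, degrees (raw mode).
#' @return data frame `time, n_f, d_f` or `time, psi, delta`.
#' @export
gen_ellipsometry <- function(truth, noise = noise_spec(), sigma_n = 1e-3,
                             sigma_d = 0.2, mode = c("nf-df", "psi-delta"),
                             known = optical_stack(), sigma_angle = 0.01) {
  mode <- match.arg(mode)
  stopifnot(all(c("time", "n_f", "d_f") %in% names(truth)))
  with_seed(noise$seed, {
    if (mode == "nf-df") {
      data.frame(time = truth$time,
                 n_f = truth$n_f + stats::rnorm(nrow(truth), 0, sigma_n),
                 d_f = pmax(0, truth$d_f +
                              stats::rnorm(nrow(truth), 0, sigma_d)))
    } else {
      pd <- t(vapply(seq_len(nrow(truth)), function(i) {
        st <- optical_stack(known$ambient_index, truth$n_f[i], truth$d_f[i],
                            known$oxide_index, known$oxide_thickness_nm,
                            known$substrate_index)
        psi_delta(st)
      }, numeric(2)))
      data.frame(time = truth$time,
                 psi = pd[, 1] + stats::rnorm(nrow(truth), 0, sigma_angle),
                 delta = pd[, 2] + stats::rnorm(nrow(truth), 0, sigma_angle))
    }
  })
}
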