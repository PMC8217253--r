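## QCM-D: single Voigt viscoelastic film under a semi-infinite Newtonian
## liquid, via the small-load approximation with exact acoustic impedances.
## Raw (unnormalised) frequency shifts in Hz internally; dissipation in
## units of 1e-6. The on-disk CSV convention is overtone-normalised df.

#' Quartz crystal sensor constants
#'
#' @param fundamental_frequency Hz (default 5 MHz, Q-Sense type).
#' @param shear_impedance acoustic shear impedance of AT-cut quartz,
#'   kg m^-2 s^-1 (default 8.8e6).
#' @return an object of class `quartz_crystal`.
#' @export
quartz_crystal <- function(fundamental_frequency = 5e6,
                           shear_impedance = 8.8e6) {
  stopifnot(fundamental_frequency > 0, shear_impedance > 0)
  structure(list(f0 = fundamental_frequency, zq = shear_impedance),
            class = "quartz_crystal")
}

#' Newtonian bulk liquid
#'
#' @param density kg m^-3 (default water at 25 C).
#' @param viscosity Pa s (default 8.9e-4).
#' @return an object of class `bulk_liquid`.
#' @export
bulk_liquid <- function(density = 1000, viscosity = 8.9e-4) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "bulk_liquid")
}

#' Voigt viscoelastic film
#'
#' @param thickness m.
#' @param density kg m^-3 (1080 for pellicle fits).
#' @param viscosity Pa s.
#' @param shear_modulus Pa.
#' @return an object of class `viscoelastic_film`.
#' @export
viscoelastic_film <- function(thickness, density = 1080, viscosity = 3e-3,
                              shear_modulus = 1e5) {
  stopifnot(thickness >= 0, density >= 0, viscosity >= 0, shear_modulus >= 0)
  structure(list(thickness = thickness, density = density,
                 viscosity = viscosity, shear_modulus = shear_modulus),
            class = "viscoelastic_film")
}

#' Voigt film response of a QCM-D overtone
#'
#' Frequency and dissipation shift of a single viscoelastic film (complex
#' shear modulus \eqn{\mu + i\omega\eta}) loaded by a semi-infinite
#' Newtonian liquid, relative to the bare crystal in the same liquid
#' (so thickness 0 returns exactly (0, 0)). Small-load approximation with
#' the exact transmission-line load impedance.
#'
#' @param film a [viscoelastic_film()] (thickness may be a vector).
#' @param bulk a [bulk_liquid()].
#' @param crystal a [quartz_crystal()].
#' @param overtone odd positive integer (3, 5, 7 in these experiments).
#' @return list with `df` (raw Hz, negative for loading) and `dd`
#'   (dissipation in 1e-6 units), each the length of `film$thickness`.
#' @export
voigt_response <- function(film, bulk, crystal, overtone) {
  stopifnot(overtone %% 2 == 1, overtone > 0)
  h <- film$thickness
  w <- 2 * pi * overtone * crystal$f0
  g_star <- film$shear_modulus + 1i * w * film$viscosity
  z_liq <- sqrt(1i * w * bulk$density * bulk$viscosity)
  res <- vapply(h, function(hi) {
    if (hi <= 0 || film$density <= 0) return(c(0, 0))
    z_f <- sqrt(as.complex(film$density * g_star))
    gamma <- 1i * w * sqrt(as.complex(film$density / g_star))
    ch <- cosh(gamma * hi); sh <- sinh(gamma * hi)
    z_load <- z_f * (z_liq * ch + z_f * sh) / (z_f * ch + z_liq * sh)
    dfc <- 1i * crystal$f0 / (pi * crystal$zq) * (z_load - z_liq)
    c(Re(dfc), 2 * Im(dfc) / (overtone * crystal$f0) * 1e6)
  }, numeric(2))
  list(df = res[1, ], dd = res[2, ])
}

#' Sauerbrey areal mass
#'
#' Rigid-film limit: \eqn{m = -Z_q/(2 f_0^2) \cdot \Delta f/n}.
#'
#' @param df frequency shift in Hz; raw by default.
#' @param overtone odd overtone number.
#' @param crystal a [quartz_crystal()].
#' @param normalized is `df` already overtone-normalised (df_raw/n)?
#' @return areal mass in mg m^-2.
#' @export
sauerbrey_mass <- function(df, overtone, crystal = quartz_crystal(),
                           normalized = FALSE) {
  stopifnot(overtone %% 2 == 1)
  dfn <- if (normalized) df else df / overtone
  -crystal$zq / (2 * crystal$f0^2) * dfn * 1e6
}

#' QCM-D time trace container
#'
#' @param time seconds, strictly increasing.
#' @param df matrix of raw frequency shifts (Hz), one column per overtone.
#' @param dd matrix of dissipation shifts (1e-6 units), same shape.
#' @param overtones integer vector naming the columns (e.g. `c(3, 5, 7)`).
#' @param steps data frame `label`, `start` (s) of the flow schedule.
#' @return an object of class `qcmd_trace`.
#' @export
qcmd_trace <- function(time, df, dd, overtones = c(3, 5, 7), steps = NULL) {
  df <- as.matrix(df); dd <- as.matrix(dd)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (length(overtones) == 0) stop("overtone set must be non-empty", call. = FALSE)
  stopifnot(ncol(df) == length(overtones), ncol(dd) == length(overtones),
            nrow(df) == length(time), nrow(dd) == length(time))
  colnames(df) <- paste0("f", overtones)
  colnames(dd) <- paste0("d", overtones)
  structure(list(time = time, df = df, dd = dd, overtones = overtones,
                 steps = steps), class = "qcmd_trace")
}

#' Segment a QCM-D trace into flow steps and extract plateau means
#'
#' For each step of the schedule, returns the mean of every signal over the
#' final plateau window (last `plateau_fraction` of the step).
#'
#' @param trace a [qcmd_trace()] with step annotations.
#' @param schedule character vector of required step labels, in order.
#' @param plateau_fraction fraction of each step used as the plateau
#'   (default 0.1, the final tenth).
#' @return data frame: one row per step with `label`, `start`, `end`,
#'   plateau means of each df/dd column.
#' @export
segment_steps <- function(trace, schedule = NULL, plateau_fraction = 0.1) {
  steps <- trace$steps
  if (is.null(steps) || nrow(steps) == 0)
    stop("trace carries no step annotations", call. = FALSE)
  if (!is.null(schedule)) {
    missing <- setdiff(schedule, steps$label)
    if (length(missing))
      stop("missing step annotation(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    steps <- steps[match(schedule, steps$label), , drop = FALSE]
  }
  ends <- c(steps$start[-1], max(trace$time) + 1e-9)
  out <- lapply(seq_len(nrow(steps)), function(i) {
    t0 <- steps$start[i]; t1 <- ends[i]
    p0 <- t1 - plateau_fraction * (t1 - t0)
    sel <- trace$time >= p0 & trace$time < t1
    if (sum(sel) < 2)
      stop(sprintf("step '%s' too short for the plateau window", steps$label[i]),
           call. = FALSE)
    c(start = t0, end = t1,
      colMeans(trace$df[sel, , drop = FALSE]),
      colMeans(trace$dd[sel, , drop = FALSE]))
  })
  res <- as.data.frame(do.call(rbind, out))
  cbind(label = steps$label, res)
}

## residuals of a Voigt model against one time point's overtone data,
## on log10(h, eta, mu); weights: sigma_f Hz on df, sigma_d (1e-6) on dd
voigt_resid <- function(lp, df_obs, dd_obs, overtones, bulk, crystal,
                        density, sigma_f = 0.2, sigma_d = 0.05) {
  film <- viscoelastic_film(10^lp[1], density, 10^lp[2], 10^lp[3])
  unlist(lapply(seq_along(overtones), function(k) {
    r <- voigt_response(film, bulk, crystal, overtones[k])
    c((r$df - df_obs[k]) / sigma_f, (r$dd - dd_obs[k]) / sigma_d)
  }))
}

#' Fit a Voigt film to a QCM-D trace
#'
#' Per (decimated) time point, least-squares fit of thickness, viscosity and
#' shear modulus across all overtones' frequency and dissipation shifts,
#' with the film density fixed. Five seeded multi-starts per point guard
#' against the known viscosity/modulus degeneracy; areal mass is
#' density x thickness.
#'
#' @param trace a [qcmd_trace()].
#' @param window `c(t0, t1)` seconds; default the whole trace.
#' @param bulk,crystal liquid and sensor constants.
#' @param fixed_density film density, kg m^-3 (1080 for pellicles).
#' @param bounds list with `thickness`, `viscosity`, `shear_modulus`
#'   `c(lower, upper)` entries (SI units).
#' @param seed integer seed (multi-start draws).
#' @param max_fits decimate so at most this many points are fitted.
#' @param sigma_f,sigma_d residual weights: instrument noise on raw df (Hz)
#'   and dd (1e-6); points with all signals below 3x these are reported as
#'   film-free (a film acoustically matching the bulk liquid is not
#'   detectable).
#' @return data frame: `time`, `thickness` (m), `viscosity`, `shear_modulus`,
#'   `areal_mass` (mg m^-2), `chi2`, `converged`.
#' @export
fit_voigt <- function(trace, window = NULL, bulk = bulk_liquid(),
                      crystal = quartz_crystal(), fixed_density = 1080,
                      bounds = list(thickness = c(1e-10, 1e-6),
                                    viscosity = c(5e-4, 0.05),
                                    shear_modulus = c(1e2, 1e9)),
                      seed = 1, max_fits = 500, sigma_f = 0.2,
                      sigma_d = 0.05) {
  stopifnot(fixed_density > 0, length(trace$overtones) >= 2)
  idx <- seq_along(trace$time)
  if (!is.null(window))
    idx <- idx[trace$time >= window[1] & trace$time <= window[2]]
  if (length(idx) > max_fits)
    idx <- idx[unique(round(seq(1, length(idx), length.out = max_fits)))]
  lb <- log10(vapply(bounds, `[`, numeric(1), 1))
  ub <- log10(vapply(bounds, `[`, numeric(1), 2))
  with_seed(seed, {
    starts <- rbind(
      (lb + ub) / 2,
      t(replicate(4, stats::runif(3, lb, ub))))
    rows <- lapply(idx, function(i) {
      df_i <- trace$df[i, ]; dd_i <- trace$dd[i, ]
      # no detectable load: report a film-free point
      if (all(abs(df_i) < 3 * sigma_f) && all(abs(dd_i) < 3 * sigma_d))
        return(data.frame(time = trace$time[i], thickness = 0,
                          viscosity = NA, shear_modulus = NA,
                          areal_mass = 0, chi2 = 0, converged = TRUE))
      best <- NULL
      for (s in seq_len(nrow(starts))) {
        fit <- try(minpack.lm::nls.lm(
          par = starts[s, ], lower = lb, upper = ub,
          fn = voigt_resid, df_obs = df_i, dd_obs = dd_i,
          overtones = trace$overtones, bulk = bulk, crystal = crystal,
          density = fixed_density, sigma_f = sigma_f, sigma_d = sigma_d,
          control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
        if (inherits(fit, "try-error")) next
        c2 <- sum(fit$fvec^2)
        if (is.null(best) || c2 < best$c2 - 1e-9 ||
            (abs(c2 - best$c2) <= 1e-9 && fit$par[1] < best$par[1]))
          best <- list(par = fit$par, c2 = c2, ok = fit$info %in% 1:4)
      }
      if (is.null(best))
        return(data.frame(time = trace$time[i], thickness = NA,
                          viscosity = NA, shear_modulus = NA,
                          areal_mass = NA, chi2 = NA, converged = FALSE))
      h <- 10^best$par[1]
      data.frame(time = trace$time[i], thickness = h,
                 viscosity = 10^best$par[2], shear_modulus = 10^best$par[3],
                 areal_mass = fixed_density * h * 1e6,  # kg/m2 -> mg/m2
                 chi2 = best$c2, converged = best$ok)
    })
    do.call(rbind, rows)
  })
}

#' Mass retention ratio
#'
#' Fraction of the film mass remaining after a treatment:
#' `mass_after / mass_before`.
#'
#' @param mass_before,mass_after areal masses (mg m^-2); `mass_before` must
#'   be positive.
#' @return the retained fraction.
#' @export
retention_ratio <- function(mass_before, mass_after) {
  if (any(mass_before <= 0))
    stop("mass_before must be positive", call. = FALSE)
  mass_after / mass_before
}
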