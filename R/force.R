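## AFM force-ramp pipeline: detector calibration on a rigid reference,
## Hertz sphere-plane contact-point determination, conversion to force vs
## tip-sample distance, exponential steric fitting and force-volume
## aggregation. Approach curves only.
##
## Conventions: piezo_z (nm) increases as the sample approaches the tip;
## deflection is positive for repulsive bending; the tip-sample distance is
## d_ts = (z0 - piezo_z) + deflection, so d_ts >= 0 off contact and ~0 in
## hard contact.

#' A single force ramp
#'
#' @param piezo_z piezo (sample) position grid in nm, monotone increasing
#'   toward contact.
#' @param signal photodetector signal in V.
#' @param direction only `"approach"` ramps are analysed.
#' @return an object of class `force_ramp`.
#' @export
force_ramp <- function(piezo_z, signal, direction = "approach") {
  stopifnot(length(piezo_z) == length(signal))
  if (any(diff(piezo_z) <= 0))
    stop("piezo_z must be strictly monotone", call. = FALSE)
  structure(list(piezo_z = piezo_z, signal = signal, direction = direction),
            class = "force_ramp")
}

#' Cantilever parameters
#'
#' @param spring_constant N m^-1 (nominal 0.1 for these levers; an input,
#'   calibrated externally).
#' @param deflection_sensitivity nm V^-1, from [deflection_sensitivity()].
#' @return an object of class `cantilever`.
#' @export
cantilever <- function(spring_constant = 0.1, deflection_sensitivity = NA) {
  stopifnot(spring_constant > 0)
  if (!is.na(deflection_sensitivity) && deflection_sensitivity <= 0)
    stop("deflection_sensitivity must be positive", call. = FALSE)
  structure(list(spring_constant = spring_constant,
                 deflection_sensitivity = deflection_sensitivity),
            class = "cantilever")
}

#' Detector sensitivity from a rigid reference ramp
#'
#' Finds the maximal-R^2 linear segment (at least `min_fraction` of the
#' samples) of detector signal vs piezo position on a hard surface; the
#' sensitivity is the inverse slope (nm/V).
#'
#' @param reference_ramp a [force_ramp()] on a rigid substrate (mica).
#' @param min_fraction minimum segment length as a fraction of the ramp.
#' @param r2_min reject the calibration below this R^2.
#' @return sensitivity in nm V^-1.
#' @export
deflection_sensitivity <- function(reference_ramp, min_fraction = 0.2,
                                   r2_min = 0.99) {
  z <- reference_ramp$piezo_z
  v <- reference_ramp$signal
  n <- length(z)
  w <- max(8L, ceiling(min_fraction * n))
  # O(n) sliding regressions via cumulative sums
  cz <- cumsum(z); cv <- cumsum(v)
  czz <- cumsum(z^2); cvv <- cumsum(v^2); czv <- cumsum(z * v)
  win_stat <- function(i) {  # window [i, i+w-1]
    j <- i + w - 1L
    sz <- cz[j] - ifelse(i > 1, cz[i - 1], 0)
    sv <- cv[j] - ifelse(i > 1, cv[i - 1], 0)
    szz <- czz[j] - ifelse(i > 1, czz[i - 1], 0)
    svv <- cvv[j] - ifelse(i > 1, cvv[i - 1], 0)
    szv <- czv[j] - ifelse(i > 1, czv[i - 1], 0)
    sxx <- szz - sz^2 / w; syy <- svv - sv^2 / w; sxy <- szv - sz * sv / w
    if (sxx <= 0 || syy <= 1e-12) return(c(NA, NA))
    slope <- sxy / sxx
    r2 <- sxy^2 / (sxx * syy)
    c(slope, r2)
  }
  stats_mat <- vapply(seq_len(n - w + 1L), win_stat, numeric(2))
  # require a rising (contact) segment
  ok <- which(is.finite(stats_mat[2, ]) & stats_mat[1, ] > 0)
  if (!length(ok))
    stop("no linear contact region found in the reference ramp", call. = FALSE)
  best <- ok[which.max(stats_mat[2, ok])]
  if (stats_mat[2, best] < r2_min)
    stop(sprintf("best linear segment has R^2 = %.4f < %.2f",
                 stats_mat[2, best], r2_min), call. = FALSE)
  1 / stats_mat[1, best]
}

#' Hertz contact-point determination
#'
#' Fits the contact region of a deflection-converted approach curve with
#' the sphere-plane Hertz law \eqn{F = F_c + B\,\delta^{3/2}} (indentation
#' \eqn{\delta} beyond the contact position `z0`; the constant offset
#' absorbs any force already acting at contact). The window is data with
#' force above 5x the noise floor, iterated once after the first `z0`
#' estimate. `z0` becomes the distance origin of the ramp.
#'
#' @param piezo_z piezo positions, nm (increasing toward contact).
#' @param deflection_nm calibrated deflection, nm.
#' @param spring_constant N m^-1 (= nN/nm).
#' @param quality_min minimum R^2 of the Hertz fit; below it the ramp is
#'   flagged.
#' @return list `z0` (nm), `hertz_prefactor` (nN nm^-3/2), `offset` (nN),
#'   `quality` (R^2), `flagged`.
#' @export
find_contact_hertz <- function(piezo_z, deflection_nm, spring_constant = 0.1,
                               quality_min = 0.95) {
  force_nn <- spring_constant * deflection_nm
  n <- length(piezo_z)
  noise <- stats::sd(force_nn[seq_len(max(5L, floor(0.15 * n)))])
  thresh <- 5 * max(noise, 1e-6)
  if (max(force_nn) < max(10 * thresh, 20 * max(noise, 1e-6)))
    return(list(z0 = NA, hertz_prefactor = NA, offset = NA,
                quality = 0, flagged = TRUE))
  fit_once <- function(sel) {
    z_w <- piezo_z[sel]; f_w <- force_nn[sel]; defl_w <- deflection_nm[sel]
    n_w <- length(f_w)
    big <- sum(f_w^2)
    # closed-form least squares of f = c0 + b * max(delta,0)^{3/2}
    ls_fit <- function(z0) {
      x <- pmax((z_w - z0) - defl_w, 0)^1.5
      sx <- sum(x); sxx <- sum(x^2) - sx^2 / n_w
      if (sum(x > 0) < 3 || sxx < 1e-9) return(NULL)
      sy <- sum(f_w); sxy <- sum(x * f_w) - sx * sy / n_w
      syy <- sum(f_w^2) - sy^2 / n_w
      b <- sxy / sxx
      list(b = b, c0 = (sy - b * sx) / n_w,
           rss = max(syy - b * sxy, 0), syy = syy)
    }
    ssq <- function(z0) {
      f <- ls_fit(z0)
      if (is.null(f) || !is.finite(f$rss)) big else f$rss
    }
    # contact position precedes the fit window in tip-sample terms:
    # scan candidates from well before the window to its far end
    cand <- seq(min(z_w) - max(defl_w) - 10, max(z_w), by = 0.5)
    vals <- vapply(cand, ssq, numeric(1))
    z0g <- cand[which.min(vals)]
    opt <- stats::optimize(ssq, c(z0g - 1, z0g + 1))
    z0 <- opt$minimum
    f <- ls_fit(z0)
    if (is.null(f)) return(list(z0 = z0, b = NA, c0 = NA, r2 = NA))
    list(z0 = z0, b = f$b, c0 = f$c0, r2 = 1 - f$rss / max(f$syy, 1e-12))
  }
  # first pass on the Hertz-dominated high-force end of the ramp
  sel1 <- force_nn > max(thresh, 0.3 * max(force_nn))
  if (sum(sel1) < 10)
    return(list(z0 = NA, hertz_prefactor = NA, offset = NA,
                quality = 0, flagged = TRUE))
  f1 <- fit_once(sel1)
  # second pass: restrict to genuinely indented points (delta > 1 nm)
  delta_all <- (piezo_z - f1$z0) - deflection_nm
  sel2 <- delta_all > 1 & force_nn > thresh
  f2 <- if (sum(sel2) >= 10) fit_once(sel2) else f1
  flagged <- !is.finite(f2$r2) || f2$r2 < quality_min ||
    !is.finite(f2$b) || f2$b <= 0
  list(z0 = unname(f2$z0), hertz_prefactor = unname(f2$b),
       offset = unname(f2$c0), quality = unname(f2$r2), flagged = flagged)
}

#' Convert a calibrated ramp to force vs tip-sample distance
#'
#' @param ramp a [force_ramp()].
#' @param cantilever a [cantilever()] with a calibrated sensitivity.
#' @param z0 contact position (nm) from [find_contact_hertz()].
#' @return an object of class `force_curve`: list `d_ts` (nm), `force` (nN),
#'   `deflection_nm`.
#' @export
to_force_distance <- function(ramp, cantilever, z0) {
  if (is.na(cantilever$deflection_sensitivity))
    stop("cantilever has no calibrated deflection sensitivity", call. = FALSE)
  defl <- ramp$signal * cantilever$deflection_sensitivity
  force <- cantilever$spring_constant * defl          # nN (N/m * nm)
  d_ts <- (z0 - ramp$piezo_z) + defl
  structure(list(d_ts = d_ts, force = force, deflection_nm = defl),
            class = "force_curve")
}

#' Exponential steric fit of the non-contact region
#'
#' Fits \eqn{F = F_0 \exp(-d_{ts}/\lambda_{exp})} to the region
#' `d_ts > d_min` (default 5 nm) by log-linear initialisation and
#' Levenberg-Marquardt polish.
#'
#' @param curve a [force_curve()].
#' @param d_min lower edge of the fit window, nm.
#' @param min_points minimum samples required in the window.
#' @return an object of class `steric_fit`: `f0` (nN), `lambda_exp` (nm),
#'   `fit_window`, `rms_residual`, `flagged`.
#' @export
fit_steric <- function(curve, d_min = 5, min_points = 20) {
  sel <- curve$d_ts > d_min & is.finite(curve$force)
  d <- curve$d_ts[sel]; f <- curve$force[sel]
  bad <- list(f0 = NA, lambda_exp = NA, fit_window = c(d_min, NA),
              rms_residual = NA, flagged = TRUE)
  class(bad) <- "steric_fit"
  if (sum(sel) < min_points) return(bad)
  pos <- f > 0
  if (mean(pos) < 0.5) return(bad)
  noise <- stats::sd(f[d > stats::quantile(d, 0.8)])
  # log-linear initialisation on clearly positive forces
  lin <- pos & f > 2 * max(noise, 1e-6)
  if (sum(lin) < 10) return(bad)
  cf <- unname(stats::coef(stats::lm(log(f[lin]) ~ d[lin])))
  if (!is.finite(cf[2]) || cf[2] >= 0) return(bad)
  lam0 <- -1 / cf[2]; f00 <- exp(cf[1])
  fit <- try(minpack.lm::nls.lm(
    par = c(log(f00), log(lam0)),
    fn = function(p) exp(p[1]) * exp(-d / exp(p[2])) - f,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(bad)
  f0 <- exp(fit$par[1]); lam <- exp(fit$par[2])
  if (!is.finite(lam) || lam <= 0 || lam > 10 * diff(range(d))) return(bad)
  structure(list(f0 = f0, lambda_exp = lam,
                 fit_window = c(d_min, max(d)),
                 rms_residual = sqrt(mean(fit$fvec^2)), flagged = FALSE),
            class = "steric_fit")
}

#' Full force-volume analysis
#'
#' Runs calibration, Hertz contact-point search, force-distance conversion
#' and steric fitting over a grid of ramps, and aggregates the accepted
#' decay lengths into a normalised distribution.
#'
#' @param ramps list of [force_ramp()] objects.
#' @param cantilever a [cantilever()]; if its sensitivity is `NA`,
#'   `reference_ramp` must be supplied.
#' @param reference_ramp optional rigid-reference [force_ramp()] used to
#'   calibrate the sensitivity.
#' @param d_min steric fit window lower edge, nm.
#' @param grid_shape optional `c(rows, cols)` bookkeeping.
#' @return an object of class `fv_result`: per-ramp `fits`, accepted
#'   `lambda` vector, `histogram` (Freedman-Diaconis, density-normalised),
#'   `density` (Gaussian KDE), `summary` (median, IQR), `n_excluded`.
#' @export
analyze_volume <- function(ramps, cantilever, reference_ramp = NULL,
                           d_min = 5, grid_shape = NULL) {
  stopifnot(length(ramps) >= 1)
  if (is.na(cantilever$deflection_sensitivity)) {
    if (is.null(reference_ramp))
      stop("no deflection sensitivity and no reference ramp", call. = FALSE)
    cantilever$deflection_sensitivity <- deflection_sensitivity(reference_ramp)
  }
  fits <- lapply(ramps, function(rmp) {
    defl <- rmp$signal * cantilever$deflection_sensitivity
    cp <- find_contact_hertz(rmp$piezo_z, defl, cantilever$spring_constant)
    if (cp$flagged || is.na(cp$z0)) {
      out <- structure(list(f0 = NA, lambda_exp = NA,
                            fit_window = c(d_min, NA), rms_residual = NA,
                            flagged = TRUE), class = "steric_fit")
      out$contact <- cp
      return(out)
    }
    curve <- to_force_distance(rmp, cantilever, cp$z0)
    sf <- fit_steric(curve, d_min = d_min)
    sf$contact <- cp
    sf
  })
  lambda <- vapply(fits, function(f) if (isTRUE(f$flagged)) NA_real_
                   else f$lambda_exp, numeric(1))
  lambda <- lambda[is.finite(lambda)]
  if (!length(lambda))
    stop("all ramps were flagged; no steric fits accepted", call. = FALSE)
  h <- if (length(lambda) > 1)
    graphics::hist(lambda, breaks = "FD", plot = FALSE) else NULL
  dens <- if (length(lambda) > 1) stats::density(lambda) else NULL
  structure(list(
    grid_shape = grid_shape, fits = fits, lambda = lambda,
    histogram = h, density = dens,
    summary = c(median = stats::median(lambda),
                iqr = if (length(lambda) > 1) stats::IQR(lambda) else 0),
    n_excluded = length(ramps) - length(lambda),
    n_total = length(ramps)), class = "fv_result")
}

#' @export
print.fv_result <- function(x, ...) {
  cat(sprintf("Force-volume result: %d/%d ramps accepted; median lambda = %.2f nm (IQR %.2f)\n",
              length(x$lambda), x$n_total, x$summary["median"], x$summary["iqr"]))
  invisible(x)
}

#' Fold change of the steric decay length between two conditions
#'
#' Ratio of median decay lengths (before/after) with a seeded bootstrap
#' 95% percentile interval.
#'
#' @param before,after [analyze_volume()] results.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list `fold_change`, `ci` (2.5/97.5 percentiles),
#'   `medians = c(before, after)`.
#' @export
condition_ratio <- function(before, after, n_boot = 1000, seed = 1) {
  stopifnot(inherits(before, "fv_result"), inherits(after, "fv_result"))
  mb <- stats::median(before$lambda); ma <- stats::median(after$lambda)
  boots <- with_seed(seed, replicate(n_boot, {
    stats::median(sample(before$lambda, replace = TRUE)) /
      stats::median(sample(after$lambda, replace = TRUE))
  }))
  list(fold_change = mb / ma,
       ci = stats::quantile(boots, c(0.025, 0.975)),
       medians = c(before = mb, after = ma))
}
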