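## Co-refinement of multi-contrast reflectivity with the two-layer pellicle
## model: seeded differential-evolution global search, bounded local polish,
## and affine-invariant ensemble MCMC for credible intervals.

nr_free_names <- function(fit_surfactant, fit_roughness) {
  nm <- c("inner_thickness", "inner_hydration",
          "outer_thickness", "outer_hydration")
  if (fit_surfactant) nm <- c(nm, "inner_surfactant", "outer_surfactant")
  if (fit_roughness) nm <- c(nm, "inner_roughness", "outer_roughness")
  nm
}

#' Default fit bounds for pellicle co-refinement
#'
#' Generic priors for hydrated pellicle films on silica: thin dense inner
#' layer (10-150 A), thick diffuse outer layer (30-800 A), hydrations in
#' broad physical ranges, surfactant dry fractions up to 50%.
#' @return named list of `c(lower, upper)` pairs.
#' @export
nr_default_bounds <- function() {
  list(inner_thickness = c(10, 150),
       inner_hydration = c(0.1, 0.95),
       outer_thickness = c(30, 800),
       outer_hydration = c(0.7, 0.999),
       inner_surfactant = c(0, 0.5),
       outer_surfactant = c(0, 0.5),
       inner_roughness = c(1, 20),
       outer_roughness = c(1, 40))
}

nr_par_from_model <- function(model, free) {
  full <- c(inner_thickness = model$inner$thickness,
            inner_hydration = model$inner$hydration,
            outer_thickness = model$outer$thickness,
            outer_hydration = model$outer$hydration,
            inner_surfactant = model$inner$surfactant_fraction,
            outer_surfactant = model$outer$surfactant_fraction,
            inner_roughness = model$inner$roughness,
            outer_roughness = model$outer$roughness)
  full[free]
}

nr_model_from_par <- function(par, base) {
  g <- function(nm, default) if (nm %in% names(par)) unname(par[nm]) else default
  inner <- pellicle_layer(
    thickness = g("inner_thickness", base$inner$thickness),
    hydration = g("inner_hydration", base$inner$hydration),
    surfactant_fraction = g("inner_surfactant", base$inner$surfactant_fraction),
    salivary_fraction = 1 - g("inner_surfactant", base$inner$surfactant_fraction),
    roughness = g("inner_roughness", base$inner$roughness))
  outer <- pellicle_layer(
    thickness = g("outer_thickness", base$outer$thickness),
    hydration = g("outer_hydration", base$outer$hydration),
    surfactant_fraction = g("outer_surfactant", base$outer$surfactant_fraction),
    salivary_fraction = 1 - g("outer_surfactant", base$outer$surfactant_fraction),
    roughness = g("outer_roughness", base$outer$roughness))
  pellicle_model(inner, outer, oxide = base$oxide,
                 substrate_sld = base$substrate_sld,
                 salivary_sld = base$salivary_sld,
                 surfactant_sld = base$surfactant_sld,
                 solvent_roughness = base$solvent_roughness)
}

nr_chi2_fun <- function(measurements, base, free, background = 1e-7) {
  force(measurements); force(base); force(free); force(background)
  function(x) {
    par <- stats::setNames(x, free)
    m <- try(nr_model_from_par(par, base), silent = TRUE)
    if (inherits(m, "try-error")) return(Inf)
    tot <- 0
    for (meas in measurements) {
      st <- stack_from_model(m, meas$contrast)
      rm_ <- reflectivity_smeared(st, meas$q, meas$dq_over_q) + background
      tot <- tot + sum(((rm_ - meas$reflectivity) / meas$dr)^2)
    }
    if (!is.finite(tot)) Inf else tot
  }
}

#' Co-refine a pellicle model against multi-contrast reflectivity
#'
#' Minimises the pooled weighted misfit
#' \eqn{\sum_c \sum_q ((R_{model} - R_{meas})/\sigma)^2} over all contrasts,
#' sharing all structural parameters; per-contrast solvent SLDs are fixed at
#' their nominal values. Global seeded differential evolution followed by a
#' bounded quasi-Newton polish on a logit-transformed scale.
#'
#' @param measurements list of [contrast_measurement()] objects.
#' @param model starting [pellicle_model()]; unfitted parts (oxide, SLDs)
#'   are taken from it and held fixed.
#' @param bounds named list of `c(lower, upper)`; defaults from
#'   [nr_default_bounds()].
#' @param seed integer seed; the fit is deterministic given it.
#' @param fit_surfactant fit the dry surfactant fractions (post-exposure
#'   stage)? If `FALSE` they are fixed at the starting model's values
#'   (0 for pre-exposure fits).
#' @param fit_roughness fit the two internal layer roughnesses?
#' @param control list: `popsize`, `maxiter` (differential evolution),
#'   `polish` (logical).
#' @param background constant instrument background added to the model
#'   reflectivity (default 1e-7).
#' @return an object of class `nr_fit`: the best-fit model, `chi2` (misfit
#'   per point), free-parameter vector, `converged` flag and bookkeeping.
#' @export
corefine <- function(measurements, model, bounds = NULL, seed = 1,
                     fit_surfactant = FALSE, fit_roughness = TRUE,
                     control = list(), background = 1e-7) {
  stopifnot(length(measurements) >= 1)
  ctrl <- utils::modifyList(list(popsize = 40, maxiter = 200, polish = TRUE),
                            control)
  free <- nr_free_names(fit_surfactant, fit_roughness)
  b <- utils::modifyList(nr_default_bounds(), if (is.null(bounds)) list() else bounds)
  lower <- vapply(free, function(n) b[[n]][1], numeric(1))
  upper <- vapply(free, function(n) b[[n]][2], numeric(1))
  fn <- nr_chi2_fun(measurements, model, free, background)
  start <- pmin(pmax(nr_par_from_model(model, free), lower), upper)
  res <- with_seed(seed, {
    de <- de_optim(fn, lower, upper, popsize = ctrl$popsize,
                   maxiter = ctrl$maxiter, init = start)
    if (isTRUE(ctrl$polish)) {
      u0 <- to_unbounded(de$par, lower, upper)
      pol <- stats::nlminb(u0, function(u) fn(to_bounded(u, lower, upper)),
                           control = list(iter.max = 400, eval.max = 800))
      if (is.finite(pol$objective) && pol$objective <= de$value)
        list(par = to_bounded(pol$par, lower, upper), value = pol$objective,
             converged = pol$convergence == 0 || pol$objective <= de$value)
      else list(par = de$par, value = de$value, converged = TRUE)
    } else list(par = de$par, value = de$value, converged = TRUE)
  })
  par <- stats::setNames(res$par, free)
  n_points <- sum(vapply(measurements, function(m) length(m$q), numeric(1)))
  structure(list(model = nr_model_from_par(par, model),
                 par = par, lower = lower, upper = upper,
                 chi2 = res$value / n_points, n_points = n_points,
                 converged = isTRUE(res$converged),
                 background = background,
                 fit_surfactant = fit_surfactant,
                 fit_roughness = fit_roughness),
            class = "nr_fit")
}

#' @export
print.nr_fit <- function(x, ...) {
  cat("Pellicle co-refinement:", x$n_points, "points, chi2/point =",
      signif(x$chi2, 4), if (!x$converged) "(NOT converged)" else "", "\n")
  print(round(x$par, 4))
  invisible(x)
}

#' Posterior sampling of a co-refined pellicle fit
#'
#' Affine-invariant ensemble MCMC (stretch move) about the optimum with a
#' Gaussian likelihood and uniform priors inside the fit bounds. Reports the
#' posterior median and the 1-sigma credible half-width (half of the
#' 16th-84th percentile range) per free parameter.
#'
#' @param fit an [corefine()] result (must be converged).
#' @param measurements the measurements used in the fit.
#' @param seed integer seed.
#' @param n_walkers,n_steps ensemble size and steps per walker.
#' @param burn_frac fraction of steps discarded as burn-in.
#' @return a data frame `parameter, median, sigma, lower, upper` with an
#'   `acceptance` attribute; a warning is attached (attribute
#'   `acceptance_warning`) if the acceptance fraction leaves `[0.1, 0.9]`.
#' @export
posterior_sample <- function(fit, measurements, seed = 1,
                             n_walkers = 24, n_steps = 400, burn_frac = 0.5) {
  stopifnot(inherits(fit, "nr_fit"))
  if (!fit$converged)
    stop("posterior sampling requires a converged fit", call. = FALSE)
  free <- names(fit$par)
  base <- fit$model
  fn <- nr_chi2_fun(measurements, base, free, fit$background)
  lower <- fit$lower; upper <- fit$upper
  log_post <- function(x) {
    if (any(x < lower | x > upper)) return(-Inf)
    -0.5 * fn(x)
  }
  sam <- with_seed(seed,
    stretch_sampler(log_post, as.numeric(fit$par), n_walkers, n_steps,
                    burn_frac = burn_frac))
  qs <- apply(sam$chain, 2, stats::quantile, probs = c(0.16, 0.5, 0.84))
  out <- data.frame(parameter = free,
                    median = qs[2, ],
                    sigma = (qs[3, ] - qs[1, ]) / 2,
                    lower = qs[1, ], upper = qs[3, ],
                    row.names = NULL)
  attr(out, "acceptance") <- sam$acceptance
  if (sam$acceptance < 0.1 || sam$acceptance > 0.9)
    attr(out, "acceptance_warning") <- sprintf(
      "MCMC acceptance fraction %.2f outside [0.1, 0.9]", sam$acceptance)
  out
}

#' Fit a bare silicon block (Si/SiO2/solvent)
#'
#' Stage-one characterisation: refines oxide thickness and the two
#' interfacial roughnesses against one or more solvent contrasts.
#'
#' @param measurements list of [contrast_measurement()] objects.
#' @param seed integer seed.
#' @param oxide_sld,substrate_sld fixed SLDs (1e-6 Angstrom^-2).
#' @return list with `oxide` (a [slab()]), `solvent_roughness`, `chi2`
#'   (per point) and `converged`.
#' @export
fit_bare_block <- function(measurements, seed = 1, oxide_sld = 3.47,
                           substrate_sld = 2.07, background = 1e-7) {
  lower <- c(t_ox = 5, r_ox = 1, r_sol = 1)
  upper <- c(t_ox = 30, r_ox = 8, r_sol = 8)
  fn <- function(x) {
    tot <- 0
    for (meas in measurements) {
      st <- data.frame(name = c("Si", "SiO2", "solvent"),
                       thickness = c(NA, x[1], NA),
                       sld = c(substrate_sld, oxide_sld,
                               meas$contrast$solvent_sld),
                       roughness = c(0, x[2], x[3]))
      rm_ <- reflectivity_smeared(st, meas$q, meas$dq_over_q) + background
      tot <- tot + sum(((rm_ - meas$reflectivity) / meas$dr)^2)
    }
    if (!is.finite(tot)) Inf else tot
  }
  res <- with_seed(seed, de_optim(fn, lower, upper, popsize = 20, maxiter = 80))
  n_points <- sum(vapply(measurements, function(m) length(m$q), numeric(1)))
  list(oxide = slab(res$par[1], oxide_sld, res$par[2], 0),
       solvent_roughness = unname(res$par[3]),
       chi2 = res$value / n_points, converged = TRUE)
}
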