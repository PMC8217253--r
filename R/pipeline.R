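## Study orchestration: staged NR refinement, wet/dry mass comparison and a
## seeded end-to-end demonstration on synthetic data that reproduces the
## study's headline contrasts and asserts its recovery tolerances.

sub_seed <- function(seed, k) (as.integer(seed) %% 20000L) * 1009L + k

#' Staged neutron-reflectivity study
#'
#' Three-stage refinement mirroring the experimental sequence: (1) bare
#' block (oxide thickness/roughness), (2) pellicle with surfactant fractions
#' fixed at zero, (3) treated pellicle with surfactant fractions free.
#' Earlier stages seed later ones; each stage reports MCMC credible
#' intervals.
#'
#' @param bare,pellicle,treated lists of [contrast_measurement()] objects
#'   (`treated` may be `NULL`).
#' @param surfactant_sld dry surfactant SLD used in stage 3.
#' @param salivary_sld dry salivary SLD.
#' @param seed integer seed.
#' @param control passed to [corefine()].
#' @param mcmc list `n_walkers`, `n_steps` (set `n_steps = 0` to skip
#'   posterior sampling).
#' @return list of per-stage results: `bare` ([fit_bare_block()] output),
#'   `pellicle` and `treated` (`nr_fit` objects with
#'   `parameter_intervals` attached), plus a `table` data frame analogous
#'   to a published two-column layer-parameter table.
#' @export
run_nr_study <- function(bare, pellicle, treated = NULL,
                         surfactant_sld = reference_slds()$capb,
                         salivary_sld = reference_slds()$salivary_dry,
                         seed = 1, control = list(),
                         mcmc = list(n_walkers = 24, n_steps = 200)) {
  stage_bare <- fit_bare_block(bare, seed = sub_seed(seed, 1))
  start <- pellicle_model(
    pellicle_layer(50, 0.6, roughness = 5),
    pellicle_layer(250, 0.95, roughness = 8),
    oxide = stage_bare$oxide,
    salivary_sld = salivary_sld, surfactant_sld = surfactant_sld,
    solvent_roughness = stage_bare$solvent_roughness)
  fit_pre <- corefine(pellicle, start, seed = sub_seed(seed, 2),
                      fit_surfactant = FALSE, control = control)
  if (!fit_pre$converged)
    return(list(bare = stage_bare, pellicle = fit_pre, treated = NULL,
                table = NULL, failed_stage = "pellicle"))
  if (mcmc$n_steps > 0)
    fit_pre$parameter_intervals <- posterior_sample(
      fit_pre, pellicle, seed = sub_seed(seed, 3),
      n_walkers = mcmc$n_walkers, n_steps = mcmc$n_steps)
  fit_post <- NULL
  if (!is.null(treated)) {
    start_post <- fit_pre$model
    fit_post <- corefine(treated, start_post, seed = sub_seed(seed, 4),
                         fit_surfactant = TRUE, control = control)
    if (fit_post$converged && mcmc$n_steps > 0)
      fit_post$parameter_intervals <- posterior_sample(
        fit_post, treated, seed = sub_seed(seed, 5),
        n_walkers = mcmc$n_walkers, n_steps = mcmc$n_steps)
  }
  tab <- nr_study_table(fit_pre, fit_post)
  list(bare = stage_bare, pellicle = fit_pre, treated = fit_post, table = tab)
}

nr_study_table <- function(fit_pre, fit_post) {
  row <- function(fit, label) {
    if (is.null(fit)) return(NULL)
    m <- fit$model
    iv <- fit$parameter_intervals
    err <- function(p) if (!is.null(iv) && p %in% iv$parameter)
      iv$sigma[iv$parameter == p] else NA_real_
    data.frame(
      state = label,
      inner_thickness_A = m$inner$thickness,
      inner_thickness_err = err("inner_thickness"),
      inner_hydration_pct = 100 * m$inner$hydration,
      inner_hydration_err = 100 * err("inner_hydration"),
      inner_surfactant_pct = 100 * m$inner$surfactant_fraction,
      outer_thickness_A = m$outer$thickness,
      outer_thickness_err = err("outer_thickness"),
      outer_hydration_pct = 100 * m$outer$hydration,
      outer_hydration_err = 100 * err("outer_hydration"),
      outer_surfactant_pct = 100 * m$outer$surfactant_fraction,
      chi2_per_point = fit$chi2)
  }
  rbind(row(fit_pre, "before"), row(fit_post, "after"))
}

#' Wet vs dry mass retention comparison
#'
#' Per surfactant, computes the retained mass fraction after treatment from
#' QCM-D (wet mass) and ellipsometry (dry mass) replicates, reporting
#' mean and SD over replicates.
#'
#' @param qcmd_results,ellipsometry_results data frames with columns
#'   `surfactant`, `before`, `after` (one row per replicate; areal masses
#'   in mg m^-2).
#' @return data frame `surfactant, technique, retention_mean, retention_sd,
#'   n`.
#' @export
run_mass_comparison <- function(qcmd_results, ellipsometry_results) {
  one <- function(df, technique) {
    do.call(rbind, lapply(split(df, df$surfactant), function(g)
      data.frame(surfactant = g$surfactant[1], technique = technique,
                 retention_mean = mean(retention_ratio(g$before, g$after)),
                 retention_sd = stats::sd(retention_ratio(g$before, g$after)),
                 n = nrow(g))))
  }
  qr <- one(qcmd_results, "qcmd")
  er <- one(ellipsometry_results, "ellipsometry")
  for (s in intersect(qr$surfactant, er$surfactant)) {
    nq <- qr$n[qr$surfactant == s]; ne <- er$n[er$surfactant == s]
    if (nq != ne)
      warning(sprintf("surfactant %s: %d QCM-D vs %d ellipsometry replicates; paired by order",
                      s, nq, ne), call. = FALSE)
  }
  out <- rbind(qr, er)
  rownames(out) <- NULL
  out
}

## QCM-D plateau wet masses for a synthetic scenario trace
qcmd_plateau_masses <- function(trace, seed, steps = c("rinse1", "rinse2"),
                                plateau_fraction = 0.1, max_fits = 8) {
  seg <- segment_steps(trace, plateau_fraction = plateau_fraction)
  vapply(steps, function(lb) {
    i <- which(seg$label == lb)
    w <- c(seg$end[i] - plateau_fraction * (seg$end[i] - seg$start[i]),
           seg$end[i])
    fit <- fit_voigt(trace, window = w, seed = seed, max_fits = max_fits)
    mean(fit$areal_mass[fit$converged], na.rm = TRUE)
  }, numeric(1))
}

#' Seeded end-to-end demonstration
#'
#' Simulates all four techniques for the three surfactant scenarios,
#' analyses them with the package's fitting pipelines (never reading the
#' generator truths during analysis), and checks the study's headline
#' recovery tolerances: CAPB steric fold change within 15% of 3, a C12E5
#' fold-change interval containing 1, the CAPB outer-layer collapse ratio
#' within 15% of its generative value, wet-vs-dry removal ordering and
#' near-complete SDS removal.
#'
#' @param seed integer seed.
#' @param out optional path for a JSON report.
#' @param fv_grid force-volume grid used per condition (default 24 x 24;
#'   a reduced grid that keeps the demonstration fast while leaving the
#'   median decay length well determined).
#' @param nr_q_points reflectivity grid size per contrast.
#' @param nr_control [corefine()] control for the demo fits.
#' @return a `study_report` list: per-technique tables, `checks` (named
#'   logical with details) and `ok` (all checks passed); `provenance`
#'   carries seed and problem sizes.
#' @export
run_demo <- function(seed = 1, out = NULL, fv_grid = c(24, 24),
                     nr_q_points = 70,
                     nr_control = list(popsize = 32, maxiter = 120)) {
  q <- default_q_grid(nr_q_points)
  pbs <- pbs_contrasts()
  report <- list(provenance = list(seed = seed, fv_grid = fv_grid,
                                   nr_q_points = nr_q_points,
                                   version = as.character(utils::packageVersion("pellifilm"))))
  checks <- list()

  ## ---- force volume: CAPB (collapse) and C12E5 (no change) ----
  fv_res <- list()
  for (sc in c("capb", "c12e5")) {
    tr <- scenario_truth(sc)
    res <- list()
    for (cond in c("before", "after")) {
      lam <- if (cond == "before") tr$lambda_before else tr$lambda_after
      k_off <- if (cond == "before") 11 else 12
      fv <- gen_force_volume(lam, tr$f0, tr$hertz_prefactor, grid = fv_grid,
                             noise = noise_spec(seed = sub_seed(seed, k_off +
                               ifelse(sc == "capb", 0, 100))))
      res[[cond]] <- analyze_volume(fv$ramps, cantilever(),
                                    reference_ramp = fv$reference,
                                    grid_shape = fv_grid)
    }
    fv_res[[sc]] <- list(
      result = res,
      ratio = condition_ratio(res$before, res$after,
                              seed = sub_seed(seed, 13)))
  }
  capb_fold <- fv_res$capb$ratio$fold_change
  checks$capb_lambda_fold <- list(
    value = capb_fold, target = 3, tol = 0.15 * 3,
    pass = abs(capb_fold - 3) <= 0.15 * 3)
  ci <- fv_res$c12e5$ratio$ci
  checks$c12e5_fold_ci_contains_1 <- list(
    value = fv_res$c12e5$ratio$fold_change, ci = unname(ci),
    pass = ci[1] <= 1 && ci[2] >= 1)
  report$force_volume <- list(
    capb = c(fv_res$capb$ratio$medians, fold = capb_fold),
    c12e5 = c(fv_res$c12e5$ratio$medians,
              fold = fv_res$c12e5$ratio$fold_change))

  ## ---- neutron reflectivity: CAPB scenario (headline collapse) ----
  tr <- scenario_truth("capb")
  bare_model <- pellicle_model(pellicle_layer(1e-3, 1), pellicle_layer(1e-3, 1))
  bare <- lapply(pbs, function(ct) {
    st <- data.frame(name = c("Si", "SiO2", "solvent"),
                     thickness = c(NA, 12, NA),
                     sld = c(2.07, 3.47, ct$solvent_sld),
                     roughness = c(0, 3, 3))
    r <- reflectivity_smeared(st, q, 0.04)
    ns <- noise_spec(seed = sub_seed(seed, 21))
    with_seed(ns$seed, {
      sig <- pmax(ns$relative_sigma * r, 1e-12)
      contrast_measurement(q, pmin(pmax(r * (1 + ns$relative_sigma *
        stats::rnorm(length(q))), 1e-8), 1), sig, 0.04, ct)
    })
  })
  pre <- gen_nr(tr$pellicle_before, pbs, q,
                noise_spec(seed = sub_seed(seed, 22)))
  post <- gen_nr(tr$pellicle_after, pbs[c("hPBS", "dPBS")], q,
                 noise_spec(seed = sub_seed(seed, 23)))
  nr <- run_nr_study(bare, pre, post, surfactant_sld = tr$surfactant_sld,
                     seed = sub_seed(seed, 24), control = nr_control,
                     mcmc = list(n_walkers = 20, n_steps = 120))
  report$nr_table <- nr$table
  truth_ratio <- tr$pellicle_before$outer$thickness /
    tr$pellicle_after$outer$thickness
  rec_ratio <- nr$pellicle$model$outer$thickness /
    nr$treated$model$outer$thickness
  checks$capb_outer_collapse <- list(
    value = rec_ratio, target = truth_ratio, tol = 0.15 * truth_ratio,
    pass = is.finite(rec_ratio) &&
      abs(rec_ratio - truth_ratio) <= 0.15 * truth_ratio)

  ## ---- QCM-D + ellipsometry retention, all three scenarios ----
  qcmd_rows <- ellip_rows <- NULL
  for (sc in c("capb", "c12e5", "sds")) {
    tr <- scenario_truth(sc)
    trace <- gen_qcmd(tr$qcmd_masses, durations = 3600,
                      noise = noise_spec(seed = sub_seed(seed, 31 +
                        match(sc, c("capb", "c12e5", "sds")))))
    m <- qcmd_plateau_masses(trace, seed = sub_seed(seed, 35))
    qcmd_rows <- rbind(qcmd_rows, data.frame(
      surfactant = sc, before = m["rinse1"], after = m["rinse2"]))
    # ellipsometry: short (n_f, d_f) plateau series around the truth masses
    n_o <- 1.335
    g2df <- function(gam) data.frame(time = 1:30, n_f = n_o + 0.05,
                                     d_f = unname(gam) * 0.18 / 0.05)
    ser_b <- gen_ellipsometry(g2df(tr$ellipsometry["before"]),
                              noise_spec(seed = sub_seed(seed, 41)))
    ser_a <- gen_ellipsometry(g2df(tr$ellipsometry["after"]),
                              noise_spec(seed = sub_seed(seed, 42)))
    ellip_rows <- rbind(ellip_rows, data.frame(
      surfactant = sc,
      before = mean(de_feijter_mass(ser_b$n_f, ser_b$d_f, n_o)),
      after = mean(de_feijter_mass(ser_a$n_f, ser_a$d_f, n_o))))
  }
  masses <- run_mass_comparison(qcmd_rows, ellip_rows)
  report$mass_comparison <- masses
  wet <- function(s) masses$retention_mean[masses$surfactant == s &
                                           masses$technique == "qcmd"]
  dry <- function(s) masses$retention_mean[masses$surfactant == s &
                                           masses$technique == "ellipsometry"]
  checks$wet_removal_order <- list(
    capb = wet("capb"), c12e5 = wet("c12e5"),
    pass = wet("capb") < wet("c12e5"))
  checks$capb_wet_below_dry <- list(
    wet = wet("capb"), dry = dry("capb"), pass = wet("capb") < dry("capb"))
  checks$sds_near_complete_removal <- list(
    value = wet("sds"), pass = wet("sds") < 0.1)

  report$checks <- checks
  report$ok <- all(vapply(checks, function(c) isTRUE(c$pass), logical(1)))
  class(report) <- "study_report"
  if (!is.null(out))
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (seed", x$provenance$seed, ")\n")
  for (nm in names(x$checks)) {
    c <- x$checks[[nm]]
    cat(sprintf("  %-28s %s\n", nm, if (isTRUE(c$pass)) "PASS" else "FAIL"))
  }
  cat(if (isTRUE(x$ok)) "All checks passed.\n" else "CHECK FAILURES.\n")
  invisible(x)
}
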