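## Neutron scattering length densities (SLD) for solvents, salivary material
## and surfactants, and the isotopic contrast series used in reflectometry.
## SLD unit throughout the package: 1e-6 Angstrom^-2.

.pellifilm_env <- new.env(parent = emptyenv())

scattering_length_table <- function() {
  if (is.null(.pellifilm_env$b_table)) {
    path <- system.file("extdata", "scattering_lengths.csv",
                        package = "pellifilm", mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .pellifilm_env$b_table <- tab
  }
  .pellifilm_env$b_table
}

#' Scattering length density from a chemical formula
#'
#' Computes the coherent neutron SLD of a material from its atomic
#' composition and mass density: \eqn{\rho = \sum_i c_i b_i / V_m}, where
#' \eqn{b_i} are bound coherent scattering lengths and the molecular volume
#' \eqn{V_m} follows from the molar mass and the mass density. Hydrogen and
#' deuterium are distinct elements (`H`, `D`).
#'
#' @param formula named numeric vector of element counts, e.g. `c(H = 2, O = 1)`.
#' @param mass_density mass density in g/cm^3 (must be positive).
#' @return SLD in 1e-6 Angstrom^-2.
#' @examples
#' sld_from_formula(c(H = 2, O = 1), 0.997)   # light water, about -0.56
#' sld_from_formula(c(D = 2, O = 1), 1.105)   # heavy water, about 6.36
#' @export
sld_from_formula <- function(formula, mass_density) {
  if (length(formula) == 0)
    stop("empty formula: at least one element is required", call. = FALSE)
  if (!is.numeric(formula) || is.null(names(formula)) || any(names(formula) == ""))
    stop("formula must be a named numeric vector of element counts", call. = FALSE)
  if (any(formula <= 0) || any(formula != round(formula)))
    stop("formula counts must be positive integers", call. = FALSE)
  if (!is.numeric(mass_density) || length(mass_density) != 1 || mass_density <= 0)
    stop("mass_density must be a single positive number (g/cm^3)", call. = FALSE)
  tab <- scattering_length_table()
  unknown <- setdiff(names(formula), tab$element)
  if (length(unknown))
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  i <- match(names(formula), tab$element)
  molar_mass <- sum(formula * tab$mass[i])          # g/mol
  b_total <- sum(formula * tab$b_fm[i])             # fm
  # molecular volume in Angstrom^3: M / (rho * N_A), with N_A*1e-24 = 0.6022141
  v_mol <- molar_mass / (mass_density * 0.6022141)
  # SLD [1e-6 A^-2] = b[fm -> 1e-5 A] / V[A^3] * 1e6 = 10 * b_fm / V
  10 * b_total / v_mol
}

#' Volume-fraction mixture of scattering length densities
#'
#' @param sld numeric vector of component SLDs (1e-6 Angstrom^-2).
#' @param volume_fraction numeric vector of volume fractions; must be
#'   non-negative and sum to 1 (within 1e-6).
#' @return the volume-weighted mean SLD.
#' @examples
#' mix_sld(c(6.36, -0.56), c(0.38, 0.62))   # silicon-matched water, 2.07
#' @export
mix_sld <- function(sld, volume_fraction) {
  stopifnot(length(sld) == length(volume_fraction), length(sld) >= 1)
  if (any(volume_fraction < 0))
    stop("volume fractions must be non-negative", call. = FALSE)
  s <- sum(volume_fraction)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("volume fractions must sum to 1 (got %.8f)", s), call. = FALSE)
  sum(sld * volume_fraction)
}

#' Reference materials of the pellicle experiments
#'
#' SLDs and default densities for the buffers (quoted pure-water values; PBS
#' salts are neglected), the silicon substrate/oxide, and the surfactants.
#' @return a named list of numbers (SLDs in 1e-6 Angstrom^-2).
#' @export
reference_slds <- function() {
  list(
    h2o   = sld_from_formula(c(H = 2, O = 1), 0.997),
    d2o   = sld_from_formula(c(D = 2, O = 1), 1.105),
    si    = 2.07,
    sio2  = 3.47,
    capb      = 0.36,
    d_c12e5   = 3.76,
    h_c12e5   = 0.129,
    salivary_dry = 2.0
  )
}

#' Define a solvent contrast
#'
#' A contrast is a solvent of given D2O volume fraction; its SLD must be the
#' linear mix of the H2O/D2O endpoint SLDs at that fraction (checked to
#' 0.01e-6 Angstrom^-2).
#'
#' @param name label, e.g. `"dPBS"`.
#' @param solvent_sld solvent SLD (1e-6 Angstrom^-2).
#' @param d2o_volume_fraction D2O volume fraction in `[0, 1]`.
#' @param endpoints length-2 numeric `c(h2o, d2o)` endpoint SLDs.
#' @return an object of class `contrast_definition`.
#' @export
contrast_definition <- function(name, solvent_sld, d2o_volume_fraction,
                                endpoints = c(reference_slds()$h2o,
                                              reference_slds()$d2o)) {
  if (d2o_volume_fraction < 0 || d2o_volume_fraction > 1)
    stop("d2o_volume_fraction must lie in [0, 1]", call. = FALSE)
  expected <- mix_sld(c(endpoints[2], endpoints[1]),
                      c(d2o_volume_fraction, 1 - d2o_volume_fraction))
  if (abs(expected - solvent_sld) > 0.01)
    stop(sprintf(
      "solvent_sld %.3f inconsistent with a %.2f D2O mix (expected %.3f)",
      solvent_sld, d2o_volume_fraction, expected), call. = FALSE)
  structure(list(name = name, solvent_sld = solvent_sld,
                 d2o_volume_fraction = d2o_volume_fraction),
            class = "contrast_definition")
}

#' Build a contrast series from D2O volume fractions
#'
#' @param d2o_fractions numeric vector of D2O volume fractions in `[0, 1]`.
#' @param names optional labels (defaults to `"phi=<f>"`).
#' @return a list of [contrast_definition()] objects.
#' @examples
#' contrast_series(c(0, 0.38, 1), names = c("hPBS", "smwPBS", "dPBS"))
#' @export
contrast_series <- function(d2o_fractions, names = NULL) {
  if (any(d2o_fractions < 0 | d2o_fractions > 1))
    stop("d2o_fractions must lie in [0, 1]", call. = FALSE)
  refs <- reference_slds()
  if (is.null(names)) names <- sprintf("phi=%.2f", d2o_fractions)
  mapply(function(f, nm) {
    s <- mix_sld(c(refs$d2o, refs$h2o), c(f, 1 - f))
    contrast_definition(nm, s, f)
  }, d2o_fractions, names, SIMPLIFY = FALSE)
}

#' The three buffers of the pellicle experiments
#'
#' hPBS (pure H2O), silicon-matched water smwPBS (0.38:0.62 D2O:H2O) and
#' dPBS (pure D2O).
#' @return a named list of three [contrast_definition()] objects.
#' @export
pbs_contrasts <- function() {
  out <- contrast_series(c(0, 0.38, 1), names = c("hPBS", "smwPBS", "dPBS"))
  names(out) <- c("hPBS", "smwPBS", "dPBS")
  out
}
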