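## Specular neutron reflectivity of a stratified Si / SiO2 / pellicle /
## solvent interface: slab containers, the two-layer pellicle
## parameterisation, the Abeles (optical matrix) reflectivity with
## Nevot-Croce roughness, and Gaussian resolution smearing.
## Geometry: solid-liquid cell, beam incident through the silicon substrate.

#' Construct a slab
#'
#' @param thickness thickness in Angstrom (`NA` for a semi-infinite medium).
#' @param sld scattering length density, 1e-6 Angstrom^-2.
#' @param roughness Gaussian roughness (Angstrom) of the interface with the
#'   preceding (incident-side) slab.
#' @param solvent_fraction volume fraction of solvent penetrating the slab.
#' @return an object of class `slab`.
#' @export
slab <- function(thickness, sld, roughness = 0, solvent_fraction = 0) {
  if (!is.na(thickness) && thickness < 0)
    stop("thickness must be >= 0", call. = FALSE)
  if (roughness < 0) stop("roughness must be >= 0", call. = FALSE)
  if (solvent_fraction < 0 || solvent_fraction > 1)
    stop("solvent_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(thickness = thickness, sld = sld, roughness = roughness,
                 solvent_fraction = solvent_fraction), class = "slab")
}

#' Construct a pellicle layer
#'
#' A hydrated layer whose dry material is a mixture of salivary material and
#' surfactant (volume fractions of the dry part summing to 1).
#'
#' @param thickness Angstrom, must be positive.
#' @param hydration solvent volume fraction in `[0, 1]`.
#' @param salivary_fraction fraction of the dry material that is salivary.
#' @param surfactant_fraction fraction of the dry material that is surfactant.
#' @param roughness Angstrom, interface with the preceding layer.
#' @return an object of class `pellicle_layer`.
#' @export
pellicle_layer <- function(thickness, hydration, salivary_fraction = 1,
                           surfactant_fraction = 1 - salivary_fraction,
                           roughness = 5) {
  if (thickness <= 0) stop("thickness must be > 0", call. = FALSE)
  if (hydration < 0 || hydration > 1)
    stop("hydration must lie in [0, 1]", call. = FALSE)
  if (abs(salivary_fraction + surfactant_fraction - 1) > 1e-6)
    stop("salivary_fraction + surfactant_fraction must equal 1", call. = FALSE)
  if (roughness < 0) stop("roughness must be >= 0", call. = FALSE)
  structure(list(thickness = thickness, hydration = hydration,
                 salivary_fraction = salivary_fraction,
                 surfactant_fraction = surfactant_fraction,
                 roughness = roughness), class = "pellicle_layer")
}

#' Two-layer pellicle model
#'
#' Inner thin dense layer plus outer thick diffuse layer on a Si/SiO2
#' substrate, each a solvated mixture of salivary material and surfactant.
#'
#' @param inner,outer [pellicle_layer()] objects.
#' @param oxide a [slab()] for the native SiO2 (default 12 A, SLD 3.47,
#'   roughness 3 A, no solvent).
#' @param substrate_sld silicon SLD (default 2.07).
#' @param salivary_sld dry salivary material SLD (default 2.0).
#' @param surfactant_sld dry surfactant SLD (default CAPB, 0.36).
#' @param solvent_roughness roughness (Angstrom) of the outer-layer/solvent
#'   interface.
#' @return an object of class `pellicle_model`.
#' @export
pellicle_model <- function(inner, outer,
                           oxide = slab(12, 3.47, 3, 0),
                           substrate_sld = 2.07,
                           salivary_sld = reference_slds()$salivary_dry,
                           surfactant_sld = reference_slds()$capb,
                           solvent_roughness = 12) {
  stopifnot(inherits(inner, "pellicle_layer"), inherits(outer, "pellicle_layer"),
            inherits(oxide, "slab"))
  structure(list(inner = inner, outer = outer, oxide = oxide,
                 substrate_sld = substrate_sld, salivary_sld = salivary_sld,
                 surfactant_sld = surfactant_sld,
                 solvent_roughness = solvent_roughness),
            class = "pellicle_model")
}

#' SLD of a hydrated pellicle layer at a given contrast
#'
#' \eqn{\rho = \phi_h \rho_{solv} + (1-\phi_h)(f_{sal}\rho_{sal} +
#' f_{surf}\rho_{surf})}, with hydration \eqn{\phi_h}.
#'
#' @param layer a [pellicle_layer()].
#' @param solvent_sld,salivary_sld,surfactant_sld SLDs in 1e-6 Angstrom^-2.
#' @return the layer SLD.
#' @export
layer_sld <- function(layer, solvent_sld, salivary_sld, surfactant_sld) {
  dry <- layer$salivary_fraction * salivary_sld +
    layer$surfactant_fraction * surfactant_sld
  layer$hydration * solvent_sld + (1 - layer$hydration) * dry
}

#' Slab stack of a pellicle model at one contrast
#'
#' Orders the slabs from the incident medium to the backing:
#' Si, SiO2, inner layer, outer layer, semi-infinite solvent. Thicknesses and
#' roughnesses are contrast-invariant; only slab SLDs change with solvent.
#'
#' @param model a [pellicle_model()].
#' @param contrast a [contrast_definition()] (or a bare solvent SLD).
#' @return a data frame with columns `name`, `thickness`, `sld`, `roughness`
#'   (roughness of row i is the interface between rows i-1 and i).
#' @export
stack_from_model <- function(model, contrast) {
  sol <- if (inherits(contrast, "contrast_definition")) contrast$solvent_sld
         else as.numeric(contrast)
  ox_sld <- model$oxide$solvent_fraction * sol +
    (1 - model$oxide$solvent_fraction) * model$oxide$sld
  rows <- list(
    list("Si", NA_real_, model$substrate_sld, 0),
    list("SiO2", model$oxide$thickness, ox_sld, model$oxide$roughness),
    list("inner", model$inner$thickness,
         layer_sld(model$inner, sol, model$salivary_sld, model$surfactant_sld),
         model$inner$roughness),
    list("outer", model$outer$thickness,
         layer_sld(model$outer, sol, model$salivary_sld, model$surfactant_sld),
         model$outer$roughness),
    list("solvent", NA_real_, sol, model$solvent_roughness)
  )
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], thickness = r[[2]], sld = r[[3]],
               roughness = r[[4]], stringsAsFactors = FALSE)))
  # drop zero-thickness internal slabs (degenerate models)
  keep <- is.na(df$thickness) | df$thickness > 0
  df[keep, , drop = FALSE]
}

#' Specular reflectivity of a slab stack (Abeles optical matrix method)
#'
#' Transfer-matrix computation of \eqn{R(q)} for a stratified interface with
#' Gaussian (Nevot-Croce) interfacial roughness. The first row of the stack
#' is the semi-infinite incident medium (silicon in the solid-liquid cell);
#' the last row is the semi-infinite backing solvent.
#'
#' @param stack data frame with columns `thickness` (Angstrom; `NA` for the
#'   two semi-infinite media), `sld` (1e-6 Angstrom^-2) and `roughness`
#'   (Angstrom, interface with the preceding row).
#' @param q momentum transfer grid, Angstrom^-1 (positive).
#' @return reflectivity values in `(0, 1]`, same length as `q`.
#' @export
reflectivity <- function(stack, q) {
  stopifnot(is.data.frame(stack), nrow(stack) >= 2, all(q > 0))
  th <- stack$thickness
  if (any(!is.na(th) & th < 0)) stop("negative slab thickness", call. = FALSE)
  sld <- stack$sld * 1e-6
  rough <- stack$roughness
  n <- nrow(stack)
  kz0 <- q / 2
  # wavevector in each medium relative to the incident one
  k <- lapply(seq_len(n), function(j)
    sqrt(as.complex(kz0^2 - 4 * pi * (sld[j] - sld[1]))))
  # Abeles characteristic matrices, accumulated as four complex vectors
  m11 <- m22 <- rep(1 + 0i, length(q))
  m12 <- m21 <- rep(0 + 0i, length(q))
  for (j in seq_len(n - 1)) {
    r_j <- (k[[j]] - k[[j + 1]]) / (k[[j]] + k[[j + 1]]) *
      exp(-2 * k[[j]] * k[[j + 1]] * rough[j + 1]^2)
    beta <- if (j == 1) 0 + 0i else 1i * k[[j]] * th[j]
    e_p <- exp(-beta); e_m <- exp(beta)
    # layer matrix: [[e^-ibeta, r*e^-ibeta], [r*e^+ibeta, e^+ibeta]]
    a11 <- m11 * e_p + m12 * r_j * e_m
    a12 <- m11 * r_j * e_p + m12 * e_m
    a21 <- m21 * e_p + m22 * r_j * e_m
    a22 <- m21 * r_j * e_p + m22 * e_m
    m11 <- a11; m12 <- a12; m21 <- a21; m22 <- a22
  }
  r <- m21 / m11
  out <- Mod(r)^2
  pmin(out, 1)
}

#' Gaussian resolution smearing of a reflectivity curve
#'
#' Convolves a sampled \eqn{R(q)} with a Gaussian of FWHM
#' \eqn{\Delta q = (\Delta q/q)\, q} (constant relative resolution, the
#' time-of-flight case). `dq_over_q = 0` returns the input unchanged.
#'
#' @param q momentum transfer grid (strictly increasing).
#' @param r reflectivity sampled on `q`.
#' @param dq_over_q relative resolution (FWHM / q), >= 0.
#' @return smeared reflectivity on the same grid.
#' @export
smear <- function(q, r, dq_over_q) {
  stopifnot(length(q) == length(r), dq_over_q >= 0)
  if (dq_over_q == 0) return(r)
  sig <- dq_over_q * q / 2.35482
  out <- vapply(seq_along(q), function(i) {
    w <- stats::dnorm(q, q[i], sig[i])
    sum(w * r) / sum(w)
  }, numeric(1))
  out
}

## Model reflectivity with resolution smearing by Gaussian quadrature over
## the resolution kernel (17 nodes, +-3.5 sigma); used by the fitting layer.
reflectivity_smeared <- function(stack, q, dq_over_q = 0) {
  if (dq_over_q <= 0) return(reflectivity(stack, q))
  nodes <- seq(-3.5, 3.5, length.out = 17)
  w <- stats::dnorm(nodes); w <- w / sum(w)
  sig <- dq_over_q / 2.35482
  qq <- as.vector(outer(q, 1 + sig * nodes))   # q_i * (1 + sig*x_k)
  qq <- pmax(qq, 1e-6)
  rr <- matrix(reflectivity(stack, qq), nrow = length(q))
  as.vector(rr %*% w)
}

#' Critical edge of total reflection
#'
#' \eqn{Q_c = \sqrt{16\pi\,\Delta\rho}} when the backing SLD exceeds the
#' incident-medium SLD; 0 otherwise (no total-reflection edge).
#'
#' @param substrate_sld,solvent_sld SLDs in 1e-6 Angstrom^-2.
#' @return \eqn{Q_c} in Angstrom^-1.
#' @examples
#' critical_edge(2.07, 6.36)   # about 0.0147
#' @export
critical_edge <- function(substrate_sld, solvent_sld) {
  d <- (solvent_sld - substrate_sld) * 1e-6
  if (d <= 0) return(0)
  sqrt(16 * pi * d)
}

#' One reflectivity measurement at one contrast
#'
#' @param q momentum transfer grid, strictly increasing, within
#'   `[0.005, 0.5]` Angstrom^-1.
#' @param reflectivity measured reflectivity in `(0, 1]`.
#' @param dr 1-sigma uncertainties (> 0).
#' @param dq_over_q relative resolution (FWHM/q).
#' @param contrast a [contrast_definition()].
#' @return an object of class `contrast_measurement`.
#' @export
contrast_measurement <- function(q, reflectivity, dr, dq_over_q, contrast) {
  stopifnot(inherits(contrast, "contrast_definition"))
  if (any(diff(q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  if (any(q < 0.005 | q > 0.5))
    stop("q must lie within [0.005, 0.5] Angstrom^-1", call. = FALSE)
  if (any(reflectivity <= 0 | reflectivity > 1))
    stop("reflectivity must lie in (0, 1]", call. = FALSE)
  if (any(dr <= 0)) stop("dr must be positive", call. = FALSE)
  structure(list(q = q, reflectivity = reflectivity, dr = dr,
                 dq_over_q = dq_over_q, contrast = contrast),
            class = "contrast_measurement")
}
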