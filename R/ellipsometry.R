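## Null-ellipsometry forward model (multilayer Fresnel, Si/SiO2/film/ambient)
## and de Feijter conversion of (n_f, d_f) to dry adsorbed mass.

#' Optical slab stack for ellipsometry
#'
#' Ambient / film / oxide / substrate, light incident from the ambient.
#' Complex substrate index uses the n - ik convention.
#'
#' @param ambient_index real refractive index of the solution (default PBS,
#'   1.335 at 442.9 nm).
#' @param film_index,film_thickness_nm the adsorbed film (index real, nm).
#' @param oxide_index,oxide_thickness_nm the SiO2 layer.
#' @param substrate_index complex silicon index (default `4.62 - 0.14i` at
#'   442.9 nm).
#' @return an object of class `optical_stack`.
#' @export
optical_stack <- function(ambient_index = 1.335,
                          film_index = ambient_index, film_thickness_nm = 0,
                          oxide_index = 1.466, oxide_thickness_nm = 2.0,
                          substrate_index = complex(real = 4.62,
                                                    imaginary = -0.14)) {
  stopifnot(film_thickness_nm >= 0, oxide_thickness_nm >= 0,
            ambient_index >= 1, Re(film_index) >= 1, Re(oxide_index) >= 1)
  structure(list(ambient_index = ambient_index, film_index = film_index,
                 film_thickness_nm = film_thickness_nm,
                 oxide_index = oxide_index,
                 oxide_thickness_nm = oxide_thickness_nm,
                 substrate_index = substrate_index),
            class = "optical_stack")
}

## recursive Fresnel amplitude reflection for a layered stack.
## n: complex indices ambient..substrate; d: thicknesses of internal layers
## (nm). Returns c(rp, rs).
fresnel_multilayer <- function(n, d, wavelength, angle_deg) {
  th0 <- angle_deg * pi / 180
  s0 <- n[1] * sin(th0)
  cth <- sqrt(as.complex(1 - (s0 / n)^2))
  m <- length(n)
  rp_int <- rs_int <- vector("complex", m - 1)
  for (j in seq_len(m - 1)) {
    ni <- n[j]; nj <- n[j + 1]; ci <- cth[j]; cj <- cth[j + 1]
    rs_int[j] <- (ni * ci - nj * cj) / (ni * ci + nj * cj)
    rp_int[j] <- (nj * ci - ni * cj) / (nj * ci + ni * cj)
  }
  rp <- rp_int[m - 1]; rs <- rs_int[m - 1]
  if (m > 2) {
    for (j in (m - 2):1) {
      beta <- 2 * pi * d[j] * n[j + 1] * cth[j + 1] / wavelength
      ph <- exp(-2i * beta)
      rp <- (rp_int[j] + rp * ph) / (1 + rp_int[j] * rp * ph)
      rs <- (rs_int[j] + rs * ph) / (1 + rs_int[j] * rs * ph)
    }
  }
  c(rp = rp, rs = rs)
}

#' Ellipsometric angles of an optical stack
#'
#' Computes \eqn{\rho = r_p/r_s} from the multilayer Fresnel solution and
#' returns \eqn{\Psi = \arctan|\rho|}, \eqn{\Delta = \arg\rho} in degrees.
#'
#' @param stack an [optical_stack()].
#' @param wavelength nm (default 442.9).
#' @param angle_deg angle of incidence from the ambient, in (0, 90).
#' @return named numeric `c(psi, delta)` in degrees.
#' @export
psi_delta <- function(stack, wavelength = 442.9, angle_deg = 68) {
  stopifnot(angle_deg > 0, angle_deg < 90)
  n <- c(stack$ambient_index, stack$film_index, stack$oxide_index,
         stack$substrate_index)
  d <- c(stack$film_thickness_nm, stack$oxide_thickness_nm)
  keep <- c(TRUE, d[1] > 0, d[2] > 0, TRUE)
  r <- fresnel_multilayer(n[keep], d[d > 0], wavelength, angle_deg)
  rho <- unname(r[1] / r[2])
  c(psi = atan(Mod(rho)) * 180 / pi, delta = Arg(rho) * 180 / pi)
}

#' Invert ellipsometric angles to film index and thickness
#'
#' Two-parameter inversion of \eqn{(\Psi, \Delta)} for `(n_f, d_f)` given
#' the known substrate/oxide/ambient: coarse grid scan followed by a local
#' Nelder-Mead polish of \eqn{|\rho_{model} - \rho_{meas}|^2}.
#'
#' @param psi,delta measured angles, degrees.
#' @param known an [optical_stack()] holding the ambient, oxide and
#'   substrate (its film entries are ignored).
#' @param bounds list `n = c(lo, hi)`, `d = c(lo, hi)` (nm).
#' @param wavelength,angle_deg as in [psi_delta()].
#' @param residual_threshold flag the solution ambiguous above this.
#' @return list `n_f`, `d_f`, `residual`, `ambiguous`.
#' @export
invert_film <- function(psi, delta, known,
                        bounds = list(n = c(1.336, 1.65), d = c(0, 300)),
                        wavelength = 442.9, angle_deg = 68,
                        residual_threshold = 1e-4) {
  rho_meas <- tan(psi * pi / 180) * exp(1i * delta * pi / 180)
  obj <- function(p) {
    st <- optical_stack(known$ambient_index, p[1], p[2], known$oxide_index,
                        known$oxide_thickness_nm, known$substrate_index)
    pd <- psi_delta(st, wavelength, angle_deg)
    rho <- tan(pd[1] * pi / 180) * exp(1i * pd[2] * pi / 180)
    Mod(rho - rho_meas)^2
  }
  ns <- seq(bounds$n[1], bounds$n[2], length.out = 25)
  ds <- seq(bounds$d[1], bounds$d[2], length.out = 61)
  grid <- expand.grid(n = ns, d = ds)
  vals <- apply(grid, 1, obj)
  p0 <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(p0, function(p) {
    if (p[1] < bounds$n[1] || p[1] > bounds$n[2] ||
        p[2] < bounds$d[1] || p[2] > bounds$d[2]) return(1e6)
    obj(p)
  }, method = "Nelder-Mead",
  control = list(maxit = 2000, reltol = 1e-14))
  list(n_f = opt$par[1], d_f = opt$par[2], residual = opt$value,
       ambiguous = opt$value > residual_threshold ||
         opt$par[2] <= bounds$d[1] + 1e-6)
}

#' De Feijter dry adsorbed mass
#'
#' \eqn{\Gamma = (n_f - n_o)\, d_f / (dn/dc)}. With `d_f` in nm and
#' `dndc` in ml/g the result is directly in mg m^-2.
#'
#' @param n_f film refractive index (vectorised).
#' @param d_f film thickness, nm (vectorised).
#' @param n_o ambient refractive index (default 1.335).
#' @param dndc refractive index increment, ml/g (default 0.18).
#' @return adsorbed amount in mg m^-2.
#' @examples
#' de_feijter_mass(1.465, 10)   # 7.22 mg m^-2
#' @export
de_feijter_mass <- function(n_f, d_f, n_o = 1.335, dndc = 0.18) {
  if (dndc <= 0) stop("dndc must be positive", call. = FALSE)
  if (any(d_f < 0)) stop("d_f must be >= 0", call. = FALSE)
  (n_f - n_o) * d_f / dndc
}
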