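# Independent oracles used across the suite. These deliberately re-derive
# the physics through different formulations than the package code paths.

# Parratt recursion for specular reflectivity (bottom-up), independent of
# the package's transfer-matrix implementation.
parratt_reflectivity <- function(stack, q) {
  sld <- stack$sld * 1e-6
  th <- stack$thickness
  rough <- stack$roughness
  n <- nrow(stack)
  kz <- lapply(seq_len(n), function(j)
    sqrt(as.complex((q / 2)^2 - 4 * pi * (sld[j] - sld[1]))))
  r_acc <- rep(0 + 0i, length(q))
  for (j in (n - 1):1) {
    r_j <- (kz[[j]] - kz[[j + 1]]) / (kz[[j]] + kz[[j + 1]]) *
      exp(-2 * kz[[j]] * kz[[j + 1]] * rough[j + 1]^2)
    ph <- if (j + 1 <= n - 1) exp(2i * kz[[j + 1]] * th[j + 1]) else 1 + 0i
    r_acc <- (r_j + r_acc * ph) / (1 + r_j * r_acc * ph)
  }
  pmin(Mod(r_acc)^2, 1)
}

# closed-form Fresnel reflectivity of a single sharp interface
fresnel_step <- function(q, sld_inc, sld_back) {
  k0 <- q / 2
  k1 <- sqrt(as.complex(k0^2 - 4 * pi * (sld_back - sld_inc) * 1e-6))
  Mod((k0 - k1) / (k0 + k1))^2
}

# random multi-layer stack for property tests
random_stack <- function(n_layers, seed) {
  set.seed(seed)
  data.frame(
    name = c("inc", paste0("L", seq_len(n_layers)), "back"),
    thickness = c(NA, runif(n_layers, 10, 300), NA),
    sld = c(2.07, runif(n_layers, -0.5, 6.5), runif(1, -0.56, 6.36)),
    roughness = c(0, runif(n_layers + 1, 0, 8)))
}

# one synthetic force curve (d_ts, F) straight from the steric + offset
# Hertz law, bypassing the piezo/detector representation
steric_curve <- function(lambda, f0 = 1, d = seq(0.2, 60, by = 0.25),
                         noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- f0 * exp(-d / lambda) + if (noise_sd > 0) rnorm(length(d), 0, noise_sd) else 0
  structure(list(d_ts = d, force = f, deflection_nm = f / 0.1),
            class = "force_curve")
}
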