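#' @keywords internal
"_PACKAGE"

## Internal numerical utilities: seeded evaluation, a bounded
## differential-evolution optimiser and an affine-invariant ensemble sampler.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded helpers never disturb the global stream.
#' @param seed integer seed (required).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop("a finite integer seed is required", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Classic rand/1/bin differential evolution on a box. `init` (optional)
## centres the initial population on a starting point (20% of span jitter).
de_optim <- function(fn, lower, upper, popsize = 10 * length(lower),
                     maxiter = 150, f_weight = 0.8, cr = 0.9,
                     init = NULL, tol = 1e-10) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  span <- upper - lower
  pop <- matrix(runif(popsize * d, lower, upper), nrow = popsize, byrow = TRUE)
  if (!is.null(init)) {
    jit <- matrix(stats::rnorm(popsize * d, 0, 0.2), nrow = popsize)
    pop <- sweep(jit, 2, span, "*") + matrix(init, popsize, d, byrow = TRUE)
    pop <- pmin(pmax(pop, matrix(lower, popsize, d, byrow = TRUE)),
                matrix(upper, popsize, d, byrow = TRUE))
    pop[1, ] <- init
  }
  cost <- apply(pop, 1, fn)
  for (iter in seq_len(maxiter)) {
    for (i in seq_len(popsize)) {
      idx <- sample(setdiff(seq_len(popsize), i), 3)
      trial <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
      cross <- runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      # reflect out-of-bounds components back into the box
      bad <- trial < lower; trial[bad] <- pmin(upper, 2 * lower - trial)[bad]
      bad <- trial > upper; trial[bad] <- pmax(lower, 2 * upper - trial)[bad]
      trial <- pmin(pmax(trial, lower), upper)
      tc <- fn(trial)
      if (is.finite(tc) && tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
    if (stats::sd(cost) < tol * (abs(mean(cost)) + tol)) break
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], iterations = iter)
}

## Affine-invariant ensemble sampler (stretch move, scale a = 2).
## log_post: function(theta) -> log posterior (may return -Inf).
## Returns list(chain = [n_keep x d], acceptance = fraction).
stretch_sampler <- function(log_post, start, n_walkers, n_steps,
                            burn_frac = 0.5, a = 2, spread = 1e-3) {
  d <- length(start)
  n_walkers <- max(n_walkers, 2 * d + 2)
  walkers <- matrix(start, n_walkers, d, byrow = TRUE) *
    (1 + spread * matrix(stats::rnorm(n_walkers * d), n_walkers, d)) +
    spread * matrix(stats::rnorm(n_walkers * d), n_walkers, d)
  lp <- apply(walkers, 1, log_post)
  # nudge any walker that started outside the support
  for (i in which(!is.finite(lp))) {
    for (k in 1:50) {
      walkers[i, ] <- start * (1 + spread * stats::rnorm(d)) + spread * stats::rnorm(d)
      lp[i] <- log_post(walkers[i, ])
      if (is.finite(lp[i])) break
    }
  }
  keep <- vector("list", n_steps)
  n_acc <- 0L; n_prop <- 0L
  for (s in seq_len(n_steps)) {
    for (i in seq_len(n_walkers)) {
      j <- sample(setdiff(seq_len(n_walkers), i), 1)
      z <- (1 + (a - 1) * runif(1))^2 / a
      prop <- walkers[j, ] + z * (walkers[i, ] - walkers[j, ])
      lp_prop <- log_post(prop)
      n_prop <- n_prop + 1L
      if (is.finite(lp_prop) &&
          log(runif(1)) < (d - 1) * log(z) + lp_prop - lp[i]) {
        walkers[i, ] <- prop
        lp[i] <- lp_prop
        n_acc <- n_acc + 1L
      }
    }
    keep[[s]] <- walkers
  }
  drop_n <- floor(burn_frac * n_steps)
  chain <- do.call(rbind, keep[(drop_n + 1):n_steps])
  list(chain = chain, acceptance = n_acc / n_prop)
}

## logit-scale transform helpers for bounded fitting
to_unbounded <- function(x, lower, upper) {
  p <- (x - lower) / (upper - lower)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

to_bounded <- function(u, lower, upper) {
  lower + (upper - lower) / (1 + exp(-u))
}
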