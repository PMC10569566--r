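# Internal optimization plumbing shared by the likelihood and minimum
# chi-square fitters: unconstrained reparameterizations of each family's
# parameter space and a multi-start minimizer.

.theta_to_par <- function(family, theta) {
  switch(family,
    homogeneous = stats::qlogis(theta[1]),
    beta = log(theta),
    logit_normal = c(theta[1], log(theta[2])))
}

.par_to_theta <- function(family, par) {
  switch(family,
    homogeneous = stats::plogis(par[1]),
    beta = exp(par),
    logit_normal = c(par[1], exp(par[2])))
}

.model_from_par <- function(family, par) {
  capture_model(family, .par_to_theta(family, par))
}

# Default transformed-scale start points.  `xbar` is the mean sighting
# count among observed individuals, used for a method-of-moments-ish first
# start; remaining starts guard against local optima.
.theta_starts <- function(family, T, xbar) {
  p0 <- min(max(xbar / T, 0.01), 0.9)
  switch(family,
    homogeneous = list(stats::qlogis(p0), stats::qlogis(p0 / 2), 0),
    beta = list(c(0, log(max(1 / p0 - 1, 0.5))), c(0, 0), c(log(0.5), log(5))),
    logit_normal = list(c(stats::qlogis(p0), 0), c(-2.5, log(0.7)),
                        c(-1, log(0.5))))
}

# Multi-start minimization of `fn` (transformed scale).  d = 1 uses Brent
# on a wide bracket; d = 2 uses Nelder-Mead, with a restart polish unless
# `polish = FALSE` (warm-started refinement loops skip it for speed).
.minimize_theta <- function(fn, starts, reltol = 1e-12, polish = TRUE) {
  d <- length(starts[[1]])
  if (d == 1L) {
    o <- stats::optimize(fn, lower = -12, upper = 8, tol = 1e-10)
    return(list(par = o$minimum, value = o$objective, converged = TRUE))
  }
  ctl <- list(maxit = 2000, reltol = reltol)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, fn, method = "Nelder-Mead", control = ctl),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (polish) {
      o2 <- tryCatch(
        stats::optim(o$par, fn, method = "Nelder-Mead", control = ctl),
        error = function(e) o)
      if (o2$value <= o$value) o <- o2
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("theta optimization failed from every start point")
  list(par = best$par, value = best$value,
       converged = best$convergence == 0L)
}
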