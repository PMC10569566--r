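#' Full multinomial log-likelihood of (N, theta)
#'
#' Log-likelihood of the complete frequency vector
#' \eqn{f = (f_0, f_1, \dots, f_T)} with \eqn{f_0 = N - n}, under
#' \eqn{f \sim \mathrm{Multinomial}_{T+1}(N, \pi_g)}.  Includes the
#' multinomial coefficient (via \code{lgamma}), so the value equals the log
#' multinomial pmf exactly.
#'
#' @param fv A [frequency_vector].
#' @param N Candidate population size, integer \eqn{\ge n}.
#' @param model A [capture_model].
#' @return Log-likelihood value (may be \code{-Inf} at boundary parameters).
#' @export
full_log_likelihood <- function(fv, N, model) {
  stopifnot(inherits(fv, "frequency_vector"))
  if (N < fv$n) stop("N must be at least n = ", fv$n, " (f_0 = N - n < 0)")
  pi <- cell_probabilities(model, fv$T)$pi
  f0 <- N - fv$n
  coef <- lgamma(N + 1) - lgamma(f0 + 1) - sum(lgamma(fv$f + 1))
  kern <- sum(ifelse(fv$f > 0, fv$f * log(pi[-1]), 0)) +
    if (f0 > 0) f0 * log(pi[1]) else 0
  coef + kern
}

#' Conditional multinomial log-likelihood of theta
#'
#' Log-likelihood of the observable frequencies \eqn{f^c} given \eqn{n},
#' under \eqn{[f^c | n] \sim \mathrm{Multinomial}_T(n, \pi_g^c)}.  The
#' multinomial coefficient is included; the value does not depend on
#' \eqn{N}.  Returns \code{-Inf} if some cell with positive count has zero
#' conditional probability.
#'
#' @inheritParams full_log_likelihood
#' @return Log-likelihood value.
#' @export
conditional_log_likelihood <- function(fv, model) {
  stopifnot(inherits(fv, "frequency_vector"))
  pic <- conditional_probabilities(cell_probabilities(model, fv$T))
  if (any(pic == 0 & fv$f > 0)) return(-Inf)
  lgamma(fv$n + 1) - sum(lgamma(fv$f + 1)) +
    sum(ifelse(fv$f > 0, fv$f * log(pic), 0))
}

# theta-dependent part of the conditional log-likelihood (coefficient
# dropped), used by both fitters.
.cond_kernel <- function(fv, pi) {
  q <- 1 - pi[1]
  if (q <= 0) return(-Inf)
  pic <- pi[-1] / q
  if (any(pic <= 0 & fv$f > 0)) return(-Inf)
  sum(ifelse(fv$f > 0, fv$f * log(pic), 0))
}

# Integer N maximizing log dbinom(n; N, q) over N >= n.  The likelihood
# ratio in N is monotone, so the maximizer is floor(n/q); a small window is
# checked to absorb ties and rounding.
.opt_N_binomial <- function(n, q) {
  Nstar <- max(n, floor(n / q))
  cand <- max(n, Nstar - 2L):(Nstar + 2L)
  list(N = cand[which.max(stats::dbinom(n, cand, q, log = TRUE))],
       cand = cand)
}

#' Maximum full-likelihood fit
#'
#' Jointly maximizes the full likelihood \eqn{L(\theta, N; f)} over integer
#' \eqn{N \ge n} and \eqn{\theta}.  Internally profiles over \eqn{\theta}:
#' the full likelihood factorizes as \eqn{[f^c|n][n]} with
#' \eqn{[n] \sim \mathrm{Binomial}(N, 1 - \pi_g(0))}, and for fixed
#' \eqn{\theta} the integer \eqn{N} maximizing the binomial factor is
#' \eqn{\lfloor n / (1 - \pi_g(0)) \rfloor} by monotonicity of the
#' likelihood ratio, so only a continuous multi-start optimization over
#' \eqn{\theta} remains.
#'
#' @param fv A [frequency_vector].
#' @param family Heterogeneity family, as in [capture_model()].
#' @return A \code{"cr_fit"} with \code{N_hat}, \code{theta_hat}, and the
#'   maximized full log-likelihood (multinomial coefficient included) as
#'   \code{objective}.
#' @examples
#' \donttest{
#' fit_full(stork_frequencies(), "homogeneous")
#' }
#' @export
fit_full <- function(fv, family = c("homogeneous", "beta", "logit_normal")) {
  family <- match.arg(family)
  stopifnot(inherits(fv, "frequency_vector"))
  xbar <- sum(seq_len(fv$T) * fv$f) / fv$n
  fn <- function(par) {
    m <- tryCatch(.model_from_par(family, par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    pi <- cell_probabilities(m, fv$T)$pi
    q <- 1 - pi[1]
    kern <- .cond_kernel(fv, pi)
    if (!is.finite(kern) || q <= 0) return(1e10)
    opt <- .opt_N_binomial(fv$n, q)
    -(kern + max(stats::dbinom(fv$n, opt$cand, q, log = TRUE)))
  }
  o <- .minimize_theta(fn, .theta_starts(family, fv$T, xbar))
  theta <- .par_to_theta(family, o$par)
  model <- capture_model(family, theta)
  q <- 1 - cell_probabilities(model, fv$T)$pi[1]
  N_hat <- .opt_N_binomial(fv$n, q)$N
  .cr_fit("full_likelihood", family, N_hat, .name_theta(family, theta),
          objective = full_log_likelihood(fv, N_hat, model),
          converged = o$converged, n = fv$n, T = fv$T)
}

#' Maximum conditional-likelihood (Horvitz-Thompson) fit
#'
#' Maximizes the conditional likelihood \eqn{L^c(\theta; f^c)} over
#' \eqn{\theta}, then estimates the population size with the
#' Horvitz-Thompson estimator
#' \eqn{\hat N = n / \{1 - \hat\pi_g(0)\}} (rounded to integer), which
#' inflates the observed count by the estimated probability of being seen
#' at least once.
#'
#' @inheritParams fit_full
#' @return A \code{"cr_fit"} with the maximized conditional log-likelihood
#'   (multinomial coefficient included) as \code{objective}.
#' @examples
#' \donttest{
#' fit_conditional(stork_frequencies(), "beta")
#' }
#' @export
fit_conditional <- function(fv,
                            family = c("homogeneous", "beta", "logit_normal")) {
  family <- match.arg(family)
  stopifnot(inherits(fv, "frequency_vector"))
  xbar <- sum(seq_len(fv$T) * fv$f) / fv$n
  fn <- function(par) {
    m <- tryCatch(.model_from_par(family, par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    kern <- .cond_kernel(fv, cell_probabilities(m, fv$T)$pi)
    if (!is.finite(kern)) return(1e10)
    -kern
  }
  o <- .minimize_theta(fn, .theta_starts(family, fv$T, xbar))
  theta <- .par_to_theta(family, o$par)
  model <- capture_model(family, theta)
  pi0 <- cell_probabilities(model, fv$T)$pi[1]
  if (pi0 >= 1 - 1e-10)
    stop("estimated pi_g(0) is ~1: Horvitz-Thompson estimate unbounded")
  .cr_fit("conditional_likelihood", family,
          N_hat = round(fv$n / (1 - pi0)),
          theta_hat = .name_theta(family, theta),
          objective = conditional_log_likelihood(fv, model),
          converged = o$converged, n = fv$n, T = fv$T)
}
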