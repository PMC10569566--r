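# Percentile bootstrap confidence intervals for the population size, by
# resampling from the fitted model (parametric) or from the estimated
# population of individuals (bootstrap of individuals).  Either scheme can
# be combined with any of the three estimators.

# Refit the chosen estimator on a replicate frequency vector.  `ref`
# warm-starts min-chi-square refits at the original fit's theta (fast
# single-start path); likelihood refits are cheap enough without it.
.refit <- function(fv, estimator, family, C, ref = NULL) {
  switch(estimator,
    min_chisq = if (is.null(ref))
      fit_min_chisq(pool_tail(fv, C), family)
    else
      fit_min_chisq(pool_tail(fv, C), family,
                    start = as.numeric(ref$theta_hat), fast = TRUE),
    full_likelihood = fit_full(fv, family),
    conditional_likelihood = fit_conditional(fv, family),
    stop("unknown estimator '", estimator, "'"))
}

# Frequency vector from sighting counts (zeros already dropped).
.counts_to_fv <- function(counts, T) {
  frequency_vector(tabulate(counts, nbins = T), T)
}

.new_bootstrap <- function(scheme, estimator, family, C, m, estimates,
                           failures, seed) {
  estimates <- as.integer(round(estimates))
  qs <- stats::quantile(estimates, c(0.025, 0.5, 0.975), names = FALSE,
                        type = 7)
  structure(list(scheme = scheme, estimator = estimator, family = family,
                 C = C, m = m, estimates = estimates,
                 ci_low = as.integer(round(qs[1])),
                 ci_high = as.integer(round(qs[3])),
                 median = as.integer(round(qs[2])),
                 failures = failures,
                 unreliable = failures > 0.2 * m, seed = seed),
            class = "cr_bootstrap")
}

#' @export
print.cr_bootstrap <- function(x, ...) {
  cat(sprintf("%s bootstrap (%s estimator%s), m = %d replicates\n",
              switch(x$scheme, parametric = "Parametric",
                     individuals = "Individuals"),
              x$estimator,
              if (!is.na(x$C)) sprintf(", C = %d", x$C) else "", x$m))
  cat(sprintf("  95%% CI for N: [%d, %d]  (median N* = %d, width = %d)\n",
              x$ci_low, x$ci_high, x$median, x$ci_high - x$ci_low))
  if (x$failures > 0)
    cat("  failed replicates:", x$failures,
        if (x$unreliable) " -- FLAGGED UNRELIABLE (> 20%)" else "", "\n")
  invisible(x)
}

# Shared replicate loop: `draw()` must return a frequency vector (or NULL
# when a redraw budget is exhausted).
.bootstrap_loop <- function(draw, m, estimator, family, C, ref = NULL) {
  est <- numeric(0)
  failures <- 0L
  for (j in seq_len(m)) {
    fvb <- NULL
    for (k in 1:10) {  # redraw all-zero replicates a bounded number of times
      fvb <- tryCatch(draw(), error = function(e) NULL)
      if (!is.null(fvb)) break
    }
    fit <- if (is.null(fvb)) NULL else
      tryCatch(suppressWarnings(.refit(fvb, estimator, family, C, ref)),
               error = function(e) NULL)
    if (is.null(fit)) failures <- failures + 1L
    else est <- c(est, fit$N_hat)
  }
  if (length(est) == 0)
    stop("every bootstrap replicate failed to refit")
  list(estimates = est, failures = failures)
}

#' Parametric bootstrap confidence interval for N
#'
#' Resamples from the fitted model: each replicate draws \eqn{\hat N}
#' capture probabilities \eqn{p_i} from \eqn{g(p; \hat\theta)}, sighting
#' counts \eqn{B_i \sim \mathrm{Binomial}(T, p_i)}, discards the never-seen
#' individuals (\eqn{B_i = 0}), and re-estimates \eqn{N} with the chosen
#' estimator (same pooling \eqn{C} as the original fit for the minimum
#' chi-square estimator).  The 95% interval is the 2.5th-97.5th percentile
#' range of the replicate estimates.
#'
#' @param fit A \code{"cr_fit"} carrying \eqn{\hat N} and
#'   \eqn{\hat\theta}.
#' @param family Heterogeneity family used for resampling and refitting;
#'   defaults to the fitted family.
#' @param T Number of occasions; defaults to the fitted value.
#' @param m Number of bootstrap replicates (paper-scale default 1000).
#' @param seed Optional integer seed.
#' @param estimator Which estimator to refit on each replicate; defaults
#'   to the method of \code{fit}.
#' @param C Pooling for min-chi-square refits; defaults to the fitted
#'   \code{C}.
#' @return An object of class \code{"cr_bootstrap"} with the replicate
#'   estimates, the percentile CI, the replicate median, and the count of
#'   failed replicates (failed refits are skipped and counted, never
#'   fabricated; more than 20% failures flags the result unreliable).
#' @export
parametric_bootstrap <- function(fit, family = fit$family, T = fit$T,
                                 m = 1000, seed = NULL,
                                 estimator = fit$method, C = fit$C) {
  stopifnot(inherits(fit, "cr_fit"), m >= 1)
  if (!is.null(seed)) set.seed(seed)
  model <- capture_model(family, as.numeric(fit$theta_hat))
  N <- fit$N_hat
  draw <- function() {
    p <- sample_capture_probabilities(model, N)
    B <- stats::rbinom(N, T, p)
    B <- B[B > 0]
    if (length(B) == 0) return(NULL)
    .counts_to_fv(B, T)
  }
  r <- .bootstrap_loop(draw, m, estimator, family, C,
                       ref = if (estimator == "min_chisq") fit)
  .new_bootstrap("parametric", estimator, family, C, m,
                 r$estimates, r$failures, seed)
}

#' Bootstrap of individuals confidence interval for N
#'
#' Resamples individuals from the estimated population: the population of
#' size \eqn{\hat N} is characterized by its sighting counts
#' (\eqn{\hat f_0 = \hat N - n} zeros, \eqn{f_1} ones, and so on); each
#' replicate draws \eqn{\hat N} counts from this multiset with
#' replacement, drops the zeros, and re-estimates \eqn{N}.  Less dependent
#' on the capture-probability model than the parametric scheme, since the
#' model is not used in the resampling step.
#'
#' @param fv The observed [frequency_vector].
#' @param fit A \code{"cr_fit"} giving \eqn{\hat N}.
#' @inheritParams parametric_bootstrap
#' @return An object of class \code{"cr_bootstrap"}; see
#'   [parametric_bootstrap()].
#' @export
bootstrap_individuals <- function(fv, fit, m = 1000, seed = NULL,
                                  estimator = fit$method,
                                  family = fit$family, C = fit$C) {
  stopifnot(inherits(fv, "frequency_vector"), inherits(fit, "cr_fit"))
  if (!is.null(seed)) set.seed(seed)
  N <- fit$N_hat
  f0 <- N - fv$n
  if (f0 < 0) stop("fit$N_hat is below n; cannot form the population")
  pop_counts <- c(f0, fv$f)  # multiset weights for sighting counts 0..T
  draw <- function() {
    B <- sample.int(fv$T + 1L, N, replace = TRUE,
                    prob = pop_counts / N) - 1L
    B <- B[B > 0]
    if (length(B) == 0) return(NULL)
    .counts_to_fv(B, fv$T)
  }
  r <- .bootstrap_loop(draw, m, estimator, family, C,
                       ref = if (estimator == "min_chisq") fit)
  .new_bootstrap("individuals", estimator, family, C, m,
                 r$estimates, r$failures, seed)
}
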