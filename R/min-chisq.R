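# Minimum chi-square estimation of population size: Pearson X^2 over the
# pooled sighting-count table (including the unobserved cell O_0 = N - n),
# partial minimization in theta, joint minimization, consonance sets by
# test inversion, and goodness-of-fit.

# X^2 for a given pooled probability vector q (length C, q[1] = unobserved
# cell).  For fixed q this is a N + c / N + const in N, which gives the
# closed-form continuous minimizer sqrt(c / a) used by .opt_N_chisq.
.x2_given_q <- function(observed, n, N, q) {
  O <- c(N - n, observed)
  E <- N * q
  sum((O - E)^2 / E)
}

.opt_N_chisq <- function(observed, n, q) {
  a <- (1 - q[1])^2 / q[1] + sum(q[-1])
  cc <- n^2 / q[1] + sum(observed^2 / q[-1])
  max(n, sqrt(cc / a))
}

.pooled_q <- function(model, pooled) {
  pool_probabilities(cell_probabilities(model, pooled$T), pooled)
}

#' Pearson chi-square statistic for a pooled table
#'
#' Evaluates
#' \deqn{X^2(N, \theta) = \sum_{i=0}^{C-1} \frac{(O_i - E_i(\theta))^2}
#'       {E_i(\theta)},}
#' where \eqn{O_0 = N - n} is the (hypothesized) count of unobserved
#' individuals, the remaining \eqn{O_i} are the pooled observed counts, and
#' \eqn{E_i(\theta) = N q_i(\theta)} with \eqn{q(\theta)} the pooled cell
#' probabilities under the capture model.
#'
#' @param pooled A \code{"pooled_counts"} table from [pool_tail()].
#' @param N Hypothesized population size, \eqn{\ge n}.
#' @param model A [capture_model].
#' @return The chi-square statistic (non-negative scalar).
#' @examples
#' pc <- pool_tail(stork_frequencies(), 5)
#' chisq_statistic(pc, 2439, capture_model("homogeneous", 0.1116))
#' @export
chisq_statistic <- function(pooled, N, model) {
  stopifnot(inherits(pooled, "pooled_counts"))
  if (N < pooled$n)
    stop("N must be at least n = ", pooled$n, " (O_0 = N - n < 0)")
  .x2_given_q(pooled$observed, pooled$n, N, .pooled_q(model, pooled))
}

#' Partial minimum chi-square statistic
#'
#' For a fixed \eqn{N}, minimizes \eqn{X^2(N, \theta)} over the family's
#' parameter domain, returning \eqn{\tilde\theta_N} and the partial minimum
#' chi-square statistic \eqn{X^2(N, \tilde\theta_N)}, which is
#' asymptotically \eqn{\chi^2_{C - 1 - d}} when \eqn{N} is the true
#' population size and the family is correctly specified.
#'
#' @inheritParams chisq_statistic
#' @param family Heterogeneity family, as in [capture_model()].
#' @param start Optional parameter vector (natural scale) used as an extra
#'   warm start.
#' @return List with \code{theta} (named, natural scale), \code{X2}, and
#'   \code{converged}.
#' @export
profile_theta <- function(pooled, N,
                          family = c("homogeneous", "beta", "logit_normal"),
                          start = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(pooled, "pooled_counts"))
  d <- if (family == "homogeneous") 1L else 2L
  if (pooled$C - 1L - d < 1L)
    stop("C - 1 - d must be >= 1 to fit this family at C = ", pooled$C)
  if (N < pooled$n) stop("N must be at least n = ", pooled$n)
  fn <- function(par) {
    m <- tryCatch(.model_from_par(family, par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    q <- .pooled_q(m, pooled)
    if (any(q <= 0)) return(1e10)
    .x2_given_q(pooled$observed, pooled$n, N, q)
  }
  xbar <- sum(seq_len(pooled$C - 1L) * pooled$observed) / pooled$n
  starts <- .theta_starts(family, pooled$T, xbar)
  if (!is.null(start))
    starts <- c(list(.theta_to_par(family, start)), starts)
  o <- .minimize_theta(fn, starts)
  list(theta = .name_theta(family, .par_to_theta(family, o$par)),
       X2 = o$value, converged = o$converged)
}

# Single-start partial minimization used inside warm-started refinement
# loops: the full multi-start of profile_theta is unnecessary one integer
# step away from an already-minimized neighbour.
.profile_warm <- function(pooled, N, family, start) {
  fn <- function(par) {
    m <- tryCatch(.model_from_par(family, par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    q <- .pooled_q(m, pooled)
    if (any(q <= 0)) return(1e10)
    .x2_given_q(pooled$observed, pooled$n, N, q)
  }
  o <- .minimize_theta(fn, list(.theta_to_par(family, start)),
                       reltol = 1e-10, polish = FALSE)
  list(theta = .name_theta(family, .par_to_theta(family, o$par)),
       X2 = o$value, converged = o$converged)
}

# Integer refinement: local descent on the profile X^2(N, theta_tilde_N)
# from a continuous minimizer, warm-starting theta at each step.
.refine_integer_N <- function(pooled, family, N0, theta0, n_probe = 5L) {
  prof <- function(N, st) .profile_warm(pooled, N, family, st)
  cand <- unique(pmax(pooled$n, round(N0) + (-n_probe):n_probe))
  fits <- lapply(cand, prof, st = theta0)
  i <- which.min(vapply(fits, `[[`, numeric(1), "X2"))
  N <- cand[i]; best <- fits[[i]]
  repeat {
    left <- if (N - 1L >= pooled$n) prof(N - 1L, best$theta) else NULL
    right <- prof(N + 1L, best$theta)
    if (!is.null(left) && left$X2 < best$X2) {
      N <- N - 1L; best <- left
    } else if (right$X2 < best$X2) {
      N <- N + 1L; best <- right
    } else break
  }
  list(N = N, fit = best)
}

#' Minimum chi-square fit of population size and model parameters
#'
#' Jointly minimizes \eqn{X^2(N, \theta)} over integer \eqn{N \ge n} and
#' \eqn{\theta}, giving the minimum chi-square estimator
#' \eqn{(\hat N, \hat\theta)}.  The search exploits that for fixed
#' \eqn{\theta}, \eqn{X^2} is of the form \eqn{aN + c/N + \mathrm{const}}
#' with closed-form continuous minimizer \eqn{\sqrt{c/a}}: a multi-start
#' continuous optimization over \eqn{\theta} alone is followed by local
#' integer refinement of \eqn{N} on the profile (ties broken toward the
#' smaller \eqn{N}).  The minimized statistic doubles as a (conservative)
#' goodness-of-fit measure for the capture-probability model, calibrated
#' against \eqn{\chi^2_{C-1-d}}.
#'
#' Cells with expected count below 5 at the minimizer trigger a warning:
#' the chi-square calibration assumes adequate cell counts.
#'
#' @inheritParams profile_theta
#' @param N_max Upper search bound for the integer population size
#'   (default \eqn{50n}); hitting it triggers a boundary warning.
#' @param start Optional extra warm start for \eqn{\theta} (natural
#'   scale).
#' @param fast Logical; \code{TRUE} runs a single warm start at reduced
#'   tolerance with a narrower integer refinement window.  Used by the
#'   bootstrap replicate refits, which are warm-started at the original
#'   fit; leave \code{FALSE} for primary analyses.
#' @return A \code{"cr_fit"} with \code{N_hat}, \code{theta_hat},
#'   \code{objective} (the minimized \eqn{X^2}), \code{df = C - 1 - d},
#'   and the goodness-of-fit \code{p_value}.
#' @examples
#' fit_min_chisq(pool_tail(stork_frequencies(), 4), "homogeneous")
#' @export
fit_min_chisq <- function(pooled,
                          family = c("homogeneous", "beta", "logit_normal"),
                          N_max = 50 * pooled$n, start = NULL,
                          fast = FALSE) {
  family <- match.arg(family)
  stopifnot(inherits(pooled, "pooled_counts"))
  d <- if (family == "homogeneous") 1L else 2L
  df <- pooled$C - 1L - d
  if (df < 1L)
    stop("C - 1 - d must be >= 1: family '", family,
         "' is not fittable at C = ", pooled$C)
  fn <- function(par) {
    m <- tryCatch(.model_from_par(family, par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    q <- .pooled_q(m, pooled)
    if (any(q <= 0)) return(1e10)
    N <- .opt_N_chisq(pooled$observed, pooled$n, q)
    if (N > N_max) N <- N_max
    .x2_given_q(pooled$observed, pooled$n, N, q)
  }
  xbar <- sum(seq_len(pooled$C - 1L) * pooled$observed) / pooled$n
  starts <- .theta_starts(family, pooled$T, xbar)
  if (!is.null(start)) starts <- c(list(.theta_to_par(family, start)), starts)
  if (fast) starts <- starts[1]
  o <- .minimize_theta(fn, starts,
                       reltol = if (fast) 1e-9 else 1e-12, polish = !fast)
  theta_c <- .par_to_theta(family, o$par)
  q_c <- .pooled_q(capture_model(family, theta_c), pooled)
  N_c <- min(.opt_N_chisq(pooled$observed, pooled$n, q_c), N_max)
  ref <- .refine_integer_N(pooled, family, N_c, theta_c,
                           n_probe = if (fast) 2L else 5L)
  if (ref$N >= N_max - 1L)
    warning("minimum chi-square search hit the upper bound N_max = ", N_max,
            "; the profile may be non-increasing (flat) in N")
  model_hat <- capture_model(family, as.numeric(ref$fit$theta))
  E <- ref$N * .pooled_q(model_hat, pooled)
  if (any(E < 5))
    warning("expected count below 5 in ", sum(E < 5),
            " cell(s); the chi-square calibration assumes all O_i >= 5")
  .cr_fit("min_chisq", family, ref$N, ref$fit$theta,
          objective = ref$fit$X2, df = df,
          p_value = stats::pchisq(ref$fit$X2, df, lower.tail = FALSE),
          converged = o$converged && ref$fit$converged,
          C = pooled$C, n = pooled$n, T = pooled$T)
}

#' Consonance set for the population size
#'
#' Inverts the partial minimum chi-square test: the \eqn{100(1-\alpha)\%}
#' consonance set for the true population size is
#' \deqn{R_{1-\alpha} = \{N : X^2(N, \tilde\theta_N) \le
#'       \chi^2_{\alpha, C-1-d}\}.}
#' The set may be empty: \eqn{1 - \alpha^*}, with
#' \eqn{\alpha^* = P(\chi^2_{C-1-d} \ge X^2(\hat N, \hat\theta))}, is the
#' smallest level with a nonempty set, and an empty set at a requested
#' level is reported as information (no model/N pair is consonant with the
#' data at that level), not as an error.  The profile is assumed unimodal
#' in \eqn{N} (checked empirically for these families); the set is
#' returned as a contiguous integer range found by bisection on each side
#' of \eqn{\hat N}.
#'
#' @inheritParams profile_theta
#' @param level Confidence level \eqn{1 - \alpha} in (0, 1).
#' @param fit Optional precomputed [fit_min_chisq()] result for the same
#'   pooled table and family (avoids refitting).
#' @param N_max Upper search bound for the set.
#' @return An object of class \code{"consonance_set"}: list with
#'   \code{level}, \code{df}, \code{lower}, \code{upper}, \code{accepted}
#'   (integer vector, empty when the set is empty), \code{empty},
#'   \code{alpha_star}, \code{N_hat}, \code{statistic} (the minimized
#'   \eqn{X^2}), and \code{crit}.
#' @examples
#' \donttest{
#' consonance_set_N(pool_tail(stork_frequencies(), 6), "beta", 0.95)
#' }
#' @export
consonance_set_N <- function(pooled,
                             family = c("homogeneous", "beta", "logit_normal"),
                             level = 0.95, fit = NULL,
                             N_max = 50 * pooled$n) {
  family <- match.arg(family)
  stopifnot(level > 0, level < 1)
  if (is.null(fit)) fit <- fit_min_chisq(pooled, family, N_max = N_max)
  df <- fit$df
  crit <- stats::qchisq(level, df)
  alpha_star <- stats::pchisq(fit$objective, df, lower.tail = FALSE)
  out <- structure(list(level = level, df = df, lower = NA_integer_,
                        upper = NA_integer_, accepted = integer(0),
                        empty = TRUE, alpha_star = alpha_star,
                        N_hat = fit$N_hat, statistic = fit$objective,
                        crit = crit),
                   class = "consonance_set")
  if (fit$objective > crit) return(out)
  prof <- function(N) .profile_warm(pooled, N, family,
                                    start = as.numeric(fit$theta_hat))$X2
  # lower edge: bisect on [n, N_hat] for the first accepted N
  lo <- if (prof(pooled$n) <= crit) pooled$n else {
    a <- pooled$n; b <- fit$N_hat
    while (b - a > 1L) {
      mid <- (a + b) %/% 2L
      if (prof(mid) <= crit) b <- mid else a <- mid
    }
    b
  }
  # upper edge: geometric expansion then bisection
  a <- fit$N_hat; b <- max(a + 1L, a)
  step <- max(1L, a %/% 10L)
  while (b < N_max && prof(min(b + step, N_max)) <= crit) {
    b <- min(b + step, N_max)
    step <- 2L * step
  }
  hi <- if (b >= N_max) N_max else {
    ub <- min(b + step, N_max)
    while (ub - b > 1L) {
      mid <- (b + ub) %/% 2L
      if (prof(mid) <= crit) b <- mid else ub <- mid
    }
    b
  }
  out$lower <- as.integer(lo)
  out$upper <- as.integer(hi)
  out$accepted <- seq.int(lo, hi)
  out$empty <- FALSE
  out
}

#' @export
print.consonance_set <- function(x, ...) {
  cat(sprintf("%.0f%% consonance set for the population size (df = %d)\n",
              100 * x$level, x$df))
  if (x$empty) {
    cat(sprintf("  EMPTY: minimal nonempty level is 1 - alpha* = %.4f\n",
                1 - x$alpha_star))
  } else {
    cat(sprintf("  accepted N: [%d, %d]  (N_hat = %d, X^2 = %.3f <= %.3f)\n",
                x$lower, x$upper, x$N_hat, x$statistic, x$crit))
  }
  invisible(x)
}

#' Consonance region for the heterogeneity parameters
#'
#' Grid-based test inversion for \eqn{\theta}: a point is accepted when
#' \eqn{X^2(N_\theta, \theta) \le \chi^2_{\alpha, C-1}}, where
#' \eqn{N_\theta = \arg\min_N X^2(N, \theta)} replaces the unknown true
#' population size.  Because \eqn{X^2(N_\theta, \theta) \le
#' X^2(N_t, \theta)}, the region is conservative: it contains the ideal
#' region built with the true \eqn{N_t}.  The reference degrees of freedom
#' are the pooled cell count minus one (no parameter is estimated under
#' the point null for \eqn{\theta}).
#'
#' @inheritParams profile_theta
#' @param level Confidence level in (0, 1).
#' @param theta_grid Matrix or data frame of candidate \eqn{\theta} values
#'   (one row per point, \code{d} columns), or a list of per-parameter
#'   vectors to be expanded into a full grid.
#' @return A data frame (class \code{"consonance_region"}) with the grid
#'   coordinates, \code{N_theta}, \code{X2}, and logical \code{accepted};
#'   attributes \code{level}, \code{df}, \code{crit}.  A warning is issued
#'   when no grid point is accepted (grid too coarse or region empty).
#' @export
consonance_region_theta <- function(pooled,
                                    family = c("homogeneous", "beta",
                                               "logit_normal"),
                                    level = 0.95, theta_grid) {
  family <- match.arg(family)
  stopifnot(inherits(pooled, "pooled_counts"), level > 0, level < 1)
  if (is.list(theta_grid) && !is.data.frame(theta_grid))
    theta_grid <- expand.grid(theta_grid)
  theta_grid <- as.matrix(theta_grid)
  d <- if (family == "homogeneous") 1L else 2L
  if (ncol(theta_grid) != d)
    stop("theta_grid must have ", d, " column(s) for family '", family, "'")
  df <- pooled$C - 1L
  crit <- stats::qchisq(level, df)
  res <- t(apply(theta_grid, 1L, function(th) {
    m <- tryCatch(capture_model(family, th), error = function(e) NULL)
    if (is.null(m)) return(c(NA_real_, Inf))
    q <- .pooled_q(m, pooled)
    Nc <- .opt_N_chisq(pooled$observed, pooled$n, q)
    cand <- unique(pmax(pooled$n, c(floor(Nc), ceiling(Nc))))
    x2 <- vapply(cand, function(N)
      .x2_given_q(pooled$observed, pooled$n, N, q), numeric(1))
    i <- which.min(x2)
    c(cand[i], x2[i])
  }))
  out <- data.frame(theta_grid, N_theta = res[, 1], X2 = res[, 2],
                    accepted = res[, 2] <= crit)
  colnames(out)[seq_len(d)] <- names(.name_theta(family, rep(0, d)))
  if (!any(out$accepted))
    warning("no grid point accepted at level ", level,
            ": grid may be too coarse to contain theta_hat")
  structure(out, level = level, df = df, crit = crit,
            class = c("consonance_region", "data.frame"))
}

#' Chi-square goodness-of-fit test of the capture-probability model
#'
#' Tests the fitted heterogeneity family using the minimized statistic
#' \eqn{X^2(\hat N, \hat\theta)} against \eqn{\chi^2_{C-1-d}}.  Because
#' \eqn{\hat N} is the most favourable population size for the model, the
#' test is conservative: its type-I error is slightly below the nominal
#' level.
#'
#' @param fit A \code{"cr_fit"} from [fit_min_chisq()].
#' @return An object of class \code{"htest"}.
#' @examples
#' gof_test(fit_min_chisq(pool_tail(stork_frequencies(), 6), "beta"))
#' @export
gof_test <- function(fit) {
  stopifnot(inherits(fit, "cr_fit"))
  if (fit$method != "min_chisq")
    stop("goodness-of-fit test requires a minimum chi-square fit")
  if (is.na(fit$df) || fit$df < 1L)
    stop("model not testable at this pooling: df = C - 1 - d < 1")
  structure(list(
    statistic = c("X-squared" = fit$objective),
    parameter = c(df = fit$df),
    p.value = fit$p_value,
    method = paste("Minimum chi-square goodness-of-fit test,",
                   fit$family, "capture-probability model (conservative)"),
    data.name = sprintf("pooled sighting counts, C = %d cells, n = %d",
                        fit$C, fit$n)),
    class = "htest")
}
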