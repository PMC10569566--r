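#' Capture-probability heterogeneity model
#'
#' Constructs a model for the distribution \eqn{g(p; \theta)} of individual
#' capture (sighting) probabilities in a closed population.  Three families
#' are supported: a degenerate point mass at a common \eqn{p}
#' (\code{"homogeneous"}, the classical M0 assumption), a beta distribution
#' (\code{"beta"}, giving beta-binomial sighting counts), and a logit-normal
#' distribution (\code{"logit_normal"}, where \eqn{\mathrm{logit}(p) \sim
#' N(\mu, \sigma^2)}).
#'
#' @param family One of \code{"homogeneous"}, \code{"beta"},
#'   \code{"logit_normal"}.
#' @param theta Numeric parameter vector: \code{p} for homogeneous
#'   (\eqn{0 < p \le 1}; \eqn{p = 1} is admitted as the degenerate
#'   certain-capture boundary), \code{c(alpha, beta)} (both positive) for
#'   beta, \code{c(mu, sigma)} (\eqn{\sigma > 0}) for logit-normal.
#'
#' @return An object of class \code{"capture_model"}: a list with elements
#'   \code{family}, \code{theta} (named), and \code{d} (parameter dimension).
#' @examples
#' capture_model("beta", c(1, 10))
#' capture_model("homogeneous", 0.11)
#' @export
capture_model <- function(family = c("homogeneous", "beta", "logit_normal"),
                          theta) {
  family <- match.arg(family)
  theta <- as.numeric(theta)
  d <- switch(family, homogeneous = 1L, beta = 2L, logit_normal = 2L)
  if (length(theta) != d)
    stop("family '", family, "' needs a parameter vector of length ", d,
         ", got ", length(theta))
  if (any(!is.finite(theta)))
    stop("non-finite parameter value in theta")
  switch(family,
    homogeneous = {
      if (theta[1] <= 0 || theta[1] > 1)
        stop("homogeneous capture probability must satisfy 0 < p <= 1")
      names(theta) <- "p"
    },
    beta = {
      if (any(theta <= 0))
        stop("beta parameters must satisfy alpha > 0, beta > 0")
      names(theta) <- c("alpha", "beta")
    },
    logit_normal = {
      if (theta[2] <= 0)
        stop("logit-normal scale must satisfy sigma > 0")
      names(theta) <- c("mu", "sigma")
    })
  structure(list(family = family, theta = theta, d = d),
            class = "capture_model")
}

#' @export
print.capture_model <- function(x, ...) {
  cat("Capture-probability model:", x$family, "\n")
  cat("  theta: ",
      paste(names(x$theta), "=", signif(x$theta, 5), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Gauss-Hermite nodes/weights via Golub-Welsch (eigen of the Jacobi matrix),
# cached per order.  Used only by the logit-normal quadrature.
.gauss_hermite <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(k - 1L)
    J <- matrix(0, k, k)
    J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
    e <- eigen(J, symmetric = TRUE)
    out <- list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
    cache[[key]] <<- out
    out
  }
})

# Logit-normal mixed-binomial cell probabilities.  With u = logit(p),
# pi(x) = E_{u ~ N(mu, sigma^2)} dbinom(x, T, plogis(u)); the substitution
# u = mu + sqrt(2) sigma z turns this into a Gauss-Hermite sum.  Order is
# doubled until successive approximations agree to `tol` per cell.
.pi_logit_normal <- function(mu, sigma, T, tol = 1e-9) {
  x <- 0:T
  eval_k <- function(k) {
    q <- .gauss_hermite(k)
    p <- stats::plogis(mu + sqrt(2) * sigma * q$nodes)
    M <- outer(x, p, function(xx, pp) stats::dbinom(xx, T, pp))
    as.vector(M %*% q$weights) / sqrt(pi)
  }
  k <- 60L
  v <- eval_k(k)
  repeat {
    k2 <- 2L * k
    v2 <- eval_k(k2)
    if (max(abs(v2 - v)) <= tol) break
    if (k2 >= 960L)
      stop("logit-normal quadrature failed to converge to ", tol,
           " for cells x = 0..", T, " at mu = ", mu, ", sigma = ", sigma)
    k <- k2
    v <- v2
  }
  v2
}

#' Marginal and conditional sighting-count probabilities
#'
#' Computes \eqn{\pi_g(x)}, the marginal probability that a randomly chosen
#' individual is sighted exactly \eqn{x} times over \eqn{T} occasions,
#' \deqn{\pi_g(x) = \int_0^1 \binom{T}{x} p^x (1-p)^{T-x}\, g(p;\theta)\, dp,}
#' for \eqn{x = 0, \dots, T}, together with the conditional probabilities
#' \eqn{\pi_g^c(x) = \pi_g(x) / \{1 - \pi_g(0)\}} given at least one
#' sighting.  The homogeneous family uses the binomial pmf, the beta family
#' the exact beta-binomial closed form
#' \eqn{\binom{T}{x} B(\alpha + x, \beta + T - x)/B(\alpha, \beta)}, and the
#' logit-normal family Gauss-Hermite quadrature (absolute cell tolerance
#' 1e-9, then renormalized to sum exactly to 1).
#'
#' @param model A [capture_model].
#' @param T Integer number of sampling occasions, \eqn{T \ge 2}.
#'
#' @return An object of class \code{"cell_probs"}: list with \code{T},
#'   \code{pi} (length \eqn{T+1}, cells \eqn{x = 0..T}), and
#'   \code{pi_conditional} (length \eqn{T}, cells \eqn{x = 1..T}).
#' @examples
#' cell_probabilities(capture_model("beta", c(1, 1)), T = 10)$pi  # all 1/11
#' @export
cell_probabilities <- function(model, T) {
  stopifnot(inherits(model, "capture_model"))
  T <- as.integer(T)
  if (T < 2) stop("need at least T = 2 sampling occasions")
  x <- 0:T
  pi <- switch(model$family,
    homogeneous = stats::dbinom(x, T, model$theta[["p"]]),
    beta = {
      a <- model$theta[["alpha"]]; b <- model$theta[["beta"]]
      exp(lchoose(T, x) + lbeta(a + x, b + T - x) - lbeta(a, b))
    },
    logit_normal = .pi_logit_normal(model$theta[["mu"]],
                                    model$theta[["sigma"]], T))
  pi <- pi / sum(pi)  # guard: downstream multinomial formulas assume exact mass 1
  out <- structure(list(T = T, pi = pi, pi_conditional = NULL),
                   class = "cell_probs")
  if (pi[1] < 1 - 1e-12)
    out$pi_conditional <- pi[-1] / (1 - pi[1])
  out
}

#' Conditional sighting-count probabilities
#'
#' Extracts \eqn{\pi_g^c(x) = \pi_g(x)/\{1 - \pi_g(0)\}}, \eqn{x = 1..T},
#' the cell probabilities conditional on being sighted at least once.
#'
#' @param cp A \code{"cell_probs"} object from [cell_probabilities()].
#' @return Numeric vector of length \code{cp$T} summing to 1.
#' @export
conditional_probabilities <- function(cp) {
  stopifnot(inherits(cp, "cell_probs"))
  if (cp$pi[1] >= 1 - 1e-12)
    stop("degenerate model: pi_g(0) ~ 1, no individual is observable")
  cp$pi[-1] / (1 - cp$pi[1])
}

#' Draw individual capture probabilities
#'
#' Draws i.i.d. capture probabilities from \eqn{g(p;\theta)}.  For the
#' homogeneous family this is the constant \eqn{p} repeated (a point mass,
#' not an error).
#'
#' @param model A [capture_model].
#' @param count Number of draws, \eqn{\ge 1}.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return Numeric vector of length \code{count} with values in (0, 1]
#'   (logit-normal draws are in the open interval).
#' @export
sample_capture_probabilities <- function(model, count, seed = NULL) {
  stopifnot(inherits(model, "capture_model"), count >= 1)
  if (!is.null(seed)) set.seed(seed)
  switch(model$family,
    homogeneous = rep(model$theta[["p"]], count),
    beta = stats::rbeta(count, model$theta[["alpha"]], model$theta[["beta"]]),
    logit_normal = stats::plogis(
      stats::rnorm(count, model$theta[["mu"]], model$theta[["sigma"]])))
}

#' @export
print.cell_probs <- function(x, ...) {
  cat("Sighting-count cell probabilities, T =", x$T, "occasions\n")
  print(stats::setNames(signif(x$pi, 5), paste0("x=", 0:x$T)))
  invisible(x)
}
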