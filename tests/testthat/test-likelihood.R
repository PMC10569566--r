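test_that("conditional log-likelihood evaluates the multinomial pmf", {
  fv <- frequency_vector(c(1, 1), T = 2)
  m <- capture_model("homogeneous", 0.5)
  # pi_c = (2/3, 1/3); coefficient choose(2,1) = 2
  expect_equal(conditional_log_likelihood(fv, m),
               log(2) + log(2 / 3) + log(1 / 3))
  # general cross-check against dmultinom
  m2 <- capture_model("beta", c(1.02, 14))
  pic <- conditional_probabilities(cell_probabilities(m2, 10))
  expect_equal(conditional_log_likelihood(stork, m2),
               stats::dmultinom(stork$f, prob = pic, log = TRUE))
})

test_that("full log-likelihood equals the complete multinomial pmf", {
  m <- capture_model("beta", c(1, 10))
  N <- 3000
  pi <- cell_probabilities(m, 10)$pi
  expect_equal(full_log_likelihood(stork, N, m),
               stats::dmultinom(c(N - stork$n, stork$f), prob = pi,
                                log = TRUE))
  expect_error(full_log_likelihood(stork, 100, m), "at least n")
})

test_that("everyone-seen-every-time data drive the full MLE to the boundary", {
  fv <- frequency_vector(c(0, 8), T = 2)
  fit <- fit_full(fv, "homogeneous")
  expect_equal(fit$N_hat, 8L)
  expect_gt(fit$theta_hat[["p"]], 0.99)
})

test_that("full-likelihood fit matches a brute-force profile oracle", {
  # oracle: exhaustive integer-N search, univariate optimization of p per N
  n <- stork$n
  prof <- function(N) {
    o <- stats::optimize(function(p)
      -full_log_likelihood(stork, N,
                           capture_model("homogeneous", p)),
      c(1e-4, 0.999))
    -o$objective
  }
  Ns <- n:(5 * n)
  vals <- vapply(Ns, prof, numeric(1))
  N_oracle <- Ns[which.max(vals)]
  fit <- fit_full(stork, "homogeneous")
  expect_lte(abs(fit$N_hat - N_oracle), 1)
  expect_equal(fit$objective, max(vals), tolerance = 1e-6)
  # profile over N at p_hat is unimodal on the searched range
  at_phat <- vapply(Ns, function(N)
    full_log_likelihood(stork, N,
                        capture_model("homogeneous", fit$theta_hat[["p"]])),
    numeric(1))
  expect_equal(sum(diff(sign(diff(at_phat))) != 0), 1)
})

test_that("Horvitz-Thompson estimate is n inflated by the sighting probability", {
  fit <- fit_conditional(stork, "beta")
  pi0 <- cell_probabilities(
    capture_model("beta", as.numeric(fit$theta_hat)), stork$T)$pi[1]
  expect_equal(fit$N_hat, round(stork$n / (1 - pi0)))
  expect_gte(fit$N_hat, stork$n)
})

test_that("full and conditional fits agree asymptotically and recover truth", {
  # similar-results property on stork-like simulated data
  design <- simulation_design(N_true = 4000, T = 10, family = "beta",
                              theta_true = c(1, 10), replicates = 15,
                              seed = 202)
  rel_diff <- vapply(seq_len(design$replicates), function(i) {
    fv <- generate_dataset(design, chisqcr:::.split_seed(design$seed, i))
    a <- fit_full(fv, "beta")$N_hat
    b <- fit_conditional(fv, "beta")$N_hat
    abs(a - b) / b
  }, numeric(1))
  expect_gte(mean(rel_diff < 0.02), 0.95)
  # parameter recovery under a homogeneous truth
  design2 <- simulation_design(N_true = 2000, T = 10, family = "homogeneous",
                               theta_true = 0.3, replicates = 25, seed = 77)
  ok <- vapply(seq_len(design2$replicates), function(i) {
    fv <- generate_dataset(design2, chisqcr:::.split_seed(design2$seed, i))
    a <- fit_full(fv, "homogeneous")
    b <- fit_conditional(fv, "homogeneous")
    all(abs(c(a$theta_hat, b$theta_hat) - 0.3) < 0.02) &&
      all(abs(c(a$N_hat, b$N_hat) / 2000 - 1) < 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
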