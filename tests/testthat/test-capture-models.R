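test_that("constructor validates family and parameter domains", {
  expect_s3_class(capture_model("beta", c(1, 10)), "capture_model")
  expect_equal(capture_model("homogeneous", 0.3)$d, 1L)
  expect_equal(capture_model("logit_normal", c(-2, 0.5))$d, 2L)
  expect_error(capture_model("homogeneous", 0), "0 < p")
  expect_error(capture_model("homogeneous", 1.2), "0 < p")
  expect_error(capture_model("beta", c(-1, 2)), "alpha > 0")
  expect_error(capture_model("logit_normal", c(0, 0)), "sigma > 0")
  expect_error(capture_model("beta", 1), "length 2")
})

test_that("closed-form cell probabilities match binomial/beta-binomial identities", {
  cp <- cell_probabilities(capture_model("homogeneous", 0.5), T = 2)
  expect_equal(cp$pi, c(0.25, 0.5, 0.25))
  # uniform p (beta(1,1)) gives discrete-uniform sighting counts
  cp <- cell_probabilities(capture_model("beta", c(1, 1)), T = 10)
  expect_equal(cp$pi, rep(1 / 11, 11))
})

test_that("cell probabilities are a proper distribution for every family", {
  models <- list(
    capture_model("homogeneous", 0.11),
    capture_model("homogeneous", 0.9),
    capture_model("beta", c(1, 10)),
    capture_model("beta", c(0.5, 0.5)),
    capture_model("logit_normal", c(-2.3, 0.5)),
    capture_model("logit_normal", c(0, 2)))
  for (m in models) for (T in c(2, 10)) {
    cp <- cell_probabilities(m, T)
    expect_length(cp$pi, T + 1)
    expect_true(all(cp$pi > 0))
    expect_equal(sum(cp$pi), 1, tolerance = 1e-10)
    expect_equal(sum(conditional_probabilities(cp)), 1, tolerance = 1e-10)
  }
})

test_that("beta-binomial closed form equals direct numerical integration", {
  T <- 10
  for (a in c(0.5, 1, 2, 10)) for (b in c(0.5, 1, 2, 10)) {
    closed <- cell_probabilities(capture_model("beta", c(a, b)), T)$pi
    direct <- integrate_cells(function(p) stats::dbeta(p, a, b), T)
    expect_equal(closed, direct, tolerance = 1e-8,
                 label = sprintf("beta(%g, %g)", a, b))
  }
})

test_that("logit-normal quadrature matches a Monte-Carlo mixture oracle", {
  T <- 10
  mu <- -2.3; sigma <- 0.5
  cp <- cell_probabilities(capture_model("logit_normal", c(mu, sigma)), T)
  set.seed(42)
  M <- 1e6
  p <- stats::plogis(stats::rnorm(M, mu, sigma))
  counts <- tabulate(stats::rbinom(M, T, p) + 1L, nbins = T + 1)
  phat <- counts / M
  se <- sqrt(phat * (1 - phat) / M)
  # empty cells get a rule-of-three bound instead of a degenerate SE
  tol <- ifelse(counts == 0, 3 / M, 3 * se)
  expect_true(all(abs(cp$pi - phat) <= tol))
})

test_that("logit-normal collapses to homogeneous as sigma -> 0", {
  mu <- -1.5
  ln <- cell_probabilities(capture_model("logit_normal", c(mu, 1e-4)), 10)
  hom <- cell_probabilities(capture_model("homogeneous", stats::plogis(mu)), 10)
  expect_equal(ln$pi, hom$pi, tolerance = 1e-4)
})

test_that("beta(1,10) sighting-count probabilities decrease in x", {
  pi <- cell_probabilities(capture_model("beta", c(1, 10)), 10)$pi
  expect_true(all(diff(pi) < 0))
})

test_that("conditional probabilities normalize and flag degenerate models", {
  cp <- cell_probabilities(capture_model("homogeneous", 0.5), 2)
  expect_equal(conditional_probabilities(cp), c(2 / 3, 1 / 3))
  # direct normalization of an arbitrary valid distribution
  cp2 <- cell_probabilities(capture_model("beta", c(2, 1)), 2)
  expect_equal(conditional_probabilities(cp2), cp2$pi[-1] / (1 - cp2$pi[1]))
  # an essentially-invisible population is not conditionable
  cp3 <- cell_probabilities(capture_model("homogeneous", 1e-15), 2)
  expect_error(conditional_probabilities(cp3), "degenerate")
})

test_that("capture-probability sampling honours the family and the seed", {
  m_hom <- capture_model("homogeneous", 0.11)
  expect_equal(sample_capture_probabilities(m_hom, 3), rep(0.11, 3))
  m_beta <- capture_model("beta", c(1, 10))
  x <- sample_capture_probabilities(m_beta, 1e5, seed = 7)
  se <- sqrt(1 / 11 * 10 / 11 / (1 + 1 + 10) / 1e5) * 3  # 3 SE of the mean
  expect_lt(abs(mean(x) - 1 / 11), 3 * stats::sd(x) / sqrt(1e5))
  expect_identical(x, sample_capture_probabilities(m_beta, 1e5, seed = 7))
  y <- sample_capture_probabilities(capture_model("logit_normal", c(-2, 1)),
                                    1000, seed = 1)
  expect_true(all(y > 0 & y < 1))
})
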