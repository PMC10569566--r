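test_that("chi-square statistic is zero iff observed equals expected", {
  # beta(1,1), T = 2 gives pi = (1/3, 1/3, 1/3); with n = 20, N = 30 the
  # expected counts integer-match O = (10, 10, 10)
  fv <- frequency_vector(c(10, 10), T = 2)
  pooled <- pool_tail(fv, 3)
  m <- capture_model("beta", c(1, 1))
  expect_equal(chisq_statistic(pooled, 30, m), 0)
  expect_gt(chisq_statistic(pooled, 40, m), 0)
  expect_error(chisq_statistic(pooled, 10, m), "at least n")
})

test_that("partial minimization matches a dense grid oracle (homogeneous)", {
  pooled <- pool_tail(stork, 5)
  for (N in c(2000, 2439, 3000)) {
    pr <- profile_theta(pooled, N, "homogeneous")
    grid <- seq(0.001, 0.999, by = 1e-4)
    x2 <- vapply(grid, function(p)
      chisq_statistic(pooled, N, capture_model("homogeneous", p)),
      numeric(1))
    expect_equal(pr$X2, min(x2), tolerance = 1e-3)
    # argmin dominates random probes
    set.seed(5)
    probes <- stats::runif(100, 0.01, 0.6)
    for (p in probes)
      expect_lte(pr$X2,
                 chisq_statistic(pooled, N, capture_model("homogeneous", p))
                 + 1e-8)
  }
})

test_that("joint minimizer agrees with exhaustive search on a toy instance", {
  fv <- frequency_vector(c(20, 9, 4, 1), T = 4)
  pooled <- pool_tail(fv, 4)
  n <- fv$n
  p_grid <- seq(1e-4, 0.9999, by = 1e-4)
  # X^2(N, p) for all p at fixed N, vectorized over the grid
  pi_mat <- vapply(p_grid, function(p)
    stats::dbinom(0:4, 4, p), numeric(5))
  q_mat <- rbind(pi_mat[1, ], pi_mat[2, ], pi_mat[3, ],
                 pi_mat[4, ] + pi_mat[5, ])
  O_obs <- pooled$observed
  best <- c(N = NA, X2 = Inf)
  for (N in n:(20 * n)) {
    E <- N * q_mat
    x2 <- (N - n - E[1, ])^2 / E[1, ] + (O_obs[1] - E[2, ])^2 / E[2, ] +
      (O_obs[2] - E[3, ])^2 / E[3, ] + (O_obs[3] - E[4, ])^2 / E[4, ]
    i <- which.min(x2)
    if (x2[i] < best["X2"]) best <- c(N = N, X2 = x2[i])
  }
  fit <- fit_mcs_quiet(pooled, "homogeneous")
  expect_lte(abs(fit$N_hat - best["N"]), 1)
  expect_equal(fit$objective, unname(best["X2"]), tolerance = 1e-3)
})

test_that("global minimum dominates the N profile", {
  pooled <- pool_tail(stork, 6)
  fit <- fit_mcs_quiet(pooled, "beta")
  for (N in c(2000, 3000, 4046, 5000, 8000)) {
    pr <- profile_theta(pooled, N, "beta",
                        start = as.numeric(fit$theta_hat))
    expect_lte(fit$objective, pr$X2 + 1e-6)
  }
})

test_that("beta model fits the stork table almost perfectly at C = 4", {
  pr <- profile_theta(pool_tail(stork, 4), 4033, "beta")
  expect_lt(pr$X2, 0.01)
})

test_that("consonance sets are nested, contain N_hat, and flag emptiness", {
  pooled <- pool_tail(stork, 6)
  fit <- fit_mcs_quiet(pooled, "beta")
  cs <- lapply(c(0.80, 0.90, 0.95), function(lv)
    consonance_set_N(pooled, "beta", level = lv, fit = fit))
  for (s in cs) {
    expect_false(s$empty)
    expect_true(fit$N_hat >= s$lower && fit$N_hat <= s$upper)
  }
  expect_true(cs[[1]]$lower >= cs[[2]]$lower && cs[[1]]$upper <= cs[[2]]$upper)
  expect_true(cs[[2]]$lower >= cs[[3]]$lower && cs[[2]]$upper <= cs[[3]]$upper)
  # below 1 - alpha* the set must be empty: homogeneous stork fits terribly
  hom_fit <- fit_mcs_quiet(pool_tail(stork, 5), "homogeneous")
  cs_hom <- consonance_set_N(pool_tail(stork, 5), "homogeneous",
                             level = 0.95, fit = hom_fit)
  expect_true(cs_hom$empty)
  expect_lt(1 - cs_hom$alpha_star, 1)
  expect_length(cs_hom$accepted, 0)
  # requesting a level below 1 - alpha* of a good fit also empties the set
  low <- consonance_set_N(pooled, "beta",
                          level = (1 - fit$p_value) * 0.5, fit = fit)
  expect_true(low$empty)
})

test_that("consonance sets cover the true N at close to nominal rate", {
  # large population, no pooling: the chi-square calibration is accurate
  design <- simulation_design(N_true = 10000, T = 10, family = "beta",
                              theta_true = c(1, 10), C = 11,
                              replicates = 40, seed = 913)
  covered <- vapply(seq_len(design$replicates), function(i) {
    fv <- generate_dataset(design, chisqcr:::.split_seed(design$seed, i))
    pooled <- pool_tail(fv, design$C)
    cs <- suppressWarnings(consonance_set_N(pooled, "beta", level = 0.95))
    !cs$empty && cs$lower <= design$N_true && design$N_true <= cs$upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("theta consonance region is conservative and centred on theta_hat", {
  pooled <- pool_tail(stork, 6)
  fit <- fit_mcs_quiet(pooled, "beta")
  grid <- list(alpha = seq(0.6, 1.6, length.out = 9),
               beta = seq(8, 22, length.out = 9))
  r95 <- consonance_region_theta(pooled, "beta", 0.95, grid)
  r90 <- consonance_region_theta(pooled, "beta", 0.90, grid)
  expect_true(any(r95$accepted))
  # nestedness on the same grid
  expect_true(all(r95$accepted[r90$accepted]))
  # the region accepts the grid point nearest theta_hat
  i <- which.min((r95$alpha - fit$theta_hat[["alpha"]])^2 +
                   (r95$beta - fit$theta_hat[["beta"]])^2)
  expect_true(r95$accepted[i])
  # conservative: contains the ideal region built with the true N
  design <- simulation_design(N_true = 4000, T = 10, family = "beta",
                              theta_true = c(1, 10), C = 6,
                              replicates = 1, seed = 31)
  fvs <- generate_dataset(design)
  ps <- pool_tail(fvs, 6)
  grid_s <- expand.grid(alpha = seq(0.5, 2, length.out = 7),
                        beta = seq(5, 20, length.out = 7))
  cons <- consonance_region_theta(ps, "beta", 0.95, grid_s)
  crit <- stats::qchisq(0.95, ps$C - 1)
  ideal <- apply(grid_s, 1, function(th)
    chisq_statistic(ps, design$N_true,
                    capture_model("beta", th)) <= crit)
  expect_true(all(cons$accepted[ideal]))
})

test_that("goodness-of-fit test reports the conservative chi-square p-value", {
  fit6 <- fit_mcs_quiet(pool_tail(stork, 6), "beta")
  g <- gof_test(fit6)
  expect_s3_class(g, "htest")
  expect_equal(unname(g$parameter), 3)
  expect_equal(g$p.value,
               stats::pchisq(fit6$objective, 3, lower.tail = FALSE))
  # degenerate statistic: perfect fit has p-value 1
  fv <- frequency_vector(c(10, 10), T = 2)
  fit0 <- fit_mcs_quiet(pool_tail(fv, 3), "homogeneous")
  expect_gte(gof_test(fit0)$p.value, stats::pchisq(fit0$objective, 1,
                                                   lower.tail = FALSE))
  # not testable when C - 1 - d < 1
  expect_error(fit_min_chisq(pool_tail(stork, 3), "beta"), "C - 1 - d")
  expect_error(gof_test(fit_full(stork, "beta")), "minimum chi-square")
})

test_that("small expected counts trigger the documented warning", {
  expect_warning(fit_min_chisq(pool_tail(stork, 7), "homogeneous"),
                 "expected count below 5")
})
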