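# Synthetic capture-recapture data and the simulation harnesses: the
# chi-square-approximation QQ study, the bootstrap coverage/geometry
# study, and a bias/RMSE comparison harness.

# Deterministic per-replicate seed splitting from a master seed, kept
# below 2^31 - 1 so it is always a valid R integer seed.
.split_seed <- function(master, i) {
  as.integer((as.double(master) * 1000003 + 7919 * as.double(i)) %%
               2147483647)
}

#' Simulation design
#'
#' Bundles the stated world of a simulation: true population size, number
#' of occasions, capture-probability family and true parameters, pooling,
#' replicate count, and master seed.  The defaults are the conditions of
#' the reference simulation study: \eqn{N = 4000}, \eqn{T = 10},
#' beta(1, 10) heterogeneity (which produces stork-like sighting
#' frequencies, mass concentrated at low counts).
#'
#' @param N_true True population size.
#' @param T Number of sampling occasions.
#' @param family Heterogeneity family.
#' @param theta_true True parameter vector.
#' @param C Total cells (including the unobserved cell) for pooled fits.
#' @param replicates Number of replicate datasets.
#' @param seed Master seed; every replicate derives its own seed from it.
#' @return An object of class \code{"simulation_design"}.
#' @export
simulation_design <- function(N_true = 4000, T = 10, family = "beta",
                              theta_true = c(1, 10), C = 6,
                              replicates = 200, seed = 1) {
  model <- capture_model(family, theta_true)  # validates family/theta
  stopifnot(replicates >= 1, N_true >= 1)
  structure(list(N_true = as.integer(N_true), T = as.integer(T),
                 family = model$family, theta_true = model$theta,
                 C = as.integer(C), replicates = as.integer(replicates),
                 seed = as.integer(seed), model = model),
            class = "simulation_design")
}

# One synthetic frequency vector under the current RNG stream.
.simulate_fv <- function(N, T, model) {
  p <- sample_capture_probabilities(model, N)
  B <- stats::rbinom(N, T, p)
  B <- B[B > 0]
  if (length(B) == 0) return(NULL)
  frequency_vector(tabulate(B, nbins = T), T)
}

#' Generate one synthetic capture-recapture dataset
#'
#' Draws \code{N_true} capture probabilities from the design's model,
#' sighting counts \eqn{B_i \sim \mathrm{Binomial}(T, p_i)}, and returns
#' the frequency vector of the individuals seen at least once.  A
#' pathological draw with zero observed individuals is regenerated (with a
#' message) up to 100 times.
#'
#' @param design A [simulation_design()].
#' @param seed Seed for this dataset; defaults to the design's master
#'   seed.
#' @return A [frequency_vector].
#' @export
generate_dataset <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  for (k in 1:100) {
    fv <- .simulate_fv(design$N_true, design$T, design$model)
    if (!is.null(fv)) return(fv)
    message("generated dataset had zero observed individuals; regenerating")
  }
  stop("design is pathological: no individuals observed in 100 attempts")
}

#' Null-distribution QQ study for the partial minimum chi-square statistic
#'
#' Assesses the finite-sample accuracy of the \eqn{\chi^2_{C-1-d}}
#' calibration: each replicate simulates data under the design, pools to
#' \eqn{C} cells, minimizes \eqn{X^2(N_{true}, \theta)} over \eqn{\theta}
#' at the \emph{true} \eqn{N}, and records the partial minimum chi-square
#' statistic.  The returned sample can be QQ-plotted against the
#' theoretical quantiles; under the reference design the simulated
#' quantiles fall below the chi-square quantiles (the approximation is
#' conservative at this population size).
#'
#' @param design A [simulation_design()].
#' @return List with \code{statistics} (one value per successful
#'   replicate), \code{df}, \code{theoretical} (matching
#'   \eqn{\chi^2_{df}} quantiles at \code{ppoints}), and \code{failures}.
#' @export
qq_study <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design$model$d
  df <- design$C - 1L - d
  if (df < 1L) stop("design has C - 1 - d < 1: statistic undefined")
  stats_out <- numeric(0)
  failures <- 0L
  for (i in seq_len(design$replicates)) {
    fv <- generate_dataset(design, .split_seed(design$seed, i))
    res <- tryCatch(
      profile_theta(pool_tail(fv, design$C), design$N_true, design$family,
                    start = as.numeric(design$theta_true)),
      error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L
    else stats_out <- c(stats_out, res$X2)
  }
  s <- sort(stats_out)
  list(statistics = s, df = df,
       theoretical = stats::qchisq(stats::ppoints(length(s)), df),
       failures = failures)
}

#' Bootstrap coverage and geometry study
#'
#' For each of \code{design$replicates} simulated datasets: fit the
#' minimum chi-square estimator at the design's pooling, build a 95%
#' bootstrap interval (either scheme) with \code{m} replicates, and record
#' whether it covers the true \eqn{N} along with the replicate median
#' \eqn{N^*_M}.  The summary reports the empirical coverage and the
#' through-origin regression slope of \eqn{N^*_M} on \eqn{\hat N} (close
#' to 1 when the point estimate sits at the centre of its bootstrap
#' interval).
#'
#' @param design A [simulation_design()].
#' @param scheme \code{"parametric"} or \code{"individuals"}.
#' @param m Bootstrap replicates per dataset.
#' @return List with \code{table} (per-dataset data frame: \code{N_hat},
#'   \code{ci_low}, \code{ci_high}, \code{covered}, \code{N_med}),
#'   \code{coverage}, \code{slope}, and \code{failures} (datasets whose
#'   fit or bootstrap failed).
#' @export
coverage_study <- function(design, scheme = c("parametric", "individuals"),
                           m = 1000) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "simulation_design"))
  rows <- vector("list", design$replicates)
  failures <- 0L
  for (i in seq_len(design$replicates)) {
    seed_i <- .split_seed(design$seed, i)
    fv <- generate_dataset(design, seed_i)
    row <- tryCatch({
      fit <- suppressWarnings(fit_min_chisq(pool_tail(fv, design$C),
                                            design$family))
      bt <- suppressWarnings(
        if (scheme == "parametric")
          parametric_bootstrap(fit, m = m, seed = seed_i + 1L)
        else
          bootstrap_individuals(fv, fit, m = m, seed = seed_i + 1L))
      data.frame(dataset = i, N_hat = fit$N_hat, ci_low = bt$ci_low,
                 ci_high = bt$ci_high,
                 covered = bt$ci_low <= design$N_true &
                   design$N_true <= bt$ci_high,
                 N_med = bt$median)
    }, error = function(e) NULL)
    if (is.null(row)) failures <- failures + 1L
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("every dataset failed to fit")
  slope <- sum(tab$N_hat * tab$N_med) / sum(tab$N_hat^2)
  list(table = tab, coverage = mean(tab$covered), slope = slope,
       failures = failures)
}

#' Bias and RMSE comparison harness
#'
#' Runs each estimator on the same replicate datasets of each design and
#' tabulates mean bias and root mean-square error of \eqn{\hat N}.
#'
#' @param designs A [simulation_design()] or list of them.
#' @param estimators Character vector from \code{"min_chisq"},
#'   \code{"full_likelihood"}, \code{"conditional_likelihood"}.
#' @param fit_family Family assumed when fitting (defaults per design to
#'   the generating family; pass a different one to study
#'   misspecification).
#' @return Data frame with one row per (design, estimator): \code{N_true},
#'   \code{family}, \code{fit_family}, \code{estimator}, \code{n_ok},
#'   \code{bias}, \code{rmse}, \code{failures}.
#' @export
bias_rmse_study <- function(designs, estimators = "min_chisq",
                            fit_family = NULL) {
  if (inherits(designs, "simulation_design")) designs <- list(designs)
  out <- list()
  for (design in designs) {
    ffam <- if (is.null(fit_family)) design$family else fit_family
    datasets <- lapply(seq_len(design$replicates), function(i)
      generate_dataset(design, .split_seed(design$seed, i)))
    for (est in estimators) {
      N_hats <- vapply(datasets, function(fv) {
        fit <- tryCatch(
          suppressWarnings(.refit(fv, est, ffam, design$C)),
          error = function(e) NULL)
        if (is.null(fit)) NA_real_ else as.numeric(fit$N_hat)
      }, numeric(1))
      ok <- N_hats[!is.na(N_hats)]
      out[[length(out) + 1L]] <- data.frame(
        N_true = design$N_true, family = design$family, fit_family = ffam,
        estimator = est, n_ok = length(ok),
        bias = mean(ok) - design$N_true,
        rmse = sqrt(mean((ok - design$N_true)^2)),
        failures = sum(is.na(N_hats)))
    }
  }
  do.call(rbind, out)
}
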