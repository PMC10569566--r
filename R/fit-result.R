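# Fit-result container shared by all three estimators.

.cr_fit <- function(method, family, N_hat, theta_hat, objective,
                    df = NA_integer_, p_value = NA_real_, converged = TRUE,
                    C = NA_integer_, n, T) {
  structure(list(method = method, family = family,
                 N_hat = as.integer(round(N_hat)),
                 theta_hat = theta_hat, objective = objective,
                 df = df, p_value = p_value, converged = converged,
                 C = C, n = n, T = T),
            class = "cr_fit")
}

#' @export
print.cr_fit <- function(x, ...) {
  lab <- c(full_likelihood = "Full likelihood",
           conditional_likelihood = "Conditional likelihood (Horvitz-Thompson)",
           min_chisq = "Minimum chi-square")[x$method]
  cat(lab, "fit,", x$family, "capture-probability model\n")
  cat("  N_hat =", x$N_hat, " (n =", x$n, "observed, T =", x$T, "occasions)\n")
  cat("  theta_hat: ",
      paste(names(x$theta_hat), "=", signif(x$theta_hat, 4), collapse = ", "),
      "\n", sep = "")
  if (x$method == "min_chisq") {
    cat("  C =", x$C, "cells;  X^2 =", signif(x$objective, 5),
        " on df =", x$df, ";  GOF p-value =", format.pval(x$p_value), "\n")
  } else {
    cat("  log-likelihood =", signif(x$objective, 8), "\n")
  }
  if (!isTRUE(x$converged)) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

# Named theta vector for a family.
.name_theta <- function(family, theta) {
  stats::setNames(theta, switch(family,
    homogeneous = "p", beta = c("alpha", "beta"),
    logit_normal = c("mu", "sigma")))
}
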