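# Shared test fixtures and small utilities.

stork <- stork_frequencies()

# Quietly fit min chi-square (small-expected-count warnings are expected
# for the homogeneous stork fits and are tested separately).
fit_mcs_quiet <- function(pooled, family, ...) {
  suppressWarnings(fit_min_chisq(pooled, family, ...))
}

# Direct numerical integration of the binomial mixture integral over p,
# used as the independent oracle for the closed-form cell probabilities.
integrate_cells <- function(density, T, rel.tol = 1e-10) {
  vapply(0:T, function(x)
    stats::integrate(function(p)
      choose(T, x) * p^x * (1 - p)^(T - x) * density(p),
      0, 1, rel.tol = rel.tol)$value,
    numeric(1))
}

# Construct a pooled_counts object directly (used where the spec's toy
# examples are not reachable through pool_tail's preconditions).
make_pooled <- function(observed, boundaries, T) {
  structure(list(C = length(observed) + 1L, observed = observed,
                 boundaries = boundaries, n = sum(observed), T = T),
            class = "pooled_counts")
}
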