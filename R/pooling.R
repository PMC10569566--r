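#' Observed sighting-frequency vector
#'
#' Container for the observable frequencies \eqn{f^c = (f_1, \dots, f_T)'},
#' where \eqn{f_x} counts the individuals sighted exactly \eqn{x} times over
#' \eqn{T} occasions.  \eqn{f_0}, the number never sighted, is unobserved;
#' \eqn{n = \sum_x f_x} is the number of distinct individuals seen.
#'
#' @param f Integer vector of counts for \eqn{x = 1..T}.
#' @param T Number of occasions; defaults to \code{length(f)}.
#' @return An object of class \code{"frequency_vector"}: list with
#'   \code{f}, \code{T}, \code{n}.
#' @examples
#' frequency_vector(c(1021, 420, 166, 50, 20, 6, 1, 0, 0, 0))
#' @export
frequency_vector <- function(f, T = length(f)) {
  T <- as.integer(T)
  if (T < 2) stop("need at least T = 2 occasions")
  if (length(f) != T) stop("length(f) must equal T")
  if (any(f < 0) || any(f != round(f))) stop("counts must be non-negative integers")
  f <- as.integer(round(f))
  n <- sum(f)
  if (n < 1) stop("at least one individual must have been observed")
  structure(list(f = f, T = T, n = n), class = "frequency_vector")
}

#' @export
print.frequency_vector <- function(x, ...) {
  cat("Sighting frequencies over T =", x$T, "occasions (n =", x$n,
      "individuals observed)\n")
  print(stats::setNames(x$f, paste0("x=", 1:x$T)))
  invisible(x)
}

#' Reduce capture histories to a frequency vector
#'
#' Counts, for each \eqn{x = 1..T}, the individuals whose binary capture
#' history has row sum \eqn{x}.
#'
#' @param history Binary matrix, individuals in rows, occasions in columns.
#'   Every row must contain at least one 1 (unobserved individuals cannot
#'   appear in capture-recapture data).
#' @return A [frequency_vector].
#' @export
histories_to_frequencies <- function(history) {
  history <- as.matrix(history)
  if (!all(history %in% c(0, 1)))
    stop("capture-history entries must be 0 or 1")
  sums <- rowSums(history)
  if (any(sums == 0))
    stop("all-zero capture history in row(s) ",
         paste(utils::head(which(sums == 0), 5L), collapse = ", "),
         ": unobserved individuals cannot appear in the data")
  T <- ncol(history)
  frequency_vector(tabulate(sums, nbins = T), T)
}

#' Aggregate sampling occasions into blocks
#'
#' Collapses groups of raw occasions into aggregated occasions: an
#' individual is recorded as captured on an aggregated occasion if it was
#' captured at least once within the block (logical OR over the block's
#' columns).  Used, e.g., to reduce 80 daily sightings to \eqn{T = 10}
#' eight-day occasions.
#'
#' @param history Binary capture-history matrix.
#' @param blocks List of integer vectors partitioning the column indices.
#' @return Binary matrix with one column per block.
#' @seealso [equal_blocks()] for the default consecutive partition.
#' @export
aggregate_occasions <- function(history, blocks) {
  history <- as.matrix(history)
  idx <- sort(unlist(blocks))
  if (length(idx) != ncol(history) || any(idx != seq_len(ncol(history))))
    stop("blocks must partition the occasion indices 1..", ncol(history),
         " without overlap or gaps")
  out <- vapply(blocks,
                function(b) as.integer(rowSums(history[, b, drop = FALSE]) > 0),
                integer(nrow(history)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(history))
  out
}

#' Equal consecutive occasion blocks
#'
#' Partitions \code{n_occasions} raw occasions into \code{n_blocks}
#' consecutive blocks of equal size (e.g. 80 days into 10 blocks of 8).
#'
#' @param n_occasions Number of raw occasions.
#' @param n_blocks Number of aggregated occasions; must divide
#'   \code{n_occasions}.
#' @return List of integer index vectors suitable for
#'   [aggregate_occasions()].
#' @export
equal_blocks <- function(n_occasions, n_blocks) {
  if (n_occasions %% n_blocks != 0)
    stop("n_blocks must divide n_occasions for equal blocks")
  size <- n_occasions %/% n_blocks
  lapply(seq_len(n_blocks), function(i) ((i - 1L) * size + 1L):(i * size))
}

#' Pool the right tail of a frequency vector
#'
#' Builds a \eqn{C}-cell table from a frequency vector: the first
#' \eqn{C - 2} observed cells keep \eqn{f_1, \dots, f_{C-2}}, the last
#' observed cell merges the right tail \eqn{\sum_{x \ge C-1} f_x}, and one
#' further cell is reserved for the unobserved individuals (count
#' \eqn{O_0 = N - n}, unknown until \eqn{N} is specified).  Pooling avoids
#' zero and small cell counts in the chi-square statistic.
#'
#' @param fv A [frequency_vector].
#' @param C Total number of cells including the unobserved cell;
#'   \eqn{3 \le C \le T + 1}.
#' @return An object of class \code{"pooled_counts"}: list with \code{C},
#'   \code{observed} (length \eqn{C-1}), \code{boundaries} (list mapping
#'   each observed cell to the raw sighting counts it covers), \code{n},
#'   \code{T}.
#' @examples
#' pool_tail(stork_frequencies(), C = 4)$observed  # 1021 420 243
#' @export
pool_tail <- function(fv, C) {
  stopifnot(inherits(fv, "frequency_vector"))
  C <- as.integer(C)
  if (C - 1L < 2L || C - 1L > fv$T)
    stop("need 2 <= C - 1 <= T; got C = ", C, " with T = ", fv$T)
  keep <- seq_len(C - 2L)
  tail_idx <- (C - 1L):fv$T
  observed <- c(fv$f[keep], sum(fv$f[tail_idx]))
  boundaries <- c(as.list(keep), list(tail_idx))
  structure(list(C = C, observed = observed, boundaries = boundaries,
                 n = fv$n, T = fv$T),
            class = "pooled_counts")
}

#' @export
print.pooled_counts <- function(x, ...) {
  lab <- vapply(x$boundaries, function(b)
    if (length(b) == 1L) as.character(b)
    else paste0(b[1], "-", b[length(b)]), "")
  cat("Pooled sighting-count table, C =", x$C,
      "cells (one unobserved cell), n =", x$n, "\n")
  print(stats::setNames(x$observed, paste0("x=", lab)))
  invisible(x)
}

#' Pool cell probabilities to match a pooled table
#'
#' Maps marginal cell probabilities \eqn{\pi_g(0..T)} onto the \eqn{C}
#' cells of a pooled table: element 1 is \eqn{\pi_g(0)} (unobserved cell),
#' the remaining elements sum \eqn{\pi_g(x)} over each pooled class.
#'
#' @param cp A \code{"cell_probs"} object.
#' @param pooled A \code{"pooled_counts"} object with matching \code{T}.
#' @return Numeric vector of length \code{pooled$C} summing to 1.
#' @export
pool_probabilities <- function(cp, pooled) {
  stopifnot(inherits(cp, "cell_probs"), inherits(pooled, "pooled_counts"))
  if (cp$T != pooled$T)
    stop("cell probabilities are for T = ", cp$T,
         " but pooled counts are for T = ", pooled$T)
  obs <- vapply(pooled$boundaries,
                function(b) sum(cp$pi[b + 1L]), numeric(1))
  out <- c(cp$pi[1], obs)
  tot <- sum(out)
  if (abs(tot - 1) > 1e-12) out <- out / tot
  out
}
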