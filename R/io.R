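#' White stork sighting frequencies
#'
#' The observed sighting-frequency vector for 1684 white storks
#' (*Ciconia ciconia*) banded in their main European wintering area in
#' southwestern Spain, after aggregating 80 daily sampling occasions into
#' \eqn{T = 10} eight-day occasions: \eqn{f^c =}
#' (1021, 420, 166, 50, 20, 6, 1, 0, 0, 0).  The same data ship as a CSV
#' at \code{system.file("extdata", "stork_frequencies.csv", package =
#' "chisqcr")}.
#'
#' @return A [frequency_vector] with \eqn{T = 10}, \eqn{n = 1684}.
#' @examples
#' stork_frequencies()
#' @export
stork_frequencies <- function() {
  frequency_vector(c(1021L, 420L, 166L, 50L, 20L, 6L, 1L, 0L, 0L, 0L), 10L)
}

#' Read a frequency vector from CSV
#'
#' Expects two columns, \code{times_sighted} (1..T) and \code{count};
#' missing sighting counts are filled with zeros and \eqn{T} defaults to
#' the largest \code{times_sighted} present.
#'
#' @param path CSV file path.
#' @param T Number of occasions; overrides the inferred maximum (useful
#'   when the right tail is all zeros).
#' @return A [frequency_vector].
#' @export
read_frequency_csv <- function(path, T = NULL) {
  d <- utils::read.csv(path)
  if (nrow(d) == 0) stop("empty frequency file: ", path)
  need <- c("times_sighted", "count")
  if (!all(need %in% names(d)))
    stop("frequency CSV must have columns 'times_sighted' and 'count'")
  x <- d$times_sighted
  cnt <- d$count
  bad <- which(x != round(x) | x < 1 | cnt != round(cnt) | cnt < 0 |
                 !is.finite(x) | !is.finite(cnt))
  if (length(bad))
    stop("invalid row ", bad[1], " in ", path,
         ": times_sighted must be a positive integer and count a",
         " non-negative integer")
  dup <- which(duplicated(x))
  if (length(dup))
    stop("duplicate times_sighted value ", x[dup[1]], " at row ", dup[1],
         " in ", path)
  if (is.null(T)) T <- max(x)
  f <- integer(T)
  f[x] <- as.integer(cnt)
  frequency_vector(f, T)
}

#' Write a frequency vector to CSV
#'
#' @param fv A [frequency_vector].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_frequency_csv <- function(fv, path) {
  stopifnot(inherits(fv, "frequency_vector"))
  utils::write.csv(
    data.frame(times_sighted = seq_len(fv$T), count = fv$f),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capture-history matrix from CSV
#'
#' One row per individual, one column per occasion (header row of
#' occasion labels).  Any nonzero state code (e.g. habitat codes 1/2) is
#' mapped to 1 = detected; only presence/absence is modelled.
#'
#' @param path CSV file path.
#' @return Binary matrix suitable for [histories_to_frequencies()].
#' @export
read_history_csv <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) == 0) stop("empty capture-history file: ", path)
  m <- as.matrix(d)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0))
    stop("capture-history entries must be non-negative numeric state codes")
  m <- matrix(as.integer(m > 0), nrow = nrow(m),
              dimnames = dimnames(m))
  m
}

#' Read a flat analysis configuration file
#'
#' Minimal `key: value` parser (YAML-like, flat): comma-separated values
#' become vectors, and numeric-looking values are converted.  Lines
#' starting with `#` are comments.  Keys mirror the arguments of
#' [run_fit_command()].
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop("config line is not 'key: value': ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(nums))) nums else parts
  }
  out
}
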