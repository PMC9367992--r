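#' Per-pair summary statistics of match incident counts
#'
#' Container for the `(n, mean, sd)` triple that every relation test consumes:
#' the number of matches between a club pair (or in the pooled benchmark
#' group), the mean incidents per match, and the sample standard deviation
#' (`n - 1` denominator). With a single match the standard deviation is
#' undefined and stored as `NA`; `n = 0` marks the explicit "no matches"
#' state, which is distinct from matches that produced zero incidents.
#'
#' @param n Non-negative integer number of matches.
#' @param mean Mean incidents per match (`NA` when `n = 0`).
#' @param sd Sample standard deviation of incidents per match; `NA` when
#'   `n < 2`.
#' @return An object of class `summary_stats`.
#' @examples
#' summary_stats(2, 6, 1.414214)
#' summarize_counts(c(0, 0, 1, 1, 1, 2))
#' @export
summary_stats <- function(n, mean, sd) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L)
    stop_config("'n' must be a single non-negative integer")
  if (n == 0L) {
    mean <- NA_real_; sd <- NA_real_
  } else {
    mean <- as.numeric(mean)
    if (is.na(mean)) stop_config("'mean' must be given when n >= 1")
    sd <- as.numeric(sd)
    if (n == 1L) sd <- NA_real_
    if (!is.na(sd) && sd < 0) stop_config("'sd' must be non-negative")
  }
  structure(list(n = n, mean = mean, sd = sd), class = "summary_stats")
}

#' @rdname summary_stats
#' @param x Integer vector of per-match incident counts.
#' @export
summarize_counts <- function(x) {
  if (length(x) == 0L) return(summary_stats(0L, NA, NA))
  summary_stats(length(x), mean(x), if (length(x) > 1L) stats::sd(x) else NA)
}

#' @rdname summary_stats
#' @export
has_data <- function(x) {
  stopifnot(inherits(x, "summary_stats"))
  x$n > 0L
}

#' @export
print.summary_stats <- function(x, ...) {
  if (x$n == 0L) {
    cat("<summary_stats> no matches\n")
  } else {
    cat(sprintf("<summary_stats> n = %d, mean = %.6g, sd = %s\n",
                x$n, x$mean, if (is.na(x$sd)) "undefined" else sprintf("%.6g", x$sd)))
  }
  invisible(x)
}

as_summary_stats <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x)))
    return(summary_stats(x$n, x$mean, x$sd))
  stop_config("cannot interpret object as summary statistics")
}
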