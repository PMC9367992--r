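#' Reconstruct integer count vectors from printed summary statistics
#'
#' Published per-pair tables report only (mean, sample SD) at a fixed printed
#' precision. For small samples of non-negative integer counts those two
#' numbers often pin down the underlying per-match counts exactly. This
#' oracle searches exhaustively over sample sizes `n = 2..n_max` and
#' non-decreasing integer vectors with entries `<= count_max`, returning the
#' smallest `n` admitting a vector whose exact mean and SD print as the given
#' values.
#'
#' Printed values are matched by round-half-away-from-zero at the printed
#' decimal count (`convention = "round"`). Some printed means are truncated
#' rather than rounded; `convention = "truncate"` matches those, and
#' `"auto"` tries rounding first and falls back to truncation.
#'
#' Pass `mean` and `sd` as strings (e.g. `"0.833"`) to fix the printed
#' precision exactly; numeric input infers the decimal count from the
#' number's default decimal representation.
#'
#' @param mean,sd Printed mean and sample SD (strings preserve trailing
#'   zeros and printed precision).
#' @param n_max,count_max Search bounds (defaults comfortably above any row
#'   of the bundled tables).
#' @param convention `"round"`, `"truncate"` or `"auto"` (see Details).
#' @return An object of class `reconstruction`: `counts` (the canonical,
#'   lexicographically smallest solution at the minimal n), `n`,
#'   `achieved_mean`, `achieved_sd`, `unique_at_n`, `solutions` (all count
#'   vectors at the minimal n), `convention_used`, and `reconstructable`
#'   (`FALSE` with empty counts when no vector exists within the bounds).
#' @examples
#' reconstruct_counts("0.833", "0.752773")  # n = 6: 0,0,1,1,1,2
#' reconstruct_counts("6", "1.414214")      # n = 2: 5,7
#' @export
reconstruct_counts <- function(mean, sd, n_max = 40L, count_max = 40L,
                               convention = c("round", "truncate", "auto")) {
  convention <- match.arg(convention)
  if (n_max < 2L || count_max < 1L) stop_config("search bounds must be positive")
  m <- parse_printed(mean)
  s <- parse_printed(sd)
  if (s$value < 0) stop_config("printed sd must be non-negative")

  tried <- if (convention == "auto") c("round", "truncate") else convention
  for (conv in tried) {
    res <- reconstruct_search(m, s, n_max, count_max, conv)
    if (res$reconstructable) return(res)
  }
  res
}

parse_printed <- function(x) {
  if (is.character(x)) {
    str <- x
    value <- as.numeric(x)
  } else {
    value <- x
    str <- format(x, scientific = FALSE, trim = TRUE)
  }
  if (is.na(value)) stop_config("cannot parse printed value '%s'", x)
  digits <- if (grepl("\\.", str)) nchar(sub("^-?[0-9]*\\.", "", str)) else 0L
  list(value = value, digits = digits)
}

# Matching interval for a printed value under a convention. Values printed
# without decimals are taken as exact (tables that print SDs to six decimals
# print "2" only when the value is exactly 2); otherwise the interval is the
# half-open set of reals that would print as the value.
printed_band <- function(printed, conv) {
  if (printed$digits == 0L)
    return(list(lo = printed$value, hi = printed$value, exact = TRUE))
  ulp <- 10^(-printed$digits)
  switch(conv,
         round = list(lo = printed$value - ulp / 2,
                      hi = printed$value + ulp / 2, exact = FALSE),
         truncate = list(lo = printed$value, hi = printed$value + ulp,
                         exact = FALSE))
}

reconstruct_search <- function(m, s, n_max, count_max, conv) {
  mb <- printed_band(m, conv)
  sb <- printed_band(s, "round")  # printed SDs are consistently rounded
  sb$lo <- max(sb$lo, 0)
  for (n in 2:n_max) {
    # admissible integer sums for the mean band
    if (mb$exact) {
      tot <- mb$lo * n
      if (abs(tot - round(tot)) > 1e-9) next
      s_lo <- s_hi <- as.integer(round(tot))
    } else {
      s_lo <- ceiling(mb$lo * n - 1e-9)
      s_hi <- ceiling(mb$hi * n - 1e-9) - 1L   # sum < mb$hi * n
    }
    s_hi <- min(s_hi, n * count_max)
    s_lo <- max(s_lo, 0L)
    if (s_hi < s_lo) next
    solutions <- list()
    for (total in s_lo:s_hi) {
      # admissible integer sums of squares for the sd band:
      # var = (Q - total^2/n) / (n - 1)
      if (sb$exact) {
        qx <- (n - 1) * sb$lo^2 + total^2 / n
        if (abs(qx - round(qx)) > 1e-9) next
        q_lo <- q_hi <- as.integer(round(qx))
      } else {
        q_lo <- ceiling((n - 1) * sb$lo^2 + total^2 / n - 1e-9)
        q_hi <- floor((n - 1) * sb$hi^2 + total^2 / n - 1e-9)
      }
      if (q_hi < q_lo) next
      for (q in q_lo:q_hi) {
        found <- enumerate_vectors(n, total, q, count_max)
        for (v in found) {
          vv <- if (n > 1) (q - total^2 / n) / (n - 1) else 0
          sdv <- sqrt(max(vv, 0))
          ok <- if (sb$exact) abs(sdv - sb$lo) <= 1e-9
            else sdv >= sb$lo - 1e-12 && sdv < sb$hi - 1e-12
          if (ok) solutions[[length(solutions) + 1L]] <- v
        }
      }
    }
    if (length(solutions) > 0L) {
      ord <- order(vapply(solutions, function(v)
        paste(sprintf("%03d", v), collapse = ""), character(1)))
      solutions <- solutions[ord]
      counts <- solutions[[1]]
      return(structure(list(
        counts = counts, n = n,
        achieved_mean = mean(counts),
        achieved_sd = stats::sd(counts),
        unique_at_n = length(solutions) == 1L,
        solutions = solutions,
        convention_used = conv,
        reconstructable = TRUE,
        printed_mean = m, printed_sd = s
      ), class = "reconstruction"))
    }
  }
  structure(list(counts = integer(0), n = NA_integer_,
                 achieved_mean = NA_real_, achieved_sd = NA_real_,
                 unique_at_n = NA, solutions = list(),
                 convention_used = conv, reconstructable = FALSE,
                 printed_mean = m, printed_sd = s),
            class = "reconstruction")
}

# All non-decreasing vectors of length n with given sum and sum of squares,
# entries in [0, count_max]. Depth-first with sum/sum-of-squares pruning.
enumerate_vectors <- function(n, total, ssq, count_max) {
  out <- list()
  rec <- function(prefix, r, s_r, q_r, lo) {
    if (r == 0L) {
      if (s_r == 0L && q_r == 0L) out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    if (s_r < r * lo || s_r > r * count_max) return(invisible())
    # bounds on achievable remaining sum of squares
    if (q_r < s_r^2 / r - 1e-9) return(invisible())       # min at equal split
    if (q_r > s_r * count_max) return(invisible())        # x_i <= count_max
    v_hi <- min(count_max, s_r - lo * (r - 1L))
    if (v_hi < lo) return(invisible())
    for (v in lo:v_hi) {
      if (v * v > q_r) break
      rec(c(prefix, v), r - 1L, s_r - v, q_r - v * v, v)
    }
  }
  rec(integer(0), n, total, ssq, 0L)
  out
}

#' @export
print.reconstruction <- function(x, ...) {
  if (!x$reconstructable) {
    cat("<reconstruction> unreconstructable within search bounds\n")
  } else {
    cat(sprintf("<reconstruction> n = %d: {%s}%s\n", x$n,
                paste(x$counts, collapse = ", "),
                if (x$unique_at_n) " (unique)" else
                  sprintf(" (1 of %d at minimal n)", length(x$solutions))))
    cat(sprintf("  mean = %.6g, sd = %.6g (%s convention)\n",
                x$achieved_mean, x$achieved_sd, x$convention_used))
  }
  invisible(x)
}

#' Reconstruct every row of a printed summary table
#'
#' Applies [reconstruct_counts()] to each (mean, sd) row and optionally
#' recomputes the benchmark test p-value from the reconstruction.
#'
#' @param rows Tibble with character columns `mean` and `sd` (printed
#'   values); other columns are carried through.
#' @param benchmark Optional [summary_stats()]; when given, a one-tailed
#'   benchmark test p-value is recomputed from each reconstruction.
#' @inheritParams reconstruct_counts
#' @inheritParams welch_test
#' @return The input tibble plus columns `n`, `counts` (list column),
#'   `achieved_mean`, `achieved_sd`, `reconstructable`, and `p_recomputed`
#'   when a benchmark is supplied.
#' @export
reconstruct_table <- function(rows, benchmark = NULL, n_max = 40L,
                              count_max = 40L, convention = "auto",
                              sidedness = "one_tailed",
                              df_rule = "welch_satterthwaite") {
  recs <- lapply(seq_len(nrow(rows)), function(i)
    reconstruct_counts(rows$mean[i], rows$sd[i], n_max = n_max,
                       count_max = count_max, convention = convention))
  rows$n <- vapply(recs, function(r) r$n, integer(1))
  rows$counts <- lapply(recs, function(r) r$counts)
  rows$achieved_mean <- vapply(recs, function(r) r$achieved_mean, numeric(1))
  rows$achieved_sd <- vapply(recs, function(r) r$achieved_sd, numeric(1))
  rows$reconstructable <- vapply(recs, function(r) r$reconstructable, logical(1))
  if (!is.null(benchmark)) {
    rows$p_recomputed <- vapply(seq_len(nrow(rows)), function(i) {
      r <- recs[[i]]
      if (!r$reconstructable || r$n < 2L || r$achieved_sd == 0) return(NA_real_)
      welch_test(summarize_counts(r$counts), benchmark,
                 sidedness = sidedness, df_rule = df_rule)$p.value
    }, numeric(1))
  }
  rows
}
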