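#' Unequal-variance mean test against a pooled benchmark
#'
#' Tests whether a club pair's mean incidents per match differs from the
#' pooled benchmark mean, from summary statistics alone, assuming unequal
#' variances:
#' \deqn{t = \frac{\bar h_{ab} - \bar h_i}{\sqrt{s_{ab}^2/n_{ab} + s_i^2/n_i}}}
#'
#' Degrees of freedom follow the Welch--Satterthwaite approximation by
#' default (fractional df; the convention consistent with the published
#' per-pair p-values). The simpler additive rule
#' \eqn{(n_{ab}-1) + (n_i-1)} is available via `df_rule = "additive"`.
#'
#' The one-tailed p-value is the tail probability in the direction of the
#' observed difference. The p-value is undefined (`NA`) when the sample has
#' fewer than two matches or zero variance, mirroring the dashes in the
#' published tables for all-zero pairs.
#'
#' @param sample,benchmark [summary_stats()] objects (or lists with `n`,
#'   `mean`, `sd`).
#' @param sidedness `"one_tailed"` (directional, default) or `"two_tailed"`.
#' @param df_rule `"welch_satterthwaite"` (default) or `"additive"`.
#' @return An object of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @examples
#' pal <- summarize_counts(c(0, 0, 1, 1, 1, 2))
#' bench <- summary_stats(330, 2.28181800, 3.91970700)
#' welch_test(pal, bench)
#' @export
welch_test <- function(sample, benchmark,
                       sidedness = c("one_tailed", "two_tailed"),
                       df_rule = c("welch_satterthwaite", "additive")) {
  sidedness <- match.arg(sidedness)
  df_rule <- match.arg(df_rule)
  sample <- as_summary_stats(sample)
  benchmark <- as_summary_stats(benchmark)
  if (benchmark$n < 2L || is.na(benchmark$sd))
    stop_config("benchmark must have n >= 2 and a defined sd")

  undefined <- sample$n < 2L || is.na(sample$sd) || sample$sd == 0
  if (undefined && !(sample$sd %in% 0) ) {
    # n < 2: nothing at all can be computed
    stat <- NA_real_; df <- NA_real_; p <- NA_real_
  } else {
    v1 <- if (undefined) 0 else sample$sd^2 / sample$n
    v0 <- benchmark$sd^2 / benchmark$n
    stat <- (sample$mean - benchmark$mean) / sqrt(v1 + v0)
    df <- switch(df_rule,
      welch_satterthwaite = (v1 + v0)^2 /
        (v1^2 / (sample$n - 1L) + v0^2 / (benchmark$n - 1L)),
      additive = (sample$n - 1L) + (benchmark$n - 1L))
    p <- if (undefined) NA_real_ else welch_p(stat, df, sidedness)
  }
  structure(list(
    statistic = c(t = stat),
    parameter = c(df = df),
    p.value = p,
    estimate = c(`sample mean` = sample$mean, `benchmark mean` = benchmark$mean),
    method = sprintf("Benchmark-referenced unequal-variance mean test (%s, %s df)",
                     gsub("_", "-", sidedness), gsub("_", "-", df_rule)),
    data.name = sprintf("sample (n = %d) vs benchmark (n = %d)",
                        sample$n, benchmark$n),
    sidedness = sidedness, df_rule = df_rule
  ), class = "htest")
}

welch_p <- function(stat, df, sidedness) {
  p_dir <- stats::pt(-abs(stat), df)
  switch(sidedness,
         one_tailed = p_dir,
         two_tailed = min(1, 2 * p_dir))
}

#' Label an underlying relation from a p-value and a direction
#'
#' Applies the two-tier significance convention: `rivalry` when the pair mean
#' exceeds the benchmark and `p < alpha_weak`, `alliance` when it falls below,
#' `undefined` otherwise; tier `strong` for `p < alpha_strong`, `weak` for
#' `alpha_strong <= p < alpha_weak`.
#'
#' @param p_value P-value (may be `NA`).
#' @param direction `"above"`, `"below"` or `"none"` — the sign of the pair
#'   mean minus the benchmark mean.
#' @param alpha_strong,alpha_weak Significance tiers; `alpha_strong` must be
#'   below `alpha_weak`.
#' @return A list with `label` and `tier`.
#' @export
relation_label <- function(p_value, direction, alpha_strong = 0.05,
                           alpha_weak = 0.1) {
  if (alpha_strong >= alpha_weak)
    stop_config("alpha_strong must be smaller than alpha_weak")
  if (is.na(p_value) || direction == "none" || p_value >= alpha_weak)
    return(list(label = "undefined", tier = "none"))
  list(label = if (direction == "above") "rivalry" else "alliance",
       tier = if (p_value < alpha_strong) "strong" else "weak")
}

#' Classify the underlying relation of a club pair
#'
#' Runs [welch_test()] for a pair against the benchmark and labels the
#' outcome via [relation_label()].
#'
#' @inheritParams welch_test
#' @param pair [summary_stats()] for the club pair.
#' @inheritParams relation_label
#' @param head_a,head_b Optional club names carried into the result.
#' @return An object of class `underlying_relation`: a list with the pair
#'   names, `n`, `mean`, `sd`, `statistic`, `df`, `p_value`, `direction`,
#'   `label` and `tier`.
#' @export
classify_underlying <- function(pair, benchmark, alpha_strong = 0.05,
                                alpha_weak = 0.1,
                                sidedness = c("one_tailed", "two_tailed"),
                                df_rule = c("welch_satterthwaite", "additive"),
                                head_a = NA_character_, head_b = NA_character_) {
  sidedness <- match.arg(sidedness)
  df_rule <- match.arg(df_rule)
  pair <- as_summary_stats(pair)
  benchmark <- as_summary_stats(benchmark)
  if (!has_data(pair)) {
    lab <- list(label = "undefined", tier = "none")
    ht <- list(statistic = c(t = NA_real_), parameter = c(df = NA_real_),
               p.value = NA_real_)
    direction <- "none"
  } else {
    ht <- welch_test(pair, benchmark, sidedness = sidedness, df_rule = df_rule)
    direction <- if (is.na(ht$p.value)) "none"
      else if (pair$mean > benchmark$mean) "above"
      else if (pair$mean < benchmark$mean) "below"
      else "none"
    lab <- relation_label(ht$p.value, direction, alpha_strong, alpha_weak)
  }
  structure(list(
    head_a = head_a, head_b = head_b,
    n = pair$n, mean = pair$mean, sd = pair$sd,
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, direction = direction,
    label = lab$label, tier = lab$tier,
    alpha_strong = alpha_strong, alpha_weak = alpha_weak
  ), class = "underlying_relation")
}

#' @export
print.underlying_relation <- function(x, ...) {
  cat(sprintf("<underlying_relation> %s vs %s: %s (%s)\n",
              x$head_a, x$head_b, x$label, x$tier))
  cat(sprintf("  n = %d, mean = %.4g, p = %s\n", x$n, x$mean,
              if (is.na(x$p_value)) "-" else format(x$p_value, digits = 5)))
  invisible(x)
}
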