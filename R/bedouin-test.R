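#' Test the Bedouin syndrome on declared alliances
#'
#' The full second-step procedure: for every (head, declared partner)
#' interaction with match data, the pair's mean incidents per match is tested
#' against the pooled benchmark ([classify_underlying()]); the observed
#' alliance/rivalry label is then compared with the relation the transitive
#' friend/enemy premises predict from the declaration registry
#' ([expected_relation()]). Each interaction receives a verdict:
#'
#' * `supports` — observed relation significant and equal to the predicted one;
#' * `contradicts` — observed relation significant and opposite;
#' * `inconclusive` — observed relation undefined (or no prediction derivable).
#'
#' @param records Incident record tibble.
#' @param registry Declared-alliance tibble (`head`, `partner`,
#'   `declared_relation`), partners named at club level.
#' @param heads Character vector of head clubs.
#' @param benchmark [summary_stats()] for the pooled benchmark group, or
#'   `NULL` to pool `records` via [pooled_benchmark()] with `scope`.
#' @param head_relations Tibble (`head_a`, `head_b`, `label`) of first-step
#'   head-pair relation labels; assumed overrides may be merged in by the
#'   caller (see `assumed_relations`).
#' @param assumed_relations Optional tibble (`head_a`, `head_b`, `label`) of
#'   user-supplied relation overrides for head pairs whose inferred relation
#'   is undefined; they are applied on top of `head_relations` and marked
#'   `assumed` in the output provenance.
#' @param alpha_strong,alpha_weak Significance tiers.
#' @param scope Benchmark scope passed to [pooled_benchmark()] when
#'   `benchmark` is `NULL`.
#' @param sidedness,df_rule Passed to [classify_underlying()].
#' @param p_adjust Multiple-testing correction method for the reported
#'   `p_adjusted` column (`"none"` by default, mirroring the original
#'   procedure; e.g. `"holm"` for a corrected view). The verdicts always use
#'   the unadjusted p-values; the adjusted column is reported separately.
#' @return An object of class `bedouin_test`: a list with `table` (one row
#'   per interaction: head, partner, n, mean, sd, statistic, df, p_value,
#'   label, tier, expected, verdict) and `summary` (interaction and club
#'   counts).
#' @export
test_bedouin_hypothesis <- function(records, registry, heads,
                                    benchmark = NULL, head_relations = NULL,
                                    assumed_relations = NULL,
                                    alpha_strong = 0.05, alpha_weak = 0.1,
                                    scope = NULL,
                                    sidedness = "one_tailed",
                                    df_rule = "welch_satterthwaite",
                                    p_adjust = "none") {
  if (length(heads) == 0L) stop_config("at least one head club is required")
  registry <- validate_registry(registry)
  if (is.null(benchmark)) benchmark <- pooled_benchmark(records, scope = scope)
  if (is.null(head_relations))
    head_relations <- infer_head_relations(records, heads, benchmark,
                                           alpha_strong, alpha_weak,
                                           sidedness, df_rule)
  provenance <- rep("inferred", nrow(head_relations))
  if (!is.null(assumed_relations) && nrow(assumed_relations) > 0L) {
    for (i in seq_len(nrow(assumed_relations))) {
      a <- assumed_relations$head_a[i]; b <- assumed_relations$head_b[i]
      sel <- (head_relations$head_a == a & head_relations$head_b == b) |
        (head_relations$head_a == b & head_relations$head_b == a)
      if (any(sel)) {
        head_relations$label[sel] <- assumed_relations$label[i]
        provenance[sel] <- "assumed"
      } else {
        head_relations <- dplyr::bind_rows(
          head_relations,
          tibble::tibble(head_a = a, head_b = b,
                         label = assumed_relations$label[i]))
        provenance <- c(provenance, "assumed")
      }
    }
  }
  head_relations$provenance <- provenance

  partners <- setdiff(unique(registry$partner), heads)
  rows <- list()
  for (h in heads) {
    for (k in partners) {
      stats_hk <- aggregate_pair_stats(records, h, k)
      if (!has_data(stats_hk)) next
      rel <- classify_underlying(stats_hk, benchmark,
                                 alpha_strong = alpha_strong,
                                 alpha_weak = alpha_weak,
                                 sidedness = sidedness, df_rule = df_rule,
                                 head_a = h, head_b = k)
      expd <- expected_relation(registry, head_relations, h, k)
      verdict <- if (rel$label == "undefined" || is.na(expd)) "inconclusive"
        else if (rel$label == expd) "supports"
        else "contradicts"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        head = h, partner = k,
        n = rel$n, mean = rel$mean, sd = rel$sd,
        statistic = rel$statistic, df = rel$df, p_value = rel$p_value,
        label = rel$label, tier = rel$tier,
        expected = ifelse(is.na(expd), NA_character_, expd),
        verdict = verdict)
    }
  }
  tab <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(head = character(0), partner = character(0),
                   n = integer(0), mean = numeric(0), sd = numeric(0),
                   statistic = numeric(0), df = numeric(0),
                   p_value = numeric(0), label = character(0),
                   tier = character(0), expected = character(0),
                   verdict = character(0))
  tab$p_adjusted <- if (p_adjust == "none") tab$p_value
    else stats::p.adjust(tab$p_value, method = p_adjust)

  supported_clubs <- unique(tab$partner[tab$verdict == "supports"])
  summary <- list(
    n_interactions = nrow(tab),
    supports = sum(tab$verdict == "supports"),
    contradicts = sum(tab$verdict == "contradicts"),
    inconclusive = sum(tab$verdict == "inconclusive"),
    clubs_total = length(partners),
    clubs_supported = length(supported_clubs),
    clubs_without_support = length(partners) - length(supported_clubs),
    significant_alliances = sum(tab$label == "alliance"),
    significant_rivalries = sum(tab$label == "rivalry"),
    contradicting_alliances = sum(tab$label == "alliance" &
                                    tab$verdict == "contradicts")
  )
  structure(list(table = tab, summary = summary,
                 head_relations = head_relations,
                 benchmark = benchmark,
                 alpha_strong = alpha_strong, alpha_weak = alpha_weak),
            class = "bedouin_test")
}

#' First-step relations among the head clubs
#'
#' Classifies every head pair against the benchmark.
#'
#' @inheritParams test_bedouin_hypothesis
#' @param sidedness,df_rule Passed to [classify_underlying()].
#' @return A tibble (`head_a`, `head_b`, `n`, `mean`, `sd`, `statistic`,
#'   `df`, `p_value`, `label`, `tier`).
#' @export
infer_head_relations <- function(records, heads, benchmark = NULL,
                                 alpha_strong = 0.05, alpha_weak = 0.1,
                                 sidedness = "one_tailed",
                                 df_rule = "welch_satterthwaite") {
  if (is.null(benchmark)) benchmark <- pooled_benchmark(records)
  combos <- utils::combn(heads, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    rel <- classify_underlying(aggregate_pair_stats(records, a, b), benchmark,
                               alpha_strong = alpha_strong,
                               alpha_weak = alpha_weak,
                               sidedness = sidedness, df_rule = df_rule,
                               head_a = a, head_b = b)
    tibble::tibble(head_a = a, head_b = b, n = rel$n, mean = rel$mean,
                   sd = rel$sd, statistic = rel$statistic, df = rel$df,
                   p_value = rel$p_value, label = rel$label, tier = rel$tier)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.bedouin_test <- function(x, ...) {
  s <- x$summary
  cat("Bedouin-syndrome concordance test\n")
  cat(sprintf("  %d interactions over %d clubs (alpha %.3g / %.3g)\n",
              s$n_interactions, s$clubs_total, x$alpha_strong, x$alpha_weak))
  cat(sprintf("  supports: %d   contradicts: %d   inconclusive: %d\n",
              s$supports, s$contradicts, s$inconclusive))
  cat(sprintf("  clubs with no support for the syndrome: %d of %d\n",
              s$clubs_without_support, s$clubs_total))
  invisible(x)
}
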