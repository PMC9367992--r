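# Shared in-code fixtures: no data files, everything built programmatically.

make_records <- function(head, opponent, counts, competition = "test",
                         category = "assault", start_id = 1L) {
  tibble::tibble(
    match_id = sprintf("T%04d", start_id + seq_along(counts) - 1L),
    date = NA_character_,
    competition = competition,
    head_club = head,
    opponent_club = opponent,
    incident_count = as.integer(counts),
    offense_category = category)
}

printed_benchmark <- function() summary_stats(330L, 2.28181800, 3.91970700)

# independent t-tail oracle: numerical integration of the explicit t density
t_tail_oracle <- function(t, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = -Inf, upper = -abs(t),
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# exhaustive truth-table oracle for the affinity taxonomy
affinity_oracle <- function(head_label, la, lb) {
  if (head_label == "alliance") {
    if (la == "rivalry" && lb == "rivalry") return("coup")
    if (la == "alliance" && lb == "alliance") return("peer")
  }
  if (head_label == "rivalry") {
    if (la == "rivalry" && lb == "rivalry") return("clash")
    if (la == "alliance" && lb == "alliance") return("split")
  }
  "undefined"
}

# drop simulator sidecar attributes for field-wise round-trip comparisons
plain_records <- function(x) {
  attr(x, "truth") <- NULL
  attr(x, "config") <- NULL
  as.data.frame(x)
}

relation_stub <- function(label, head_a = "A", head_b = "B") {
  structure(list(head_a = head_a, head_b = head_b, n = 10L, mean = 1, sd = 1,
                 statistic = 0, df = 10, p_value = 0.01, direction = "below",
                 label = label, tier = if (label == "undefined") "none" else "strong",
                 alpha_strong = 0.05, alpha_weak = 0.1),
            class = "underlying_relation")
}
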