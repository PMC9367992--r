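test_that("relation labels follow the two-tier convention on printed values", {
  # printed first-step rows: p and direction reproduce the printed labels
  lab1 <- relation_label(0.018, "above")
  expect_equal(lab1$label, "rivalry"); expect_equal(lab1$tier, "strong")
  lab2 <- relation_label(0.048, "above")
  expect_equal(lab2$label, "rivalry"); expect_equal(lab2$tier, "strong")
  lab3 <- relation_label(0.477, "above")
  expect_equal(lab3$label, "undefined"); expect_equal(lab3$tier, "none")
  lab4 <- relation_label(0.06417, "below")
  expect_equal(lab4$label, "alliance"); expect_equal(lab4$tier, "weak")
  expect_error(relation_label(0.01, "above", alpha_strong = 0.1,
                              alpha_weak = 0.05),
               class = "hoolinet_config_error")
})

test_that("relation labelling agrees with an exhaustive direction-tier oracle", {
  oracle <- function(p, direction, a_s, a_w) {
    if (is.na(p) || direction == "none" || p >= a_w)
      return(c("undefined", "none"))
    lab <- if (direction == "above") "rivalry" else "alliance"
    c(lab, if (p < a_s) "strong" else "weak")
  }
  ps <- c(NA, 0.001, 0.049, 0.05, 0.0501, 0.0999, 0.1, 0.3, 0.9)
  for (p in ps) for (d in c("above", "below", "none")) {
    got <- relation_label(p, d)
    want <- oracle(p, d, 0.05, 0.1)
    expect_equal(c(got$label, got$tier), want,
                 label = sprintf("p=%s dir=%s", p, d))
  }
})

test_that("classify_underlying ties the test, direction and label together", {
  bench <- printed_benchmark()
  rel <- classify_underlying(summarize_counts(c(0, 0, 1, 1, 1, 2)), bench,
                             head_a = "Sport Club Recife",
                             head_b = "SE Palmeiras")
  expect_equal(rel$label, "alliance")
  expect_equal(rel$tier, "strong")
  expect_equal(rel$direction, "below")
  expect_equal(round(rel$p_value, 5), 0.00131)
  # rivalry only when the pair mean exceeds the benchmark mean
  riv <- classify_underlying(summary_stats(30L, 12, 4), bench)
  expect_equal(riv$label, "rivalry")
  expect_equal(riv$direction, "above")
  # undefined p propagates to an undefined label
  und <- classify_underlying(summarize_counts(c(0, 0)), bench)
  expect_equal(und$label, "undefined")
  expect_equal(und$tier, "none")
  # no-data pair classifies as undefined rather than erroring
  expect_equal(classify_underlying(summary_stats(0, NA, NA), bench)$label,
               "undefined")
})

test_that("affinity classification agrees with the exhaustive truth table", {
  labels <- c("alliance", "rivalry", "undefined")
  for (h in labels) for (a in labels) for (b in labels) {
    got <- classify_affinity(relation_stub(h),
                             relation_stub(a, "A", "K"),
                             relation_stub(b, "B", "K"))
    expect_equal(got$affinity, affinity_oracle(h, a, b),
                 label = sprintf("(%s, %s, %s)", h, a, b))
  }
  # restricted to defined inputs the map is total onto the four classes
  defined <- c("alliance", "rivalry")
  out <- character(0)
  for (h in defined) for (a in defined) for (b in defined)
    out <- c(out, classify_affinity(relation_stub(h),
                                    relation_stub(a, "A", "K"),
                                    relation_stub(b, "B", "K"))$affinity)
  expect_setequal(setdiff(out, "undefined"),
                  c("coup", "peer", "clash", "split"))
})

test_that("components naming different clubs is a contract error", {
  expect_error(classify_affinity(relation_stub("alliance"),
                                 relation_stub("rivalry", "A", "K1"),
                                 relation_stub("rivalry", "B", "K2")),
               class = "hoolinet_config_error")
})

test_that("expected relations compose declarations transitively", {
  registry <- tibble::tibble(
    head = c("A", "A", "B"),
    partner = c("K1", "K2", "K3"),
    declared_relation = c("enemy", "friend", "friend"))
  head_rel <- tibble::tibble(head_a = "A", head_b = "B", label = "alliance")
  # direct declaration wins
  expect_equal(expected_relation(registry, head_rel, "A", "K1"), "rivalry")
  expect_equal(expected_relation(registry, head_rel, "A", "K2"), "alliance")
  # friend of my friend is my friend
  expect_equal(expected_relation(registry, head_rel, "A", "K3"), "alliance")
  # enemy of my friend is my enemy
  expect_equal(expected_relation(registry, head_rel, "B", "K1"), "rivalry")
  # under head rivalry the composition flips: friend of my enemy is my enemy
  head_riv <- tibble::tibble(head_a = "A", head_b = "B", label = "rivalry")
  expect_equal(expected_relation(registry, head_riv, "B", "K2"), "rivalry")
  # enemy of my enemy is my friend
  expect_equal(expected_relation(registry, head_riv, "B", "K1"), "alliance")
  # absent partner: no expectation
  expect_true(is.na(expected_relation(registry, head_rel, "A", "K9")))
  # undefined head relation blocks composition (but not direct declarations)
  head_und <- tibble::tibble(head_a = "A", head_b = "B", label = "undefined")
  expect_true(is.na(expected_relation(registry, head_und, "A", "K3")))
  expect_equal(expected_relation(registry, head_und, "A", "K1"), "rivalry")
})

test_that("expected affinity maps declarations through the taxonomy", {
  registry <- tibble::tibble(
    head = c("A", "A"), partner = c("K", "Kf"),
    declared_relation = c("enemy", "friend"))
  allied <- tibble::tibble(head_a = "A", head_b = "B", label = "alliance")
  # friends whose mutual associate is an enemy of one: coup expected
  expect_equal(expected_affinity(registry, allied, "A", "B", "K"), "coup")
  expect_equal(expected_affinity(registry, allied, "A", "B", "Kf"), "peer")
  # missing club: inconclusive
  expect_true(is.na(expected_affinity(registry, allied, "A", "B", "K9")))
  # undefined heads: inconclusive
  und <- tibble::tibble(head_a = "A", head_b = "B", label = "undefined")
  expect_true(is.na(expected_affinity(registry, und, "A", "B", "K")))
})
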