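#' The affinity taxonomy
#'
#' The four simultaneous affinities of two heads `a`, `b` with a third club
#' `k`, as a function of the underlying head-pair relation and the two
#' component relations `(a, k)` and `(b, k)`:
#'
#' | heads    | components            | affinity |
#' |----------|-----------------------|----------|
#' | alliance | rivalry  + rivalry    | coup     |
#' | alliance | alliance + alliance   | peer     |
#' | rivalry  | rivalry  + rivalry    | clash    |
#' | rivalry  | alliance + alliance   | split    |
#'
#' Any combination involving an undefined relation, or mixed component
#' labels, is `undefined`.
#'
#' @param head_label,label_a,label_b Relation labels (`"alliance"`,
#'   `"rivalry"` or `"undefined"`).
#' @return The affinity class as a string.
#' @export
affinity_class <- function(head_label, label_a, label_b) {
  if (head_label == "alliance" && label_a == "rivalry" && label_b == "rivalry")
    return("coup")
  if (head_label == "alliance" && label_a == "alliance" && label_b == "alliance")
    return("peer")
  if (head_label == "rivalry" && label_a == "rivalry" && label_b == "rivalry")
    return("clash")
  if (head_label == "rivalry" && label_a == "alliance" && label_b == "alliance")
    return("split")
  "undefined"
}

#' Classify the affinity of a (head, head, club) triple
#'
#' Combines the underlying relation of the two heads with the two component
#' relations of a third club via the affinity taxonomy (see
#' [affinity_class()]). Undefined inputs propagate to an undefined affinity.
#'
#' @param head_relation [classify_underlying()] result for the head pair.
#' @param component_a,component_b [classify_underlying()] results for
#'   `(head_a, club)` and `(head_b, club)`.
#' @return An object of class `affinity_relation`.
#' @export
classify_affinity <- function(head_relation, component_a, component_b) {
  stopifnot(inherits(head_relation, "underlying_relation"),
            inherits(component_a, "underlying_relation"),
            inherits(component_b, "underlying_relation"))
  club <- component_a$head_b
  if (!is.na(club) && !is.na(component_b$head_b) && club != component_b$head_b)
    stop_config("components refer to different clubs ('%s' vs '%s')",
                club, component_b$head_b)
  structure(list(
    head_a = head_relation$head_a, head_b = head_relation$head_b,
    club = club,
    head_label = head_relation$label,
    label_a = component_a$label, label_b = component_b$label,
    component_a = component_a, component_b = component_b,
    affinity = affinity_class(head_relation$label, component_a$label,
                              component_b$label)
  ), class = "affinity_relation")
}

#' @export
print.affinity_relation <- function(x, ...) {
  cat(sprintf("<affinity_relation> (%s, %s) with %s: %s\n",
              x$head_a, x$head_b, x$club, x$affinity))
  invisible(x)
}

# friend/enemy composition under the transitive (Bedouin) premises:
# friend of friend = friend, friend of enemy = enemy,
# enemy of friend = enemy, enemy of enemy = friend.
compose_declared <- function(rel_ab, rel_bk) {
  if (is.na(rel_ab) || is.na(rel_bk)) return(NA_character_)
  if (rel_ab == rel_bk) "friend" else "enemy"
}

declared_lookup <- function(registry, x, y) {
  sel <- (registry$head == x & registry$partner == y) |
    (registry$head == y & registry$partner == x)
  rels <- unique(registry$declared_relation[sel])
  if (length(rels) == 0L) return(NA_character_)
  if (length(rels) > 1L)
    stop_validation("contradictory declarations for %s / %s", x, y)
  rels
}

relation_to_declared <- function(label) {
  switch(label, alliance = "friend", rivalry = "enemy", NA_character_)
}

declared_to_relation <- function(rel) {
  switch(rel, friend = "alliance", enemy = "rivalry", NA_character_)
}

#' Expected relation of a head with a partner under the transitive premises
#'
#' Resolves what relation (alliance/rivalry) a head *should* have with a
#' partner club if the declared alliances were transitive: a direct
#' declaration wins; otherwise the partner's declaration toward another head
#' is composed with that head pair's (inferred or assumed) relation. When
#' several chains disagree the expectation is ambiguous and `NA` is returned.
#'
#' @param registry Declared-alliance tibble (`head`, `partner`,
#'   `declared_relation`).
#' @param head_relations Tibble (`head_a`, `head_b`, `label`) of head-pair
#'   relation labels (from the first-step tests, possibly with assumed
#'   overrides).
#' @param head,partner Club names.
#' @return `"alliance"`, `"rivalry"` or `NA`.
#' @export
expected_relation <- function(registry, head_relations, head, partner) {
  direct <- declared_lookup(registry, head, partner)
  if (!is.na(direct)) return(declared_to_relation(direct))
  heads <- unique(c(head_relations$head_a, head_relations$head_b))
  expectations <- character(0)
  for (g in setdiff(heads, head)) {
    rel_gk <- declared_lookup(registry, g, partner)
    if (is.na(rel_gk)) next
    sel <- (head_relations$head_a == head & head_relations$head_b == g) |
      (head_relations$head_a == g & head_relations$head_b == head)
    if (!any(sel)) next
    lab_hg <- head_relations$label[sel][1]
    rel_hg <- relation_to_declared(lab_hg)
    if (is.na(rel_hg)) next
    composed <- compose_declared(rel_hg, rel_gk)
    expectations <- c(expectations, declared_to_relation(composed))
  }
  expectations <- unique(expectations[!is.na(expectations)])
  if (length(expectations) == 1L) expectations else NA_character_
}

#' Expected affinity class of a triple from the declaration registry
#'
#' Maps the declared friend/enemy labels of a (head, head, club) triple
#' through the transitive premises to the affinity class that the Bedouin
#' syndrome predicts. Returns `NA` (inconclusive) when the registry does not
#' cover the triple.
#'
#' @inheritParams expected_relation
#' @param head_a,head_b,club The triple.
#' @return `"coup"`, `"peer"`, `"clash"`, `"split"` or `NA`.
#' @export
expected_affinity <- function(registry, head_relations, head_a, head_b, club) {
  sel <- (head_relations$head_a == head_a & head_relations$head_b == head_b) |
    (head_relations$head_a == head_b & head_relations$head_b == head_a)
  head_label <- if (any(sel)) head_relations$label[sel][1] else NA_character_
  if (is.na(head_label) || head_label == "undefined") return(NA_character_)
  rel_a <- expected_relation(registry, head_relations, head_a, club)
  rel_b <- expected_relation(registry, head_relations, head_b, club)
  if (is.na(rel_a) || is.na(rel_b)) return(NA_character_)
  out <- affinity_class(head_label, rel_a, rel_b)
  if (out == "undefined") NA_character_ else out
}
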