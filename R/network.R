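#' Build the signed hooligan network
#'
#' One node per club with at least one incident against any head, one edge
#' per (head, club) pair with at least one incident. Node size is an affine
#' map of `log(1 + total incidents)` onto `scaling$size_range` (stable across
#' the heavy-tailed count regime); edge strength is the incident sum, with
#' the rendered layout distance proportional to `1/(1 + incident_sum)` so
#' more violent interactions draw clubs closer. Each edge carries a relevance
#' score: the share of its head's total incidents, so a head's relevance
#' scores sum to one — a high score flags the opponent whose matches
#' concentrate that head's violence.
#'
#' Clubs are partitioned into head clusters by their dominant head (the head
#' with the largest incident sum against them; ties resolve in `heads`
#' order); direct vs indirect enemies are read off this partition attribute.
#'
#' @param records Incident record tibble.
#' @param heads Character vector of head clubs.
#' @param scaling List; `size_range` gives the node-size interval (default
#'   `c(1, 5)`).
#' @return An object of class `hooligan_network`: list with `nodes`
#'   (tibble: club, is_head, total_incidents, n_matches_with_incidents,
#'   size_scale, cluster), `edges` (tibble: head, club, incident_sum,
#'   match_count, relevance, strength, length), `heads`, `scaling`.
#' @export
build_network <- function(records, heads, scaling = list(size_range = c(1, 5))) {
  if (length(heads) == 0L) stop_config("at least one head club is required")
  pair <- records |>
    dplyr::filter(.data$head_club %in% heads) |>
    dplyr::group_by(.data$head_club, .data$opponent_club) |>
    dplyr::summarise(incident_sum = sum(.data$incident_count),
                     match_count = dplyr::n(),
                     matches_with_incidents = sum(.data$incident_count > 0),
                     .groups = "drop") |>
    dplyr::filter(.data$incident_sum >= 1)
  if (nrow(pair) == 0L) {
    warning("no incidents at all; returning an empty network", call. = FALSE)
    return(structure(list(
      nodes = tibble::tibble(club = character(0), is_head = logical(0),
                             total_incidents = integer(0),
                             n_matches_with_incidents = integer(0),
                             size_scale = numeric(0), cluster = integer(0)),
      edges = tibble::tibble(head = character(0), club = character(0),
                             incident_sum = integer(0), match_count = integer(0),
                             relevance = numeric(0), strength = numeric(0),
                             length = numeric(0)),
      heads = heads, scaling = scaling), class = "hooligan_network"))
  }
  edges <- pair |>
    dplyr::rename(head = "head_club", club = "opponent_club") |>
    dplyr::group_by(.data$head) |>
    dplyr::mutate(relevance = .data$incident_sum / sum(.data$incident_sum)) |>
    dplyr::ungroup() |>
    dplyr::mutate(strength = as.numeric(.data$incident_sum),
                  length = 1 / (1 + .data$incident_sum))

  clubs <- union(heads, unique(c(edges$head, edges$club)))
  totals <- vapply(clubs, function(cl)
    sum(edges$incident_sum[edges$head == cl | edges$club == cl]),
    numeric(1), USE.NAMES = FALSE)
  nmwi <- vapply(clubs, function(cl)
    sum(edges$matches_with_incidents[edges$head == cl | edges$club == cl]),
    numeric(1), USE.NAMES = FALSE)
  keep <- totals >= 1 | clubs %in% heads
  clubs <- clubs[keep]; totals <- totals[keep]; nmwi <- nmwi[keep]

  sz <- scaling$size_range %||% c(1, 5)
  lg <- log1p(totals)
  size_scale <- if (diff(range(lg)) == 0) rep(mean(sz), length(lg))
    else sz[1] + (lg - min(lg)) / diff(range(lg)) * diff(sz)

  cluster_of <- function(cl) {
    if (cl %in% heads) return(match(cl, heads))
    e <- edges[edges$club == cl & edges$head %in% heads, ]
    if (nrow(e) == 0L) return(NA_integer_)
    best <- e$head[order(-e$incident_sum, match(e$head, heads))][1]
    match(best, heads)
  }
  nodes <- tibble::tibble(
    club = clubs, is_head = clubs %in% heads,
    total_incidents = as.integer(totals),
    n_matches_with_incidents = as.integer(nmwi),
    size_scale = size_scale,
    cluster = vapply(clubs, cluster_of, integer(1), USE.NAMES = FALSE))

  structure(list(nodes = nodes,
                 edges = edges[, c("head", "club", "incident_sum",
                                   "match_count", "relevance", "strength",
                                   "length")],
                 heads = heads, scaling = scaling),
            class = "hooligan_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hooligan_network <- function(x, ...) {
  cat(sprintf("<hooligan_network> %d nodes (%d heads), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_head), nrow(x$edges)))
  invisible(x)
}

#' Relevance score of one edge
#'
#' The head-conditional incident share: the edge's incident sum divided by
#' its head's total over all its edges. Scores over a head's edges sum to 1.
#'
#' @param incident_sum Incident sum of the edge.
#' @param head_total Total incident sum over the head's edges; must be
#'   positive.
#' @return A value in `[0, 1]`.
#' @export
relevance_score <- function(incident_sum, head_total) {
  if (any(head_total <= 0)) stop_config("head total must be positive")
  incident_sum / head_total
}

#' Relation labels for every head pair and (head, club) component
#'
#' Computes the relation labels that drive affinity extraction and layout.
#' `mode = "statistical"` classifies each pair against the benchmark via
#' [classify_underlying()]; `mode = "incident"` uses the broader network
#' semantics in which any (head, club) pair with at least one incident is a
#' hostile (rivalry) association — the reading under which the published
#' coup/clash subnetworks enumerate their members.
#'
#' @param records Incident record tibble.
#' @param heads Head clubs.
#' @param benchmark [summary_stats()] benchmark (required for
#'   `"statistical"`).
#' @param mode `"statistical"` or `"incident"`.
#' @param head_relations Optional tibble (`head_a`, `head_b`, `label`)
#'   overriding the head-pair labels (e.g. printed or assumed labels).
#' @param ... Passed to [classify_underlying()].
#' @return A list of class `relation_set` with `heads` (tibble: head_a,
#'   head_b, label, statistic, p_value) and `components` (tibble: head, club,
#'   label, statistic, p_value).
#' @export
relation_set <- function(records, heads, benchmark = NULL,
                         mode = c("statistical", "incident"),
                         head_relations = NULL, ...) {
  mode <- match.arg(mode)
  clubs <- setdiff(unique(c(records$head_club, records$opponent_club)), heads)
  comp_rows <- list()
  for (h in heads) for (k in clubs) {
    st <- aggregate_pair_stats(records, h, k)
    if (!has_data(st)) next
    if (mode == "incident") {
      lab <- if (st$mean * st$n >= 1) "rivalry" else "undefined"
      comp_rows[[length(comp_rows) + 1L]] <- tibble::tibble(
        head = h, club = k, label = lab,
        statistic = st$mean * st$n, p_value = NA_real_)
    } else {
      if (is.null(benchmark)) stop_config("statistical mode needs a benchmark")
      rel <- classify_underlying(st, benchmark, head_a = h, head_b = k, ...)
      comp_rows[[length(comp_rows) + 1L]] <- tibble::tibble(
        head = h, club = k, label = rel$label,
        statistic = rel$statistic, p_value = rel$p_value)
    }
  }
  if (is.null(head_relations)) {
    if (is.null(benchmark)) stop_config("head relations need a benchmark (or pass head_relations)")
    head_relations <- infer_head_relations(records, heads, benchmark, ...)
    head_relations <- head_relations[, c("head_a", "head_b", "label",
                                         "statistic", "p_value")]
  } else {
    if (!"statistic" %in% names(head_relations))
      head_relations$statistic <- NA_real_
    if (!"p_value" %in% names(head_relations))
      head_relations$p_value <- NA_real_
    head_relations <- head_relations[, c("head_a", "head_b", "label",
                                         "statistic", "p_value")]
  }
  structure(list(heads = head_relations,
                 components = dplyr::bind_rows(comp_rows), mode = mode),
            class = "relation_set")
}

required_head_label <- function(class) {
  switch(class, coup = "alliance", peer = "alliance",
         clash = "rivalry", split = "rivalry",
         stop_config("unknown affinity class '%s'", class))
}

required_component_label <- function(class) {
  switch(class, coup = "rivalry", clash = "rivalry",
         peer = "alliance", split = "alliance")
}

#' Extract the clubs forming a given affinity with two heads
#'
#' Members are exactly the clubs adjacent to both heads in the network whose
#' component relations with each head carry the label the affinity taxonomy
#' requires (enemies of both for coup/clash, friends of both for peer/split),
#' given the head-pair relation the class presupposes. When the inferred
#' head-pair relation does not match the requested class, an
#' `assumed_relation` override must be supplied and the result is marked
#' `assumed`.
#'
#' @param network A [build_network()] result.
#' @param relations A [relation_set()].
#' @param head_a,head_b The two heads.
#' @param class `"coup"`, `"peer"`, `"clash"` or `"split"`.
#' @param assumed_relation Optional `"alliance"` or `"rivalry"` override for
#'   the head pair.
#' @return An object of class `affinity_subnetwork`: list with `head_a`,
#'   `head_b`, `class`, `member_clubs`, `provenance` (`"inferred"` or
#'   `"assumed"`).
#' @export
extract_affinity_subnetwork <- function(network, relations, head_a, head_b,
                                        class = c("coup", "clash", "peer", "split"),
                                        assumed_relation = NULL) {
  class <- match.arg(class)
  sel <- (relations$heads$head_a == head_a & relations$heads$head_b == head_b) |
    (relations$heads$head_a == head_b & relations$heads$head_b == head_a)
  inferred <- if (any(sel)) relations$heads$label[sel][1] else "undefined"
  need <- required_head_label(class)
  if (!is.null(assumed_relation)) {
    head_label <- assumed_relation
    provenance <- "assumed"
  } else {
    head_label <- inferred
    provenance <- "inferred"
  }
  if (head_label != need)
    stop_config(
      "head pair relation is '%s' but a %s requires '%s'; supply assumed_relation to override",
      head_label, class, need)

  adjacency <- function(h) network$edges$club[network$edges$head == h]
  candidates <- intersect(adjacency(head_a), adjacency(head_b))
  comp_need <- required_component_label(class)
  label_of <- function(h, k) {
    s <- relations$components$label[relations$components$head == h &
                                      relations$components$club == k]
    if (length(s) == 0L) "undefined" else s[1]
  }
  members <- candidates[vapply(candidates, function(k)
    label_of(head_a, k) == comp_need && label_of(head_b, k) == comp_need,
    logical(1))]
  structure(list(head_a = head_a, head_b = head_b, class = class,
                 member_clubs = sort(members), provenance = provenance),
            class = "affinity_subnetwork")
}

#' @export
print.affinity_subnetwork <- function(x, ...) {
  cat(sprintf("<affinity_subnetwork> %s of (%s, %s): %d clubs [%s]\n",
              x$class, x$head_a, x$head_b, length(x$member_clubs),
              x$provenance))
  invisible(x)
}

#' Circular two-layer layout
#'
#' Deterministic layout mirroring the published landscape convention: heads
#' sit on an inner circle, with the separation of a head pair decreasing in
#' its rivalry grade (incident sum between them); opponent clubs are placed
#' on outer rings (alternating over `layers` rings by incident rank) at the
#' angle of the weighted mean of the head directions, weighted by the
#' affinity statistic toward each head — so a club lands nearer the head
#' whose affinity statistic is larger, and equidistant when they tie.
#'
#' @param network A [build_network()] result.
#' @param relations Optional [relation_set()] supplying affinity statistics;
#'   edge incident sums are used as weights when absent.
#' @param layers Number of opponent rings (default 2).
#' @param seed Accepted for interface symmetry; the layout is fully
#'   deterministic and ignores it.
#' @return A tibble with `club`, `x`, `y`, `ring`.
#' @export
layout_circular <- function(network, relations = NULL, layers = 2L,
                            seed = NULL) {
  nodes <- network$nodes
  if (nrow(nodes) == 0L) stop_config("cannot lay out an empty network")
  heads <- network$heads[network$heads %in% nodes$club]
  nh <- length(heads)
  # head angles equally spaced; radius shrinks with total head-head rivalry
  hh <- network$edges[network$edges$head %in% heads &
                        network$edges$club %in% heads, ]
  rivalry_grade <- if (nrow(hh) > 0) sum(hh$incident_sum) else 0
  r_head <- 1 / (1 + log1p(rivalry_grade))
  theta_h <- 2 * pi * (seq_len(nh) - 1) / max(nh, 1)
  coords <- tibble::tibble(club = heads,
                           x = r_head * cos(theta_h),
                           y = r_head * sin(theta_h),
                           ring = 0L)

  opponents <- nodes$club[!nodes$is_head]
  if (length(opponents) > 0L) {
    weight_of <- function(h, k) {
      if (!is.null(relations)) {
        s <- relations$components$statistic[relations$components$head == h &
                                              relations$components$club == k]
        if (length(s) > 0 && !is.na(s[1])) return(abs(s[1]))
      }
      e <- network$edges[network$edges$head == h & network$edges$club == k, ]
      if (nrow(e) > 0) e$incident_sum[1] else 0
    }
    ord <- order(-nodes$total_incidents[match(opponents, nodes$club)],
                 opponents)
    opponents <- opponents[ord]
    ring <- (seq_along(opponents) - 1L) %% layers + 1L
    radii <- 2 + (ring - 1L)
    op <- lapply(seq_along(opponents), function(i) {
      k <- opponents[i]
      w <- vapply(heads, function(h) weight_of(h, k), numeric(1))
      if (sum(w) == 0) w <- rep(1, nh)
      ux <- sum(w * cos(theta_h)) / sum(w)
      uy <- sum(w * sin(theta_h)) / sum(w)
      nrm <- sqrt(ux^2 + uy^2)
      if (nrm < 1e-12) {
        # weights cancel (e.g. equal affinity toward two opposed heads):
        # place on the perpendicular bisector so distances tie exactly
        ux <- -sin(theta_h[1]); uy <- cos(theta_h[1]); nrm <- 1
      }
      tibble::tibble(club = k, x = radii[i] * ux / nrm,
                     y = radii[i] * uy / nrm, ring = ring[i])
    })
    coords <- dplyr::bind_rows(coords, dplyr::bind_rows(op))
  }
  coords
}
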