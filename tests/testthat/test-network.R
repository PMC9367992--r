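sim_network_inputs <- function(n_opponents = 8L, seed = 17L,
                               matches_per_pair = 10L) {
  cfg <- simulation_config(n_opponents = n_opponents,
                           matches_per_pair = matches_per_pair, seed = seed)
  rec <- generate_dataset(cfg)
  list(records = rec, heads = cfg$heads,
       benchmark = pooled_benchmark(rec))
}

test_that("nodes and edges follow the at-least-one-incident rule", {
  heads <- c("Head A", "Head B")
  rec <- dplyr::bind_rows(
    make_records("Head A", "Club X", c(2, 0, 1)),
    make_records("Head A", "Club Y", c(0, 0)),     # matches, no incidents
    make_records("Head B", "Club X", c(4)),
    make_records("Head B", "Head A", c(3, 3)))
  net <- build_network(rec, heads)
  expect_false("Club Y" %in% net$nodes$club)
  expect_equal(nrow(net$edges), 3L)  # A-X, B-X, B-A
  # edge count equals (head, club) pairs with >= 1 incident
  pairs_with <- rec |>
    dplyr::group_by(head_club, opponent_club) |>
    dplyr::summarise(s = sum(incident_count), .groups = "drop")
  expect_equal(nrow(net$edges), sum(pairs_with$s >= 1))
  expect_true(all(net$edges$incident_sum >= 1))
  # every edge endpoint is a node, partition covers all nodes
  expect_true(all(c(net$edges$head, net$edges$club) %in% net$nodes$club))
  expect_true(all(!is.na(net$nodes$cluster)))
})

test_that("a synthetic 72-club fixture yields 72 non-head nodes", {
  # one incident-bearing match per (head, opponent) for 72 opponents
  heads <- c("Head A", "Head B", "Head C")
  opponents <- sprintf("Club %02d", 1:72)
  rec <- dplyr::bind_rows(lapply(seq_along(opponents), function(i)
    make_records(heads[(i - 1L) %% 3L + 1L], opponents[i],
                 counts = 1L + (i %% 4L), start_id = i * 10L)))
  net <- build_network(rec, heads)
  expect_equal(sum(!net$nodes$is_head), 72L)
})

test_that("relevance scores are head-conditional shares summing to one", {
  inp <- sim_network_inputs()
  net <- build_network(inp$records, inp$heads)
  sums <- tapply(net$edges$relevance, net$edges$head, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(relevance_score(10, 100), 0.1)
  expect_equal(relevance_score(7, 7), 1)
  expect_error(relevance_score(1, 0), class = "hoolinet_config_error")
  # planted dominant rival at ~60% of a head's incidents ranks first
  heads <- "Head A"
  rec <- dplyr::bind_rows(
    make_records("Head A", "Dominant", c(30, 30)),
    make_records("Head A", "Minor 1", c(10, 10)),
    make_records("Head A", "Minor 2", c(10, 10)))
  net2 <- build_network(rec, heads)
  top <- net2$edges$club[which.max(net2$edges$relevance)]
  expect_equal(top, "Dominant")
  expect_equal(max(net2$edges$relevance), 0.6)
})

test_that("doubling all counts preserves node size ordering", {
  inp <- sim_network_inputs()
  net1 <- build_network(inp$records, inp$heads)
  rec2 <- inp$records
  rec2$incident_count <- rec2$incident_count * 2L
  net2 <- build_network(rec2, inp$heads)
  ord1 <- net1$nodes$club[order(net1$nodes$size_scale, net1$nodes$club)]
  ord2 <- net2$nodes$club[order(net2$nodes$size_scale, net2$nodes$club)]
  expect_equal(ord1, ord2)
  # edge strength is monotone in incidents, rendered length inverse
  expect_true(all(diff(net1$edges$length[order(net1$edges$incident_sum)]) <= 0))
})

test_that("subnetwork membership matches the taxonomy truth table", {
  heads <- c("Head A", "Head B")
  # clubs hostile to both, to one, and to none
  rec <- dplyr::bind_rows(
    make_records("Head A", "Head B", c(0, 1)),
    make_records("Head A", "Both 1", 2), make_records("Head B", "Both 1", 3),
    make_records("Head A", "Both 2", 1), make_records("Head B", "Both 2", 1),
    make_records("Head A", "OnlyA", 5),
    make_records("Head B", "OnlyB", 4))
  net <- build_network(rec, heads)
  rels <- relation_set(rec, heads, mode = "incident",
                       head_relations = tibble::tibble(
                         head_a = "Head A", head_b = "Head B",
                         label = "rivalry"))
  clash <- extract_affinity_subnetwork(net, rels, "Head A", "Head B", "clash")
  expect_equal(clash$member_clubs, c("Both 1", "Both 2"))
  expect_equal(clash$provenance, "inferred")
  # truth-table oracle over every adjacent club
  adj_a <- net$edges$club[net$edges$head == "Head A"]
  adj_b <- net$edges$club[net$edges$head == "Head B"]
  want <- sort(setdiff(intersect(adj_a, adj_b), heads))
  expect_equal(clash$member_clubs, want)
  # coup on rival heads requires an assumed override
  expect_error(extract_affinity_subnetwork(net, rels, "Head A", "Head B",
                                           "coup"),
               class = "hoolinet_config_error")
  coup <- extract_affinity_subnetwork(net, rels, "Head A", "Head B", "coup",
                                      assumed_relation = "alliance")
  expect_equal(coup$member_clubs, c("Both 1", "Both 2"))
  expect_equal(coup$provenance, "assumed")
})

test_that("an assumed friendship over 16 shared enemies forms a 16-club coup", {
  heads <- c("Head A", "Head B")
  shared <- sprintf("Shared %02d", 1:16)
  rec <- dplyr::bind_rows(
    lapply(shared, function(k) dplyr::bind_rows(
      make_records("Head A", k, 1), make_records("Head B", k, 2))))
  rec <- dplyr::bind_rows(rec, make_records("Head A", "Solo", 3))
  net <- build_network(rec, heads)
  rels <- relation_set(rec, heads, mode = "incident",
                       head_relations = tibble::tibble(
                         head_a = "Head A", head_b = "Head B",
                         label = "undefined"))
  coup <- extract_affinity_subnetwork(net, rels, "Head A", "Head B", "coup",
                                      assumed_relation = "alliance")
  expect_equal(length(coup$member_clubs), 16L)
  expect_false("Solo" %in% coup$member_clubs)
  # empty candidate set: empty subnetwork, not an error
  rels2 <- rels
  none <- extract_affinity_subnetwork(build_network(
    make_records("Head A", "Solo", 3), heads), rels2,
    "Head A", "Head B", "coup", assumed_relation = "alliance")
  expect_equal(length(none$member_clubs), 0L)
})

test_that("layout places clubs nearer the head with the larger affinity", {
  heads <- c("Head A", "Head B")
  rec <- dplyr::bind_rows(
    make_records("Head A", "Head B", 2),
    make_records("Head A", "NearA", 9), make_records("Head B", "NearA", 1),
    make_records("Head A", "Tied", 4), make_records("Head B", "Tied", 4))
  net <- build_network(rec, heads)
  lay <- layout_circular(net)
  d <- function(k, h) {
    i <- match(k, lay$club); j <- match(h, lay$club)
    sqrt((lay$x[i] - lay$x[j])^2 + (lay$y[i] - lay$y[j])^2)
  }
  expect_lt(d("NearA", "Head A"), d("NearA", "Head B"))
  expect_equal(d("Tied", "Head A"), d("Tied", "Head B"), tolerance = 1e-9)
  # determinism: same inputs, identical coordinates
  expect_identical(lay, layout_circular(net))
})

test_that("pajek export writes the documented dialect and round-trips byte-identically", {
  inp <- sim_network_inputs(n_opponents = 5L)
  net <- build_network(inp$records, inp$heads)
  base <- file.path(withr::local_tempdir(), "net")
  export_network(net, "pajek", base)
  lines <- readLines(paste0(base, ".net"))
  expect_true(any(grepl(sprintf("^\\*Vertices %d$", nrow(net$nodes)), lines)))
  expect_equal(sum(grepl("^\\d+ \\d+ ", lines)), nrow(net$edges))
  clu <- readLines(paste0(base, ".clu"))
  expect_equal(length(clu) - 2L, nrow(net$nodes))  # header + comment
  expect_true(all(net$nodes$cluster %in% seq_along(inp$heads)))
  # export -> import -> export is byte-identical
  imp <- import_network(base, "pajek")
  base2 <- file.path(withr::local_tempdir(), "net2")
  hoolinet:::write_pajek_from_import(imp, base2)
  expect_identical(readLines(paste0(base2, ".net")),
                   readLines(paste0(base, ".net")))
  expect_identical(readLines(paste0(base2, ".clu")),
                   readLines(paste0(base, ".clu")))
})

test_that("graphml and csv exports re-import to attribute-equal networks", {
  inp <- sim_network_inputs(n_opponents = 4L)
  net <- build_network(inp$records, inp$heads)
  gml <- file.path(withr::local_tempdir(), "net.graphml")
  export_network(net, "graphml", gml)
  back <- import_network(gml, "graphml")
  cmp <- function(a, b, key) {
    a <- as.data.frame(a[order(a[[key]]), ])
    b <- as.data.frame(b[order(b[[key]]), names(a)])
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-9)
  }
  cmp(net$nodes, back$nodes, "club")
  e1 <- net$edges; e1$key <- paste(e1$head, e1$club)
  e2 <- back$edges; e2$key <- paste(e2$head, e2$club)
  cmp(e1, e2, "key")
  base <- file.path(withr::local_tempdir(), "csvnet")
  export_network(net, "edge_csv", base)
  back2 <- import_network(base, "edge_csv")
  cmp(net$nodes, back2$nodes, "club")
  expect_error(export_network(net, "dot", base))
})

test_that("a dataset with no incidents yields an empty network with warning", {
  rec <- make_records("Head A", "Club X", c(0, 0, 0))
  expect_warning(net <- build_network(rec, "Head A"), "no incidents")
  expect_equal(nrow(net$edges), 0L)
})
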