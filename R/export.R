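#' Convert a hooligan network to an igraph object
#'
#' Node and edge attributes are carried over; the partition becomes the
#' `cluster` vertex attribute.
#'
#' @param network A [build_network()] result.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = as.data.frame(network$edges),
    directed = FALSE,
    vertices = as.data.frame(network$nodes))
}

#' Export a hooligan network
#'
#' Three formats:
#' * `"pajek"` — writes `<path>.net` and `<path>.clu`. Dialect (stated in the
#'   file header): 1-based vertex ids; vertex lines
#'   `id "label" x y size`; `*Edges` lines `i j weight` with weight the
#'   incident sum; the `.clu` holds one 1-based cluster id per vertex line.
#'   All reals are printed with six decimals so export, import and re-export
#'   are byte-identical.
#' * `"graphml"` — all node/edge attributes, via igraph.
#' * `"edge_csv"` — `<path>_nodes.csv` and `<path>_edges.csv`.
#'
#' @param network A [build_network()] result.
#' @param format `"pajek"`, `"graphml"` or `"edge_csv"`.
#' @param path Output path; for pajek and edge_csv a base path without
#'   extension.
#' @param layout Optional [layout_circular()] tibble supplying pajek x/y
#'   coordinates (zeros when absent).
#' @return Character vector of the files written, invisibly.
#' @export
export_network <- function(network, format = c("pajek", "graphml", "edge_csv"),
                           path, layout = NULL) {
  format <- match.arg(format)
  switch(format,
         pajek = write_pajek(network, path, layout),
         graphml = {
           igraph::write_graph(as_igraph(network), path, format = "graphml")
           invisible(path)
         },
         edge_csv = {
           nodes_path <- paste0(path, "_nodes.csv")
           edges_path <- paste0(path, "_edges.csv")
           utils::write.csv(as.data.frame(network$nodes), nodes_path,
                            row.names = FALSE, fileEncoding = "UTF-8")
           utils::write.csv(as.data.frame(network$edges), edges_path,
                            row.names = FALSE, fileEncoding = "UTF-8")
           invisible(c(nodes_path, edges_path))
         })
}

num6 <- function(x) sprintf("%.6f", x)

write_pajek <- function(network, path, layout = NULL) {
  net_path <- paste0(path, ".net")
  clu_path <- paste0(path, ".clu")
  nodes <- network$nodes
  ids <- seq_len(nrow(nodes))
  coord <- function(club) {
    if (is.null(layout)) return(c(0, 0))
    i <- match(club, layout$club)
    if (is.na(i)) c(0, 0) else c(layout$x[i], layout$y[i])
  }
  lines <- c(
    "% hooligan network, pajek dialect: 1-based ids; vertex: id \"label\" x y size; edge: i j weight",
    sprintf("*Vertices %d", nrow(nodes)),
    vapply(ids, function(i) {
      xy <- coord(nodes$club[i])
      sprintf("%d \"%s\" %s %s %s", i, nodes$club[i], num6(xy[1]),
              num6(xy[2]), num6(nodes$size_scale[i]))
    }, character(1)),
    "*Edges",
    vapply(seq_len(nrow(network$edges)), function(j) {
      e <- network$edges[j, ]
      sprintf("%d %d %s", match(e$head, nodes$club),
              match(e$club, nodes$club), num6(e$strength))
    }, character(1)))
  writeLines(lines, net_path, useBytes = TRUE)
  clu <- c("% cluster ids are 1-based",
           sprintf("*Vertices %d", nrow(nodes)),
           as.character(nodes$cluster))
  writeLines(clu, clu_path, useBytes = TRUE)
  invisible(c(net_path, clu_path))
}

#' Import a previously exported network
#'
#' Rebuilds a `hooligan_network` from files written by [export_network()].
#' Pajek import preserves exactly the fields of the documented dialect
#' (labels, coordinates, sizes, edge weights, clusters); GraphML and
#' edge-CSV imports restore all node and edge attributes.
#'
#' @param path Base path (pajek, edge_csv) or file (graphml).
#' @param format Export format used.
#' @return For `"pajek"`, a list with `nodes`, `edges`, `clusters`,
#'   `layout`; for the others a `hooligan_network`.
#' @export
import_network <- function(path, format = c("pajek", "graphml", "edge_csv")) {
  format <- match.arg(format)
  switch(format,
         pajek = read_pajek(path),
         graphml = {
           g <- igraph::read_graph(path, format = "graphml")
           nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices"))
           names(nodes)[names(nodes) == "name"] <- "club"
           edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
           # igraph stores endpoints as from/to; restore head/club roles
           names(edges)[names(edges) == "from"] <- "head"
           names(edges)[names(edges) == "to"] <- "club"
           heads <- nodes$club[as.logical(nodes$is_head)]
           nodes$is_head <- as.logical(nodes$is_head)
           nodes$total_incidents <- as.integer(nodes$total_incidents)
           nodes$n_matches_with_incidents <- as.integer(nodes$n_matches_with_incidents)
           nodes$cluster <- as.integer(nodes$cluster)
           edges$incident_sum <- as.integer(edges$incident_sum)
           edges$match_count <- as.integer(edges$match_count)
           # undirected igraph may swap endpoints; orient edges head-first
           swap <- !(edges$head %in% heads) & (edges$club %in% heads)
           tmp <- edges$head[swap]; edges$head[swap] <- edges$club[swap]
           edges$club[swap] <- tmp
           structure(list(nodes = nodes, edges = edges, heads = heads,
                          scaling = list(size_range = range(nodes$size_scale))),
                     class = "hooligan_network")
         },
         edge_csv = {
           nodes <- tibble::as_tibble(utils::read.csv(paste0(path, "_nodes.csv"),
                                                      fileEncoding = "UTF-8"))
           edges <- tibble::as_tibble(utils::read.csv(paste0(path, "_edges.csv"),
                                                      fileEncoding = "UTF-8"))
           structure(list(nodes = nodes, edges = edges,
                          heads = nodes$club[nodes$is_head],
                          scaling = list(size_range = range(nodes$size_scale))),
                     class = "hooligan_network")
         })
}

read_pajek <- function(path) {
  net_lines <- readLines(paste0(path, ".net"), encoding = "UTF-8")
  clu_lines <- readLines(paste0(path, ".clu"), encoding = "UTF-8")
  net_lines <- net_lines[!startsWith(net_lines, "%")]
  clu_lines <- clu_lines[!startsWith(clu_lines, "%")]
  nv <- as.integer(sub("\\*Vertices ", "", net_lines[1]))
  vlines <- net_lines[2:(1 + nv)]
  m <- regmatches(vlines,
                  regexec('^(\\d+) "(.*)" ([-0-9.]+) ([-0-9.]+) ([-0-9.]+)$',
                          vlines))
  nodes <- tibble::tibble(
    id = vapply(m, function(g) as.integer(g[2]), integer(1)),
    club = vapply(m, function(g) g[3], character(1)),
    x = vapply(m, function(g) as.numeric(g[4]), numeric(1)),
    y = vapply(m, function(g) as.numeric(g[5]), numeric(1)),
    size_scale = vapply(m, function(g) as.numeric(g[6]), numeric(1)))
  estart <- which(net_lines == "*Edges")
  edges <- if (estart < length(net_lines)) {
    el <- strsplit(net_lines[(estart + 1):length(net_lines)], " ", fixed = TRUE)
    tibble::tibble(
      from = vapply(el, function(g) as.integer(g[1]), integer(1)),
      to = vapply(el, function(g) as.integer(g[2]), integer(1)),
      weight = vapply(el, function(g) as.numeric(g[3]), numeric(1)))
  } else tibble::tibble(from = integer(0), to = integer(0), weight = numeric(0))
  clusters <- as.integer(clu_lines[-1])
  list(nodes = nodes, edges = edges, clusters = clusters,
       layout = nodes[, c("club", "x", "y")])
}

# Re-export a pajek import verbatim (round-trip support): rebuilds the exact
# byte stream of the documented dialect from the parsed fields.
write_pajek_from_import <- function(imported, path) {
  nodes <- imported$nodes
  lines <- c(
    "% hooligan network, pajek dialect: 1-based ids; vertex: id \"label\" x y size; edge: i j weight",
    sprintf("*Vertices %d", nrow(nodes)),
    vapply(seq_len(nrow(nodes)), function(i)
      sprintf("%d \"%s\" %s %s %s", nodes$id[i], nodes$club[i],
              num6(nodes$x[i]), num6(nodes$y[i]), num6(nodes$size_scale[i])),
      character(1)),
    "*Edges",
    vapply(seq_len(nrow(imported$edges)), function(j)
      sprintf("%d %d %s", imported$edges$from[j], imported$edges$to[j],
              num6(imported$edges$weight[j])), character(1)))
  writeLines(lines, paste0(path, ".net"), useBytes = TRUE)
  clu <- c("% cluster ids are 1-based",
           sprintf("*Vertices %d", nrow(nodes)),
           as.character(imported$clusters))
  writeLines(clu, paste0(path, ".clu"), useBytes = TRUE)
  invisible(paste0(path, c(".net", ".clu")))
}
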