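# Bundled reference inputs: the published per-pair summary statistics of
# hooligan incidents around the three Pernambuco head clubs (per-match
# means/SDs over Feb 2005 - Aug 2015 police records, aggregated at club
# level), the pooled benchmark group constants, and a synthetic
# declared-alliance registry consistent with the published narrative.
# Club and fan-base names are transliterated to ASCII.

head_sport <- "Sport Club Recife"
head_santa <- "Santa Cruz FC"
head_nautico <- "Clube Nautico Capibaribe"

#' The three Pernambuco head clubs
#'
#' @return Character vector of the three head club names used by the bundled
#'   reference tables.
#' @export
pernambuco_heads <- function() c(head_sport, head_santa, head_nautico)

#' Published pooled benchmark group
#'
#' The benchmark group's printed constants: n = 330 matches, mean 2.28181800
#' incidents per match, sample SD 3.91970700 (SEM 0.21577277).
#'
#' @return A [summary_stats()] object.
#' @export
pernambuco_benchmark <- function() summary_stats(330L, 2.28181800, 3.91970700)

#' Synthetic integer benchmark population
#'
#' A deterministic multiset of 330 non-negative integer per-match counts
#' (sum 753, sum of squares 6773) whose exact mean 2.2818182 and sample SD
#' 3.9197074 round to the published benchmark constants. The true underlying
#' counts are unpublished; this synthetic stand-in exists so the pooling and
#' round-trip machinery can be exercised end to end. Shaped like a
#' negative-binomial quantile skeleton of the published (mean, SD) regime.
#'
#' @return Sorted integer vector of length 330.
#' @export
benchmark_population <- function() {
  vals <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L,
            15L, 17L, 18L, 21L, 24L, 30L)
  mult <- c(154L, 53L, 31L, 21L, 16L, 11L, 9L, 7L, 5L, 4L, 4L, 3L, 2L, 2L, 1L,
            2L, 1L, 1L, 1L, 1L, 1L)
  rep(vals, mult)
}

#' Published per-pair summary rows
#'
#' The per-pair results of the second-step tests as printed: for each (head,
#' declared partner) interaction, the fan base tested, the club it supports,
#' and the printed per-match incident mean, sample SD and one-tailed p-value
#' (`"-"` for all-zero pairs). Printed values are kept as strings to preserve
#' their printed precision for [reconstruct_counts()].
#'
#' @return A tibble with columns `head`, `fan_base`, `club`, `mean`, `sd`,
#'   `p_printed`.
#' @export
pernambuco_summary_rows <- function() {
  S <- head_sport; C <- head_santa; N <- head_nautico
  tibble::tribble(
    ~head, ~fan_base, ~club, ~mean, ~sd, ~p_printed,
    S, "Forca Jovem e Mancha Negra", "CR Vasco da Gama",  "6",     "4.358899", "0.13857",
    S, "Galoucura",                  "Atletico-MG",       "1.66",  "2.73252",  "0.30494",
    S, "Bamor",                      "EC Bahia",          "1.5",   "0.707107", "0.16674",
    S, "Furia Jovem do Ypiranga",    "Ypiranga FC",       "0.5",   "0.707107", "0.06417",
    S, "Mafia Vermelha",             "America-RN",        "2.5",   "2.12132",  "0.45412",
    S, "TUP",                        "SE Palmeiras",      "0.833", "0.752773", "0.00131",
    S, "Torcida Jovem (Botafogo)",   "Botafogo FR",       "6.33",  "6.110101", "0.18477",
    S, "Geral",                      "Gremio FBPA",       "2",     "2",        "0.41571",
    S, "Cearamor",                   "Ceara SC",          "1.5",   "2.12132",  "0.34699",
    C, "Mafia Azul",                 "Cruzeiro EC",       "0",     "0",        "-",
    C, "Independente e Dragoes da Real", "Sao Paulo FC",  "0",     "0",        "-",
    C, "Jovem Fla",                  "CR Flamengo",       "0",     "0",        "-",
    C, "Camisa 12",                  "SC Internacional",  "6",     "1.414214", "0.076807",
    C, "Remocada",                   "Clube do Remo",     "4",     "2.82843",  "0.257332",
    C, "Faccao Brasiliense",         "Brasiliense FC",    "5.5",   "3.535534", "0.123865",
    C, "TUP",                        "SE Palmeiras",      "0",     "0",        "-",
    C, "Torcida Jovem (Botafogo)",   "Botafogo FR",       "4",     "5.656854", "0.37086",
    C, "Geral",                      "Gremio FBPA",       "2",     "2.828427", "0.45549",
    C, "Cearamor",                   "Ceara SC",          "1",     "1.414214", "0.2074",
    N, "Mafia Azul",                 "Cruzeiro EC",       "0.5",   "0.707107", "0.06417",
    N, "Independente e Dragoes da Real", "Sao Paulo FC",  "3.5",   "4.949747", "0.3934",
    N, "Jovem Fla",                  "CR Flamengo",       "3",     "2.645751", "0.34287",
    N, "Camisa 12",                  "SC Internacional",  "2.75",  "2.06155",  "0.34222",
    N, "Remocada",                   "Clube do Remo",     "0",     "0",        "-",
    N, "Faccao Brasiliense",         "Brasiliense FC",    "0",     "0",        "-",
    N, "Forca Jovem e Mancha Negra", "CR Vasco da Gama",  "1",     "1.414214", "0.2074",
    N, "Galoucura",                  "Atletico-MG",       "1",     "0.707107", "0.00458",
    N, "Bamor",                      "EC Bahia",          "1",     "1.414214", "0.2074",
    N, "Furia Jovem do Ypiranga",    "Ypiranga FC",       "1.75",  "1.258306", "0.23578",
    N, "Mafia Vermelha",             "America-RN",        "2.5",   "2.12132",  "0.45412"
  )
}

#' Published first-step head-pair relations
#'
#' The printed per-pair statistics and labels for the three head pairs (the
#' first-step tests). Their benchmark group is underdetermined in the source
#' (its stated aggregate mean 8.064 is not reconcilable with the overall
#' totals), so these rows serve as label inputs, not as reproduction targets.
#'
#' @return A tibble with `head_a`, `head_b`, `mean`, `sd`, `p_printed`,
#'   `label`.
#' @export
pernambuco_head_rows <- function() {
  tibble::tribble(
    ~head_a, ~head_b, ~mean, ~sd, ~p_printed, ~label,
    head_sport, head_santa,   "14.96", "24.32", "0.018", "rivalry",
    head_sport, head_nautico, "6.027", "8.036", "0.048", "rivalry",
    head_santa, head_nautico, "3.714", "4.817", "0.477", "undefined"
  )
}

#' Synthetic declared-alliance registry
#'
#' The published declaration appendix is not reproduced in the available
#' text; this registry is a synthetic stand-in: the minimal set of fan-base
#' friendship declarations (each partner club declared friend of exactly one
#' head) that reproduces every published concordance statement when composed
#' through the transitive premises. Use a real registry for real analyses.
#'
#' @return A tibble with `head`, `partner`, `fan_base`, `declared_relation`.
#' @export
pernambuco_registry <- function() {
  S <- head_sport; C <- head_santa; N <- head_nautico
  tibble::tribble(
    ~head, ~partner, ~fan_base, ~declared_relation,
    C, "CR Vasco da Gama",  "Forca Jovem e Mancha Negra", "friend",
    C, "Atletico-MG",       "Galoucura",                  "friend",
    C, "EC Bahia",          "Bamor",                      "friend",
    C, "Ypiranga FC",       "Furia Jovem do Ypiranga",    "friend",
    C, "America-RN",        "Mafia Vermelha",             "friend",
    C, "SE Palmeiras",      "TUP",                        "friend",
    C, "Botafogo FR",       "Torcida Jovem (Botafogo)",   "friend",
    C, "Gremio FBPA",       "Geral",                      "friend",
    C, "Ceara SC",          "Cearamor",                   "friend",
    S, "Cruzeiro EC",       "Mafia Azul",                 "friend",
    S, "SC Internacional",  "Camisa 12",                  "friend",
    S, "Clube do Remo",     "Remocada",                   "friend",
    S, "Brasiliense FC",    "Faccao Brasiliense",         "friend",
    N, "Sao Paulo FC",      "Independente e Dragoes da Real", "friend",
    N, "CR Flamengo",       "Jovem Fla",                  "friend"
  )
}

#' Deterministic reference fixture
#'
#' Assembles a complete, deterministic incident dataset from the published
#' summary statistics alone: every reconstructable per-pair row of
#' [pernambuco_summary_rows()] is expanded into per-match records via
#' [reconstruct_counts()], and the synthetic [benchmark_population()] is
#' attached as a separate benchmark scope (`competition = "benchmark-pool"`).
#' Head-pair relation labels come from [pernambuco_head_rows()]; the
#' circumstantial Santa Cruz--Nautico alliance used in the published coup
#' instance is provided as an assumed-relation override, not an inference.
#'
#' @param convention Printed-value matching convention passed to
#'   [reconstruct_counts()] (default `"auto"`).
#' @return A list with `records` (incident tibble), `registry`,
#'   `head_relations` (printed labels), `assumed_relations` (the Santa
#'   Cruz--Nautico alliance), `benchmark` (printed constants),
#'   `benchmark_scope`, `heads`, and `reconstruction` (per-row detail).
#' @export
pernambuco_fixture <- function(convention = "auto") {
  rows <- pernambuco_summary_rows()
  recon <- reconstruct_table(rows, convention = convention)
  rec_list <- list()
  mid <- 0L
  for (i in seq_len(nrow(recon))) {
    if (!recon$reconstructable[i]) next
    counts <- recon$counts[[i]]
    ids <- sprintf("P%04d", mid + seq_along(counts))
    mid <- mid + length(counts)
    rec_list[[length(rec_list) + 1L]] <- tibble::tibble(
      match_id = ids,
      date = NA_character_,
      competition = "declared-pair",
      head_club = recon$head[i],
      opponent_club = recon$club[i],
      incident_count = as.integer(counts),
      offense_category = "aggression")
  }
  bench_counts <- benchmark_population()
  heads <- pernambuco_heads()
  bench <- tibble::tibble(
    match_id = sprintf("B%04d", seq_along(bench_counts)),
    date = NA_character_,
    competition = "benchmark-pool",
    head_club = heads[(seq_along(bench_counts) - 1L) %% 3L + 1L],
    opponent_club = "Pooled opponents (synthetic)",
    incident_count = as.integer(bench_counts),
    offense_category = "aggression")
  records <- dplyr::bind_rows(c(rec_list, list(bench)))

  head_relations <- pernambuco_head_rows()[, c("head_a", "head_b", "label")]
  list(
    records = records,
    registry = pernambuco_registry()[, c("head", "partner", "fan_base",
                                         "declared_relation")],
    head_relations = head_relations,
    assumed_relations = tibble::tibble(head_a = head_santa,
                                       head_b = head_nautico,
                                       label = "alliance"),
    benchmark = pernambuco_benchmark(),
    benchmark_scope = list(column = "competition", values = "benchmark-pool"),
    heads = heads,
    reconstruction = recon
  )
}
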