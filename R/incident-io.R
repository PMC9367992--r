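#' Column mapping for incident tables
#'
#' Police exports arrive in many layouts; a schema maps the canonical field
#' names onto the column names actually present in the file. Only `head_club`,
#' `opponent_club` and `incident_count` are required; the rest are filled with
#' `NA` when absent.
#'
#' @param match_id,date,competition,head_club,opponent_club,incident_count,offense_category
#'   Column names in the source file for each canonical field.
#' @return A named list of class `incident_schema`.
#' @export
incident_schema <- function(match_id = "match_id", date = "date",
                            competition = "competition",
                            head_club = "head_club",
                            opponent_club = "opponent_club",
                            incident_count = "incident_count",
                            offense_category = "offense_category") {
  structure(list(match_id = match_id, date = date, competition = competition,
                 head_club = head_club, opponent_club = opponent_club,
                 incident_count = incident_count,
                 offense_category = offense_category),
            class = "incident_schema")
}

canonical_record_columns <- c("match_id", "date", "competition", "head_club",
                              "opponent_club", "incident_count",
                              "offense_category")

#' Read and validate a per-match incident table
#'
#' Reads a CSV of per-match incident records (one row per match between a head
#' club and an opponent), validates every row, and returns a tibble with the
#' canonical columns. Malformed rows are not silently dropped: any row-level
#' problem raises a validation error whose condition carries a `problems`
#' tibble naming each offending row.
#'
#' @param path Path to a comma-separated, UTF-8, headered CSV file.
#' @param schema An [incident_schema()] mapping canonical fields to file
#'   columns.
#' @param heads Optional character vector of configured head clubs; when
#'   given, every `head_club` value must belong to it.
#' @return A tibble with columns `match_id`, `date`, `competition`,
#'   `head_club`, `opponent_club`, `incident_count`, `offense_category`.
#' @export
read_incident_table <- function(path, schema = incident_schema(), heads = NULL) {
  if (!file.exists(path)) stop_config("incident file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  required <- c("head_club", "opponent_club", "incident_count")
  for (field in required) {
    if (!schema[[field]] %in% names(raw))
      stop_config("required column '%s' (field %s) missing from %s",
                  schema[[field]], field, path)
  }
  get_col <- function(field, default = NA_character_) {
    col <- schema[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]]
    else rep(default, nrow(raw))
  }
  records <- tibble::tibble(
    match_id = as.character(get_col("match_id")),
    date = as.character(get_col("date")),
    competition = as.character(get_col("competition")),
    head_club = as.character(get_col("head_club")),
    opponent_club = as.character(get_col("opponent_club")),
    incident_count_raw = get_col("incident_count"),
    offense_category = as.character(get_col("offense_category"))
  )
  if (all(is.na(records$match_id)))
    records$match_id <- sprintf("M%05d", seq_len(nrow(records)))
  validate_incident_records(records, heads = heads)
}

validate_incident_records <- function(records, heads = NULL) {
  counts <- suppressWarnings(as.numeric(records$incident_count_raw))
  problems <- list()
  note <- function(row, issue) problems[[length(problems) + 1L]] <<-
    tibble::tibble(row = row, issue = issue)
  for (i in seq_len(nrow(records))) {
    cnt <- counts[i]
    if (is.na(cnt)) note(i, sprintf("incident_count '%s' is not a number",
                                    records$incident_count_raw[i]))
    else if (cnt < 0) note(i, sprintf("incident_count %s is negative", cnt))
    else if (cnt != round(cnt)) note(i, sprintf("incident_count %s is not an integer", cnt))
    if (!is.na(records$head_club[i]) && !is.na(records$opponent_club[i]) &&
        records$head_club[i] == records$opponent_club[i])
      note(i, "head_club equals opponent_club")
    if (!is.null(heads) && !records$head_club[i] %in% heads)
      note(i, sprintf("head_club '%s' is not a configured head", records$head_club[i]))
  }
  if (length(problems) > 0L) {
    problems <- dplyr::bind_rows(problems)
    stop_validation(
      "invalid incident rows: %s",
      paste(sprintf("row %d: %s", problems$row, problems$issue), collapse = "; "),
      problems = problems)
  }
  records$incident_count <- as.integer(counts)
  records$incident_count_raw <- NULL
  records[, canonical_record_columns]
}

#' Write an incident table to CSV
#'
#' Writes the canonical columns so that [read_incident_table()] round-trips
#' the records unchanged.
#'
#' @param records Incident record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_incident_table <- function(records, path) {
  utils::write.csv(records[, canonical_record_columns], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict records to aggression-based offense categories
#'
#' The relation tests are meant for opportunistic aggression (turmoil, threat,
#' assault, battery, ...); property offenses, drug traffic and other
#' misdemeanors follow different criminological dynamics and are removed
#' before testing. Records lacking a category pass through with a warning by
#' default; `strict = TRUE` rejects them instead.
#'
#' @param records Incident record tibble.
#' @param allowed_categories Non-empty character vector of categories to keep.
#' @param strict Drop uncategorised records instead of keeping them.
#' @return The filtered tibble.
#' @export
filter_aggression_offenses <- function(records, allowed_categories,
                                       strict = FALSE) {
  if (length(allowed_categories) == 0L)
    stop_config("'allowed_categories' must be non-empty")
  uncat <- is.na(records$offense_category)
  keep <- records$offense_category %in% allowed_categories
  if (any(uncat)) {
    if (strict) {
      keep <- keep & !uncat
    } else {
      warning(sprintf("%d records lack an offense category and were kept",
                      sum(uncat)), call. = FALSE)
      keep <- keep | uncat
    }
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no records remain after offense filtering", call. = FALSE)
  out
}

#' Summary statistics for one club pair
#'
#' Aggregates the per-match incident counts of all matches between two clubs
#' (in either orientation) into a [summary_stats()] triple. A pair with
#' matches but all-zero incidents yields `mean 0, sd 0` and is kept; a pair
#' with no matches at all returns the explicit no-data state (`n = 0`).
#'
#' @param records Incident record tibble.
#' @param club_a,club_b Club names.
#' @return A `summary_stats` object.
#' @export
aggregate_pair_stats <- function(records, club_a, club_b) {
  sel <- (records$head_club == club_a & records$opponent_club == club_b) |
    (records$head_club == club_b & records$opponent_club == club_a)
  summarize_counts(records$incident_count[sel])
}

#' Pooled benchmark statistics
#'
#' The reference distribution for every relation test: per-match incident
#' counts pooled over all club pairs in the configured scope. The scope is
#' configurable because the published analyses use different benchmark groups
#' at different stages.
#'
#' @param records Incident record tibble.
#' @param scope `NULL` for all records, or `list(column =, values =)` naming a
#'   record column and the values that delimit the benchmark group (e.g.
#'   `list(column = "competition", values = "benchmark-pool")`).
#' @return A `summary_stats` object.
#' @export
pooled_benchmark <- function(records, scope = NULL) {
  if (nrow(records) == 0L) stop_validation("no records to pool")
  x <- records
  if (!is.null(scope)) {
    if (!scope$column %in% names(x))
      stop_config("benchmark scope column '%s' not present", scope$column)
    x <- x[x[[scope$column]] %in% scope$values, , drop = FALSE]
    if (nrow(x) == 0L) stop_validation("benchmark scope selects no records")
  }
  summarize_counts(x$incident_count)
}

#' Per-pair summary table
#'
#' Tabulates `(n, mean, sd)` for every observed (head, opponent) pair,
#' mirroring the layout of the published per-pair results tables.
#'
#' @param records Incident record tibble.
#' @return A tibble with one row per pair.
#' @export
pair_summary_table <- function(records) {
  records |>
    dplyr::group_by(.data$head_club, .data$opponent_club) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$incident_count),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$incident_count), NA_real_),
      .groups = "drop"
    )
}

#' Read a declared-alliance registry
#'
#' The registry lists, for each head, the fan bases or clubs it has publicly
#' declared as friends or enemies. Contradictory duplicate declarations are a
#' validation error.
#'
#' @param path CSV with columns `head`, `partner`, `declared_relation`
#'   (optionally `fan_base`).
#' @return A tibble with those columns.
#' @export
read_alliance_registry <- function(path) {
  if (!file.exists(path)) stop_config("registry file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("head", "partner", "declared_relation"))
    if (!col %in% names(raw))
      stop_config("registry column '%s' missing from %s", col, path)
  reg <- tibble::as_tibble(raw)
  validate_registry(reg)
}

validate_registry <- function(registry) {
  bad <- !registry$declared_relation %in% c("friend", "enemy")
  if (any(bad))
    stop_validation("declared_relation must be 'friend' or 'enemy' (rows %s)",
                    paste(which(bad), collapse = ", "))
  key <- paste(pmin(registry$head, registry$partner),
               pmax(registry$head, registry$partner))
  for (k in unique(key)) {
    rels <- unique(registry$declared_relation[key == k])
    if (length(rels) > 1L)
      stop_validation("contradictory declarations for pair %s", k)
  }
  registry
}
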