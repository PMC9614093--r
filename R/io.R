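# Roster input/output.
#
# Rosters are two delimited tables.  Multi-valued cells (races, languages,
# contexts) use "|" (";" is also accepted on input).  Category profiles are
# encoded as "category:proportion|category:proportion".

SET_SEP <- "[|;]"

split_set <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  out <- trimws(strsplit(cell, SET_SEP)[[1]])
  out[nzchar(out)]
}

join_set <- function(x) paste(x, collapse = "|")

parse_profile <- function(cell, row, field) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NULL)
  parts <- split_set(cell)
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop(sprintf("row %d, field '%s': malformed profile entry (want 'category:proportion')",
                 row, field), call. = FALSE)
  p <- as.numeric(vapply(kv, `[`, "", 2L))
  names(p) <- trimws(vapply(kv, `[`, "", 1L))
  validate_profile(p, sprintf("row %d, field '%s'", row, field))
  p
}

validate_profile <- function(p, what = "profile") {
  if (any(is.na(p)) || any(p < 0))
    stop(sprintf("%s: proportions must be numeric and >= 0", what), call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("%s: proportions must sum to 1 (got %.12g)", what, sum(p)),
         call. = FALSE)
  p
}

format_profile <- function(p) {
  if (is.null(p) || length(p) == 0L) return("")
  paste(sprintf("%s:%s", names(p), formatC(p, format = "g", digits = 15)),
        collapse = "|")
}

parse_logical <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA)
  v <- toupper(trimws(cell))
  if (v %in% c("TRUE", "T", "1", "YES")) return(TRUE)
  if (v %in% c("FALSE", "F", "0", "NO")) return(FALSE)
  NA
}

parse_num <- function(cell, row, field, min = -Inf, max = Inf) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA_real_)
  v <- suppressWarnings(as.numeric(cell))
  if (is.na(v))
    stop(sprintf("row %d, field '%s': not a number ('%s')", row, field, cell),
         call. = FALSE)
  if (v < min || v > max)
    stop(sprintf("row %d, field '%s': value %g outside [%g, %g]",
                 row, field, v, min, max), call. = FALSE)
  v
}

read_raw <- function(path, sep) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           blank.lines.skip = TRUE)
  raw
}

col_or_na <- function(raw, name) {
  if (name %in% names(raw)) raw[[name]] else rep(NA_character_, nrow(raw))
}

#' Read an ego (child) table
#'
#' One row per child.  Required columns: `ego_id`, `age_months`, `races`.
#' Optional: `languages`, `childcare_out_of_home`, `urbanicity`
#' (`urban` / `suburban_rural`), `neighborhood_race_profile`,
#' `neighborhood_language_profile` (encoded `"cat:prop|cat:prop"`), and
#' `density_collected` (whether interaction-context data was collected for
#' this child's roster; defaults to `TRUE`).
#'
#' @param path file path of a delimited table with a header row.
#' @param sep field separator (default `","`; use `"\t"` for TSV).
#' @return data.frame with one validated row per ego; `races`, `languages`
#'   and the neighborhood profiles are list-columns.
#' @export
read_ego_table <- function(path, sep = ",") {
  raw <- read_raw(path, sep)
  if (nrow(raw) == 0L) {
    warning("empty ego table: ", path)
    return(empty_ego_table())
  }
  need <- c("ego_id", "age_months", "races")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("ego table missing column(s): ", paste(miss, collapse = ", "))

  n <- nrow(raw)
  out <- data.frame(ego_id = trimws(raw$ego_id), stringsAsFactors = FALSE)
  if (anyDuplicated(out$ego_id))
    stop("duplicate ego_id values in ego table")
  out$age_months <- vapply(seq_len(n), function(i)
    parse_num(raw$age_months[i], i, "age_months", min = 1e-9), 0)
  out$races <- lapply(seq_len(n), function(i) {
    toks <- split_set(raw$races[i])
    if (length(toks) == 0L)
      stop(sprintf("row %d, field 'races': egos must have at least one race", i),
           call. = FALSE)
    normalize_races(toks)
  })
  langs <- col_or_na(raw, "languages")
  out$languages <- lapply(langs, split_set)
  out$childcare_out_of_home <-
    vapply(col_or_na(raw, "childcare_out_of_home"), parse_logical, NA)
  urb <- trimws(col_or_na(raw, "urbanicity"))
  urb[!is.na(urb) & !nzchar(urb)] <- NA_character_
  bad <- !is.na(urb) & !urb %in% c("urban", "suburban_rural")
  if (any(bad))
    stop(sprintf("row %d, field 'urbanicity': must be 'urban' or 'suburban_rural'",
                 which(bad)[1]), call. = FALSE)
  out$urbanicity <- unname(urb)
  out$neighborhood_race_profile <- lapply(seq_len(n), function(i)
    parse_profile(col_or_na(raw, "neighborhood_race_profile")[i], i,
                  "neighborhood_race_profile"))
  out$neighborhood_language_profile <- lapply(seq_len(n), function(i)
    parse_profile(col_or_na(raw, "neighborhood_language_profile")[i], i,
                  "neighborhood_language_profile"))
  dc <- vapply(col_or_na(raw, "density_collected"), parse_logical, NA)
  out$density_collected <- ifelse(is.na(dc), TRUE, dc)
  rownames(out) <- NULL
  out
}

empty_ego_table <- function() {
  data.frame(ego_id = character(0), age_months = numeric(0),
             races = I(list()), languages = I(list()),
             childcare_out_of_home = logical(0), urbanicity = character(0),
             neighborhood_race_profile = I(list()),
             neighborhood_language_profile = I(list()),
             density_collected = logical(0), stringsAsFactors = FALSE)
}

#' Read an alter (network member) table
#'
#' One row per alter.  Required columns: `ego_id`, `alter_id`, `contexts`
#' (non-empty set of interaction settings such as `"family"`, `"daycare"`).
#' Optional: `is_group` (multi-person nodes such as a preschool class),
#' `age_years`, `races`, `languages`, `preverbal`, `relationship`
#' (free-text label, e.g. `"mother"`), and the three intensity measures
#' `n_activities`, `closeness`, `prop_waking_hours`.
#'
#' Missing demographic cells are allowed (the record stays valid and the
#' affected metrics are reported as missing); a duplicate
#' `(ego_id, alter_id)` pair is an error.
#'
#' @inheritParams read_ego_table
#' @return data.frame with one validated row per alter; `races`, `languages`
#'   and `contexts` are list-columns.
#' @export
read_alter_table <- function(path, sep = ",") {
  raw <- read_raw(path, sep)
  if (nrow(raw) == 0L) {
    warning("empty alter table: ", path)
    return(empty_alter_table())
  }
  need <- c("ego_id", "alter_id", "contexts")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("alter table missing column(s): ", paste(miss, collapse = ", "))

  n <- nrow(raw)
  out <- data.frame(ego_id = trimws(raw$ego_id),
                    alter_id = trimws(raw$alter_id),
                    stringsAsFactors = FALSE)
  key <- paste(out$ego_id, out$alter_id, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (ego_id, alter_id) pair at row %d: (%s, %s)",
                 which(duplicated(key))[1],
                 out$ego_id[which(duplicated(key))[1]],
                 out$alter_id[which(duplicated(key))[1]]), call. = FALSE)
  ig <- vapply(col_or_na(raw, "is_group"), parse_logical, NA)
  out$is_group <- ifelse(is.na(ig), FALSE, ig)
  out$age_years <- vapply(seq_len(n), function(i)
    parse_num(col_or_na(raw, "age_years")[i], i, "age_years", min = 0), 0)
  races <- col_or_na(raw, "races")
  out$races <- lapply(seq_len(n), function(i) {
    toks <- split_set(races[i])
    if (length(toks) == 0L) character(0) else normalize_races(toks)
  })
  out$languages <- lapply(col_or_na(raw, "languages"), split_set)
  pv <- vapply(col_or_na(raw, "preverbal"), parse_logical, NA)
  out$preverbal <- ifelse(is.na(pv), FALSE, pv)
  rel <- trimws(col_or_na(raw, "relationship"))
  rel[is.na(rel)] <- ""
  out$relationship <- unname(rel)
  out$contexts <- lapply(seq_len(n), function(i) {
    cx <- split_set(raw$contexts[i])
    if (length(cx) == 0L)
      stop(sprintf("row %d, field 'contexts': every alter needs at least one context", i),
           call. = FALSE)
    cx
  })
  out$n_activities <- vapply(seq_len(n), function(i)
    parse_num(col_or_na(raw, "n_activities")[i], i, "n_activities", min = 0), 0)
  out$closeness <- vapply(seq_len(n), function(i)
    parse_num(col_or_na(raw, "closeness")[i], i, "closeness"), 0)
  out$prop_waking_hours <- vapply(seq_len(n), function(i)
    parse_num(col_or_na(raw, "prop_waking_hours")[i], i, "prop_waking_hours",
              min = 0, max = 1), 0)
  rownames(out) <- NULL
  out
}

empty_alter_table <- function() {
  data.frame(ego_id = character(0), alter_id = character(0),
             is_group = logical(0), age_years = numeric(0),
             races = I(list()), languages = I(list()), preverbal = logical(0),
             relationship = character(0), contexts = I(list()),
             n_activities = numeric(0), closeness = numeric(0),
             prop_waking_hours = numeric(0), stringsAsFactors = FALSE)
}

#' Write ego / alter tables
#'
#' Inverse of [read_ego_table()] / [read_alter_table()]: list-columns are
#' flattened back to `"|"`-separated cells so that a written roster re-reads
#' to field-identical records.
#'
#' @param egos,alters data.frames as returned by the readers (or
#'   [simulate_cohort()]).
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_ego_table <- function(egos, path, sep = ",") {
  flat <- data.frame(
    ego_id = egos$ego_id,
    age_months = egos$age_months,
    races = vapply(egos$races, join_set, ""),
    languages = vapply(egos$languages, join_set, ""),
    childcare_out_of_home = egos$childcare_out_of_home,
    urbanicity = ifelse(is.na(egos$urbanicity), "", egos$urbanicity),
    neighborhood_race_profile =
      vapply(egos$neighborhood_race_profile, format_profile, ""),
    neighborhood_language_profile =
      vapply(egos$neighborhood_language_profile, format_profile, ""),
    density_collected = egos$density_collected,
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_ego_table
#' @export
write_alter_table <- function(alters, path, sep = ",") {
  flat <- data.frame(
    ego_id = alters$ego_id,
    alter_id = alters$alter_id,
    is_group = alters$is_group,
    age_years = alters$age_years,
    races = vapply(alters$races, join_set, ""),
    languages = vapply(alters$languages, join_set, ""),
    preverbal = alters$preverbal,
    relationship = alters$relationship,
    contexts = vapply(alters$contexts, join_set, ""),
    n_activities = alters$n_activities,
    closeness = alters$closeness,
    prop_waking_hours = alters$prop_waking_hours,
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}
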