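# 7-level FFQ frequency coding and conversion to weekly consumption frequencies.

ffq_frequency_labels <- c(
  "not at all",
  "less than once a month",
  "1–3 d per month",
  "1–2 d per week",
  "3–5 d per week",
  "daily or almost daily",
  "more than once a day"
)

ffq_weekly_values <- c(0, 0.12, 0.47, 1.5, 4, 6, 8)

#' FFQ frequency levels and their weekly conversion values
#'
#' The food frequency questionnaire records how often each of 52 food items was
#' consumed over the past month on a 7-level ordinal scale. Each level maps to
#' a fixed weekly consumption frequency (times/week) used throughout scoring.
#'
#' @return A tibble with columns `code` (0--6), `label` and `weekly`
#'   (times/week).
#' @examples
#' ffq_levels()
#' @export
ffq_levels <- function() {
  tibble::tibble(
    code = 0:6,
    label = ffq_frequency_labels,
    weekly = ffq_weekly_values
  )
}

# Accepts integer codes 0-6, the English level labels (en dash or ASCII
# hyphen), or strings "0".."6"; returns integer codes with NA preserved.
# Errors naming every offending value.
normalize_frequency_level <- function(x, what = "frequency response") {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    code <- suppressWarnings(as.integer(round(x)))
    bad <- !is.na(x) & (is.na(code) | code < 0L | code > 6L |
                          abs(x - code) > 1e-9)
    code[is.na(x)] <- NA_integer_
    bad_vals <- unique(x[bad])
  } else {
    chr <- trimws(as.character(x))
    chr[!is.na(chr) & chr == ""] <- NA_character_
    ascii <- gsub("–", "-", ffq_frequency_labels)
    pos <- match(chr, ffq_frequency_labels)
    pos2 <- match(chr, ascii)
    pos3 <- match(chr, as.character(0:6))
    pos <- dplyr::coalesce(pos, pos2, pos3)
    code <- as.integer(pos - 1L)
    bad <- !is.na(chr) & is.na(code)
    bad_vals <- unique(chr[bad])
  }
  if (any(bad)) {
    stop(sprintf(
      "undefined %s value(s): %s",
      what, paste(sQuote(bad_vals), collapse = ", ")
    ), call. = FALSE)
  }
  code
}

#' Convert FFQ frequency levels to weekly consumption frequencies
#'
#' Maps the 7 ordinal response options to fixed weekly values: not at all (0),
#' less than once a month (0.12), 1--3 d per month (0.47), 1--2 d per week
#' (1.5), 3--5 d per week (4), daily or almost daily (6), more than once a day
#' (8 times per week).
#'
#' @param level Vector of frequency levels: integer codes 0--6 or level labels.
#' @return Numeric vector of weekly frequencies; `NA` maps to `NA`.
#' @examples
#' frequency_to_weekly(c("not at all", "3–5 d per week"))
#' frequency_to_weekly(0:6)
#' @export
frequency_to_weekly <- function(level) {
  code <- normalize_frequency_level(level)
  ffq_weekly_values[code + 1L]
}

#' Default 52-item FFQ schema
#'
#' Item identifiers of the 52-item FFQ, read from the packaged YAML schema.
#' Items not referenced by any scoring-table component are parsed and carried
#' through but never scored.
#'
#' @param path Optional path to an alternative YAML schema (a list under key
#'   `items`).
#' @return Character vector of item identifiers.
#' @export
default_item_schema <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ffq_items.yaml", package = "mhfii")
  items <- unlist(yaml::read_yaml(path)$items)
  as.character(items)
}

#' Read a table of FFQ responses
#'
#' Reads a CSV with one row per participant (`participant_id` column) and one
#' column per FFQ item, coded either as level labels or integer codes 0--6.
#' Missing cells are preserved as missing.
#'
#' @param path Path to the CSV file.
#' @param item_schema Character vector of expected item columns.
#' @return A tibble of class `ffq_tbl`: `participant_id` plus one integer-coded
#'   (0--6) column per item.
#' @export
read_ffq_table <- function(path, item_schema = default_item_schema()) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop(sprintf(
      "malformed CSV %s: first problem at row %d, column %d (%s)",
      path, prob$row[1], prob$col[1], prob$expected[1]
    ), call. = FALSE)
  }
  if (!"participant_id" %in% names(raw)) {
    stop("FFQ table must contain a 'participant_id' column", call. = FALSE)
  }
  if (anyDuplicated(raw$participant_id)) {
    dup <- unique(raw$participant_id[duplicated(raw$participant_id)])
    stop(sprintf("duplicated participant_id: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  item_cols <- setdiff(names(raw), "participant_id")
  unknown <- setdiff(item_cols, item_schema)
  if (length(unknown) > 0) {
    stop(sprintf("unknown FFQ item column(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(item_schema, item_cols)
  if (length(absent) > 0) {
    warning(sprintf("FFQ items absent from file (treated as missing): %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(participant_id = as.character(raw$participant_id))
  for (it in item_schema) {
    if (it %in% item_cols) {
      out[[it]] <- tryCatch(
        normalize_frequency_level(raw[[it]]),
        error = function(e) {
          stop(sprintf("column '%s': %s", it, conditionMessage(e)),
               call. = FALSE)
        }
      )
    } else {
      out[[it]] <- NA_integer_
    }
  }
  class(out) <- c("ffq_tbl", class(out))
  out
}

#' Write a table of FFQ responses
#'
#' Writes integer level codes (0--6), one column per item, so that
#' `read_ffq_table(write_ffq_table(x, f))` round-trips cell-for-cell.
#'
#' @param ffq An `ffq_tbl` (see [read_ffq_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ffq_table <- function(ffq, path) {
  readr::write_csv(as.data.frame(ffq), path, na = "")
  invisible(path)
}

#' Weekly frequencies for an FFQ table
#'
#' @param ffq An `ffq_tbl` of integer level codes.
#' @return A tibble of the same shape with weekly frequencies (times/week).
#' @export
ffq_weekly <- function(ffq) {
  out <- tibble::as_tibble(ffq)
  items <- setdiff(names(out), "participant_id")
  for (it in items) out[[it]] <- ffq_weekly_values[out[[it]] + 1L]
  out
}

#' Aggregate FFQ items into a food-group weekly frequency
#'
#' A group's weekly frequency is the sum of its member items' weekly
#' frequencies (a participant eating two vegetable items once a week consumes
#' vegetables twice a week). Missing member items are ignored when at least one
#' member is observed; a participant with all member items missing gets `NA`.
#'
#' @param ffq An `ffq_tbl`.
#' @param group A scoring-table component (a list with an `items` field) or a
#'   character vector of item ids.
#' @return Numeric vector of weekly group frequencies, one per participant.
#' @export
aggregate_group <- function(ffq, group) {
  items <- if (is.list(group)) group$items else group
  items <- as.character(unlist(items))
  missing_items <- setdiff(items, names(ffq))
  if (length(missing_items) > 0) {
    stop(sprintf("group references unknown item(s): %s",
                 paste(missing_items, collapse = ", ")), call. = FALSE)
  }
  wk <- ffq_weekly(ffq)
  mat <- as.matrix(wk[, items, drop = FALSE])
  n_obs <- rowSums(!is.na(mat))
  freq <- rowSums(mat, na.rm = TRUE)
  freq[n_obs == 0] <- NA_real_
  freq
}
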