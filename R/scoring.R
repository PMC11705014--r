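# mHFII scoring: declarative scoring table -> per-component points -> 0-18 total.

#' Read an mHFII scoring table from YAML
#'
#' The scoring table declares the 11 index components: member items, scoring
#' direction (`favourable`: higher frequency earns points; `limiting`: lower
#' frequency earns points), strictly increasing weekly-frequency thresholds
#' (one per point) and the maximum points (1 or 2).
#'
#' @param path Path to a scoring-table YAML file.
#' @return A `scoring_table` object (list with `index_name`, `max_total`,
#'   `components`).
#' @export
read_scoring_table <- function(path) {
  raw <- yaml::read_yaml(path)
  comps <- lapply(raw$components, function(cmp) {
    list(
      name = as.character(cmp$name),
      direction = as.character(cmp$direction),
      max_points = as.integer(cmp$max_points),
      thresholds = as.numeric(unlist(cmp$thresholds)),
      items = as.character(unlist(cmp$items))
    )
  })
  names(comps) <- vapply(comps, `[[`, "", "name")
  structure(
    list(
      index_name = raw$index_name %||% "mHFII",
      max_total = as.integer(raw$max_total %||% 18L),
      components = comps
    ),
    class = "scoring_table"
  )
}

#' The packaged default mHFII scoring table
#'
#' Eleven food-group components with a 0--18 total: seven 2-point components
#' (vegetables, fruits and berries, fibre-rich grains, fish, milk, red and
#' processed meat, sugar-sweetened beverages) and four 1-point components
#' (vegetable oil, nuts and seeds, fat spreads, snacks). Red and processed
#' meat, sugar-sweetened beverages and snacks are reverse-scored (limiting).
#'
#' @return A `scoring_table` object.
#' @export
default_scoring_table <- function() {
  read_scoring_table(
    system.file("extdata", "scoring_table.yaml", package = "mhfii")
  )
}

#' Validate an mHFII scoring table
#'
#' Checks the structural constraints of the index: exactly 11 components with
#' unique names, maximum points in \{1, 2\} summing to 18 (hence seven 2-point
#' and four 1-point components), strictly increasing non-negative thresholds
#' with one threshold per point, a known direction, and (when an item schema is
#' supplied) member items covered by the schema with no item scored twice.
#'
#' @param table A `scoring_table`.
#' @param item_schema Optional character vector of known item ids.
#' @return A list with elements `valid` (logical) and `messages` (character
#'   vector of failures, empty when valid).
#' @export
validate_scoring_table <- function(table, item_schema = NULL) {
  msgs <- character()
  comps <- table$components
  if (length(comps) != 11L) {
    msgs <- c(msgs, sprintf("expected 11 components, found %d", length(comps)))
  }
  nm <- vapply(comps, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    msgs <- c(msgs, "component names must be unique")
  }
  mp <- vapply(comps, `[[`, 0L, "max_points")
  if (!all(mp %in% c(1L, 2L))) {
    msgs <- c(msgs, "max_points must be 1 or 2 for every component")
  }
  if (sum(mp) != 18L) {
    msgs <- c(msgs, sprintf("component maximum points must sum to 18, got %d",
                            sum(mp)))
  }
  for (cmp in comps) {
    if (!cmp$direction %in% c("favourable", "limiting")) {
      msgs <- c(msgs, sprintf("component '%s': unknown direction '%s'",
                              cmp$name, cmp$direction))
    }
    th <- cmp$thresholds
    if (length(th) != cmp$max_points) {
      msgs <- c(msgs, sprintf(
        "component '%s': %d thresholds for %d points (need one per point)",
        cmp$name, length(th), cmp$max_points))
    }
    if (length(th) > 1 && any(diff(th) <= 0)) {
      msgs <- c(msgs, sprintf("component '%s': thresholds must be strictly increasing",
                              cmp$name))
    }
    if (any(th < 0)) {
      msgs <- c(msgs, sprintf("component '%s': thresholds must be non-negative",
                              cmp$name))
    }
    if (length(cmp$items) == 0) {
      msgs <- c(msgs, sprintf("component '%s': no member items", cmp$name))
    }
  }
  if (!is.null(item_schema)) {
    all_items <- unlist(lapply(comps, `[[`, "items"))
    unknown <- setdiff(all_items, item_schema)
    if (length(unknown) > 0) {
      msgs <- c(msgs, sprintf("items not in schema: %s",
                              paste(unknown, collapse = ", ")))
    }
    if (anyDuplicated(all_items)) {
      msgs <- c(msgs, sprintf(
        "items scored in more than one component: %s",
        paste(unique(all_items[duplicated(all_items)]), collapse = ", ")))
    }
  }
  list(valid = length(msgs) == 0, messages = msgs)
}

#' Score a single mHFII component from a weekly group frequency
#'
#' Favourable components award one point per threshold at or below the weekly
#' frequency ("at least" bands, boundary included); limiting components award
#' one point per threshold at or above it ("at most" bands, boundary
#' included). A frequency exactly at a cut-off therefore earns the higher
#' band's score.
#'
#' @param weekly_freq Numeric vector of weekly group frequencies (>= 0).
#' @param rule One scoring-table component entry.
#' @return Integer points in `[0, rule$max_points]`; `NA` propagates.
#' @examples
#' tab <- default_scoring_table()
#' score_component(c(0, 7, 14), tab$components$vegetables)
#' @export
score_component <- function(weekly_freq, rule) {
  if (any(weekly_freq < 0, na.rm = TRUE)) {
    stop(sprintf("component '%s': negative weekly frequency", rule$name),
         call. = FALSE)
  }
  th <- rule$thresholds
  if (rule$direction == "favourable") {
    cmp <- outer(weekly_freq, th, `>=`)
  } else {
    cmp <- outer(weekly_freq, th, `<=`)
  }
  as.integer(rowSums(cmp))
}

#' Compute mHFII component scores and totals for an FFQ table
#'
#' Aggregates each component's member items into a weekly group frequency
#' (see [aggregate_group()]), scores each of the 11 components and sums them
#' into the 0--18 total. A component whose member items are all missing is
#' scored `NA` and the participant is flagged `incomplete` (such participants
#' are excluded from downstream analyses); components with at least one
#' observed member item are scored on the observed items.
#'
#' @param ffq An `ffq_tbl` (see [read_ffq_table()]).
#' @param table A `scoring_table`; defaults to the packaged table.
#' @return A tibble with `participant_id`, one integer column per component,
#'   `n_missing_components`, `total` (`NA` when incomplete) and `incomplete`.
#' @export
score_mhfii <- function(ffq, table = default_scoring_table()) {
  chk <- validate_scoring_table(table)
  if (!chk$valid) {
    stop(paste(c("invalid scoring table:", chk$messages), collapse = "\n  "),
         call. = FALSE)
  }
  out <- tibble::tibble(participant_id = ffq$participant_id)
  for (cmp in table$components) {
    freq <- aggregate_group(ffq, cmp)
    out[[cmp$name]] <- score_component(freq, cmp)
  }
  comp_cols <- names(table$components)
  score_mat <- as.matrix(out[, comp_cols, drop = FALSE])
  out$n_missing_components <- as.integer(rowSums(is.na(score_mat)))
  out$total <- as.integer(rowSums(score_mat))
  out$incomplete <- out$n_missing_components > 0L
  out
}
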