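# HFIAS: nine-item individual-level food-insecurity scale (30-day recall),
# scored into four ordered categories with the standard Coates decision table.

hfias_frequency_labels <- c("never", "rarely", "sometimes", "often")

fi_category_labels <- c("food_secure", "mild", "moderate", "severe")

#' Food-insecurity category levels
#'
#' The four ordered HFIAS categories, from `food_secure` (code 0) to `severe`
#' (code 3).
#'
#' @return A tibble with columns `code` (0--3) and `label`.
#' @export
fi_levels <- function() {
  tibble::tibble(code = 0:3, label = fi_category_labels)
}

fi_factor <- function(x, ordered = TRUE) {
  factor(as.character(x), levels = fi_category_labels, ordered = ordered)
}

normalize_hfias_frequency <- function(x, what = "HFIAS frequency") {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    code <- suppressWarnings(as.integer(round(x)))
    bad <- !is.na(x) & (is.na(code) | code < 0L | code > 3L |
                          abs(x - code) > 1e-9)
    code[is.na(x)] <- NA_integer_
    bad_vals <- unique(x[bad])
  } else {
    chr <- trimws(tolower(as.character(x)))
    chr[!is.na(chr) & chr == ""] <- NA_character_
    pos <- match(chr, hfias_frequency_labels)
    pos2 <- match(chr, as.character(0:3))
    pos <- dplyr::coalesce(pos, pos2)
    code <- as.integer(pos - 1L)
    bad <- !is.na(chr) & is.na(code)
    bad_vals <- unique(chr[bad])
  }
  if (any(bad)) {
    stop(sprintf("undefined %s value(s): %s", what,
                 paste(sQuote(bad_vals), collapse = ", ")), call. = FALSE)
  }
  code
}

hfias_question_cols <- paste0("q", 1:9)

# coerce a 9-column object (or length-9 vector) of frequency responses into an
# n x 9 integer matrix of codes 0-3
as_hfias_matrix <- function(responses) {
  if (is.null(dim(responses)) && length(responses) == 9) {
    responses <- matrix(responses, nrow = 1,
                        dimnames = list(NULL, hfias_question_cols))
  }
  if (is.data.frame(responses)) {
    missing_cols <- setdiff(hfias_question_cols, names(responses))
    if (length(missing_cols) > 0) {
      stop(sprintf("missing HFIAS column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    responses <- responses[, hfias_question_cols]
    mat <- vapply(responses, normalize_hfias_frequency,
                  integer(nrow(responses)))
    if (nrow(responses) == 1) mat <- matrix(mat, nrow = 1)
  } else {
    mat <- apply(responses, 2, normalize_hfias_frequency)
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  }
  colnames(mat) <- hfias_question_cols
  mat
}

#' Categorise HFIAS responses into food-insecurity categories
#'
#' Applies the standard HFIAS categorisation: the most severe category whose
#' trigger is met wins.
#' \itemize{
#'   \item severe: Q5 or Q6 = often, or Q7, Q8 or Q9 >= rarely
#'   \item moderate: Q3 or Q4 >= sometimes, or Q5 or Q6 in \{rarely, sometimes\}
#'   \item mild: Q1 >= sometimes, or Q2 >= rarely, or Q3 or Q4 = rarely
#'   \item food secure otherwise (Q1 at most rarely, Q2--Q9 never)
#' }
#' A response with any missing item yields `NA` (the participant is excluded
#' from downstream analyses).
#'
#' @param responses A data frame or matrix with columns `q1`..`q9` coded
#'   never/rarely/sometimes/often (labels or codes 0--3), or a single length-9
#'   vector.
#' @return Ordered factor with levels food_secure < mild < moderate < severe.
#' @examples
#' categorize_hfias(rep("never", 9))
#' categorize_hfias(c(0, 0, 0, 0, 0, 0, 0, 0, 1))  # only Q9 rarely -> severe
#' @export
categorize_hfias <- function(responses) {
  m <- as_hfias_matrix(responses)
  severe <- m[, "q5"] == 3L | m[, "q6"] == 3L |
    m[, "q7"] >= 1L | m[, "q8"] >= 1L | m[, "q9"] >= 1L
  moderate <- m[, "q3"] >= 2L | m[, "q4"] >= 2L |
    (m[, "q5"] >= 1L & m[, "q5"] <= 2L) | (m[, "q6"] >= 1L & m[, "q6"] <= 2L)
  mild <- m[, "q1"] >= 2L | m[, "q2"] >= 1L |
    m[, "q3"] == 1L | m[, "q4"] == 1L
  code <- ifelse(severe, 3L, ifelse(moderate, 2L, ifelse(mild, 1L, 0L)))
  code[rowSums(is.na(m)) > 0] <- NA_integer_
  fi_factor(fi_category_labels[code + 1L])
}

#' HFIAS continuous score
#'
#' Sum of the nine 0--3 item frequencies (0--27). Exported for convenience;
#' not used by the analyses, which work on the four categories.
#'
#' @inheritParams categorize_hfias
#' @return Integer vector in 0--27, `NA` when any item is missing.
#' @export
hfias_score <- function(responses) {
  m <- as_hfias_matrix(responses)
  as.integer(rowSums(m))
}

#' Read a table of HFIAS responses
#'
#' Reads a CSV with a `participant_id` column plus either nine combined
#' frequency columns `q1`..`q9` (never/rarely/sometimes/often or codes 0--3),
#' or additionally nine occurrence columns `q1_occ`..`q9_occ` (logical/0-1).
#' When occurrence columns are present, occurrence and frequency must be
#' consistent (`occurrence = FALSE` iff `frequency = never`); inconsistent
#' rows raise a validation error listing the rows.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `participant_id`, integer `q1`..`q9`, the continuous
#'   `hfias_score` (0--27), and the `fi_category` as both ordered factor and
#'   integer `fi_code` (0--3).
#' @export
read_hfias_table <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"participant_id" %in% names(raw)) {
    stop("HFIAS table must contain a 'participant_id' column", call. = FALSE)
  }
  if (anyDuplicated(raw$participant_id)) {
    dup <- unique(raw$participant_id[duplicated(raw$participant_id)])
    stop(sprintf("duplicated participant_id: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  missing_cols <- setdiff(hfias_question_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing HFIAS column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  freq <- vapply(raw[, hfias_question_cols], normalize_hfias_frequency,
                 integer(nrow(raw)))
  if (nrow(raw) == 1) freq <- matrix(freq, nrow = 1,
                                     dimnames = list(NULL, hfias_question_cols))
  occ_cols <- paste0(hfias_question_cols, "_occ")
  if (any(occ_cols %in% names(raw))) {
    present <- intersect(occ_cols, names(raw))
    occ_raw <- raw[, present, drop = FALSE]
    occ <- vapply(occ_raw, function(x) {
      x <- trimws(tolower(as.character(x)))
      out <- rep(NA, length(x))
      out[x %in% c("1", "true", "yes")] <- TRUE
      out[x %in% c("0", "false", "no")] <- FALSE
      out
    }, logical(nrow(raw)))
    if (nrow(raw) == 1) occ <- matrix(occ, nrow = 1,
                                      dimnames = list(NULL, present))
    bad_rows <- integer()
    for (j in seq_along(present)) {
      qi <- sub("_occ$", "", present[j])
      f <- freq[, qi]
      o <- occ[, j]
      inconsistent <- which(!is.na(o) & !is.na(f) & (o != (f > 0L)))
      bad_rows <- union(bad_rows, inconsistent)
    }
    if (length(bad_rows) > 0) {
      stop(sprintf(
        "inconsistent occurrence/frequency pairs in row(s): %s",
        paste(sort(bad_rows), collapse = ", ")), call. = FALSE)
    }
  }
  out <- tibble::tibble(participant_id = as.character(raw$participant_id))
  for (q in hfias_question_cols) out[[q]] <- freq[, q]
  out$hfias_score <- as.integer(rowSums(freq))
  out$fi_category <- categorize_hfias(out)
  out$fi_code <- as.integer(out$fi_category) - 1L
  out
}
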