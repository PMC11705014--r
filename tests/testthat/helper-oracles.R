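# Test helpers: fixture builders and independent brute-force oracles.

# Build a complete 52-item FFQ record (codes); unspecified items default to
# "not at all" (0) or NA when default = NA.
make_ffq <- function(..., id = "p1", default = 0L) {
  levels <- list(...)
  schema <- default_item_schema()
  rec <- tibble::tibble(participant_id = id)
  for (it in schema) rec[[it]] <- as.integer(default)
  for (it in names(levels)) {
    stopifnot(it %in% schema)
    rec[[it]] <- as.integer(levels[[it]])
  }
  class(rec) <- c("ffq_tbl", class(rec))
  rec
}

# Independent scalar transcription of the standard HFIAS decision table
# (most severe triggered category wins); q is a length-9 vector of codes 0-3.
hfias_oracle <- function(q) {
  if (q[5] == 3 || q[6] == 3 || q[7] > 0 || q[8] > 0 || q[9] > 0) {
    return("severe")
  }
  if (q[3] >= 2 || q[4] >= 2 || (q[5] >= 1 && q[5] <= 2) ||
      (q[6] >= 1 && q[6] <= 2)) {
    return("moderate")
  }
  if (q[1] >= 2 || q[2] >= 1 || q[3] == 1 || q[4] == 1) {
    return("mild")
  }
  "food_secure"
}

# Independent brute-force component scorer: walks the bands one by one
# instead of counting threshold crossings.
score_component_oracle <- function(w, rule) {
  if (is.na(w)) return(NA_integer_)
  pts <- 0L
  if (rule$direction == "favourable") {
    for (th in rule$thresholds) if (w >= th) pts <- pts + 1L
  } else {
    for (th in rev(rule$thresholds)) if (w <= th) pts <- pts + 1L
  }
  pts
}

write_csv_text <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
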