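# Bioactivity curation: raw activity tables -> one standardized record per
# (compound, target) pair, following the ChEMBL-style conventions: pChEMBL
# units, ranked activity types, duplicate averaging.

.activity_types <- c("Ki", "IC50", "EC50", "Kd") # priority order, best first

#' Convert a concentration to a pChEMBL value
#'
#' @param value positive concentration.
#' @param unit one of `"nM"`, `"uM"` (micromolar), `"M"`.
#' @return the pChEMBL value, \eqn{-\log_{10}} of the molar concentration,
#'   so 100 nM gives 7.00.
#' @examples
#' pchembl_from_concentration(100, "nM") # 7
#' @export
pchembl_from_concentration <- function(value, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    stop("concentration must be a finite positive number")
  }
  molar <- value * switch(unit, nM = 1e-9, uM = 1e-6, M = 1)
  -log10(molar)
}

#' Keep only the highest-priority activity type
#'
#' For measurements of one (compound, target) pair reported under several
#' activity types, keeps only the records of the best-ranked type present,
#' with priority Ki > IC50 > EC50 > Kd. Lower-priority measurements are
#' discarded, not averaged in.
#'
#' @param records data.frame with at least an `activity_type` column.
#' @return the subset of `records` with the best-ranked type.
#' @export
select_activity_unit <- function(records) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "select_activity_unit needs a nonempty data.frame")
  rank <- match(records$activity_type, .activity_types)
  assert_that(!anyNA(rank), paste("unknown activity_type:",
              paste(unique(records$activity_type[is.na(rank)]), collapse = ", ")))
  records[rank == min(rank), , drop = FALSE]
}

#' Average duplicate measurements into a single record
#'
#' @param records data.frame of measurements for one (compound, target) pair,
#'   already reduced to a single activity type; columns `pchembl` and
#'   optionally `year`.
#' @return one-row data.frame with the mean `pchembl`, `n_merged`, and the
#'   earliest `year` present (`NA` if no record carries a year).
#' @export
aggregate_duplicates <- function(records) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "aggregate_duplicates needs a nonempty data.frame")
  assert_that(length(unique(records$activity_type)) == 1L,
              "mixed activity types: run select_activity_unit first")
  yrs <- if ("year" %in% names(records)) records$year else rep(NA_integer_, nrow(records))
  year <- if (all(is.na(yrs))) NA_integer_ else as.integer(min(yrs, na.rm = TRUE))
  data.frame(pchembl = mean(records$pchembl), n_merged = nrow(records), year = year)
}

#' Curate a raw bioactivity table
#'
#' Runs the full per-pair pipeline: compound standardization, activity-type
#' selection, duplicate averaging. Records whose SMILES cannot be parsed or
#' whose target has no sequence in `sequences` are dropped and counted.
#'
#' @param raw data.frame with columns `compound_id`, `smiles`, `target_id`,
#'   `activity_type`, `pchembl` (already in -log10 molar) and optionally
#'   `year`.
#' @param sequences named character vector (or `Biostrings::AAStringSet`) of
#'   target sequences; every retained record's `target_id` must be present.
#'   `NULL` skips the sequence check.
#' @return list with `records` (data.frame: `standardized_smiles`,
#'   `target_id`, `pchembl`, `year`, `n_merged`, one row per pair) and
#'   `report` (counts in/out and rejection reasons).
#' @export
curate_dataset <- function(raw, sequences = NULL) {
  assert_that(is.data.frame(raw), "raw must be a data.frame")
  need <- c("smiles", "target_id", "activity_type", "pchembl")
  assert_that(all(need %in% names(raw)),
              paste("raw is missing columns:", paste(setdiff(need, names(raw)), collapse = ", ")))
  if (!is.null(sequences)) sequences <- as_named_chr(sequences)
  empty <- data.frame(standardized_smiles = character(0), target_id = character(0),
                      pchembl = numeric(0), year = integer(0), n_merged = integer(0))
  report <- list(n_in = nrow(raw), n_out = 0L, n_unparseable = 0L,
                 n_missing_sequence = 0L, n_nonfinite = 0L)
  if (nrow(raw) == 0L) return(list(records = empty, report = report))

  bad_val <- !is.finite(raw$pchembl)
  report$n_nonfinite <- sum(bad_val)
  raw <- raw[!bad_val, , drop = FALSE]

  usmi <- unique(raw$smiles)
  ustd <- standardize_compound(usmi)
  std <- as.character(ustd)[match(raw$smiles, usmi)]
  report$n_unparseable <- sum(is.na(std))
  keep <- !is.na(std)
  raw <- raw[keep, , drop = FALSE]
  raw$standardized_smiles <- std[keep]

  if (!is.null(sequences)) {
    miss <- !(raw$target_id %in% names(sequences))
    report$n_missing_sequence <- sum(miss)
    raw <- raw[!miss, , drop = FALSE]
  }
  if (nrow(raw) == 0L) return(list(records = empty, report = report))

  key <- paste(raw$standardized_smiles, raw$target_id, sep = "\r")
  parts <- split(raw, key)
  rows <- lapply(parts, function(p) {
    sel <- select_activity_unit(p)
    agg <- aggregate_duplicates(sel)
    data.frame(standardized_smiles = p$standardized_smiles[1],
               target_id = p$target_id[1],
               pchembl = agg$pchembl, year = agg$year, n_merged = agg$n_merged)
  })
  records <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  records <- records[order(records$target_id, records$standardized_smiles), , drop = FALSE]
  rownames(records) <- NULL
  report$n_out <- nrow(records)
  list(records = records, report = report)
}

#' Read an activity table from CSV/TSV
#'
#' Accepts either a `pchembl` column or a `value` + `unit` pair (converted
#' with [pchembl_from_concentration()]).
#'
#' @param path file path; tab- or comma-separated, with header.
#' @return data.frame ready for [curate_dataset()].
#' @export
read_activities <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                         quote = "\"", comment.char = "")
  if (!"pchembl" %in% names(x)) {
    assert_that(all(c("value", "unit") %in% names(x)),
                "activity table needs either a pchembl column or value+unit columns")
    x$pchembl <- mapply(pchembl_from_concentration, x$value, x$unit)
  }
  x
}
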