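# End-to-end orchestration and CSV I/O.

TABLE_NAMES <- c("enrollment", "pharmacy", "medical", "patients",
                 "ground_truth")

#' Write claim tables to a directory of CSV files
#'
#' Writes `enrollment.csv`, `pharmacy.csv`, `medical.csv`, `patients.csv`
#' and (when present) `ground_truth.csv`. Dates are ISO-8601.
#'
#' @param tables named list of tables.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_claims_dir <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in intersect(TABLE_NAMES, names(tables))) {
    data.table::fwrite(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read claim tables from a directory of CSV files
#'
#' @param dir directory holding the CSVs written by [write_claims_dir()].
#' @return named list of `data.table`s with date columns restored.
#' @export
read_claims_dir <- function(dir) {
  out <- list()
  date_cols <- c("fill_date", "service_date", "admission_date",
                 "discharge_date", "start_date", "end_date", "dob",
                 "index_date")
  for (nm in TABLE_NAMES) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) next
    dt <- data.table::fread(f)
    for (cl in intersect(date_cols, names(dt)))
      dt[[cl]] <- as.Date(dt[[cl]])
    out[[nm]] <- dt
  }
  out
}

#' Run the full analysis pipeline on claim tables
#'
#' Cohort selection, exposure/adherence, baseline comorbidity, utilization
#' and expenditures, and the report tables, in one call.
#'
#' @param tables named list with `enrollment`, `pharmacy`, `medical`,
#'   `patients` (e.g. from [generate_population()] or [read_claims_dir()]).
#' @param window identification window for the index fill.
#' @param threshold adherence threshold (default 0.8).
#' @return list: `cohort`, `attrition`, `exposure`, `flags`, `hru`,
#'   `tables` (the four report tables).
#' @export
run_pipeline <- function(tables,
                         window = as.Date(c("2016-07-01", "2019-12-31")),
                         threshold = 0.8) {
  for (nm in c("enrollment", "pharmacy", "medical", "patients")) {
    if (is.null(tables[[nm]]))
      stop(sprintf("missing input table '%s'", nm))
  }
  sel <- apply_inclusion(tables, window)
  exposure <- compute_exposure(sel$cohort, tables$pharmacy, tables$medical,
                               threshold = threshold)
  flags <- compute_baseline_flags(sel$cohort, tables$medical)
  hru <- compute_hru_costs(sel$cohort, tables$medical, tables$pharmacy)
  reports <- if (nrow(sel$cohort) > 0L) {
    build_tables(sel$cohort, flags, exposure, hru, sel$attrition)
  } else NULL
  list(cohort = sel$cohort, attrition = sel$attrition, exposure = exposure,
       flags = flags, hru = hru, tables = reports)
}
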