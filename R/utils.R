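# Shared constants and small helpers.
#
# All within-patient arithmetic is done on integer day offsets relative to the
# patient's index date (index day = 0). Calendar dates appear only at I/O
# boundaries.

# 6-month baseline and 12-month follow-up, in index-anchored day offsets.
BASELINE_START <- -182L
BASELINE_END   <- -1L
FOLLOWUP_START <- 0L
FOLLOWUP_END   <- 364L
FOLLOWUP_DAYS  <- 365L

#' Study windows relative to the index date
#'
#' Returns the fixed baseline (days -182..-1) and follow-up (days 0..364)
#' windows used throughout the pipeline, as integer day offsets from the
#' index date (day 0). The follow-up is 365 days; leap days are ignored so
#' the adherence denominator is always 365.
#'
#' @return A list with integer vectors `baseline = c(start, end)` and
#'   `followup = c(start, end)`.
#' @export
study_windows <- function() {
  list(baseline = c(BASELINE_START, BASELINE_END),
       followup = c(FOLLOWUP_START, FOLLOWUP_END))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize ICD-10 diagnosis codes
#'
#' Uppercases and strips dots so that prefix matching is dot-insensitive
#' ("E11.9" and "E119" are the same code).
#'
#' @param codes character vector of ICD-10 codes (NA allowed).
#' @return character vector of normalized codes.
#' @export
normalize_icd10 <- function(codes) {
  out <- toupper(gsub(".", "", as.character(codes), fixed = TRUE))
  out[is.na(codes)] <- NA_character_
  out
}

# TRUE where `codes` (already normalized) start with any of `prefixes`
# (already normalized).
icd_prefix_match <- function(codes, prefixes) {
  if (length(codes) == 0L) return(logical(0))
  hit <- rep(FALSE, length(codes))
  ok <- !is.na(codes)
  for (p in prefixes) {
    hit[ok] <- hit[ok] | startsWith(codes[ok], p)
  }
  hit
}

# Any-position diagnosis match against a single prefix family (e.g. "F20")
# on a claims data.table with columns dx1..dxk.
dx_cols <- function(dt) grep("^dx[0-9]+$", names(dt), value = TRUE)

claim_has_dx_prefix <- function(dt, prefix) {
  cols <- dx_cols(dt)
  if (length(cols) == 0L || nrow(dt) == 0L) return(rep(FALSE, nrow(dt)))
  hit <- rep(FALSE, nrow(dt))
  for (cl in cols) {
    v <- normalize_icd10(dt[[cl]])
    hit <- hit | (!is.na(v) & startsWith(v, prefix))
  }
  hit
}

# IRanges helpers -----------------------------------------------------------

# Build a reduced IRanges from start/end day offsets, clipped to [lo, hi].
# Rows that fall entirely outside the window are dropped.
days_to_ranges <- function(start, end, lo = FOLLOWUP_START, hi = FOLLOWUP_END) {
  keep <- !is.na(start) & !is.na(end) & end >= lo & start <= hi
  s <- pmax(as.integer(start[keep]), lo)
  e <- pmin(as.integer(end[keep]), hi)
  IRanges::reduce(IRanges::IRanges(start = s, end = e))
}

n_days <- function(ir) sum(IRanges::width(ir))

empty_ranges <- function() IRanges::IRanges()
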