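# 12-month all-cause and schizophrenia-related utilization and expenditures.

#' Merge inpatient claims into stays
#'
#' Overlapping or same-day-adjacent inpatient claims (one claim's admission
#' on or before the previous claim's discharge, or on the day after it)
#' merge into a single stay. Stay length of stay (LOS) is inclusive:
#' `discharge - admission + 1` days, clipped to the follow-up window.
#' Rows with discharge before admission are rejected with a warning.
#'
#' @param inpatient `data.table` of one patient's inpatient claims
#'   (`admission_date`, `discharge_date`, diagnosis columns).
#' @param index_date the patient's index date.
#' @return `data.table` of merged stays: `start_day`, `end_day` (clipped
#'   offsets), `los` (days).
#' @export
build_stays <- function(inpatient, index_date) {
  empty <- data.table::data.table(start_day = integer(), end_day = integer(),
                                  los = integer())
  if (is.null(inpatient) || nrow(inpatient) == 0L) return(empty)
  adm <- as.integer(inpatient$admission_date - index_date)
  dis <- as.integer(inpatient$discharge_date - index_date)
  bad <- is.na(adm) | is.na(dis) | dis < adm
  if (any(bad)) {
    warning(sprintf("%d inpatient row(s) with malformed dates rejected",
                    sum(bad)))
    adm <- adm[!bad]; dis <- dis[!bad]
  }
  if (length(adm) == 0L) return(empty)
  # merge with a 1-day gap tolerance (same-day-adjacent), then clip
  ir <- IRanges::reduce(IRanges::IRanges(start = adm, end = dis),
                        min.gapwidth = 1L)
  st <- pmax(IRanges::start(ir), FOLLOWUP_START)
  en <- pmin(IRanges::end(ir), FOLLOWUP_END)
  keep <- en >= st
  data.table::data.table(start_day = st[keep], end_day = en[keep],
                         los = en[keep] - st[keep] + 1L)
}

# scope filter: all claims, or only claims carrying an F20.x diagnosis.
# A precomputed logical column `f20` (added by compute_hru_costs) is used
# when present to avoid rescanning diagnosis columns per patient.
scope_rows <- function(claims, scope) {
  if (scope == "all_cause") rep(TRUE, nrow(claims))
  else if ("f20" %in% names(claims)) claims$f20
  else claim_has_dx_prefix(claims, "F20")
}

#' Count visits for one patient and scope
#'
#' Inpatient visits are merged stays; ED visits are distinct service dates
#' (same-day ED claims collapse to one visit); outpatient visits count claim
#' rows ("visits/services"). The schizophrenia-related scope keeps only
#' claims carrying an F20.x diagnosis in any position. ED claims falling
#' inside an inpatient stay are still counted as ED visits (no roll-up).
#' Only claims with service dates inside follow-up (days 0..364) count.
#'
#' @param medical `data.table` of one patient's medical claims.
#' @param index_date the patient's index date.
#' @param scope `"all_cause"` or `"schizophrenia"`.
#' @return list: `inpatient_visits`, `inpatient_days` (NA when no stay),
#'   `ed_visits`, `outpatient_visits`, `any_inpatient`, `any_ed`,
#'   `any_outpatient`.
#' @export
count_visits <- function(medical, index_date,
                         scope = c("all_cause", "schizophrenia")) {
  scope <- match.arg(scope)
  md <- medical[scope_rows(medical, scope), ]
  day <- as.integer(md$service_date - index_date)
  inwin <- !is.na(day) & day >= FOLLOWUP_START & day <= FOLLOWUP_END
  ip <- md[md$setting == "inpatient" & inwin, ]
  stays <- build_stays(ip, index_date)
  ed_days <- unique(day[md$setting == "ed" & inwin])
  n_op <- sum(md$setting == "outpatient" & inwin)
  list(inpatient_visits = nrow(stays),
       inpatient_days = if (nrow(stays) > 0L) sum(stays$los) else NA_integer_,
       ed_visits = length(ed_days),
       outpatient_visits = n_op,
       any_inpatient = nrow(stays) >= 1L,
       any_ed = length(ed_days) >= 1L,
       any_outpatient = n_op >= 1L)
}

#' Sum expenditures for one patient and scope
#'
#' Paid amounts within follow-up summed by category. The all-cause
#' prescription bucket contains every outpatient pharmacy claim; the
#' schizophrenia-related drug bucket contains OAAP claims only. Medical
#' total = inpatient + ED + outpatient; grand total adds the drug bucket.
#' Rows with negative paid amounts are rejected with a warning (claim
#' reversals are out of scope).
#'
#' @param medical one patient's medical claims.
#' @param pharmacy one patient's pharmacy claims.
#' @param index_date the patient's index date.
#' @param scope `"all_cause"` or `"schizophrenia"`.
#' @return list: `inpatient`, `ed`, `outpatient`, `rx`, `total_medical`,
#'   `total` (2020 USD).
#' @export
sum_expenditures <- function(medical, pharmacy, index_date,
                             scope = c("all_cause", "schizophrenia")) {
  scope <- match.arg(scope)
  md <- medical[scope_rows(medical, scope), ]
  day <- as.integer(md$service_date - index_date)
  inwin <- !is.na(day) & day >= FOLLOWUP_START & day <= FOLLOWUP_END
  md <- md[inwin, ]
  neg <- !is.na(md$paid) & md$paid < 0
  if (any(neg)) {
    warning(sprintf("%d claim(s) with negative paid amount rejected", sum(neg)))
    md <- md[!neg, ]
  }
  by_setting <- function(s) sum(md$paid[md$setting == s], na.rm = TRUE)

  rxday <- as.integer(pharmacy$fill_date - index_date)
  rxin <- !is.na(rxday) & rxday >= FOLLOWUP_START & rxday <= FOLLOWUP_END
  rx <- pharmacy[rxin & (if (scope == "all_cause") TRUE else
    pharmacy$drug_class == "OAAP"), ]
  negrx <- !is.na(rx$paid) & rx$paid < 0
  if (any(negrx)) {
    warning(sprintf("%d fill(s) with negative paid amount rejected",
                    sum(negrx)))
    rx <- rx[!negrx, ]
  }
  ipx <- by_setting("inpatient"); edx <- by_setting("ed")
  opx <- by_setting("outpatient")
  rxx <- sum(rx$paid, na.rm = TRUE)
  list(inpatient = ipx, ed = edx, outpatient = opx, rx = rxx,
       total_medical = ipx + edx + opx, total = ipx + edx + opx + rxx)
}

#' Per-patient utilization and expenditure summaries for a cohort
#'
#' @param cohort cohort table from [apply_inclusion()].
#' @param medical medical claims table.
#' @param pharmacy pharmacy claims table.
#' @return `data.table` with one row per patient and scope
#'   (`all_cause`/`schizophrenia`): visit counts, any-visit flags,
#'   inpatient days, and expenditure categories.
#' @export
compute_hru_costs <- function(cohort, medical, pharmacy) {
  md <- data.table::as.data.table(medical)
  ph <- data.table::as.data.table(pharmacy)
  md$f20 <- claim_has_dx_prefix(md, "F20")
  md_by <- split(seq_len(nrow(md)), md$patient_id)
  ph_by <- split(seq_len(nrow(ph)), ph$patient_id)
  out <- vector("list", 2L * nrow(cohort))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$patient_id[i]
    m <- md[md_by[[id]] %||% integer(0), ]
    p <- ph[ph_by[[id]] %||% integer(0), ]
    for (sc in c("all_cause", "schizophrenia")) {
      v <- count_visits(m, cohort$index_date[i], sc)
      e <- sum_expenditures(m, p, cohort$index_date[i], sc)
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        patient_id = id, scope = sc,
        inpatient_visits = v$inpatient_visits,
        inpatient_days = v$inpatient_days,
        ed_visits = v$ed_visits, outpatient_visits = v$outpatient_visits,
        any_inpatient = v$any_inpatient, any_ed = v$any_ed,
        any_outpatient = v$any_outpatient,
        exp_inpatient = e$inpatient, exp_ed = e$ed,
        exp_outpatient = e$outpatient, exp_rx = e$rx,
        exp_total_medical = e$total_medical, exp_total = e$total)
    }
  }
  data.table::rbindlist(out)
}

#' Mean-expenditure contrast between two groups
#'
#' Per-group mean totals and their difference (first group minus second),
#' e.g. hospitalized vs. not hospitalized. An empty group yields `NA`
#' means/difference.
#'
#' @param totals numeric vector of per-patient total expenditures.
#' @param flag logical grouping flag, same length (`NA` not allowed).
#' @return list: `mean_flagged`, `mean_unflagged`, `difference`.
#' @export
cost_contrast <- function(totals, flag) {
  stopifnot(length(totals) == length(flag), !anyNA(flag))
  m1 <- if (any(flag)) mean(totals[flag]) else NA_real_
  m0 <- if (any(!flag)) mean(totals[!flag]) else NA_real_
  list(mean_flagged = m1, mean_unflagged = m0, difference = m1 - m0)
}
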