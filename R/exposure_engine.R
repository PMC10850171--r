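# Coverage-day construction, hospitalization-adjusted PDC, adherence,
# switching and augmentation. All set operations are done with interval
# algebra (IRanges); the test suite checks them against an independent
# per-day boolean-array oracle.

#' Build a patient's coverage profile
#'
#' Converts a patient's pharmacy fills into per-drug sets of covered day
#' offsets inside follow-up (days 0..364), and the hospital-day set from
#' inpatient claims. A fill on day `d` with supply `s` covers days
#' `d..d+s-1`, truncated to the follow-up window; same-drug coverage is the
#' union of fill intervals (no stockpiling shift), and pre-index fills
#' contribute only their in-window tail. Rows with non-positive days supply,
#' or stays with discharge before admission, are rejected and counted in
#' `n_rejected`.
#'
#' @param fills `data.table` of the patient's pharmacy claims (`drug_name`,
#'   `drug_class`, `fill_date`, `days_supply`).
#' @param index_date the patient's index date (day 0).
#' @param index_drug name of the index OAAP product.
#' @param inpatient optional `data.table` of the patient's inpatient claims
#'   (`admission_date`, `discharge_date`) used for the hospital-day set.
#' @return An object of class `coverage_profile`: a list with `patient_id`,
#'   `index_drug`, `drugs` (named list of reduced `IRanges`, OAAP products
#'   only), `fill_days` (named list of integer fill-day offsets), `hospital`
#'   (reduced `IRanges`), `n_rejected`.
#' @export
build_coverage <- function(fills, index_date, index_drug,
                           inpatient = NULL) {
  oaap <- fills[fills$drug_class == "OAAP", ]
  day <- as.integer(oaap$fill_date - index_date)
  bad <- is.na(oaap$days_supply) | oaap$days_supply < 1L
  n_rejected <- sum(bad)
  if (n_rejected > 0L) {
    warning(sprintf("%d fill(s) with non-positive days supply rejected",
                    n_rejected))
    oaap <- oaap[!bad, ]; day <- day[!bad]
  }
  drugs <- list(); fill_days <- list()
  for (dr in unique(oaap$drug_name)) {
    sel <- oaap$drug_name == dr
    drugs[[dr]] <- days_to_ranges(day[sel], day[sel] + oaap$days_supply[sel] - 1L)
    fill_days[[dr]] <- sort(day[sel][day[sel] >= FOLLOWUP_START &
                                       day[sel] <= FOLLOWUP_END])
  }
  hosp <- empty_ranges()
  if (!is.null(inpatient) && nrow(inpatient) > 0L) {
    adm <- as.integer(inpatient$admission_date - index_date)
    dis <- as.integer(inpatient$discharge_date - index_date)
    bad <- is.na(adm) | is.na(dis) | dis < adm
    if (any(bad)) {
      warning(sprintf("%d inpatient row(s) with discharge before admission rejected",
                      sum(bad)))
      n_rejected <- n_rejected + sum(bad)
      adm <- adm[!bad]; dis <- dis[!bad]
    }
    hosp <- days_to_ranges(adm, dis)
  }
  structure(list(patient_id = fills$patient_id[1] %||% NA_character_,
                 index_drug = index_drug, drugs = drugs,
                 fill_days = fill_days, hospital = hosp,
                 n_rejected = n_rejected),
            class = "coverage_profile")
}

# union of covered days across a subset of drugs
coverage_union <- function(profile, scope = c("all", "index")) {
  scope <- match.arg(scope)
  sets <- if (scope == "index") {
    profile$drugs[names(profile$drugs) == profile$index_drug]
  } else profile$drugs
  if (length(sets) == 0L) return(empty_ranges())
  IRanges::reduce(do.call(c, unname(sets)))
}

#' Total medication days
#'
#' Number of distinct follow-up days on which the patient possessed the
#' index drug (`scope = "index"`) or any OAAP (`scope = "all"`). A day
#' covered by two concurrent OAAPs counts once.
#'
#' @param profile a `coverage_profile`.
#' @param scope `"index"` or `"all"`.
#' @return integer day count.
#' @export
total_medication_days <- function(profile, scope = c("index", "all")) {
  n_days(coverage_union(profile, match.arg(scope)))
}

#' Hospital-day set from inpatient claims
#'
#' Union of admission..discharge day ranges clipped to follow-up, with
#' overlapping stays merged. Rows with discharge before admission are
#' rejected with a warning.
#'
#' @param inpatient `data.table` with `admission_date`, `discharge_date`.
#' @param index_date the patient's index date.
#' @return reduced `IRanges` of hospital day offsets.
#' @export
hospital_days <- function(inpatient, index_date) {
  if (is.null(inpatient) || nrow(inpatient) == 0L) return(empty_ranges())
  adm <- as.integer(inpatient$admission_date - index_date)
  dis <- as.integer(inpatient$discharge_date - index_date)
  bad <- is.na(adm) | is.na(dis) | dis < adm
  if (any(bad))
    warning(sprintf("%d inpatient row(s) with discharge before admission rejected",
                    sum(bad)))
  days_to_ranges(adm[!bad], dis[!bad])
}

#' Hospitalization-adjusted proportion of days covered
#'
#' `PDC = |covered \ hospital| / (365 - |hospital|)`, capped at 1. Days in
#' hospital are removed from the numerator as well as the denominator, so
#' the ratio cannot exceed 1. A patient hospitalized all 365 days has an
#' empty denominator and is assigned PDC 1 by convention (fully
#' institutionalized; medication supply is the institution's concern).
#'
#' @param covered `IRanges` of covered day offsets (0..364).
#' @param hospital `IRanges` of hospital day offsets (0..364).
#' @return PDC in `[0,1]`.
#' @export
compute_pdc <- function(covered, hospital = empty_ranges()) {
  h <- n_days(hospital)
  if (h >= FOLLOWUP_DAYS) return(1)
  num <- n_days(IRanges::setdiff(covered, hospital))
  min(1, num / (FOLLOWUP_DAYS - h))
}

#' Adherence classification
#'
#' @param pdc PDC value(s) in `[0,1]`.
#' @param threshold adherence threshold; the closed bound `pdc >= threshold`
#'   classifies as adherent (default 0.8).
#' @return logical vector.
#' @export
classify_adherent <- function(pdc, threshold = 0.8) {
  pdc >= threshold
}

#' Detect switching away from the index product
#'
#' Let `E` be the last covered day of the index drug's (unioned) supply
#' within follow-up. The patient switched iff some non-index OAAP fill falls
#' in the half-open window `(E, E+30]` and the index drug is not refilled on
#' or after that fill day. Returns the first qualifying fill day.
#'
#' @param profile a `coverage_profile`.
#' @return list with `switched` (logical) and `switch_day` (integer day
#'   offset or `NA`).
#' @export
detect_switch <- function(profile) {
  idx_cov <- coverage_union(profile, "index")
  if (n_days(idx_cov) == 0L)
    return(list(switched = FALSE, switch_day = NA_integer_))
  e <- max(IRanges::end(idx_cov))
  idx_fills <- profile$fill_days[[profile$index_drug]] %||% integer(0)
  others <- setdiff(names(profile$drugs), profile$index_drug)
  cand <- sort(unlist(profile$fill_days[others], use.names = FALSE))
  cand <- cand[cand > e & cand <= e + 30L]
  for (d in cand) {
    if (!any(idx_fills >= d)) return(list(switched = TRUE, switch_day = d))
  }
  list(switched = FALSE, switch_day = NA_integer_)
}

#' Detect augmentation of the index product
#'
#' TRUE iff the index drug was refilled (at least two fills in follow-up)
#' and some single non-index OAAP's covered-day set overlaps the index
#' drug's covered-day set on at least 60 days.
#'
#' @param profile a `coverage_profile`.
#' @return logical scalar.
#' @export
detect_augmentation <- function(profile) {
  idx_fills <- profile$fill_days[[profile$index_drug]] %||% integer(0)
  if (length(idx_fills) < 2L) return(FALSE)
  idx_cov <- coverage_union(profile, "index")
  for (dr in setdiff(names(profile$drugs), profile$index_drug)) {
    if (n_days(IRanges::intersect(profile$drugs[[dr]], idx_cov)) >= 60L)
      return(TRUE)
  }
  FALSE
}

#' Per-patient exposure results for a cohort
#'
#' Runs coverage construction, medication-day counting, PDC, adherence,
#' switch and augmentation detection for every cohort patient.
#'
#' @param cohort cohort table from [apply_inclusion()].
#' @param pharmacy pharmacy claims table.
#' @param medical medical claims table (inpatient rows supply hospital days).
#' @param threshold adherence threshold (default 0.8).
#' @return `data.table` with one row per patient: `index_medication_days`,
#'   `all_oaap_medication_days`, `hospital_day_count`, `pdc_index`,
#'   `pdc_all`, `adherent_index`, `adherent_all`, `switched`, `switch_day`,
#'   `augmented`.
#' @export
compute_exposure <- function(cohort, pharmacy, medical, threshold = 0.8) {
  ph <- data.table::as.data.table(pharmacy)
  ip <- data.table::as.data.table(medical)
  ip <- ip[ip$setting == "inpatient", ]
  ph_by <- split(seq_len(nrow(ph)), ph$patient_id)
  ip_by <- split(seq_len(nrow(ip)), ip$patient_id)

  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$patient_id[i]
    fills <- ph[ph_by[[id]] %||% integer(0), ]
    stays <- ip[ip_by[[id]] %||% integer(0), ]
    prof <- build_coverage(fills, cohort$index_date[i],
                           cohort$index_drug[i], inpatient = stays)
    cov_idx <- coverage_union(prof, "index")
    cov_all <- coverage_union(prof, "all")
    pdc_i <- compute_pdc(cov_idx, prof$hospital)
    pdc_a <- compute_pdc(cov_all, prof$hospital)
    sw <- detect_switch(prof)
    out[[i]] <- data.table::data.table(
      patient_id = id,
      index_medication_days = n_days(cov_idx),
      all_oaap_medication_days = n_days(cov_all),
      hospital_day_count = n_days(prof$hospital),
      pdc_index = pdc_i, pdc_all = pdc_a,
      adherent_index = classify_adherent(pdc_i, threshold),
      adherent_all = classify_adherent(pdc_a, threshold),
      switched = sw$switched, switch_day = sw$switch_day,
      augmented = detect_augmentation(prof))
  }
  data.table::rbindlist(out)
}
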