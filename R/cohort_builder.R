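# Incident-user cohort selection: index-event identification and the ordered
# inclusion cascade with an attrition ledger.

#' Find a patient's index event
#'
#' The index event is the chronologically first oral atypical antipsychotic
#' (OAAP) fill inside the identification window. If two or more distinct
#' OAAP products are filled on that first date the patient cannot be
#' assigned a single index product and is flagged (`multi_product = TRUE`);
#' such patients are excluded from the single-product cohort downstream.
#'
#' @param fills `data.table` of pharmacy claims for one patient
#'   (columns `drug_name`, `drug_class`, `fill_date`).
#' @param window length-2 Date vector of earliest/latest allowed index dates.
#' @return `NULL` if the patient has no qualifying fill; otherwise a list
#'   with `patient_id`, `index_date`, `index_drug`, `multi_product`.
#' @export
find_index_event <- function(fills, window) {
  oaap <- fills[fills$drug_class == "OAAP" &
                  fills$fill_date >= window[1] &
                  fills$fill_date <= window[2], ]
  if (nrow(oaap) == 0L) return(NULL)
  d0 <- min(oaap$fill_date)
  first <- oaap[oaap$fill_date == d0, ]
  drugs <- sort(unique(first$drug_name))
  list(patient_id = fills$patient_id[1], index_date = d0,
       index_drug = drugs[1], multi_product = length(drugs) > 1L)
}

# index events for every patient in a pharmacy table
index_events <- function(pharmacy, window) {
  dt <- data.table::as.data.table(pharmacy)
  oaap <- dt[dt$drug_class == "OAAP" & dt$fill_date >= window[1] &
               dt$fill_date <= window[2], ]
  if (nrow(oaap) == 0L)
    return(data.table::data.table(patient_id = character(),
                                  index_date = as.Date(character()),
                                  index_drug = character(),
                                  multi_product = logical()))
  data.table::setorder(oaap, patient_id, fill_date, drug_name)
  oaap[, {
    d0 <- fill_date[1]
    drugs <- unique(drug_name[fill_date == d0])
    list(index_date = d0, index_drug = drugs[1],
         multi_product = length(drugs) > 1L)
  }, by = "patient_id"]
}

#' Schizophrenia diagnostic evidence
#'
#' TRUE iff the patient has at least one inpatient claim, or at least two
#' outpatient/ED claim rows, carrying an ICD-10 F20.x code in any diagnosis
#' position with a service date inside baseline or follow-up. Counting is at
#' the claim-row level (two same-day claims count as two), and emergency
#' department claims count with outpatient claims for this purpose.
#'
#' @param medical `data.table` of one patient's medical claims.
#' @param index_date the patient's index date.
#' @return logical scalar.
#' @export
schizophrenia_evidence <- function(medical, index_date) {
  if (nrow(medical) == 0L) return(FALSE)
  day <- as.integer(medical$service_date - index_date)
  inwin <- !is.na(day) & day >= BASELINE_START & day <= FOLLOWUP_END
  f20 <- claim_has_dx_prefix(medical, "F20") & inwin
  ip <- medical$setting == "inpatient"
  sum(f20 & ip) >= 1L || sum(f20 & !ip) >= 2L
}

#' Apply the seven inclusion criteria and build the attrition ledger
#'
#' Applies, in order: (1) an index OAAP fill inside the identification
#' window; (1a) a single OAAP product on the index date; (2) no typical or
#' atypical antipsychotic fill during the 6-month baseline; (3) no
#' Medicaid-Medicare dual eligibility; (4) schizophrenia evidence (one
#' inpatient or two outpatient claims with F20.x, baseline or follow-up);
#' (5) age 18-63 at index; (6) continuous enrollment over days -182..364
#' with zero gap tolerance; (7) no long-acting injectable antipsychotic
#' claim at any time. Patients with missing birth dates or enrollment fail
#' the relevant criterion rather than erroring.
#'
#' @param tables list with `pharmacy`, `medical`, `enrollment`, `patients`
#'   tables (as produced by [generate_population()] or read from disk).
#' @param window length-2 Date identification window for the index fill.
#' @return list with `cohort` (a `data.table` of patient_id, index_date,
#'   index_drug, age_at_index, sex, race) and `attrition` (ordered
#'   criterion/n_remaining ledger whose first row is the input patient
#'   count).
#' @export
apply_inclusion <- function(tables,
                            window = as.Date(c("2016-07-01", "2019-12-31"))) {
  ph <- data.table::as.data.table(tables$pharmacy)
  md <- data.table::as.data.table(tables$medical)
  en <- data.table::as.data.table(tables$enrollment)
  pt <- data.table::as.data.table(tables$patients)

  all_ids <- sort(unique(c(ph$patient_id, md$patient_id, en$patient_id,
                           pt$patient_id)))
  ledger <- data.table::data.table(criterion = "input_patients",
                                   n_remaining = length(all_ids))
  log_step <- function(label, ids) {
    ledger <<- data.table::rbindlist(list(
      ledger, data.table::data.table(criterion = label,
                                     n_remaining = length(ids))))
    ids
  }

  # (1) index OAAP fill in window
  ie <- index_events(ph, window)
  keep <- ie$patient_id
  keep <- log_step("index_oaap", keep)
  # (1a) single OAAP product at index
  keep <- log_step("single_product", ie$patient_id[!ie$multi_product])
  ie <- ie[match(keep, ie$patient_id), ]

  rel_day <- function(dt, datecol) {
    i <- match(dt$patient_id, ie$patient_id)
    as.integer(dt[[datecol]] - ie$index_date[i])
  }

  # (2) washout: no typical or atypical AP fill in days -182..-1
  ap <- ph[ph$drug_class %in% c("OAAP", "TYPICAL"), ]
  apd <- rel_day(ap, "fill_date")
  bad <- unique(ap$patient_id[!is.na(apd) & apd >= BASELINE_START &
                                apd <= BASELINE_END])
  keep <- log_step("baseline_ap_washout", setdiff(keep, bad))

  # (3) dual eligibility on any enrollment span touching the study window
  end <- rel_day(en, "end_date"); enst <- rel_day(en, "start_date")
  dual <- unique(en$patient_id[en$dual_eligible %in% TRUE &
                                 !is.na(end) & end >= BASELINE_START &
                                 !is.na(enst) & enst <= FOLLOWUP_END])
  keep <- log_step("dual_eligible", setdiff(keep, dual))

  # (4) schizophrenia evidence: >=1 inpatient or >=2 outpatient/ED F20 claims
  mdd <- rel_day(md, "service_date")
  inwin <- !is.na(mdd) & mdd >= BASELINE_START & mdd <= FOLLOWUP_END
  f20 <- claim_has_dx_prefix(md, "F20") & inwin
  ipn <- tapply(f20 & md$setting == "inpatient", md$patient_id, sum)
  opn <- tapply(f20 & md$setting != "inpatient", md$patient_id, sum)
  ok4 <- function(id) isTRUE(ipn[id] >= 1) || isTRUE(opn[id] >= 2)
  keep <- log_step("schizophrenia_dx", keep[vapply(keep, ok4, TRUE)])

  # (5) age 18-63 at index
  dob <- pt$dob[match(keep, pt$patient_id)]
  idxd <- ie$index_date[match(keep, ie$patient_id)]
  age <- floor(as.numeric(idxd - dob) / 365.25)
  keep <- log_step("age_18_63", keep[!is.na(age) & age >= 18 & age <= 63])

  # (6) continuous enrollment over days -182..364, zero-gap
  en_by <- split(seq_len(nrow(en)), en$patient_id)
  cont <- vapply(keep, function(id) {
    rows <- en_by[[id]]
    if (is.null(rows)) return(FALSE)
    i0 <- ie$index_date[match(id, ie$patient_id)]
    st <- as.integer(en$start_date[rows] - i0)
    e2 <- as.integer(en$end_date[rows] - i0)
    covered <- rep(FALSE, FOLLOWUP_END - BASELINE_START + 1L)
    for (j in seq_along(rows)) {
      lo <- max(st[j], BASELINE_START); hi <- min(e2[j], FOLLOWUP_END)
      if (!is.na(lo) && !is.na(hi) && lo <= hi)
        covered[(lo:hi) - BASELINE_START + 1L] <- TRUE
    }
    all(covered)
  }, TRUE)
  keep <- log_step("continuous_enrollment", keep[cont])

  # (7) no LAI claim at any time
  lai <- unique(ph$patient_id[ph$drug_class == "LAI"])
  keep <- log_step("no_lai", setdiff(keep, lai))

  ie <- ie[match(keep, ie$patient_id), ]
  dob <- pt$dob[match(keep, pt$patient_id)]
  cohort <- data.table::data.table(
    patient_id = keep,
    index_date = ie$index_date,
    index_drug = ie$index_drug,
    age_at_index = floor(as.numeric(ie$index_date - dob) / 365.25),
    sex = pt$sex[match(keep, pt$patient_id)],
    race = pt$race[match(keep, pt$patient_id)])
  list(cohort = cohort, attrition = ledger)
}
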