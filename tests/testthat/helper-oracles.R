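# Independent per-day boolean-array oracles and small table builders.
# These deliberately avoid the package's interval-algebra (IRanges) route:
# every set operation is done on logical vectors indexed by day offset.

ORACLE_LEN <- 365L

oracle_cover <- function(fill_days, supplies) {
  a <- logical(ORACLE_LEN)
  for (i in seq_along(fill_days)) {
    lo <- max(fill_days[i], 0L)
    hi <- min(fill_days[i] + supplies[i] - 1L, ORACLE_LEN - 1L)
    if (lo <= hi) a[(lo:hi) + 1L] <- TRUE
  }
  a
}

oracle_span <- function(starts, ends) {
  a <- logical(ORACLE_LEN)
  for (i in seq_along(starts)) {
    lo <- max(starts[i], 0L); hi <- min(ends[i], ORACLE_LEN - 1L)
    if (lo <= hi) a[(lo:hi) + 1L] <- TRUE
  }
  a
}

oracle_pdc <- function(cov, hosp) {
  h <- sum(hosp)
  if (h >= ORACLE_LEN) return(1)
  min(1, sum(cov & !hosp) / (ORACLE_LEN - h))
}

# maximal runs of TRUE days: stays by day sweep
oracle_stays <- function(day_array) {
  r <- rle(day_array)
  n_vis <- sum(r$values)
  list(visits = n_vis, days = sum(day_array))
}

ranges_to_array <- function(ir) {
  a <- logical(ORACLE_LEN)
  st <- IRanges::start(ir); en <- IRanges::end(ir)
  for (i in seq_along(st)) {
    lo <- max(st[i], 0L); hi <- min(en[i], ORACLE_LEN - 1L)
    if (lo <= hi) a[(lo:hi) + 1L] <- TRUE
  }
  a
}

# ---- minimal table builders ------------------------------------------------

IDX0 <- as.Date("2018-01-01")

rx_tbl <- function(patient_id, drug, day, supply, class = "OAAP",
                   paid = 10, index = IDX0) {
  data.table::data.table(patient_id = patient_id, drug_name = drug,
                         drug_class = class, fill_date = index + day,
                         days_supply = as.integer(supply), paid = paid)
}

med_tbl <- function(patient_id, setting, day, adm = NA_integer_,
                    dis = NA_integer_, dx1 = NA_character_,
                    dx2 = NA_character_, paid = 100, index = IDX0) {
  data.table::data.table(
    patient_id = patient_id, setting = setting,
    service_date = index + day,
    admission_date = index + adm, discharge_date = index + dis,
    dx1 = dx1, dx2 = dx2, dx3 = NA_character_, paid = paid)
}

enr_tbl <- function(patient_id, start = -200, end = 400, dual = FALSE,
                    index = IDX0) {
  data.table::data.table(patient_id = patient_id, start_date = index + start,
                         end_date = index + end, dual_eligible = dual)
}

pt_tbl <- function(patient_id, age = 40, sex = "M", race = "Unknown",
                   index = IDX0) {
  data.table::data.table(
    patient_id = patient_id,
    dob = index - as.integer(round(age * 365.25)) - 10L,
    sex = sex, race = race)
}

# assemble a full table set from per-patient pieces, with sane defaults:
# every patient gets enrollment, demographics and two outpatient F20 claims
# unless overridden
full_tables <- function(pharmacy, medical = NULL, enrollment = NULL,
                        patients = NULL) {
  ids <- unique(pharmacy$patient_id)
  if (is.null(medical)) {
    medical <- data.table::rbindlist(lapply(ids, function(id)
      med_tbl(id, "outpatient", c(10, 40), dx1 = "F20.9")))
  }
  if (is.null(enrollment))
    enrollment <- data.table::rbindlist(lapply(ids, enr_tbl))
  if (is.null(patients))
    patients <- data.table::rbindlist(lapply(ids, pt_tbl))
  list(enrollment = enrollment, pharmacy = pharmacy, medical = medical,
       patients = patients)
}

# a coverage_profile from fill-day offsets, for exposure-engine unit tests
mk_profile <- function(index_drug, drugs, days, supplies,
                       hosp_adm = integer(0), hosp_dis = integer(0)) {
  fills <- rx_tbl("p1", drugs, days, supplies)
  ip <- if (length(hosp_adm) > 0)
    med_tbl("p1", "inpatient", hosp_adm, adm = hosp_adm, dis = hosp_dis)
  else NULL
  build_coverage(fills, IDX0, index_drug, inpatient = ip)
}

default_window <- as.Date(c("2016-07-01", "2019-12-31"))
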