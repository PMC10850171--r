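#' Configuration for the synthetic claims generator
#'
#' Builds and validates the parameter set that [generate_population()]
#' consumes. Defaults describe a Medicaid-like population of adults with
#' schizophrenia newly started on an oral atypical antipsychotic (OAAP):
#' the index-drug mix, switch/augment/LAI probabilities, hospitalization and
#' visit rates, and cost scales are anchored to published cohort-level
#' summaries for this population; refill persistence is a per-patient
#' two-state process (refill probability at supply exhaustion plus a
#' geometric gap) whose defaults put the expected all-OAAP proportion of
#' days covered near 0.50.
#'
#' @param n_patients positive integer, number of patients to simulate.
#' @param seed integer RNG seed; generation is fully reproducible for a
#'   fixed seed.
#' @param index_window length-2 Date vector, earliest and latest possible
#'   index dates.
#' @param drug_mix named numeric vector of index-OAAP probabilities; must
#'   sum to 1 (tolerance 1e-9).
#' @param persistence_model list with `days_supply` (days per fill),
#'   `refill_shape1`/`refill_shape2` (Beta parameters of the per-patient
#'   refill probability at supply exhaustion) and `gap_prob` (geometric
#'   parameter of the gap, in days, between supply exhaustion and the next
#'   fill; mean gap = (1-gap_prob)/gap_prob) and `tight_prob` (fraction of
#'   patients who always refill on time, i.e. with zero gap — these produce
#'   the point mass at PDC = 1 seen in real cohorts).
#' @param switch_prob probability that a discontinuing patient starts a
#'   different OAAP within 30 days of the end of index supply.
#' @param augment_prob probability that a persistent patient adds a second
#'   OAAP overlapping the index drug for at least 60 days.
#' @param lai_prob probability of a long-acting injectable (LAI)
#'   antipsychotic claim during follow-up (an exclusion criterion).
#' @param typical_ap_baseline_prob probability of a typical-antipsychotic
#'   fill during the 6-month baseline (violates the washout criterion).
#' @param dual_eligible_prob probability of Medicaid-Medicare dual
#'   eligibility (an exclusion criterion).
#' @param enroll_gap_prob probability of a coverage gap inside the
#'   continuous-enrollment window (an exclusion criterion).
#' @param hosp_rate expected inpatient stays per patient-year (negative
#'   binomial mean); `hosp_size` is the dispersion parameter.
#' @param hosp_size negative binomial size for inpatient stay counts.
#' @param hosp_los_mean mean length of stay in days (stays are
#'   `1 + Poisson(hosp_los_mean - 1)` days).
#' @param visit_rates list of negative binomial (`mu`, `size`) pairs for
#'   `ed` and `outpatient` follow-up visit counts per patient-year.
#' @param cost_params list of per-setting lognormal `(meanlog, sdlog)`
#'   pairs, 2020 USD: `inpatient` (per stay), `ed`, `outpatient` (per
#'   visit), `rx` (per fill).
#' @param demographics list with `age_range` (inclusive integer bounds of
#'   age at index; the default deliberately extends beyond 18-63 so the age
#'   criterion is exercised), `male_prob`, and `race_probs` (named,
#'   sums to 1).
#' @param dx_model list of diagnosis-coding probabilities: `f20_inpatient`,
#'   `f20_ed`, `f20_outpatient` (per-claim probability of an F20.x
#'   schizophrenia code), `bipolar`, `mdd`, `schizoaffective` (patient-level
#'   comorbid severe-mental-illness prevalence), `smi_code_prob` (per-claim
#'   probability that a patient's SMI code appears), and `charlson_lambda`
#'   (Poisson mean of the number of Charlson categories per patient).
#'
#' @return A validated list of class `oaap_config`.
#' @export
generator_config <- function(
    n_patients,
    seed = 1L,
    index_window = as.Date(c("2016-07-01", "2019-12-31")),
    drug_mix = c(quetiapine = 0.256, risperidone = 0.248, olanzapine = 0.197,
                 aripiprazole = 0.137, lurasidone = 0.051, ziprasidone = 0.043,
                 paliperidone = 0.030, cariprazine = 0.020, clozapine = 0.018),
    persistence_model = list(days_supply = 30L, refill_shape1 = 1.70,
                             refill_shape2 = 0.45, gap_prob = 1 / 8,
                             tight_prob = 0.20),
    switch_prob = 0.163,
    augment_prob = 0.032,
    lai_prob = 0.207,
    typical_ap_baseline_prob = 0.05,
    dual_eligible_prob = 0.08,
    enroll_gap_prob = 0.04,
    hosp_rate = 0.97,
    hosp_size = 0.45,
    hosp_los_mean = 7,
    visit_rates = list(ed = list(mu = 3.5, size = 0.6),
                       outpatient = list(mu = 43.2, size = 1.2)),
    cost_params = list(inpatient = c(meanlog = log(5000), sdlog = 1.1),
                       ed = c(meanlog = log(200), sdlog = 1.0),
                       outpatient = c(meanlog = log(90), sdlog = 1.05),
                       rx = c(meanlog = log(300), sdlog = 1.3)),
    demographics = list(age_range = c(16L, 70L), male_prob = 0.57,
                        race_probs = c(Black = 0.361, White = 0.318,
                                       Hispanic = 0.097, Other = 0.018,
                                       Unknown = 0.206)),
    dx_model = list(f20_inpatient = 0.50, f20_ed = 0.054,
                    f20_outpatient = 0.22, bipolar = 0.392, mdd = 0.265,
                    schizoaffective = 0.40, smi_code_prob = 0.30,
                    charlson_lambda = 0.5)) {
  cfg <- list(
    n_patients = n_patients, seed = seed, index_window = index_window,
    drug_mix = drug_mix, persistence_model = persistence_model,
    switch_prob = switch_prob, augment_prob = augment_prob,
    lai_prob = lai_prob, typical_ap_baseline_prob = typical_ap_baseline_prob,
    dual_eligible_prob = dual_eligible_prob,
    enroll_gap_prob = enroll_gap_prob,
    hosp_rate = hosp_rate, hosp_size = hosp_size,
    hosp_los_mean = hosp_los_mean,
    visit_rates = visit_rates, cost_params = cost_params,
    demographics = demographics, dx_model = dx_model)
  class(cfg) <- "oaap_config"
  validate_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 1 ||
      cfg$n_patients != floor(cfg$n_patients))
    config_error("n_patients", "must be a positive integer")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    config_error("seed", "must be a single integer")
  iw <- cfg$index_window
  if (!inherits(iw, "Date") || length(iw) != 2 || anyNA(iw))
    config_error("index_window", "must be two calendar dates")
  if (!(iw[1] < iw[2]))
    config_error("index_window", "start must precede end")
  dm <- cfg$drug_mix
  if (is.null(names(dm)) || any(!nzchar(names(dm))))
    config_error("drug_mix", "must be a named probability vector")
  if (any(dm < 0) || any(dm > 1))
    config_error("drug_mix", "probabilities must lie in [0,1]")
  if (abs(sum(dm) - 1) > 1e-9)
    config_error("drug_mix", "must sum to 1 (tolerance 1e-9)")
  pm <- cfg$persistence_model
  if (!is.list(pm) || is.null(pm$days_supply) || pm$days_supply < 1)
    config_error("persistence_model", "needs days_supply >= 1")
  if (is.null(pm$refill_shape1) || is.null(pm$refill_shape2) ||
      pm$refill_shape1 <= 0 || pm$refill_shape2 <= 0)
    config_error("persistence_model", "needs positive Beta shapes")
  if (is.null(pm$gap_prob) || pm$gap_prob <= 0 || pm$gap_prob > 1)
    config_error("persistence_model", "needs gap_prob in (0,1]")
  tp <- pm$tight_prob %||% 0
  if (tp < 0 || tp > 1)
    config_error("persistence_model", "needs tight_prob in [0,1]")
  for (f in c("switch_prob", "augment_prob", "lai_prob",
              "typical_ap_baseline_prob", "dual_eligible_prob",
              "enroll_gap_prob")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      config_error(f, "must be a probability in [0,1]")
  }
  if (cfg$hosp_rate < 0) config_error("hosp_rate", "must be >= 0")
  if (cfg$hosp_size <= 0) config_error("hosp_size", "must be > 0")
  if (cfg$hosp_los_mean < 1) config_error("hosp_los_mean", "must be >= 1 day")
  dg <- cfg$demographics
  if (dg$age_range[1] > dg$age_range[2])
    config_error("demographics", "age_range must be nondecreasing")
  if (abs(sum(dg$race_probs) - 1) > 1e-9)
    config_error("demographics", "race_probs must sum to 1")
  if (dg$male_prob < 0 || dg$male_prob > 1)
    config_error("demographics", "male_prob must be in [0,1]")
  dx <- cfg$dx_model
  for (f in c("f20_inpatient", "f20_ed", "f20_outpatient", "bipolar", "mdd",
              "schizoaffective", "smi_code_prob")) {
    if (is.null(dx[[f]]) || dx[[f]] < 0 || dx[[f]] > 1)
      config_error("dx_model", sprintf("needs probability '%s' in [0,1]", f))
  }
  invisible(cfg)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' The file holds a flat mapping of [generator_config()] arguments; omitted
#' arguments take their defaults. `index_window` entries are parsed as
#' `YYYY-MM-DD` dates.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `oaap_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$index_window)) raw$index_window <- as.Date(raw$index_window)
  if (!is.null(raw$drug_mix)) raw$drug_mix <- unlist(raw$drug_mix)
  do.call(generator_config, raw)
}
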