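# Synthetic Medicaid-like claims generator with per-patient ground truth.
#
# Every quantity the downstream pipeline estimates (coverage days, hospital
# days, PDC, switch/augment labels, inclusion status) is recomputed here by an
# independent per-day boolean-array route, so pipeline tests can check exact
# recovery without external data.

INCLUSION_LABELS <- c("index_oaap", "single_product", "baseline_ap_washout",
                      "dual_eligible", "schizophrenia_dx", "age_18_63",
                      "continuous_enrollment", "no_lai")

NEUTRAL_DX <- c("Z00.0", "J06.9", "R10.9", "M54.5", "I10", "K21.9", "R51")

CHARLSON_EXAMPLE_CODES <- c(
  mi = "I21.9", chf = "I50.9", pvd = "I70.0", cvd = "I63.9",
  dementia = "F03", chronic_pulmonary = "J44.9", rheumatic = "M06.9",
  peptic_ulcer = "K25.9", mild_liver = "K70.30",
  diabetes_uncomplicated = "E11.9", diabetes_complicated = "E11.5",
  paraplegia = "G81.9", renal = "N18.5", malignancy = "C50.9",
  severe_liver = "K72.90", metastatic = "C78.7", hiv = "B20")

# One index-anchored refill trajectory: fill at `start`, supply `s`; at each
# supply exhaustion refill with probability p after a geometric(q) gap.
# Returns fill-day offsets (fills after `horizon` are unobserved).
sim_fill_schedule <- function(p, s, q, start = 0L, horizon = 364L) {
  fills <- integer(0)
  t <- as.integer(start)
  repeat {
    fills <- c(fills, t)
    if (stats::runif(1) >= p) break
    t <- t + s + stats::rgeom(1, q)
    if (t > horizon) break
  }
  fills
}

# Day-array coverage for fills with a common days supply, clipped to 0..364.
# This is the generator's own ground-truth route, deliberately distinct from
# the interval algebra used by the exposure engine.
cover_days_array <- function(fill_days, supply, len = 365L) {
  a <- logical(len)
  for (f in fill_days) {
    lo <- max(f, 0L); hi <- min(f + supply - 1L, len - 1L)
    if (lo <= hi) a[(lo:hi) + 1L] <- TRUE
  }
  a
}

span_days_array <- function(start, end, len = 365L) {
  a <- logical(len)
  for (i in seq_along(start)) {
    lo <- max(start[i], 0L); hi <- min(end[i], len - 1L)
    if (!is.na(lo) && !is.na(hi) && lo <= hi) a[(lo:hi) + 1L] <- TRUE
  }
  a
}

#' Generate a synthetic claims population
#'
#' Simulates enrollment spans, pharmacy claims, medical claims and
#' demographics for `config$n_patients` patients, together with a
#' ground-truth table holding each patient's true coverage/hospital day
#' counts, true all-OAAP PDC, treatment-pattern label and inclusion status.
#' Output is fully deterministic for a fixed `config$seed`.
#'
#' @param config an `oaap_config` from [generator_config()].
#' @return A named list of `data.table`s: `enrollment` (patient_id,
#'   start_date, end_date, dual_eligible), `pharmacy` (patient_id, drug_name,
#'   drug_class in OAAP/TYPICAL/LAI, fill_date, days_supply, paid),
#'   `medical` (patient_id, setting in inpatient/ed/outpatient, service_date,
#'   admission_date, discharge_date, dx1..dx3, paid), `patients` (patient_id,
#'   dob, sex, race) and `ground_truth`.
#' @export
generate_population <- function(config) {
  validate_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(config$seed))

  n <- as.integer(config$n_patients)
  pid <- sprintf("P%05d", seq_len(n))
  pm <- config$persistence_model
  s <- as.integer(pm$days_supply)
  q <- pm$gap_prob
  dgc <- config$demographics
  dxm <- config$dx_model

  # -- patient-level draws ---------------------------------------------------
  window_len <- as.integer(config$index_window[2] - config$index_window[1]) + 1L
  index_date <- config$index_window[1] + (sample.int(window_len, n, TRUE) - 1L)
  age <- sample(seq(dgc$age_range[1], dgc$age_range[2]), n, replace = TRUE)
  dob <- index_date - as.integer(round((age + stats::runif(n)) * 365.25))
  sex <- ifelse(stats::runif(n) < dgc$male_prob, "M", "F")
  race <- sample(names(dgc$race_probs), n, TRUE, prob = dgc$race_probs)
  index_drug <- sample(names(config$drug_mix), n, TRUE,
                       prob = config$drug_mix)
  p_refill <- stats::rbeta(n, pm$refill_shape1, pm$refill_shape2)

  dual <- stats::runif(n) < config$dual_eligible_prob
  has_gap <- stats::runif(n) < config$enroll_gap_prob
  has_lai <- stats::runif(n) < config$lai_prob
  typ_base <- stats::runif(n) < config$typical_ap_baseline_prob
  smi_bip <- stats::runif(n) < dxm$bipolar
  smi_mdd <- stats::runif(n) < dxm$mdd
  smi_sza <- stats::runif(n) < dxm$schizoaffective
  wants_switch <- stats::runif(n) < config$switch_prob
  wants_augment <- stats::runif(n) < config$augment_prob

  # -- pharmacy fills (sequential per patient) -------------------------------
  rx_pid <- vector("list", n); rx_drug <- vector("list", n)
  rx_day <- vector("list", n); rx_class <- vector("list", n)
  rx_supply <- vector("list", n)
  non_index_choices <- function(dr) setdiff(names(config$drug_mix), dr)

  idx_fill_days <- vector("list", n)
  other_fills <- vector("list", n)   # per patient: list(drug -> fill days)

  tight <- stats::runif(n) < (pm$tight_prob %||% 0)
  for (i in seq_len(n)) {
    fills <- if (tight[i]) {
      # on-time refiller: zero gap at every refill
      f <- 0L
      while (stats::runif(1) < p_refill[i] && max(f) + s <= FOLLOWUP_END)
        f <- c(f, max(f) + s)
      f
    } else sim_fill_schedule(p_refill[i], s, q)
    idx_fill_days[[i]] <- fills
    oth <- list()
    last_cov <- max(fills) + s - 1L
    discontinued_early <- last_cov < FOLLOWUP_END

    if (discontinued_early && wants_switch[i]) {
      e <- min(last_cov, FOLLOWUP_END)
      sw_day <- e + sample.int(30L, 1L)
      if (sw_day <= FOLLOWUP_END) {
        dr <- sample(non_index_choices(index_drug[i]), 1L)
        oth[[dr]] <- sim_fill_schedule(p_refill[i], s, q, start = sw_day)
      }
    } else if (wants_augment[i] && length(fills) >= 2L &&
               sum(cover_days_array(fills[-1L], s)) >= 60L) {
      # second agent added at the first index refill and co-refilled with it
      # (starting it on day 0 would make the patient multi-product at index)
      dr <- sample(non_index_choices(index_drug[i]), 1L)
      oth[[dr]] <- fills[-1L]
    }
    other_fills[[i]] <- oth

    days <- c(fills, unlist(oth, use.names = FALSE))
    drugs <- c(rep(index_drug[i], length(fills)),
               rep(names(oth), lengths(oth)))
    cls <- rep("OAAP", length(days))
    if (typ_base[i]) {
      days <- c(days, -sample(30:150, 1L))
      drugs <- c(drugs, "haloperidol"); cls <- c(cls, "TYPICAL")
    }
    if (has_lai[i]) {
      days <- c(days, sample(60:300, 1L))
      drugs <- c(drugs, "paliperidone palmitate"); cls <- c(cls, "LAI")
    }
    rx_pid[[i]] <- rep(pid[i], length(days))
    rx_drug[[i]] <- drugs; rx_day[[i]] <- days; rx_class[[i]] <- cls
    rx_supply[[i]] <- ifelse(cls == "LAI", 28L, s)
  }

  rx_day_all <- unlist(rx_day)
  rx_pid_all <- unlist(rx_pid)
  pharmacy <- data.table::data.table(
    patient_id = rx_pid_all,
    drug_name = unlist(rx_drug),
    drug_class = unlist(rx_class),
    fill_date = index_date[match(rx_pid_all, pid)] + rx_day_all,
    days_supply = as.integer(unlist(rx_supply)),
    paid = round(stats::rlnorm(length(rx_day_all),
                               config$cost_params$rx["meanlog"],
                               config$cost_params$rx["sdlog"]), 2))

  # -- medical claims (vectorized) -------------------------------------------
  mk_dx1 <- function(k, p_f20) {
    ifelse(stats::runif(k) < p_f20,
           sample(c("F20.0", "F20.1", "F20.3", "F20.9"), k, TRUE),
           sample(NEUTRAL_DX, k, TRUE))
  }
  # per-patient pool of comorbid SMI codes, flattened for O(1) lookup
  smi_pools <- lapply(seq_len(n), function(j) {
    c(if (smi_bip[j]) "F31.9", if (smi_mdd[j]) "F32.9",
      if (smi_sza[j]) "F25.0")
  })
  pool_len <- lengths(smi_pools)
  pool_flat <- unlist(smi_pools)
  pool_off <- cumsum(c(0L, pool_len))
  smi_code_for <- function(idx, k) {
    # one of the claim's patient's comorbid SMI codes, or NA
    out <- rep(NA_character_, k)
    hit <- stats::runif(k) < dxm$smi_code_prob & pool_len[idx] > 0L
    sel <- idx[hit]
    pick <- ceiling(stats::runif(sum(hit)) * pool_len[sel])
    out[hit] <- pool_flat[pool_off[sel] + pick]
    out
  }

  # inpatient stays (follow-up window)
  n_ip <- stats::rnbinom(n, size = config$hosp_size, mu = config$hosp_rate)
  ip_idx <- rep(seq_len(n), n_ip)
  k_ip <- length(ip_idx)
  ip_adm <- sample(0:355, k_ip, replace = TRUE)
  ip_los <- 1L + stats::rpois(k_ip, max(config$hosp_los_mean - 1, 0))
  ip_dis <- ip_adm + ip_los - 1L
  ip <- data.table::data.table(
    patient_id = pid[ip_idx], setting = "inpatient",
    day = ip_adm, adm_day = ip_adm, dis_day = ip_dis,
    dx1 = mk_dx1(k_ip, dxm$f20_inpatient),
    dx2 = smi_code_for(ip_idx, k_ip),
    paid = round(stats::rlnorm(k_ip, config$cost_params$inpatient["meanlog"],
                               config$cost_params$inpatient["sdlog"]), 2))

  # ED visits (dates sampled with replacement: same-day repeats occur)
  n_ed <- stats::rnbinom(n, size = config$visit_rates$ed$size,
                         mu = config$visit_rates$ed$mu)
  ed_idx <- rep(seq_len(n), n_ed); k_ed <- length(ed_idx)
  ed <- data.table::data.table(
    patient_id = pid[ed_idx], setting = "ed",
    day = sample(0:364, k_ed, replace = TRUE),
    adm_day = NA_integer_, dis_day = NA_integer_,
    dx1 = mk_dx1(k_ed, dxm$f20_ed),
    dx2 = smi_code_for(ed_idx, k_ed),
    paid = round(stats::rlnorm(k_ed, config$cost_params$ed["meanlog"],
                               config$cost_params$ed["sdlog"]), 2))

  # outpatient visits, follow-up and baseline
  n_op <- stats::rnbinom(n, size = config$visit_rates$outpatient$size,
                         mu = config$visit_rates$outpatient$mu)
  n_bop <- stats::rnbinom(n, size = config$visit_rates$outpatient$size,
                          mu = config$visit_rates$outpatient$mu * 182 / 365)
  op_idx <- c(rep(seq_len(n), n_op), rep(seq_len(n), n_bop))
  op_day <- c(sample(0:364, sum(n_op), replace = TRUE),
              sample(-182:-1, sum(n_bop), replace = TRUE))
  k_op <- length(op_idx)
  op <- data.table::data.table(
    patient_id = pid[op_idx], setting = "outpatient",
    day = op_day, adm_day = NA_integer_, dis_day = NA_integer_,
    dx1 = mk_dx1(k_op, dxm$f20_outpatient),
    dx2 = smi_code_for(op_idx, k_op),
    paid = round(stats::rlnorm(k_op, config$cost_params$outpatient["meanlog"],
                               config$cost_params$outpatient["sdlog"]), 2))

  medical <- data.table::rbindlist(list(ip, ed, op))
  medical[, dx3 := NA_character_]

  # Charlson-category codes land on baseline outpatient claims (the CCI is a
  # baseline measure); patients with no baseline claim carry none.
  n_cc <- stats::rpois(n, dxm$charlson_lambda)
  base_rows <- which(medical$setting == "outpatient" & medical$day < 0)
  base_by_pt <- split(base_rows, medical$patient_id[base_rows])
  for (i in which(n_cc > 0L)) {
    rows <- base_by_pt[[pid[i]]]
    if (is.null(rows)) next
    cats <- sample(names(CHARLSON_EXAMPLE_CODES), min(n_cc[i], 17L))
    take <- rows[sample.int(length(rows), min(length(cats), length(rows)))]
    data.table::set(medical, i = take, j = "dx3",
                    value = CHARLSON_EXAMPLE_CODES[cats[seq_along(take)]])
  }

  med_idx <- match(medical$patient_id, pid)
  medical[, `:=`(
    service_date = index_date[med_idx] + day,
    admission_date = index_date[med_idx] + adm_day,
    discharge_date = index_date[med_idx] + dis_day)]
  medical <- medical[, list(patient_id, setting, service_date, admission_date,
                            discharge_date, dx1, dx2, dx3, paid)]
  data.table::setorder(medical, patient_id, service_date, setting)

  # -- enrollment -------------------------------------------------------------
  gap_start <- sample(-150:330, n, replace = TRUE)
  gap_len <- sample(5:30, n, replace = TRUE)
  enr_list <- vector("list", n)
  for (i in seq_len(n)) {
    if (has_gap[i]) {
      enr_list[[i]] <- data.table::data.table(
        patient_id = pid[i],
        start_date = index_date[i] + c(-250L, gap_start[i] + gap_len[i]),
        end_date = index_date[i] + c(gap_start[i] - 1L, 400L),
        dual_eligible = dual[i])
    } else {
      enr_list[[i]] <- data.table::data.table(
        patient_id = pid[i], start_date = index_date[i] - 250L,
        end_date = index_date[i] + 400L, dual_eligible = dual[i])
    }
  }
  enrollment <- data.table::rbindlist(enr_list)

  patients <- data.table::data.table(patient_id = pid, dob = dob,
                                     sex = sex, race = race)

  # -- ground truth (day-array route) ----------------------------------------
  ip_by_pt <- split(seq_len(nrow(ip)), ip$patient_id)
  f20_ip <- claim_has_dx_prefix(ip, "F20")
  f20_amb <- claim_has_dx_prefix(data.table::rbindlist(list(ed, op)), "F20")
  amb_pt <- c(ed$patient_id, op$patient_id)
  n_f20_ip <- tapply(f20_ip, ip$patient_id, sum)
  n_f20_amb <- tapply(f20_amb, amb_pt, sum)

  gt <- vector("list", n)
  age_at_index <- floor(as.numeric(index_date - dob) / 365.25)
  for (i in seq_len(n)) {
    cov_idx <- cover_days_array(idx_fill_days[[i]], s)
    cov_all <- cov_idx
    sw <- FALSE; aug <- FALSE
    e_idx <- max(which(cov_idx)) - 1L
    idx_fills <- idx_fill_days[[i]]
    for (dr in names(other_fills[[i]])) {
      fd <- other_fills[[i]][[dr]]
      cov_dr <- cover_days_array(fd, s)
      cov_all <- cov_all | cov_dr
      first_fill <- min(fd)
      if (first_fill > e_idx && first_fill <= e_idx + 30L &&
          !any(idx_fills >= first_fill)) sw <- TRUE
      if (length(idx_fills) >= 2L && sum(cov_dr & cov_idx) >= 60L) aug <- TRUE
    }
    rows <- ip_by_pt[[pid[i]]]
    hosp <- if (is.null(rows)) logical(365L) else
      span_days_array(ip$adm_day[rows], ip$dis_day[rows])
    hosp_n <- sum(hosp)
    cov_n <- sum(cov_all & !hosp)
    pdc <- if (hosp_n == 365L) 1 else min(1, cov_n / (365L - hosp_n))
    pattern <- if (sw) "switched" else if (aug) "augmented" else
      if (cov_idx[365L]) "persistent" else "discontinued"

    fail <- NA_character_
    if (typ_base[i]) fail <- "baseline_ap_washout"
    else if (dual[i]) fail <- "dual_eligible"
    else if (!(isTRUE(n_f20_ip[pid[i]] >= 1) ||
               isTRUE(n_f20_amb[pid[i]] >= 2))) fail <- "schizophrenia_dx"
    else if (age_at_index[i] < 18 || age_at_index[i] > 63) fail <- "age_18_63"
    else if (has_gap[i] && gap_start[i] <= 364L &&
             gap_start[i] + gap_len[i] - 1L >= -182L)
      fail <- "continuous_enrollment"
    else if (has_lai[i]) fail <- "no_lai"

    gt[[i]] <- data.table::data.table(
      patient_id = pid[i], index_date = index_date[i],
      index_drug = index_drug[i],
      true_covered_day_count = as.integer(cov_n),
      true_hospital_day_count = as.integer(hosp_n),
      true_pdc = pdc, true_switched = sw, true_augmented = aug,
      true_pattern = pattern,
      passes_inclusion = is.na(fail), failing_criterion = fail,
      is_edge = FALSE)
  }
  ground_truth <- data.table::rbindlist(gt)

  list(enrollment = enrollment, pharmacy = pharmacy, medical = medical,
       patients = patients, ground_truth = ground_truth)
}

#' Closed-form expected all-OAAP PDC under the generator's refill process
#'
#' Computes the expectation of the ground-truth PDC implied by a
#' configuration by exact renewal recursion over the 365 follow-up days
#' (probability mass of a fill starting on each day), integrated over the
#' Beta distribution of the per-patient refill probability by quadrature.
#' Valid only when hospitalizations, switching and augmentation are switched
#' off (they alter coverage); a warning is issued otherwise. Serves as the
#' independent oracle for Monte-Carlo checks of [generate_population()].
#'
#' @param config an `oaap_config`.
#' @param grid_points number of quadrature points for the Beta integral.
#' @return Expected PDC (scalar in `[0,1]`).
#' @export
expected_all_oaap_pdc <- function(config, grid_points = 401L) {
  if (config$hosp_rate > 0 || config$switch_prob > 0 || config$augment_prob > 0)
    warning("expected_all_oaap_pdc assumes hosp_rate = switch_prob = ",
            "augment_prob = 0; result is approximate")
  pm <- config$persistence_model
  s <- as.integer(pm$days_supply); q <- pm$gap_prob
  tight <- pm$tight_prob %||% 0
  horizon <- 365L
  maxgap <- as.integer(stats::qgeom(1 - 1e-9, q))
  gk_geom <- stats::dgeom(0:maxgap, q)

  cov_given_p <- function(p, gk) {
    f <- numeric(horizon); f[1] <- 1
    ec <- 0
    for (d in 0:(horizon - 1L)) {
      pd <- f[d + 1L]
      if (pd <= 0) next
      ec <- ec + pd * min(s, horizon - d)
      nxt <- d + s + seq_along(gk) - 1L
      ok <- nxt <= horizon - 1L
      if (any(ok)) f[nxt[ok] + 1L] <- f[nxt[ok] + 1L] + pd * p * gk[ok]
    }
    ec
  }
  # quantile-transform quadrature: robust to the (1-p)^(shape2-1)
  # density singularity at p = 1 when shape2 < 1
  ugrid <- (seq_len(grid_points) - 0.5) / grid_points
  pgrid <- stats::qbeta(ugrid, pm$refill_shape1, pm$refill_shape2)
  e_gap <- mean(vapply(pgrid, cov_given_p, 0, gk = gk_geom))
  e_tight <- if (tight > 0) mean(vapply(pgrid, cov_given_p, 0, gk = 1)) else 0
  ((1 - tight) * e_gap + tight * e_tight) / horizon
}

#' Append hand-built boundary-case patients to generated tables
#'
#' Adds a fixed set of fixture patients that exercise the rule boundaries of
#' the downstream pipeline: same-day duplicate fills, overlapping same-drug
#' fills, a fill straddling the end of follow-up, hospitalization overlapping
#' drug supply, a switch at exactly 30 (and 31) days after index supply end,
#' augmentation overlap of exactly 60 (and 59) days, a PDC of exactly 0.8,
#' a dual-eligible exclusion and an LAI-user exclusion. Fixture ground-truth
#' rows are computed by hand and flagged `is_edge = TRUE`.
#'
#' @param tables list of tables from [generate_population()].
#' @return The same list with fixture rows appended to every table.
#' @export
inject_edge_cases <- function(tables) {
  stopifnot(all(c("enrollment", "pharmacy", "medical", "patients",
                  "ground_truth") %in% names(tables)))
  idx <- as.Date("2018-01-01")

  ids <- c("edge-dup-fill", "edge-overlap-fill", "edge-year-boundary",
           "edge-hosp-overlap", "edge-switch-30", "edge-switch-31",
           "edge-augment-60", "edge-augment-59", "edge-pdc-080",
           "edge-dual", "edge-lai")

  rx <- function(id, drug, day, supply, class = "OAAP")
    data.table::data.table(patient_id = id, drug_name = drug,
                           drug_class = class, fill_date = idx + day,
                           days_supply = as.integer(supply), paid = 25)
  pharmacy <- data.table::rbindlist(list(
    rx("edge-dup-fill", "risperidone", c(0, 0), 30),
    rx("edge-overlap-fill", "risperidone", c(0, 15), 30),
    rx("edge-year-boundary", "risperidone", c(0, 350), 30),
    rx("edge-hosp-overlap", "risperidone", 0, 60),
    rx("edge-switch-30", "risperidone", 0, 30),
    rx("edge-switch-30", "quetiapine", 59, 30),
    rx("edge-switch-31", "risperidone", 0, 30),
    rx("edge-switch-31", "quetiapine", 60, 30),
    rx("edge-augment-60", "risperidone", c(0, 60), 60),
    rx("edge-augment-60", "quetiapine", 30, 60),
    rx("edge-augment-59", "risperidone", c(0, 60), 60),
    rx("edge-augment-59", "quetiapine", 30, 59),
    rx("edge-pdc-080", "risperidone", c(0, 100), 100),
    rx("edge-pdc-080", "risperidone", 200, 92),
    rx("edge-dual", "risperidone", 0, 30),
    rx("edge-lai", "risperidone", 0, 30),
    rx("edge-lai", "paliperidone palmitate", 100, 28, class = "LAI")))

  # two outpatient F20 claims per fixture patient secure criterion 4
  med_list <- lapply(ids, function(id) data.table::data.table(
    patient_id = id, setting = "outpatient",
    service_date = idx + c(10, 40),
    admission_date = as.Date(NA), discharge_date = as.Date(NA),
    dx1 = "F20.9", dx2 = NA_character_, dx3 = NA_character_, paid = 50))
  medical <- data.table::rbindlist(med_list)
  medical <- data.table::rbindlist(list(medical, data.table::data.table(
    patient_id = "edge-hosp-overlap", setting = "inpatient",
    service_date = idx + 10, admission_date = idx + 10,
    discharge_date = idx + 19, dx1 = "F20.9", dx2 = NA_character_,
    dx3 = NA_character_, paid = 8000)))

  enrollment <- data.table::data.table(
    patient_id = ids, start_date = idx - 200, end_date = idx + 400,
    dual_eligible = ids == "edge-dual")
  patients <- data.table::data.table(
    patient_id = ids, dob = idx - as.integer(round(40 * 365.25)),
    sex = "M", race = "Unknown")

  gt_row <- function(id, cov, hosp, pattern, sw = FALSE, aug = FALSE,
                     fail = NA_character_) {
    pdc <- if (hosp == 365L) 1 else min(1, cov / (365L - hosp))
    data.table::data.table(
      patient_id = id, index_date = idx, index_drug = "risperidone",
      true_covered_day_count = as.integer(cov),
      true_hospital_day_count = as.integer(hosp),
      true_pdc = pdc, true_switched = sw, true_augmented = aug,
      true_pattern = pattern, passes_inclusion = is.na(fail),
      failing_criterion = fail, is_edge = TRUE)
  }
  ground_truth <- data.table::rbindlist(list(
    gt_row("edge-dup-fill", 30, 0, "discontinued"),
    gt_row("edge-overlap-fill", 45, 0, "discontinued"),
    gt_row("edge-year-boundary", 45, 0, "persistent"),
    gt_row("edge-hosp-overlap", 50, 10, "discontinued"),
    gt_row("edge-switch-30", 60, 0, "switched", sw = TRUE),
    gt_row("edge-switch-31", 60, 0, "discontinued"),
    gt_row("edge-augment-60", 120, 0, "augmented", aug = TRUE),
    gt_row("edge-augment-59", 120, 0, "discontinued"),
    gt_row("edge-pdc-080", 292, 0, "discontinued"),
    gt_row("edge-dual", 30, 0, "discontinued", fail = "dual_eligible"),
    gt_row("edge-lai", 30, 0, "discontinued", fail = "no_lai")))

  list(
    enrollment = data.table::rbindlist(list(tables$enrollment, enrollment)),
    pharmacy = data.table::rbindlist(list(tables$pharmacy, pharmacy)),
    medical = data.table::rbindlist(list(tables$medical, medical)),
    patients = data.table::rbindlist(list(tables$patients, patients)),
    ground_truth = data.table::rbindlist(list(tables$ground_truth,
                                              ground_truth)))
}
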