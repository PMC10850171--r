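test_that("inpatient claims merge into stays with inclusive LOS", {
  # overlapping at the shared day: one stay, LOS 10
  ip <- med_tbl("p1", "inpatient", c(10, 14), adm = c(10, 14),
                dis = c(14, 19))
  st <- build_stays(ip, IDX0)
  expect_equal(nrow(st), 1)
  expect_equal(st$los, 10)

  # same-day admission and discharge: LOS 1
  st <- build_stays(med_tbl("p1", "inpatient", 10, adm = 10, dis = 10), IDX0)
  expect_equal(st$los, 1)

  # disjoint stays: two visits, days summed
  ip <- med_tbl("p1", "inpatient", c(10, 100), adm = c(10, 100),
                dis = c(14, 104))
  st <- build_stays(ip, IDX0)
  expect_equal(nrow(st), 2)
  expect_equal(sum(st$los), 10)

  # stay crossing the end of follow-up is clipped
  st <- build_stays(med_tbl("p1", "inpatient", 360, adm = 360, dis = 380),
                    IDX0)
  expect_equal(st$los, 5)

  expect_warning(
    st <- build_stays(med_tbl("p1", "inpatient", 10, adm = 10, dis = 5),
                      IDX0), "rejected")
  expect_equal(nrow(st), 0)
})

test_that("visit counting follows per-setting conventions and scope", {
  med <- data.table::rbindlist(list(
    med_tbl("p1", "ed", c(5, 5, 5, 9), dx1 = "F20.9"),
    med_tbl("p1", "outpatient", c(20, 30), dx1 = c("F25.0", "F20.9")),
    med_tbl("p1", "inpatient", 50, adm = 50, dis = 55, dx1 = "F20.9")))
  v <- count_visits(med, IDX0, "all_cause")
  expect_equal(v$ed_visits, 2)            # 3 same-day claims collapse to 1
  expect_equal(v$outpatient_visits, 2)    # claim rows, not distinct dates
  expect_equal(v$inpatient_visits, 1)
  expect_equal(v$inpatient_days, 6)
  expect_true(v$any_inpatient && v$any_ed && v$any_outpatient)

  # schizophrenia scope keeps only F20-carrying claims
  vs <- count_visits(med, IDX0, "schizophrenia")
  expect_equal(vs$outpatient_visits, 1)   # the F25-only claim drops out
  expect_equal(vs$ed_visits, 2)
  expect_equal(vs$inpatient_visits, 1)

  # no inpatient claims: inpatient_days undefined (NA), counts zero
  v0 <- count_visits(med[med$setting == "ed", ], IDX0, "all_cause")
  expect_equal(v0$inpatient_visits, 0)
  expect_true(is.na(v0$inpatient_days))
  expect_false(v0$any_inpatient)
})

test_that("expenditures sum by category with scope-specific drug buckets", {
  med <- data.table::rbindlist(list(
    med_tbl("p1", "inpatient", 10, adm = 10, dis = 12, dx1 = "F20.9",
            paid = 100),
    med_tbl("p1", "ed", 20, dx1 = "Z00.0", paid = 50),
    med_tbl("p1", "outpatient", 30, dx1 = "F20.9", paid = 25)))
  rx <- rx_tbl("p1", c("risperidone", "sertraline"), c(0, 5), 30,
               paid = c(6, 4))
  rx$drug_class <- c("OAAP", "OTHER")

  e <- sum_expenditures(med, rx, IDX0, "all_cause")
  expect_equal(e$total_medical, 175)
  expect_equal(e$rx, 10)
  expect_equal(e$total, 185)

  es <- sum_expenditures(med, rx, IDX0, "schizophrenia")
  expect_equal(es$inpatient, 100)       # F20 stay in both scopes, full amount
  expect_equal(es$ed, 0)                # non-F20 ED claim excluded
  expect_equal(es$outpatient, 25)
  expect_equal(es$rx, 6)                # OAAP fills only
  expect_equal(es$total, 131)

  # claims outside follow-up are excluded
  late <- med_tbl("p1", "outpatient", 400, dx1 = "F20.9", paid = 999)
  e2 <- sum_expenditures(data.table::rbindlist(list(med, late)), rx, IDX0,
                         "all_cause")
  expect_equal(e2$total, 185)

  # no claims at all
  e0 <- sum_expenditures(med[0, ], rx[0, ], IDX0, "all_cause")
  expect_equal(e0$total, 0)

  # negative paid amounts are rejected with a warning
  neg <- med_tbl("p1", "ed", 21, dx1 = "Z00.0", paid = -5)
  expect_warning(
    en <- sum_expenditures(data.table::rbindlist(list(med, neg)), rx, IDX0,
                           "all_cause"), "negative")
  expect_equal(en$total, 185)
})

test_that("stay merging equals a day-sweep oracle on random instances", {
  set.seed(88)
  for (rep in seq_len(200)) {
    k <- sample(1:6, 1)
    adm <- sample(0:360, k, replace = TRUE)
    los <- sample(1:25, k, replace = TRUE)
    ip <- med_tbl("p", "inpatient", adm, adm = adm, dis = adm + los - 1)
    st <- build_stays(ip, IDX0)
    arr <- oracle_span(adm, pmin(adm + los - 1, 364))
    orc <- oracle_stays(arr)
    expect_equal(nrow(st), orc$visits)
    expect_equal(sum(st$los), orc$days)
  }
})

test_that("cost_contrast returns group means and their difference", {
  cc <- cost_contrast(c(10, 20, 30, 40), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cc$mean_flagged, 15)
  expect_equal(cc$mean_unflagged, 35)
  expect_equal(cc$difference, -20)
  # identical groups: difference 0
  cc <- cost_contrast(c(5, 5, 5, 5), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cc$difference, 0)
  # empty group: undefined difference
  cc <- cost_contrast(c(1, 2), c(TRUE, TRUE))
  expect_true(is.na(cc$difference))
})

test_that("per-patient summaries respect additivity and scope monotonicity", {
  tabs <- generate_population(generator_config(n_patients = 80, seed = 17))
  sel <- apply_inclusion(tabs)
  hru <- compute_hru_costs(sel$cohort, tabs$medical, tabs$pharmacy)
  expect_equal(hru$exp_total_medical,
               hru$exp_inpatient + hru$exp_ed + hru$exp_outpatient,
               tolerance = 1e-9)
  expect_equal(hru$exp_total, hru$exp_total_medical + hru$exp_rx,
               tolerance = 1e-9)
  expect_identical(hru$any_inpatient, hru$inpatient_visits >= 1L)
  expect_identical(hru$any_ed, hru$ed_visits >= 1L)
  wide <- merge(hru[hru$scope == "all_cause", ],
                hru[hru$scope == "schizophrenia", ],
                by = "patient_id", suffixes = c(".all", ".sz"))
  for (col in c("ed_visits", "outpatient_visits", "exp_inpatient", "exp_ed",
                "exp_outpatient", "exp_rx", "exp_total")) {
    expect_true(all(wide[[paste0(col, ".sz")]] <=
                      wide[[paste0(col, ".all")]] + 1e-9))
  }
})
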