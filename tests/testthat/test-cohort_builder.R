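test_that("find_index_event returns the first qualifying OAAP fill", {
  fills <- rx_tbl("p1", c("haloperidol", "risperidone", "risperidone"),
                  c(-200, 59, 120), 30)
  fills$drug_class <- c("TYPICAL", "OAAP", "OAAP")
  ev <- find_index_event(fills, default_window)
  expect_equal(ev$index_date, IDX0 + 59)
  expect_equal(ev$index_drug, "risperidone")
  expect_false(ev$multi_product)

  # only LAI products: no index event at this stage
  lai <- rx_tbl("p2", "paliperidone palmitate", 0, 28, class = "LAI")
  expect_null(find_index_event(lai, default_window))

  # fills outside the identification window do not qualify
  early <- rx_tbl("p3", "olanzapine", 0, 30,
                  index = as.Date("2016-01-01"))
  expect_null(find_index_event(early, default_window))

  # two distinct OAAP products on the first date: flagged multi-product
  two <- rx_tbl("p4", c("olanzapine", "quetiapine"), c(0, 0), 30)
  ev2 <- find_index_event(two, default_window)
  expect_true(ev2$multi_product)
})

test_that("schizophrenia evidence counts one inpatient or two other claims", {
  one_ip <- med_tbl("p1", "inpatient", 10, adm = 10, dis = 12, dx1 = "F20.0")
  expect_true(schizophrenia_evidence(one_ip, IDX0))

  # two same-day outpatient claims count as two claim rows
  two_op <- med_tbl("p1", "outpatient", c(10, 10), dx1 = "F20.9")
  expect_true(schizophrenia_evidence(two_op, IDX0))

  # schizoaffective (F25) is not schizophrenia (F20)
  mix <- med_tbl("p1", "outpatient", c(10, 40), dx1 = c("F20.9", "F25.0"))
  expect_false(schizophrenia_evidence(mix, IDX0))

  # one outpatient only: insufficient
  one_op <- med_tbl("p1", "outpatient", 10, dx1 = "F20.9")
  expect_false(schizophrenia_evidence(one_op, IDX0))

  # baseline window claims count; far pre-baseline claims do not
  base <- med_tbl("p1", "outpatient", c(-100, -10), dx1 = "F20.9")
  expect_true(schizophrenia_evidence(base, IDX0))
  old <- med_tbl("p1", "outpatient", c(-400, -300), dx1 = "F20.9")
  expect_false(schizophrenia_evidence(old, IDX0))

  # any diagnosis position matches
  pos2 <- med_tbl("p1", "outpatient", c(5, 6), dx1 = "Z00.0", dx2 = "F20.1")
  expect_true(schizophrenia_evidence(pos2, IDX0))
})

make_cascade_tables <- function() {
  # one patient failing each criterion, plus one passing everything
  ids <- c("ok", "no-rx", "multi", "washout", "dual", "one-op-dx", "age64",
           "gap", "lai")
  washout_rx <- rx_tbl("washout", c("haloperidol", "risperidone"),
                       c(-90, 0), 30)
  washout_rx$drug_class <- c("TYPICAL", "OAAP")
  rx <- data.table::rbindlist(list(
    rx_tbl("ok", "risperidone", 0, 30),
    rx_tbl("multi", c("risperidone", "quetiapine"), c(0, 0), 30),
    washout_rx,
    rx_tbl("dual", "risperidone", 0, 30),
    rx_tbl("one-op-dx", "risperidone", 0, 30),
    rx_tbl("age64", "risperidone", 0, 30),
    rx_tbl("gap", "risperidone", 0, 30),
    rx_tbl("lai", "risperidone", 0, 30),
    rx_tbl("lai", "paliperidone palmitate", 90, 28, class = "LAI")))
  med <- data.table::rbindlist(c(
    lapply(setdiff(ids, c("no-rx", "one-op-dx")), function(id)
      med_tbl(id, "outpatient", c(10, 40), dx1 = "F20.9")),
    list(med_tbl("no-rx", "outpatient", c(10, 40), dx1 = "F20.9"),
         med_tbl("one-op-dx", "outpatient", 10, dx1 = "F20.9"))))
  enr <- data.table::rbindlist(c(
    lapply(setdiff(ids, c("dual", "gap")), enr_tbl),
    list(enr_tbl("dual", dual = TRUE),
         data.table::rbindlist(list(enr_tbl("gap", -200, 99),
                                    enr_tbl("gap", 130, 400))))))
  pt <- data.table::rbindlist(c(
    lapply(setdiff(ids, "age64"), pt_tbl),
    list(pt_tbl("age64", age = 64))))
  list(enrollment = enr, pharmacy = rx, medical = med, patients = pt)
}

test_that("the inclusion cascade excludes each failure mode in order", {
  tabs <- make_cascade_tables()
  res <- apply_inclusion(tabs, default_window)
  led <- res$attrition
  expect_equal(led$criterion,
               c("input_patients", "index_oaap", "single_product",
                 "baseline_ap_washout", "dual_eligible", "schizophrenia_dx",
                 "age_18_63", "continuous_enrollment", "no_lai"))
  expect_equal(led$n_remaining[1], 9)       # all ids incl. claim-less no-rx
  expect_equal(led$n_remaining,
               c(9, 8, 7, 6, 5, 4, 3, 2, 1))
  expect_equal(res$cohort$patient_id, "ok")
  expect_equal(res$cohort$index_drug, "risperidone")
  expect_equal(res$cohort$age_at_index, 40)
})

test_that("attrition is monotone and ends at the cohort size", {
  tabs <- generate_population(generator_config(n_patients = 250, seed = 31))
  res <- apply_inclusion(tabs)
  expect_true(all(diff(res$attrition$n_remaining) <= 0))
  expect_equal(res$attrition$n_remaining[1], 250)
  expect_equal(res$attrition$n_remaining[nrow(res$attrition)],
               nrow(res$cohort))
})

test_that("cohort selection is invariant to input row order", {
  tabs <- generate_population(generator_config(n_patients = 120, seed = 13))
  res1 <- apply_inclusion(tabs)
  set.seed(99)
  shuf <- lapply(tabs, function(dt) dt[sample(nrow(dt)), ])
  res2 <- apply_inclusion(shuf)
  expect_setequal(res1$cohort$patient_id, res2$cohort$patient_id)
  expect_equal(res1$attrition, res2$attrition)
})

test_that("retained patients pass an independent brute-force recheck", {
  tabs <- inject_edge_cases(
    generate_population(generator_config(n_patients = 150, seed = 21)))
  res <- apply_inclusion(tabs)
  gt <- tabs$ground_truth
  # generator-side truth and pipeline-side selection agree patient by patient
  expect_setequal(res$cohort$patient_id,
                  gt$patient_id[gt$passes_inclusion])
  # and every retained patient passes a row-scan re-check of key predicates
  for (id in res$cohort$patient_id) {
    i0 <- res$cohort$index_date[res$cohort$patient_id == id]
    ph <- tabs$pharmacy[tabs$pharmacy$patient_id == id, ]
    expect_equal(sum(ph$drug_class == "LAI"), 0)
    rel <- as.integer(ph$fill_date - i0)
    expect_equal(sum(ph$drug_class %in% c("OAAP", "TYPICAL") &
                       rel >= -182 & rel <= -1), 0)
    md <- tabs$medical[tabs$medical$patient_id == id, ]
    expect_true(schizophrenia_evidence(md, i0))
  }
})

test_that("missing demographics fail the age criterion without crashing", {
  tabs <- full_tables(rx_tbl("p1", "risperidone", 0, 30))
  tabs$patients <- tabs$patients[0, ]
  res <- apply_inclusion(tabs, default_window)
  expect_equal(nrow(res$cohort), 0)
  led <- res$attrition
  expect_equal(led$n_remaining[led$criterion == "schizophrenia_dx"], 1)
  expect_equal(led$n_remaining[led$criterion == "age_18_63"], 0)
})
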