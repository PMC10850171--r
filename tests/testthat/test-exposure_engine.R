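test_that("coverage construction unions fills and clips to follow-up", {
  # one fill, day 0, supply 30
  p <- mk_profile("risperidone", "risperidone", 0, 30)
  expect_equal(total_medication_days(p, "index"), 30)

  # two overlapping same-drug fills: union, not end-to-end stockpiling
  p <- mk_profile("risperidone", c("risperidone", "risperidone"),
                  c(0, 15), c(30, 30))
  expect_equal(total_medication_days(p, "index"), 45)

  # fill straddling the end of follow-up is truncated
  p <- mk_profile("risperidone", "risperidone", 350, 30)
  expect_equal(total_medication_days(p, "index"), 15)

  # pre-index fill contributes only its in-window tail
  p <- mk_profile("risperidone", "risperidone", -10, 30)
  expect_equal(total_medication_days(p, "index"), 20)

  # identical duplicate fills count once
  p <- mk_profile("risperidone", c("risperidone", "risperidone"),
                  c(0, 0), c(30, 30))
  expect_equal(total_medication_days(p, "index"), 30)

  # non-positive days supply is rejected with a warning
  fills <- rx_tbl("p1", "risperidone", c(0, 40), c(30, 0))
  expect_warning(p <- build_coverage(fills, IDX0, "risperidone"),
                 "rejected")
  expect_equal(total_medication_days(p, "index"), 30)
  expect_equal(p$n_rejected, 1)
})

test_that("all-OAAP days count concurrent coverage once", {
  p <- mk_profile("drugA", c("drugA", "drugB"), c(0, 20), c(30, 30))
  expect_equal(total_medication_days(p, "all"), 50)
  expect_equal(total_medication_days(p, "index"), 30)
  # no fills at all
  empty <- build_coverage(rx_tbl("p1", "x", 0, 30)[0, ], IDX0, "drugA")
  expect_equal(total_medication_days(empty, "all"), 0)
})

test_that("hospital day sets merge overlapping stays and clip", {
  ip <- med_tbl("p1", "inpatient", 10, adm = 10, dis = 19)
  expect_equal(sum(IRanges::width(hospital_days(ip, IDX0))), 10)

  ip2 <- med_tbl("p1", "inpatient", c(10, 15), adm = c(10, 15),
                 dis = c(19, 24))
  expect_equal(sum(IRanges::width(hospital_days(ip2, IDX0))), 15)

  expect_equal(sum(IRanges::width(hospital_days(ip2[0, ], IDX0))), 0)

  bad <- med_tbl("p1", "inpatient", 10, adm = 10, dis = 5)
  expect_warning(h <- hospital_days(bad, IDX0), "rejected")
  expect_equal(sum(IRanges::width(h)), 0)
})

test_that("PDC follows the hospitalization-adjusted formula", {
  ir <- function(s, e) IRanges::IRanges(s, e)
  # 292 covered, no hospital days: exactly the 0.8 threshold
  expect_equal(compute_pdc(ir(0, 291)), 0.8)
  # 180 covered disjoint from 65 hospital days: 180/300
  expect_equal(compute_pdc(ir(100, 279), ir(0, 64)), 0.6)
  # nothing covered
  expect_equal(compute_pdc(IRanges::IRanges()), 0)
  # hospital days subtract from the numerator too, capping at 1
  expect_equal(compute_pdc(ir(0, 364), ir(0, 99)), 1)
  # fully institutionalized year: defined as 1
  expect_equal(compute_pdc(IRanges::IRanges(), ir(0, 364)), 1)
})

test_that("the adherence threshold is a closed bound", {
  expect_true(classify_adherent(0.8))
  expect_false(classify_adherent(0.7999))
  expect_true(classify_adherent(1.0))
  expect_equal(classify_adherent(c(0, 0.5, 0.8, 1)),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("switch detection uses the half-open 30-day window", {
  # index supply ends day 100; other OAAP on day 130 (= E + 30): switched
  p <- mk_profile("drugA", c("drugA", "drugB"), c(0, 130), c(101, 30))
  sw <- detect_switch(p)
  expect_true(sw$switched)
  expect_equal(sw$switch_day, 130)

  # day 131: just outside the window
  p <- mk_profile("drugA", c("drugA", "drugB"), c(0, 131), c(101, 30))
  expect_false(detect_switch(p)$switched)

  # an index refill on/after the candidate fill blocks the switch
  p <- mk_profile("drugA", c("drugA", "drugB", "drugA"),
                  c(0, 130, 150), c(101, 30, 30))
  expect_false(detect_switch(p)$switched)

  # no non-index fills
  p <- mk_profile("drugA", "drugA", 0, 30)
  expect_false(detect_switch(p)$switched)
})

test_that("augmentation requires an index refill and >= 60 overlap days", {
  # index covered 0..119 via two fills; other drug 30..99: overlap 70
  p <- mk_profile("drugA", c("drugA", "drugA", "drugB"),
                  c(0, 60, 30), c(60, 60, 70))
  expect_true(detect_augmentation(p))

  # overlap exactly 59: not augmented
  p <- mk_profile("drugA", c("drugA", "drugA", "drugB"),
                  c(0, 60, 30), c(60, 60, 59))
  expect_false(detect_augmentation(p))

  # overlap exactly 60: augmented
  p <- mk_profile("drugA", c("drugA", "drugA", "drugB"),
                  c(0, 60, 30), c(60, 60, 60))
  expect_true(detect_augmentation(p))

  # single index fill: no refill, no augmentation regardless of overlap
  p <- mk_profile("drugA", c("drugA", "drugB"), c(0, 0), c(120, 120))
  expect_false(detect_augmentation(p))

  # two non-index drugs each overlapping < 60 days do not combine
  p <- mk_profile("drugA", c("drugA", "drugA", "drugB", "drugC"),
                  c(0, 60, 0, 70), c(60, 60, 40, 40))
  expect_false(detect_augmentation(p))
})

test_that("interval algebra agrees exactly with the per-day array oracle", {
  set.seed(424)
  for (rep in seq_len(200)) {
    n_fills <- sample(0:20, 1)
    drugs <- sample(c("A", "B", "C"), n_fills, replace = TRUE)
    days <- sample(-30:400, max(n_fills, 1), replace = TRUE)[seq_len(n_fills)]
    sup <- sample(1:40, max(n_fills, 1), replace = TRUE)[seq_len(n_fills)]
    n_stays <- sample(0:5, 1)
    adm <- sample(-10:380, max(n_stays, 1), replace = TRUE)[seq_len(n_stays)]
    los <- sample(1:30, max(n_stays, 1), replace = TRUE)[seq_len(n_stays)]

    fills <- rx_tbl("p", drugs, days, sup)
    ip <- if (n_stays > 0)
      med_tbl("p", "inpatient", adm, adm = adm, dis = adm + los - 1)
    else NULL
    prof <- build_coverage(fills, IDX0, "A", inpatient = ip)

    cov_idx_arr <- oracle_cover(days[drugs == "A"], sup[drugs == "A"])
    cov_all_arr <- oracle_cover(days, sup)
    hosp_arr <- if (n_stays > 0) oracle_span(adm, adm + los - 1)
      else logical(365)

    expect_equal(total_medication_days(prof, "index"), sum(cov_idx_arr))
    expect_equal(total_medication_days(prof, "all"), sum(cov_all_arr))
    expect_equal(sum(IRanges::width(prof$hospital)), sum(hosp_arr))
    pdc_i <- compute_pdc(oaapflow:::coverage_union(prof, "index"),
                         prof$hospital)
    pdc_a <- compute_pdc(oaapflow:::coverage_union(prof, "all"),
                         prof$hospital)
    expect_equal(pdc_i, oracle_pdc(cov_idx_arr, hosp_arr))
    expect_equal(pdc_a, oracle_pdc(cov_all_arr, hosp_arr))
    # invariants: bounds, ordering, exhaustive/exclusive partition
    expect_true(pdc_a >= pdc_i)
    expect_true(pdc_a >= 0 && pdc_a <= 1)
    expect_identical(classify_adherent(pdc_a), !(pdc_a < 0.8))
  }
})
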