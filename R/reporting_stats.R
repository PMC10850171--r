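# Cohort-level report tables and between-group tests.

#' Format a count with its percentage
#'
#' Renders the "n (pct)" cell convention, percentage to one decimal:
#' `format_count_pct(3344, 13007)` is `"3344 (25.7)"`.
#'
#' @param n numerator count.
#' @param total denominator.
#' @param digits decimals for the percentage.
#' @return character scalar.
#' @export
format_count_pct <- function(n, total, digits = 1) {
  sprintf("%d (%s)", n, formatC(100 * n / total, format = "f",
                                digits = digits))
}

#' Format mean (sd) [median]
#'
#' @param x numeric vector.
#' @param digits decimals (1 for days/ages, 2 for PDC, 0 for dollars).
#' @return character scalar like `"0.50 (0.31) [0.42]"`.
#' @export
format_mean_sd_med <- function(x, digits = 1) {
  f <- function(v) formatC(v, format = "f", digits = digits, big.mark = "")
  sprintf("%s (%s) [%s]", f(mean(x)), f(stats::sd(x)),
          f(stats::median(x)))
}

#' Compare a variable between groups
#'
#' Categorical variables use Pearson's chi-square on the contingency table
#' (no continuity correction); continuous variables use the two-sided
#' Mann-Whitney-Wilcoxon test for two groups and the Kruskal-Wallis H test
#' for more than two. Significance is declared at alpha = 0.05, per test,
#' with no multiplicity adjustment. When the contingency table has an
#' all-zero row or column the test is skipped and the comparison flagged.
#'
#' @param values vector of observations (factor/character for categorical,
#'   numeric for continuous).
#' @param groups group labels, same length.
#' @param kind `"categorical"` or `"continuous"`.
#' @param variable display name for the variable.
#' @return object of class `group_comparison`: list with `variable`,
#'   `kind`, `groups`, `summary` (per-group n/% or mean/sd/median),
#'   `test`, `statistic`, `p_value`, `significant`, `skipped`.
#' @export
compare_groups <- function(values, groups,
                           kind = c("categorical", "continuous"),
                           variable = deparse(substitute(values))) {
  kind <- match.arg(kind)
  groups <- as.factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L)
    stop("compare_groups requires at least two non-empty groups")

  skipped <- FALSE; test <- NA_character_
  statistic <- NA_real_; p <- NA_real_

  if (kind == "categorical") {
    tab <- table(values, groups)
    summ <- lapply(levels(groups), function(g) {
      n <- tab[, g]
      data.table::data.table(level = rownames(tab), n = as.integer(n),
                             pct = 100 * as.integer(n) / sum(n))
    })
    names(summ) <- levels(groups)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
        nrow(tab) < 2L) {
      skipped <- TRUE
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      test <- "chi-square"; statistic <- unname(ct$statistic)
      p <- ct$p.value
    }
  } else {
    summ <- lapply(levels(groups), function(g) {
      v <- values[groups == g]
      data.table::data.table(n = length(v), mean = mean(v),
                             sd = stats::sd(v), median = stats::median(v))
    })
    names(summ) <- levels(groups)
    if (nlevels(groups) == 2L) {
      wt <- suppressWarnings(stats::wilcox.test(
        values[groups == levels(groups)[1]],
        values[groups == levels(groups)[2]], exact = FALSE))
      test <- "mann-whitney-wilcoxon"
      statistic <- unname(wt$statistic); p <- wt$p.value
    } else {
      kt <- stats::kruskal.test(values, groups)
      test <- "kruskal-wallis"; statistic <- unname(kt$statistic)
      p <- kt$p.value
    }
  }
  structure(list(variable = variable, kind = kind, groups = levels(groups),
                 summary = summ, test = test, statistic = statistic,
                 p_value = p,
                 significant = isTRUE(p < 0.05), skipped = skipped),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s] groups: %s\n", x$variable, x$kind,
              paste(x$groups, collapse = ", ")))
  if (x$skipped) cat("  test skipped (degenerate table)\n")
  else cat(sprintf("  %s: statistic = %.4g, p = %.4g%s\n", x$test,
                   x$statistic, x$p_value,
                   if (x$significant) " *" else ""))
  invisible(x)
}

# pool index drugs beyond the top k into "other"
pool_index_drugs <- function(index_drug, top = 4L) {
  counts <- sort(table(index_drug), decreasing = TRUE)
  keep <- names(counts)[seq_len(min(top, length(counts)))]
  factor(ifelse(index_drug %in% keep, index_drug, "other"),
         levels = c(keep, "other"))
}

#' Assemble the four cohort report tables and the attrition report
#'
#' Builds analogues of the standard reporting tables for this design:
#' baseline characteristics by index drug (top 4 products individually,
#' the rest pooled as "other"), treatment patterns by index drug, baseline
#' characteristics by adherence status, and utilization/expenditures by
#' adherence status. Cells use the `n (pct)` and `mean (sd) [median]`
#' conventions; each variable carries the appropriate test p-value
#' (chi-square / Kruskal-Wallis across drugs, chi-square /
#' Mann-Whitney-Wilcoxon across adherence groups).
#'
#' @param cohort cohort table from [apply_inclusion()].
#' @param flags baseline flags from [compute_baseline_flags()].
#' @param exposure exposure results from [compute_exposure()].
#' @param hru utilization/expenditure table from [compute_hru_costs()].
#' @param attrition attrition ledger from [apply_inclusion()].
#' @return list of `data.table`s: `table1`, `table2`, `table3`, `table4`,
#'   `attrition`.
#' @export
build_tables <- function(cohort, flags, exposure, hru, attrition) {
  stopifnot(nrow(cohort) > 0)
  dt <- data.table::as.data.table(cohort)
  dt <- merge(dt, flags, by = "patient_id")
  dt <- merge(dt, exposure, by = "patient_id")
  dt$drug_group <- pool_index_drugs(dt$index_drug)
  dt$adh_group <- factor(ifelse(dt$adherent_all, "adherent", "nonadherent"),
                         levels = c("adherent", "nonadherent"))
  dt$age_group <- cut(dt$age_at_index, c(17, 34, 44, 54, 63),
                      labels = c("18-34", "35-44", "45-54", "55-63"))

  cell_cat <- function(x, by) {
    # one row per level: n (pct) per group, chi-square p
    cmp <- compare_groups(x, by, "categorical")
    lv <- sort(unique(as.character(x)))
    rows <- lapply(lv, function(l) {
      cells <- vapply(levels(by), function(g)
        format_count_pct(sum(x == l & by == g), sum(by == g)), "")
      c(list(level = l), as.list(cells))
    })
    out <- data.table::rbindlist(rows)
    out$p_value <- cmp$p_value
    out
  }
  cell_cont <- function(x, by, digits = 1) {
    cmp <- compare_groups(x, by, "continuous")
    cells <- vapply(levels(by), function(g)
      format_mean_sd_med(x[by == g], digits), "")
    out <- data.table::as.data.table(as.list(cells))
    out <- cbind(data.table::data.table(level = "mean"), out)
    out$p_value <- cmp$p_value
    out
  }
  characteristics_by <- function(by) {
    blocks <- list(
      sex = cell_cat(dt$sex, by),
      age = cell_cont(dt$age_at_index, by),
      age_group = cell_cat(as.character(dt$age_group), by),
      race = cell_cat(dt$race, by),
      cci = cell_cont(dt$cci_score, by, digits = 2),
      cci_group = cell_cat(as.character(dt$cci_group), by),
      bipolar = cell_cat(ifelse(dt$bipolar, "yes", "no"), by),
      mdd = cell_cat(ifelse(dt$mdd, "yes", "no"), by),
      schizoaffective = cell_cat(ifelse(dt$schizoaffective, "yes", "no"), by))
    data.table::rbindlist(lapply(names(blocks), function(v)
      cbind(data.table::data.table(variable = v), blocks[[v]])),
      use.names = TRUE)
  }

  table1 <- characteristics_by(dt$drug_group)
  table3 <- characteristics_by(dt$adh_group)

  by <- dt$drug_group
  t2 <- list(
    index_days = cell_cont(dt$index_medication_days, by),
    all_oaap_days = cell_cont(dt$all_oaap_medication_days, by),
    augmented = cell_cat(ifelse(dt$augmented, "yes", "no"), by),
    switched = cell_cat(ifelse(dt$switched, "yes", "no"), by),
    pdc_index = cell_cont(dt$pdc_index, by, digits = 2),
    adherent_index = cell_cat(ifelse(dt$adherent_index, "yes", "no"), by),
    pdc_all = cell_cont(dt$pdc_all, by, digits = 2),
    adherent_all = cell_cat(ifelse(dt$adherent_all, "yes", "no"), by))
  table2 <- data.table::rbindlist(lapply(names(t2), function(v)
    cbind(data.table::data.table(variable = v), t2[[v]])), use.names = TRUE)

  hdt <- merge(data.table::as.data.table(hru),
               dt[, c("patient_id", "adh_group"), with = FALSE],
               by = "patient_id")
  by4 <- function(scope, col, kind, digits = 1) {
    sub <- hdt[hdt$scope == scope, ]
    if (kind == "flag")
      cell_cat(ifelse(sub[[col]], "yes", "no"), sub$adh_group)
    else cell_cont(sub[[col]], sub$adh_group, digits)
  }
  t4 <- list()
  for (sc in c("all_cause", "schizophrenia")) {
    t4[[paste0(sc, ".any_inpatient")]] <- by4(sc, "any_inpatient", "flag")
    t4[[paste0(sc, ".any_ed")]] <- by4(sc, "any_ed", "flag")
    t4[[paste0(sc, ".any_outpatient")]] <- by4(sc, "any_outpatient", "flag")
    t4[[paste0(sc, ".inpatient_visits")]] <-
      by4(sc, "inpatient_visits", "cont", 2)
    sub_ip <- hdt[hdt$scope == sc & hdt$inpatient_visits >= 1L, ]
    if (nrow(sub_ip) > 0L && length(unique(sub_ip$adh_group)) == 2L)
      t4[[paste0(sc, ".inpatient_days")]] <-
        cell_cont(sub_ip$inpatient_days, droplevels(sub_ip$adh_group), 1)
    t4[[paste0(sc, ".ed_visits")]] <- by4(sc, "ed_visits", "cont", 1)
    t4[[paste0(sc, ".outpatient_visits")]] <-
      by4(sc, "outpatient_visits", "cont", 1)
    for (col in c("exp_inpatient", "exp_ed", "exp_outpatient",
                  "exp_total_medical", "exp_rx", "exp_total")) {
      t4[[paste0(sc, ".", col)]] <- by4(sc, col, "cont", 0)
    }
  }
  table4 <- data.table::rbindlist(lapply(names(t4), function(v)
    cbind(data.table::data.table(variable = v), t4[[v]])), use.names = TRUE)

  list(table1 = table1, table2 = table2, table3 = table3, table4 = table4,
       attrition = data.table::as.data.table(attrition))
}
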