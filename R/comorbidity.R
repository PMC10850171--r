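# Quan ICD-10 Charlson comorbidity index and severe-mental-illness flags.

#' Load the Quan ICD-10 Charlson coding map
#'
#' The map ships as a plain CSV resource (one row per ICD-10 prefix:
#' category, prefix, weight, supersedes) implementing Quan's ICD-10 coding
#' algorithm for the 17 Charlson categories with the original Charlson
#' weights (1/2/3/6). `supersedes` encodes the hierarchy pairs: complicated
#' diabetes supersedes uncomplicated, moderate/severe liver disease
#' supersedes mild, metastatic solid tumor supersedes any malignancy.
#'
#' @param path optional path to an alternative map CSV with the same
#'   columns (e.g. Quan-2011 weights).
#' @return `data.table` with columns `category`, `prefix`, `weight`,
#'   `supersedes`.
#' @export
charlson_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "quan_charlson_icd10.csv",
                                package = "oaapflow", mustWork = TRUE)
  map <- data.table::fread(path, colClasses = "character")
  map$weight <- as.integer(map$weight)
  stopifnot(all(nzchar(map$prefix)), all(map$weight >= 1L))
  partners <- map$supersedes[nzchar(map$supersedes)]
  stopifnot(all(partners %in% map$category))
  map
}

#' Quan-Charlson comorbidity index
#'
#' A category is present iff any diagnosis code matches any of its ICD-10
#' prefixes (dot-insensitive). Hierarchy rules then drop the lesser member
#' of conflicting pairs, and the score is the sum of the weights of the
#' remaining present categories. Codes matching no category are ignored.
#'
#' @param codes character vector of ICD-10 codes (typically the patient's
#'   baseline-window diagnoses).
#' @param map coding map from [charlson_map()].
#' @param apply_hierarchy drop superseded categories (default TRUE).
#' @return integer score >= 0.
#' @export
quan_cci <- function(codes, map = charlson_map(), apply_hierarchy = TRUE) {
  cci_score(codes, prepare_charlson(map), apply_hierarchy)
}

# pre-index the map once: prefix list, weight and hierarchy per category
prepare_charlson <- function(map) {
  if (inherits(map, "charlson_prepared")) return(map)
  cats <- unique(map$category)
  sup <- unique(as.data.frame(map[nzchar(map$supersedes),
                                  c("category", "supersedes")]))
  structure(list(
    cats = cats,
    prefixes = lapply(cats, function(cat) map$prefix[map$category == cat]),
    weights = vapply(cats, function(cat) map$weight[map$category == cat][1],
                     1L),
    sup = sup), class = "charlson_prepared")
}

cci_score <- function(codes, prep, apply_hierarchy = TRUE) {
  codes <- unique(normalize_icd10(codes))
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) return(0L)
  present <- vapply(seq_along(prep$cats), function(i) {
    any(icd_prefix_match(codes, prep$prefixes[[i]]))
  }, TRUE)
  names(present) <- prep$cats
  if (apply_hierarchy) {
    for (i in seq_len(nrow(prep$sup))) {
      if (present[[prep$sup$category[i]]])
        present[[prep$sup$supersedes[i]]] <- FALSE
    }
  }
  sum(prep$weights[present])
}

#' Charlson score group
#'
#' @param score integer CCI score(s).
#' @return factor with levels `0`, `1`, `2+`.
#' @export
cci_group <- function(score) {
  factor(ifelse(score >= 2, "2+", as.character(score)),
         levels = c("0", "1", "2+"))
}

#' Severe-mental-illness flags
#'
#' Comorbid severe mental illness from ICD-10 codes: bipolar disorder
#' (F31.x), major depressive disorder (F32.x/F33.x), schizoaffective
#' disorder (F25.x). Prefix matching is dot-insensitive; F20.x itself sets
#' none of the flags.
#'
#' @param codes character vector of ICD-10 codes (baseline and follow-up).
#' @return list of logicals `bipolar`, `mdd`, `schizoaffective`.
#' @export
smi_flags <- function(codes) {
  codes <- normalize_icd10(codes)
  list(bipolar = any(icd_prefix_match(codes, "F31")),
       mdd = any(icd_prefix_match(codes, c("F32", "F33"))),
       schizoaffective = any(icd_prefix_match(codes, "F25")))
}

#' Baseline comorbidity flags for a cohort
#'
#' Computes the Quan-Charlson score from baseline-window diagnoses (days
#' -182..-1 relative to index) and the severe-mental-illness flags from
#' baseline plus follow-up diagnoses (days -182..364), per patient.
#'
#' @param cohort cohort table from [apply_inclusion()].
#' @param medical medical claims table.
#' @param map Charlson coding map.
#' @return `data.table`: `patient_id`, `cci_score`, `cci_group`, `bipolar`,
#'   `mdd`, `schizoaffective`.
#' @export
compute_baseline_flags <- function(cohort, medical, map = charlson_map()) {
  md <- data.table::as.data.table(medical)
  cols <- dx_cols(md)
  idx <- match(md$patient_id, cohort$patient_id)
  day <- as.integer(md$service_date - cohort$index_date[idx])
  long <- data.table::rbindlist(lapply(cols, function(cl)
    data.table::data.table(patient_id = md$patient_id, day = day,
                           code = md[[cl]])))
  long <- long[!is.na(long$code) & !is.na(long$day), ]
  base <- long[long$day >= BASELINE_START & long$day <= BASELINE_END, ]
  full <- long[long$day >= BASELINE_START & long$day <= FOLLOWUP_END, ]
  base_by <- split(base$code, base$patient_id)
  full_by <- split(full$code, full$patient_id)

  prep <- prepare_charlson(map)
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$patient_id[i]
    score <- cci_score(base_by[[id]] %||% character(0), prep)
    sm <- smi_flags(full_by[[id]] %||% character(0))
    out[[i]] <- data.table::data.table(
      patient_id = id, cci_score = score,
      bipolar = sm$bipolar, mdd = sm$mdd,
      schizoaffective = sm$schizoaffective)
  }
  res <- data.table::rbindlist(out)
  res$cci_group <- cci_group(res$cci_score)
  res
}
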