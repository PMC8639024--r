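#' Extract one child's source records from a record set
#'
#' @param rs an [record_set()].
#' @param child_id a single child id.
#' @return list of source-record lists (`child_id`, `site`, `source_type`,
#'   `accessible`, and the `icd_codes`, `sped`, `evaluations`, `cognitive`
#'   content tables of that record).
#' @export
child_records <- function(rs, child_id) {
  stopifnot(inherits(rs, "asdsurv_record_set"), length(child_id) == 1L)
  rows <- rs$records[rs$records$child_id == child_id, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    rid <- rows$record_id[i]
    list(child_id = rows$child_id[i], site = rows$site[i],
         source_type = rows$source_type[i], accessible = rows$accessible[i],
         icd_codes = rs$icd[rs$icd$record_id == rid, , drop = FALSE],
         sped = rs$sped[rs$sped$record_id == rid, , drop = FALSE],
         evaluations = rs$evaluations[rs$evaluations$record_id == rid, ,
                                      drop = FALSE],
         cognitive = rs$cognitive[rs$cognitive$record_id == rid, ,
                                  drop = FALSE])
  })
}

#' Merge one child's records across data sources
#'
#' Indicators and documents are unioned across sources.  Inaccessible
#' records contribute only their transmitted trigger codes — ICD codes and
#' special-education eligibilities — while their evaluations and cognitive
#' assessments are dropped (content requiring a manual chart review cannot
#' be observed on an inaccessible record).
#'
#' @param records non-empty list of source records (see [child_records()])
#'   sharing one `child_id`.
#' @return an `asdsurv_merged_record` list with `child_id` and the unioned
#'   `icd_codes`, `sped`, `evaluations`, `cognitive` tables.
#' @export
merge_child_records <- function(records) {
  if (!is.list(records) || length(records) == 0L) {
    abort("`records` must be a non-empty list of source records",
          class = "asdsurv_consistency_error")
  }
  ids <- unique(vapply(records, `[[`, character(1), "child_id"))
  if (length(ids) != 1L) {
    abort(sprintf("records mix child ids: %s", paste(ids, collapse = ", ")),
          class = "asdsurv_consistency_error")
  }
  templates <- list(
    icd_codes = empty_icd()[-1],
    sped = empty_sped()[-1],
    evaluations = empty_evaluations()[-1],
    cognitive = empty_cognitive()[-1])
  pick <- function(field, accessible_only) {
    keep <- records
    if (accessible_only) {
      keep <- keep[vapply(keep, function(r) isTRUE(r$accessible), logical(1))]
    }
    out <- dplyr::bind_rows(lapply(keep, `[[`, field))
    if (ncol(out) == 0) templates[[field]] else out
  }
  structure(
    list(child_id = ids,
         icd_codes = pick("icd_codes", accessible_only = FALSE),
         sped = pick("sped", accessible_only = FALSE),
         evaluations = pick("evaluations", accessible_only = TRUE),
         cognitive = pick("cognitive", accessible_only = TRUE)),
    class = "asdsurv_merged_record")
}

min_or_na <- function(x) if (length(x)) min(x) else NA_integer_
max_or_na <- function(x) if (length(x)) max(x) else NA_integer_

#' Diagnosis history of a merged record
#'
#' The earliest known diagnosis age is the minimum over directly documented
#' qualified diagnostic conclusions and historically reported prior
#' diagnosis ages.  A ruled-out conclusion counts as "more recent" only when
#' its maximum age strictly exceeds the maximum age of every confirming
#' diagnosis or special-education eligibility (equal months are not ordered).
#'
#' @param merged an [merge_child_records()] result.
#' @return list with `earliest_dx_age_months` (`NA` when none),
#'   `suspected_ever`, `ruled_out_ever`, `ruled_out_more_recent`.
#' @export
diagnosis_history <- function(merged) {
  ev <- merged$evaluations
  dx_direct <- ev[!is.na(ev$conclusion) & ev$conclusion == "asd-diagnosis" &
                    ev$by_qualified_professional, , drop = FALSE]
  reported <- ev$reported_prior_dx_age_months
  reported <- reported[!is.na(reported)]
  dx_ages <- c(dx_direct$age_months, reported)
  sped_ages <- merged$sped$age_months[
    merged$sped$classification %in% c("autism-primary",
                                      "autism-eligibility-met")]
  ro_ages <- ev$age_months[!is.na(ev$conclusion) &
                             ev$conclusion == "asd-ruled-out"]
  confirm <- max_or_na(c(dx_ages, sped_ages))
  list(
    earliest_dx_age_months = min_or_na(dx_ages),
    suspected_ever = any(ev$conclusion == "asd-suspected", na.rm = TRUE),
    ruled_out_ever = length(ro_ages) > 0,
    ruled_out_more_recent = length(ro_ages) > 0 && !is.na(confirm) &&
      max(ro_ages) > confirm)
}

#' Earliest developmental evaluation age
#'
#' Minimum over accessible evaluation ages and historically reported prior
#' diagnosis ages; children without any evaluation information are excluded
#' from evaluation-timing denominators.  The early-evaluation flag is true
#' at or before 36 months (boundary inclusive).
#'
#' @param merged an [merge_child_records()] result.
#' @return list with `age_months` (`NA` when no evaluation information) and
#'   `by_36_months`.
#' @export
earliest_evaluation_age <- function(merged) {
  ev <- merged$evaluations
  ages <- c(ev$age_months,
            ev$reported_prior_dx_age_months[
              !is.na(ev$reported_prior_dx_age_months)])
  age <- min_or_na(ages)
  list(age_months = age,
       by_36_months = if (is.na(age)) NA else age <= 36)
}

#' Cognitive classification from the most recent assessment
#'
#' Uses the most recent (largest age) accessible cognitive entry; at equal
#' ages a test score beats an examiner statement, and remaining ties break
#' toward the higher score.  Scores map to the bands `<=70`, `71-85`, `>85`.
#'
#' @param merged an [merge_child_records()] result.
#' @return one of `"<=70"`, `"71-85"`, `">85"`, or `NA` when no cognitive
#'   data are available.
#' @export
classify_cognitive <- function(merged) {
  cg <- merged$cognitive
  if (nrow(cg) == 0) return(NA_character_)
  ord <- order(cg$age_months, cg$kind == "test-score",
               ifelse(is.na(cg$iq_score), -Inf, cg$iq_score))
  top <- cg[ord[length(ord)], ]
  iq_band(top$iq_score, top$stated_band)
}

iq_band <- function(score, stated) {
  ifelse(!is.na(score),
         ifelse(score <= 70, "<=70", ifelse(score <= 85, "71-85", ">85")),
         stated)
}

#' Apply the surveillance case definition to one merged record
#'
#' A child meets the case definition when resident in the surveillance area
#' during the analysis year, born in the cohort birth year, and carrying at
#' least one of the three indicators: a qualified professional's ASD
#' diagnostic statement (directly documented or historically reported), a
#' special-education autism classification/eligibility, or an ASD ICD code.
#'
#' @param merged an [merge_child_records()] result.
#' @param resident_in_year did the child live in the surveillance area for
#'   at least one day of the analysis year?
#' @param birth_year the child's birth year.
#' @param cohort_birth_year the cohort birth year of the surveillance design
#'   (default 2010).
#' @return a one-row tibble with the case-status fields.
#' @export
classify_case <- function(merged, resident_in_year = TRUE,
                          birth_year = 2010L, cohort_birth_year = 2010L) {
  stopifnot(inherits(merged, "asdsurv_merged_record"))
  has_icd <- nrow(merged$icd_codes) > 0 &&
    any(is_asd_indicator_code(merged$icd_codes$code))
  has_sped <- any(merged$sped$classification %in%
                    c("autism-primary", "autism-eligibility-met"))
  hist <- diagnosis_history(merged)
  has_dx <- !is.na(hist$earliest_dx_age_months)
  eligible <- isTRUE(resident_in_year) && birth_year == cohort_birth_year
  is_case <- eligible && (has_dx || has_sped || has_icd)
  ev_age <- earliest_evaluation_age(merged)
  tibble::tibble(
    child_id = merged$child_id,
    has_dx_statement = has_dx,
    has_sped = has_sped,
    has_icd = has_icd,
    is_case = is_case,
    region = if (is_case) region_label(has_dx, has_sped, has_icd) else "none",
    earliest_dx_age_months = hist$earliest_dx_age_months,
    earliest_eval_age_months = ev_age$age_months,
    eval_by_36_months = ev_age$by_36_months,
    suspected_ever = hist$suspected_ever,
    ruled_out_ever = hist$ruled_out_ever,
    ruled_out_more_recent = hist$ruled_out_more_recent,
    cognitive_band = classify_cognitive(merged))
}

#' Ascertain case status for every child with records
#'
#' Vectorized application of [merge_child_records()] + [classify_case()]
#' over a whole record set: indicators are unioned across sources, content
#' of inaccessible records is restricted to transmitted ICD and
#' special-education codes, and every child carrying at least one record
#' receives a case-status row joined with its demographics.
#'
#' @param children the `children` tibble from [generate_population()] (or a
#'   compatible table with `child_id`, `site`, `sex`, `race_ethnicity`,
#'   `resident_in_year`, `census_tract`).
#' @param rs an [record_set()].
#' @param birth_year birth year of the children (all children in a
#'   surveillance run share the cohort birth year).
#' @param cohort_birth_year cohort birth year of the design (default 2010).
#' @return tibble of case statuses, one row per child with any record.
#' @export
ascertain_cases <- function(children, rs, birth_year = 2010L,
                            cohort_birth_year = 2010L) {
  stopifnot(inherits(rs, "asdsurv_record_set"))
  recs <- rs$records
  unknown <- setdiff(recs$child_id, children$child_id)
  if (length(unknown)) {
    abort(sprintf("records reference children absent from the population (e.g. %s)",
                  unknown[1]), class = "asdsurv_consistency_error")
  }
  rid2cid <- setNames(recs$child_id, recs$record_id)
  rid_acc <- setNames(recs$accessible, recs$record_id)

  # indicator flags (trigger codes count regardless of accessibility)
  icd <- rs$icd
  icd_children <- unique(rid2cid[icd$record_id[is_asd_indicator_code(icd$code)]])
  sped <- rs$sped[rs$sped$classification %in%
                    c("autism-primary", "autism-eligibility-met"), ,
                  drop = FALSE]
  sped_cid <- rid2cid[sped$record_id]
  sped_max <- tapply_num(sped$age_months, sped_cid, max)

  # evaluation content exists only on accessible records
  ev <- rs$evaluations[rid_acc[rs$evaluations$record_id], , drop = FALSE]
  ev_cid <- rid2cid[ev$record_id]
  dx_sel <- ev$conclusion == "asd-diagnosis" & ev$by_qualified_professional
  rep_sel <- !is.na(ev$reported_prior_dx_age_months)
  dx_ages_cid <- c(ev_cid[dx_sel], ev_cid[rep_sel])
  dx_ages <- c(ev$age_months[dx_sel],
               ev$reported_prior_dx_age_months[rep_sel])
  dx_min <- tapply_num(dx_ages, dx_ages_cid, min)
  dx_max <- tapply_num(dx_ages, dx_ages_cid, max)
  eval_min <- tapply_num(c(ev$age_months, dx_ages),
                         c(ev_cid, dx_ages_cid), min)
  susp_children <- unique(ev_cid[ev$conclusion == "asd-suspected"])
  ro_max <- tapply_num(ev$age_months[ev$conclusion == "asd-ruled-out"],
                       ev_cid[ev$conclusion == "asd-ruled-out"], max)

  # most recent cognitive entry (test-score beats statement at equal age,
  # then the higher score wins)
  cg <- rs$cognitive[rid_acc[rs$cognitive$record_id], , drop = FALSE]
  cg_band <- rep(NA_character_, 0)
  if (nrow(cg) > 0) {
    cg_cid <- rid2cid[cg$record_id]
    ord <- order(cg_cid, cg$age_months, cg$kind == "test-score",
                 ifelse(is.na(cg$iq_score), -Inf, cg$iq_score))
    last <- !duplicated(cg_cid[ord], fromLast = TRUE)
    keep <- ord[last]
    cg_band <- setNames(iq_band(cg$iq_score[keep], cg$stated_band[keep]),
                        cg_cid[keep])
  }

  ids <- unique(recs$child_id)
  has_icd <- ids %in% icd_children
  has_sped <- ids %in% names(sped_max)
  dx_min_v <- unname(dx_min[ids])
  has_dx <- !is.na(dx_min_v)
  confirm <- unname(pmax(na_to(dx_max[ids], -Inf),
                         na_to(sped_max[ids], -Inf)))
  ro_v <- unname(ro_max[ids])

  chdem <- children[match(ids, children$child_id),
                    intersect(c("site", "sex", "race_ethnicity",
                                "resident_in_year", "census_tract",
                                "is_true_case"), names(children)),
                    drop = FALSE]
  resident <- if ("resident_in_year" %in% names(chdem))
    chdem$resident_in_year else rep(TRUE, length(ids))
  eligible <- resident & (birth_year == cohort_birth_year)
  is_case <- eligible & (has_dx | has_sped | has_icd)

  eval_min_v <- unname(eval_min[ids])
  out <- tibble::tibble(
    child_id = ids,
    has_dx_statement = has_dx,
    has_sped = has_sped,
    has_icd = has_icd,
    is_case = is_case,
    region = ifelse(is_case, region_label(has_dx, has_sped, has_icd), "none"),
    earliest_dx_age_months = as.integer(dx_min_v),
    earliest_eval_age_months = as.integer(eval_min_v),
    eval_by_36_months = ifelse(is.na(eval_min_v), NA, eval_min_v <= 36),
    suspected_ever = ids %in% susp_children,
    ruled_out_ever = !is.na(ro_v),
    ruled_out_more_recent = !is.na(ro_v) & is.finite(confirm) &
      ro_v > confirm,
    cognitive_band = unname(cg_band[ids]))
  dplyr::bind_cols(out, tibble::as_tibble(chdem))
}

tapply_num <- function(x, by, fn) {
  if (length(x) == 0) return(setNames(numeric(0), character(0)))
  vapply(split(as.numeric(x), by), fn, numeric(1))
}

na_to <- function(x, value) ifelse(is.na(x), value, x)

#' Tabulate identification-type Euler regions among cases
#'
#' Counts cases over the seven non-empty combinations of the three
#' identification types and derives the summary shares: any diagnostic
#' statement, special education without a diagnostic statement, ICD code
#' only, and at least two identification types.  The first three shares
#' partition the cases and sum to 100%.
#'
#' @param statuses case-status tibble (all rows must be cases).
#' @return list with `counts` (tibble region/n) and `shares` (named
#'   percentages: `any_dx`, `sped_no_dx`, `icd_only`, `two_plus`).
#' @export
identification_regions <- function(statuses) {
  if (any(!statuses$is_case)) {
    abort("`statuses` must contain cases only",
          class = "asdsurv_validation_error")
  }
  n <- nrow(statuses)
  counts <- table(factor(statuses$region, levels = REGIONS))
  cn <- as.numeric(counts)
  names(cn) <- REGIONS
  shares <- c(
    any_dx = sum(cn[c("dx-only", "dx+sped", "dx+icd", "all-three")]),
    sped_no_dx = sum(cn[c("sped-only", "sped+icd")]),
    icd_only = cn[["icd-only"]],
    two_plus = sum(cn[c("dx+sped", "dx+icd", "sped+icd", "all-three")]))
  list(counts = tibble::tibble(region = REGIONS, n = cn),
       shares = 100 * shares / max(n, 1))
}
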