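clamp_age <- function(x, lo = 12, hi = 107) pmin(hi, pmax(lo, round(x)))

#' Construct a record set
#'
#' A record set is the relational form of multi-source provider records: one
#' table of records (one row per requested record) and four content tables
#' keyed by `record_id` (ICD codes, special-education eligibilities,
#' evaluations, cognitive assessments).
#'
#' @param records tibble with `record_id`, `child_id`, `site`, `source_type`
#'   (`health`, `education`, `service-program`), `accessible` (logical).
#' @param icd tibble with `record_id`, `code`, `age_months`.
#' @param sped tibble with `record_id`, `classification`, `age_months`.
#' @param evaluations tibble with `record_id`, `age_months`, `conclusion`
#'   (`asd-diagnosis`, `asd-suspected`, `asd-ruled-out`, `other`),
#'   `by_qualified_professional`, `reported_prior_dx_age_months`.
#' @param cognitive tibble with `record_id`, `age_months`, `kind`
#'   (`test-score`, `examiner-statement`), `iq_score`, `stated_band`.
#' @return an `asdsurv_record_set`.
#' @export
record_set <- function(records = empty_records(), icd = empty_icd(),
                       sped = empty_sped(), evaluations = empty_evaluations(),
                       cognitive = empty_cognitive()) {
  records <- tibble::as_tibble(records)
  content <- list(icd = tibble::as_tibble(icd),
                  sped = tibble::as_tibble(sped),
                  evaluations = tibble::as_tibble(evaluations),
                  cognitive = tibble::as_tibble(cognitive))
  for (nm in names(content)) {
    dangling <- setdiff(content[[nm]]$record_id, records$record_id)
    if (length(dangling)) {
      abort(sprintf("`%s` refers to unknown record ids (e.g. %s)", nm,
                    dangling[1]), class = "asdsurv_consistency_error")
    }
  }
  ages <- c(content$icd$age_months, content$sped$age_months,
            content$evaluations$age_months, content$cognitive$age_months)
  if (length(ages) && (any(ages < 0) || any(ages > 107))) {
    abort("ages must lie in [0, 107] months",
          class = "asdsurv_consistency_error")
  }
  structure(c(list(records = records), content), class = "asdsurv_record_set")
}

empty_records <- function() tibble::tibble(
  record_id = character(), child_id = character(), site = character(),
  source_type = character(), accessible = logical())
empty_icd <- function() tibble::tibble(
  record_id = character(), code = character(), age_months = integer())
empty_sped <- function() tibble::tibble(
  record_id = character(), classification = character(),
  age_months = integer())
empty_evaluations <- function() tibble::tibble(
  record_id = character(), age_months = integer(), conclusion = character(),
  by_qualified_professional = logical(),
  reported_prior_dx_age_months = integer())
empty_cognitive <- function() tibble::tibble(
  record_id = character(), age_months = integer(), kind = character(),
  iq_score = integer(), stated_band = character())

#' @export
print.asdsurv_record_set <- function(x, ...) {
  cat(sprintf(
    "<record_set> %d records / %d children; %d ICD, %d sped, %d evaluations, %d cognitive rows\n",
    nrow(x$records), length(unique(x$records$child_id)), nrow(x$icd),
    nrow(x$sped), nrow(x$evaluations), nrow(x$cognitive)))
  invisible(x)
}

# Sample an IQ score inside a band (integer points, inclusive bounds).
sample_iq_in_band <- function(band) {
  n <- length(band)
  lo <- c("<=70" = 40, "71-85" = 71, ">85" = 86)[band]
  hi <- c("<=70" = 70, "71-85" = 85, ">85" = 130)[band]
  as.integer(floor(runif(n, lo, hi + 1)))
}

#' Generate multi-source provider records for a population
#'
#' Every true case is assigned one of the seven identification-type
#' combinations from the site mixture and receives records carrying exactly
#' those indicators: a clinician diagnostic evaluation (health source), a
#' special-education autism eligibility (education source; generated but not
#' emitted at sites without an education data source), and/or an ASD ICD
#' code.  Evaluation and diagnosis ages follow the configured truncated
#' log-normal distributions; suspected and ruled-out conclusions, cognitive
#' assessments, and per-record accessibility are inserted with the configured
#' probabilities.  Non-case children receive, at the false-trigger rate, a
#' record whose only code is the non-indicator Rett-syndrome code F84.2.
#'
#' @param children the `children` tibble from [generate_population()].
#' @param config the same [generator_config()] used to generate `children`.
#' @param seed integer seed.
#' @return an [record_set()].
#' @export
generate_records <- function(children, config, seed = config$global_seed) {
  if (!inherits(config, "asdsurv_generator_config")) {
    abort("`config` must be a generator_config()",
          class = "asdsurv_config_error")
  }
  required <- c("child_id", "site", "sex", "is_true_case")
  if (!is.data.frame(children) || !all(required %in% names(children))) {
    abort("`children` must come from generate_population()",
          class = "asdsurv_consistency_error")
  }
  unknown <- setdiff(unique(children$site), names(config$sites))
  if (length(unknown)) {
    abort(sprintf("children reference sites absent from config: %s",
                  paste(unknown, collapse = ", ")),
          class = "asdsurv_consistency_error")
  }
  with_seed(seed, {
    parts <- lapply(names(config$sites), function(nm) {
      generate_site_records(children[children$site == nm, , drop = FALSE],
                            config$sites[[nm]])
    })
    collect <- function(field, template) {
      d <- dplyr::bind_rows(lapply(parts, `[[`, field))
      if (nrow(d) == 0) template else d
    }
    record_set(
      records = collect("records", empty_records()),
      icd = collect("icd", empty_icd()),
      sped = collect("sped", empty_sped()),
      evaluations = collect("evaluations", empty_evaluations()),
      cognitive = collect("cognitive", empty_cognitive()))
  })
}

# Fraction of diagnoses entering the record only as a historically reported
# prior diagnosis (an evaluation at a later age carrying the original
# diagnosis age), rather than a directly documented diagnostic conclusion.
P_REPORTED_PRIOR_DX <- 0.2

ASD_ICD_CODE_POOL <- c("F84.0", "F84.5", "F84.9", "299.00", "299.80")

generate_site_records <- function(children, s) {
  cases <- children[children$is_true_case, , drop = FALSE]
  ncase <- nrow(cases)

  out_records <- list(); out_icd <- list(); out_sped <- list()
  out_eval <- list(); out_cog <- list()

  if (ncase > 0) {
    combo <- sample(REGIONS, ncase, replace = TRUE,
                    prob = s$identification_mixture)
    has_dx <- combo %in% c("dx-only", "dx+sped", "dx+icd", "all-three")
    has_sped <- combo %in% c("sped-only", "dx+sped", "sped+icd", "all-three")
    has_icd <- combo %in% c("icd-only", "dx+icd", "sped+icd", "all-three")

    band <- sample(IQ_BANDS, ncase, replace = TRUE, prob = s$iq_band_probs)
    dxd <- s$dx_age_months_distribution
    dx_age <- clamp_age(rlnorm(ncase, dxd$meanlog[band], dxd$sdlog))
    fed <- s$first_eval_age_months_distribution
    first_eval_age <- clamp_age(rlnorm(ncase, fed$meanlog, fed$sdlog))
    first_eval_age <- ifelse(has_dx, pmin(first_eval_age, dx_age),
                             first_eval_age)
    sped_age <- clamp_age(rlnorm(ncase, log(55), 0.30), lo = 30)
    icd_age <- clamp_age(rlnorm(ncase, log(60), 0.35))

    # a health record for every case; an education record for sped cases at
    # sites with an education source
    hid <- sprintf("%s-h", cases$child_id)
    out_records$health <- tibble::tibble(
      record_id = hid, child_id = cases$child_id, site = s$site_name,
      source_type = "health",
      accessible = runif(ncase) < s$record_accessible_fraction)

    emit_edu <- has_sped & s$has_education_source
    if (any(emit_edu)) {
      eid <- sprintf("%s-e", cases$child_id[emit_edu])
      out_records$education <- tibble::tibble(
        record_id = eid, child_id = cases$child_id[emit_edu],
        site = s$site_name, source_type = "education",
        accessible = runif(sum(emit_edu)) < s$record_accessible_fraction)
      out_sped$case <- tibble::tibble(
        record_id = eid,
        classification = sample(c("autism-primary", "autism-eligibility-met"),
                                sum(emit_edu), replace = TRUE),
        age_months = sped_age[emit_edu])
    }

    if (any(has_icd)) {
      out_icd$case <- tibble::tibble(
        record_id = hid[has_icd],
        code = sample(ASD_ICD_CODE_POOL, sum(has_icd), replace = TRUE),
        age_months = icd_age[has_icd])
    }

    # diagnostic conclusion, either documented directly or historically
    # reported inside a later evaluation
    if (any(has_dx)) {
      reported <- has_dx & (runif(ncase) < P_REPORTED_PRIOR_DX)
      direct <- has_dx & !reported
      if (any(direct)) {
        out_eval$dx <- tibble::tibble(
          record_id = hid[direct], age_months = dx_age[direct],
          conclusion = "asd-diagnosis", by_qualified_professional = TRUE,
          reported_prior_dx_age_months = NA_integer_)
      }
      if (any(reported)) {
        rep_age <- pmin(107, dx_age[reported] +
                          clamp_age(rlnorm(sum(reported), log(12), 0.5),
                                    lo = 1, hi = 60))
        out_eval$reported <- tibble::tibble(
          record_id = hid[reported], age_months = rep_age,
          conclusion = "other", by_qualified_professional = TRUE,
          reported_prior_dx_age_months = as.integer(dx_age[reported]))
      }
    }

    # first developmental evaluation for every case (suspected or other)
    suspected <- runif(ncase) < s$p_suspected_before_confirmed
    out_eval$first <- tibble::tibble(
      record_id = hid, age_months = first_eval_age,
      conclusion = ifelse(suspected, "asd-suspected", "other"),
      by_qualified_professional = TRUE,
      reported_prior_dx_age_months = NA_integer_)

    # ruled-out conclusions, placed before or after the confirming ages so
    # that the configured more-recent share is realized; only meaningful for
    # cases carrying a diagnosis or eligibility indicator
    can_ro <- has_dx | has_sped
    ro <- can_ro & (runif(ncase) < s$p_ruled_out_ever)
    if (any(ro)) {
      p_recent <- if (s$p_ruled_out_ever > 0)
        s$p_ruled_out_more_recent / s$p_ruled_out_ever else 0
      recent <- ro & (runif(ncase) < p_recent)
      confirm <- pmax(ifelse(has_dx, dx_age, -Inf),
                      ifelse(has_sped, sped_age, -Inf))
      ro_age <- ifelse(recent, pmin(107, confirm + 1 +
                                      floor(runif(ncase) * 12)),
                       pmax(12, confirm - 1 - floor(runif(ncase) * 12)))
      out_eval$ruled_out <- tibble::tibble(
        record_id = hid[ro], age_months = as.integer(ro_age[ro]),
        conclusion = "asd-ruled-out", by_qualified_professional = TRUE,
        reported_prior_dx_age_months = NA_integer_)
    }

    has_iq <- runif(ncase) < s$iq_available_fraction
    if (any(has_iq)) {
      kind <- sample(c("test-score", "examiner-statement"), sum(has_iq),
                     replace = TRUE, prob = c(0.8, 0.2))
      b <- band[has_iq]
      out_cog$case <- tibble::tibble(
        record_id = hid[has_iq],
        age_months = clamp_age(rlnorm(sum(has_iq), log(72), 0.30)),
        kind = kind,
        iq_score = ifelse(kind == "test-score", sample_iq_in_band(b),
                          NA_integer_),
        stated_band = ifelse(kind == "examiner-statement", b, NA_character_))
    }
  }

  # false triggers: non-cases whose only requested code is Rett syndrome
  noncases <- children[!children$is_true_case, , drop = FALSE]
  trig <- runif(nrow(noncases)) < s$false_trigger_rate
  if (any(trig)) {
    tid <- sprintf("%s-h", noncases$child_id[trig])
    out_records$trigger <- tibble::tibble(
      record_id = tid, child_id = noncases$child_id[trig],
      site = s$site_name, source_type = "health",
      accessible = runif(sum(trig)) < s$record_accessible_fraction)
    out_icd$trigger <- tibble::tibble(
      record_id = tid, code = "F84.2",
      age_months = clamp_age(rlnorm(sum(trig), log(48), 0.40)))
  }

  fix_int <- function(d) {
    if ("age_months" %in% names(d)) {
      d$age_months <- as.integer(d$age_months)
    }
    d
  }
  list(records = dplyr::bind_rows(out_records),
       icd = fix_int(dplyr::bind_rows(out_icd)),
       sped = fix_int(dplyr::bind_rows(out_sped)),
       evaluations = fix_int(dplyr::bind_rows(out_eval)),
       cognitive = fix_int(dplyr::bind_rows(out_cog)))
}
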