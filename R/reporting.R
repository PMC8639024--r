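pct1 <- function(num, den) {
  ifelse(den > 0, round_half_away(100 * num / den, 1), NA_real_)
}

med1 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else as.numeric(median(x))
}

case_rows <- function(statuses) {
  statuses[statuses$is_case, , drop = FALSE]
}

# site roster: union of denominator sites (keeps sites with zero cases)
site_roster <- function(statuses, denominators = NULL) {
  if (!is.null(denominators)) unique(denominators$site)
  else sort(unique(statuses$site))
}

#' Site-level prevalence table, overall and by sex
#'
#' One row per site plus a network total row: case count, population,
#' overall prevalence with Wilson interval, sex-specific prevalence, and
#' the male-to-female prevalence ratio with Katz interval.  Suppressed
#' cells render as an em dash.
#'
#' @param statuses case-status tibble from [ascertain_cases()].
#' @param denominators a [denominator_table()].
#' @param cfg an [analysis_config()].
#' @return tibble with formatted and numeric columns.
#' @export
build_table2 <- function(statuses, denominators, cfg = NULL) {
  cfg <- default_cfg(cfg)
  cases <- case_rows(statuses)
  sites <- site_roster(statuses, denominators)
  row_for <- function(site_sel, label) {
    cc <- if (identical(site_sel, "all")) cases else
      cases[cases$site %in% site_sel, , drop = FALSE]
    den_all <- denominator_for(denominators, site = site_sel)
    if (den_all == 0) {
      abort(sprintf("missing denominator for site %s", label),
            class = "asdsurv_data_error")
    }
    den_m <- denominator_for(denominators, site = site_sel, sex = "male")
    den_f <- denominator_for(denominators, site = site_sel, sex = "female")
    p_all <- prevalence(nrow(cc), den_all, cfg)
    n_m <- sum(cc$sex == "male")
    n_f <- sum(cc$sex == "female")
    p_m <- prevalence(n_m, max(den_m, 1e-9), cfg)
    p_f <- prevalence(n_f, max(den_f, 1e-9), cfg)
    ratio_txt <- if (n_f > 0) {
      render_estimate(prevalence_ratio(p_m, p_f, cfg))
    } else "—"
    tibble::tibble(
      site = label, n_with_asd = nrow(cc), population = den_all,
      prevalence_per_1000 = round_half_away(p_all$per_1000),
      overall = render_estimate(p_all),
      male = render_estimate(p_m), female = render_estimate(p_f),
      mf_ratio = ratio_txt)
  }
  dplyr::bind_rows(c(lapply(sites, function(s) row_for(s, s)),
                     list(row_for("all", "total"))))
}

#' Race/ethnicity-specific prevalence and prevalence-ratio table
#'
#' Prevalence per race/ethnicity group and pairwise prevalence ratios, per
#' site and network-wide.  Children coded other/multiracial are excluded
#' from both numerators and denominators.
#'
#' @inheritParams build_table2
#' @return tibble, one row per site (plus total).
#' @export
build_table3 <- function(statuses, denominators, cfg = NULL) {
  cfg <- default_cfg(cfg)
  cases <- case_rows(statuses)
  sites <- site_roster(statuses, denominators)
  groups <- c("white-nh", "black-nh", "hispanic", "api-nh")
  pairs <- list(c("white-nh", "black-nh"), c("white-nh", "hispanic"),
                c("black-nh", "hispanic"), c("white-nh", "api-nh"),
                c("black-nh", "api-nh"), c("hispanic", "api-nh"))
  row_for <- function(site_sel, label) {
    cc <- if (identical(site_sel, "all")) cases else
      cases[cases$site %in% site_sel, , drop = FALSE]
    est <- lapply(groups, function(g) {
      den <- denominator_for(denominators, site = site_sel, race = g)
      if (den <= 0) return(NULL)
      prevalence(sum(cc$race_ethnicity == g), den, cfg)
    })
    names(est) <- groups
    out <- tibble::tibble(site = label)
    for (g in groups) {
      out[[paste0("prev_", gsub("-", "_", g))]] <-
        if (is.null(est[[g]])) "—" else render_estimate(est[[g]])
    }
    for (p in pairs) {
      nm <- paste0("ratio_", gsub("-", "_", p[1]), "_to_",
                   gsub("-", "_", p[2]))
      a <- est[[p[1]]]; b <- est[[p[2]]]
      out[[nm]] <- if (is.null(a) || is.null(b) || b$numerator == 0) "—"
        else render_estimate(prevalence_ratio(a, b, cfg))
    }
    out
  }
  dplyr::bind_rows(c(lapply(sites, function(s) row_for(s, s)),
                     list(row_for("all", "total"))))
}

#' Identification-information table
#'
#' Per-site shares of cases carrying each identification type (ICD code,
#' special-education eligibility, diagnostic statement) and the
#' suspected/ruled-out evaluation-history shares.
#'
#' @param statuses case-status tibble.
#' @return tibble, one row per site (plus total).
#' @export
build_table4 <- function(statuses) {
  cases <- case_rows(statuses)
  sites <- sort(unique(cases$site))
  row_for <- function(cc, label) {
    n <- nrow(cc)
    tibble::tibble(
      site = label, n_with_asd = n,
      pct_icd = pct1(sum(cc$has_icd), n),
      pct_sped = pct1(sum(cc$has_sped), n),
      pct_dx = pct1(sum(cc$has_dx_statement), n),
      pct_suspected = pct1(sum(cc$suspected_ever), n),
      pct_ruled_out_ever = pct1(sum(cc$ruled_out_ever), n),
      pct_ruled_out_more_recent = pct1(sum(cc$ruled_out_more_recent), n))
  }
  dplyr::bind_rows(c(
    lapply(sites, function(s) row_for(cases[cases$site == s, ], s)),
    list(row_for(cases, "total"))))
}

#' Cognitive-ability availability and band table
#'
#' IQ-data availability and cognitive-band distribution among cases, by
#' site, by sex, and by race/ethnicity.
#'
#' @param statuses case-status tibble.
#' @return tibble with one row per stratum.
#' @export
build_table5 <- function(statuses) {
  cases <- case_rows(statuses)
  row_for <- function(cc, stratum, level) {
    n <- nrow(cc)
    iq <- cc$cognitive_band[!is.na(cc$cognitive_band)]
    tibble::tibble(
      stratum = stratum, level = level, n_with_asd = n,
      n_with_iq = length(iq), pct_with_iq = pct1(length(iq), n),
      pct_iq_le70 = pct1(sum(iq == "<=70"), length(iq)),
      pct_iq_71_85 = pct1(sum(iq == "71-85"), length(iq)),
      pct_iq_gt85 = pct1(sum(iq == ">85"), length(iq)))
  }
  sites <- sort(unique(cases$site))
  races <- c("white-nh", "black-nh", "hispanic")
  dplyr::bind_rows(c(
    lapply(sites, function(s)
      row_for(cases[cases$site == s, ], "site", s)),
    list(row_for(cases, "site", "total")),
    lapply(c("female", "male"), function(s)
      row_for(cases[cases$sex == s, ], "sex", s)),
    lapply(races, function(r)
      row_for(cases[cases$race_ethnicity == r, ], "race", r))))
}

#' Early-evaluation table by intellectual-disability status
#'
#' Among cases with any recorded evaluation: share evaluated at or before
#' 36 months and median age at earliest recorded evaluation, overall and
#' split by cognitive band (IQ at most 70 versus above 70).
#'
#' @param statuses case-status tibble.
#' @return tibble, one row per site (plus total).
#' @export
build_table6 <- function(statuses) {
  cases <- case_rows(statuses)
  sites <- sort(unique(cases$site))
  row_for <- function(cc, label) {
    ev <- cc[!is.na(cc$earliest_eval_age_months), , drop = FALSE]
    lo <- ev[!is.na(ev$cognitive_band) & ev$cognitive_band == "<=70", ]
    hi <- ev[!is.na(ev$cognitive_band) & ev$cognitive_band != "<=70", ]
    tibble::tibble(
      site = label, n_with_asd = nrow(cc), n_evaluated = nrow(ev),
      pct_by_36 = pct1(sum(ev$eval_by_36_months), nrow(ev)),
      median_eval_age = med1(ev$earliest_eval_age_months),
      n_evaluated_iq_le70 = nrow(lo),
      pct_by_36_iq_le70 = pct1(sum(lo$eval_by_36_months), nrow(lo)),
      median_eval_age_iq_le70 = med1(lo$earliest_eval_age_months),
      n_evaluated_iq_gt70 = nrow(hi),
      pct_by_36_iq_gt70 = pct1(sum(hi$eval_by_36_months), nrow(hi)),
      median_eval_age_iq_gt70 = med1(hi$earliest_eval_age_months))
  }
  dplyr::bind_rows(c(
    lapply(sites, function(s) row_for(cases[cases$site == s, ], s)),
    list(row_for(cases, "total"))))
}

#' Diagnosed-case table: counts, diagnosed prevalence, median diagnosis age
#'
#' Among cases with a documented diagnostic statement: count, prevalence of
#' documented diagnosis per 1,000, and median age at earliest known
#' diagnosis, overall and by cognitive band.
#'
#' @inheritParams build_table2
#' @return tibble, one row per site (plus total).
#' @export
build_table7 <- function(statuses, denominators, cfg = NULL) {
  cfg <- default_cfg(cfg)
  cases <- case_rows(statuses)
  sites <- site_roster(statuses, denominators)
  row_for <- function(site_sel, label) {
    cc <- if (identical(site_sel, "all")) cases else
      cases[cases$site %in% site_sel, , drop = FALSE]
    dx <- cc[cc$has_dx_statement, , drop = FALSE]
    den <- denominator_for(denominators, site = site_sel)
    lo <- dx[!is.na(dx$cognitive_band) & dx$cognitive_band == "<=70", ]
    hi <- dx[!is.na(dx$cognitive_band) & dx$cognitive_band != "<=70", ]
    tibble::tibble(
      site = label, n_with_asd = nrow(cc), n_diagnosed = nrow(dx),
      diagnosed_prevalence_per_1000 =
        round_half_away(prevalence(nrow(dx), den, cfg)$per_1000),
      median_dx_age = med1(dx$earliest_dx_age_months),
      n_diagnosed_iq_le70 = nrow(lo),
      median_dx_age_iq_le70 = med1(lo$earliest_dx_age_months),
      n_diagnosed_iq_gt70 = nrow(hi),
      median_dx_age_iq_gt70 = med1(hi$earliest_dx_age_months))
  }
  dplyr::bind_rows(c(lapply(sites, function(s) row_for(s, s)),
                     list(row_for("all", "total"))))
}

#' Prevalence by socioeconomic tertile with trend test
#'
#' For every site (and all sites combined): prevalence per tertile using
#' tract-sum denominators (estimated 8-year-old populations of the site's
#' tracts in each tertile) and the Cochran-Armitage trend p value across
#' the ordered tertiles.  Children without a geocodable tract are excluded.
#' Sites with fewer than 3 tracts are skipped with a warning.
#'
#' @param statuses case-status tibble.
#' @param children the population's children tibble.
#' @param tracts tract table (tertiles are assigned here if absent, on all
#'   sites combined).
#' @param cfg an [analysis_config()].
#' @return tibble: one row per site x tertile with the estimate columns and
#'   the site's trend p value.
#' @export
build_fig1 <- function(statuses, children, tracts, cfg = NULL) {
  cfg <- default_cfg(cfg)
  if (!"tertile" %in% names(tracts)) tracts <- assign_tertiles(tracts)
  cases <- case_rows(statuses)
  cases$tertile <- child_ses_group(cases, tracts)
  tert_levels <- c("low", "medium", "high")
  sites <- sort(unique(tracts$site))
  row_for <- function(site_sel, label) {
    tr <- if (identical(site_sel, "all")) tracts else
      tracts[tracts$site %in% site_sel, , drop = FALSE]
    cc <- if (identical(site_sel, "all")) cases else
      cases[cases$site %in% site_sel, , drop = FALSE]
    num <- unname(vapply(tert_levels, function(t)
      sum(!is.na(cc$tertile) & cc$tertile == t), numeric(1)))
    den <- unname(vapply(tert_levels, function(t)
      sum(tr$est_age_8[tr$tertile == t]), numeric(1)))
    if (any(den <= 0)) return(NULL)
    est <- prevalence(num, den, cfg)
    trend <- cochran_armitage_trend(num, den)
    tibble::tibble(
      site = label, tertile = tert_levels,
      numerator = num, denominator = den,
      per_1000 = round_half_away(est$per_1000),
      estimate = render_estimate(est),
      suppressed = est$suppressed,
      trend_p = trend$p)
  }
  keep <- vapply(sites, function(s) sum(tracts$site == s) >= 3, logical(1))
  if (any(!keep)) {
    warn(sprintf("site(s) with fewer than 3 tracts skipped: %s",
                 paste(sites[!keep], collapse = ", ")))
  }
  out <- dplyr::bind_rows(c(lapply(sites[keep], function(s) row_for(s, s)),
                            list(row_for("all", "all"))))
  if (ncol(out) == 0) {
    out <- tibble::tibble(site = character(), tertile = character(),
                          numerator = numeric(), denominator = numeric(),
                          per_1000 = numeric(), estimate = character(),
                          suppressed = logical(), trend_p = numeric())
  }
  out
}

#' Euler-region counts of identification types
#'
#' @param statuses case-status tibble.
#' @return tibble of the seven region counts with the summary shares as
#'   attributes (`shares`).
#' @export
build_fig2 <- function(statuses) {
  regions <- identification_regions(case_rows(statuses))
  structure(regions$counts, shares = regions$shares)
}

#' Prevalence by identification type and site
#'
#' Per-site prevalence per 1,000 computed separately for each (overlapping)
#' identification type: diagnostic statement, special-education
#' eligibility, ICD code.
#'
#' @inheritParams build_table2
#' @return tibble, one row per site x identification type.
#' @export
build_fig3 <- function(statuses, denominators, cfg = NULL) {
  cfg <- default_cfg(cfg)
  cases <- case_rows(statuses)
  sites <- site_roster(statuses, denominators)
  types <- c(dx = "has_dx_statement", sped = "has_sped", icd = "has_icd")
  rows <- lapply(c(sites, list("all")), function(site_sel) {
    label <- if (identical(site_sel, "all")) "total" else site_sel
    cc <- if (identical(site_sel, "all")) cases else
      cases[cases$site %in% site_sel, , drop = FALSE]
    den <- denominator_for(denominators, site = site_sel)
    num <- unname(vapply(types, function(col) sum(cc[[col]]), numeric(1)))
    est <- prevalence(num, den, cfg)
    tibble::tibble(site = label, identification_type = names(types),
                   numerator = num, denominator = den,
                   per_1000 = round_half_away(est$per_1000),
                   estimate = render_estimate(est))
  })
  dplyr::bind_rows(rows)
}
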