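#' Configure one surveillance site for the synthetic-record generator
#'
#' A site bundles everything the generator needs to emulate one surveillance
#' catchment: population size and demographics, the latent case-generating
#' process (true prevalence, male:female rate ratio, identification-type
#' mixture), the record-generating process (source availability, per-record
#' accessibility, evaluation-age distributions), and the census-tract frame.
#'
#' Defaults reproduce the all-sites network profile of the 2018 surveillance
#' year: 51.1% male, the network race/ethnicity mix, true prevalence 23.0 per
#' 1,000 with a 4.2 male:female rate ratio, 87.1% of requested records fully
#' accessible, 6.4% of children without a geocodable tract, and an
#' identification mixture calibrated to the published network-wide Euler
#' shares of the three case-definition indicators.
#'
#' @param site_name site label (unique within a configuration).
#' @param n_children number of 8-year-old residents to simulate.
#' @param pct_male proportion male.
#' @param race_mix named proportions over
#'   `c("white-nh","black-nh","hispanic","api-nh","aian-nh","other-multiracial")`,
#'   summing to 1.
#' @param true_prevalence latent ASD prevalence (proportion, both sexes).
#' @param male_female_rate_ratio male:female prevalence rate ratio (> 0).
#' @param has_education_source whether education-source records are available
#'   to the site; when `FALSE`, special-education indicators are still
#'   generated but never observable downstream.
#' @param record_accessible_fraction probability that a requested record is
#'   fully accessible for chart review; inaccessible records transmit only
#'   ICD and special-education trigger codes.
#' @param tract_count number of census tracts in the catchment.
#' @param tract_mhi_range length-2 USD range from which tract median household
#'   incomes are drawn uniformly.
#' @param missing_tract_fraction proportion of children whose residence cannot
#'   be geocoded to a tract.
#' @param identification_mixture named weights over the seven non-empty
#'   combinations of the indicators (`"dx-only"`, ..., `"all-three"`),
#'   summing to 1; each true case is assigned one combination.
#' @param p_suspected_before_confirmed probability that a case has an earlier
#'   evaluation concluding suspected (not confirmed) ASD.
#' @param p_ruled_out_ever probability that a case ever has an evaluation
#'   ruling out ASD.
#' @param p_ruled_out_more_recent probability that a case's most recent
#'   ruled-out conclusion postdates every confirming diagnosis/eligibility
#'   (must not exceed `p_ruled_out_ever`).
#' @param iq_available_fraction probability a case has cognitive data.
#' @param iq_band_probs named probabilities over `c("<=70","71-85",">85")`.
#' @param dx_age_months_distribution list with `family = "lognormal"`,
#'   `meanlog` (named per IQ band) and `sdlog`; ages truncated to
#'   \[12, 107\] months.
#' @param first_eval_age_months_distribution list with `family = "lognormal"`,
#'   scalar `meanlog` and `sdlog`; same truncation.
#' @param false_trigger_rate probability that a non-case child's records carry
#'   a requested code that is not an ASD indicator (a lone Rett-syndrome
#'   F84.2 code).
#' @return a validated `asdsurv_site_config` list.
#' @seealso [generator_config()], [scenario_preset()]
#' @export
#' @examples
#' site_config("demo", n_children = 500)
site_config <- function(site_name,
                        n_children,
                        pct_male = 0.511,
                        race_mix = network_race_mix(),
                        true_prevalence = 0.023,
                        male_female_rate_ratio = 4.2,
                        has_education_source = TRUE,
                        record_accessible_fraction = 0.871,
                        tract_count = max(3L, as.integer(round(n_children / 60))),
                        tract_mhi_range = c(35000, 130000),
                        missing_tract_fraction = 0.064,
                        identification_mixture = network_identification_mixture(),
                        p_suspected_before_confirmed = 0.331,
                        p_ruled_out_ever = 0.109,
                        p_ruled_out_more_recent = 0.041,
                        iq_available_fraction = 0.595,
                        iq_band_probs = c("<=70" = 0.352, "71-85" = 0.231,
                                          ">85" = 0.417),
                        dx_age_months_distribution = list(
                          family = "lognormal",
                          meanlog = c("<=70" = log(44), "71-85" = log(53),
                                      ">85" = log(53)),
                          sdlog = 0.35),
                        first_eval_age_months_distribution = list(
                          family = "lognormal", meanlog = log(38),
                          sdlog = 0.40),
                        false_trigger_rate = 5e-4) {
  if (!is.character(site_name) || length(site_name) != 1L ||
      !nzchar(site_name)) {
    abort("`site_name` must be a non-empty string",
          class = "asdsurv_config_error")
  }
  n_children <- check_count(n_children, "n_children", min = 1)
  check_prob(pct_male, "pct_male")
  check_weights(race_mix, "race_mix", RACE_LEVELS)
  check_prob(true_prevalence, "true_prevalence")
  check_prob(male_female_rate_ratio, "male_female_rate_ratio",
             lo = 1e-9, hi = Inf)
  stopifnot(is.logical(has_education_source), length(has_education_source) == 1L)
  check_prob(record_accessible_fraction, "record_accessible_fraction")
  tract_count <- check_count(tract_count, "tract_count", min = 1)
  if (!is.numeric(tract_mhi_range) || length(tract_mhi_range) != 2L ||
      any(tract_mhi_range < 0) || diff(tract_mhi_range) < 0) {
    abort("`tract_mhi_range` must be a nondecreasing nonnegative USD interval",
          class = "asdsurv_config_error")
  }
  check_prob(missing_tract_fraction, "missing_tract_fraction")
  check_weights(identification_mixture, "identification_mixture", REGIONS)
  check_prob(p_suspected_before_confirmed, "p_suspected_before_confirmed")
  check_prob(p_ruled_out_ever, "p_ruled_out_ever")
  check_prob(p_ruled_out_more_recent, "p_ruled_out_more_recent")
  if (p_ruled_out_more_recent > p_ruled_out_ever + 1e-12) {
    abort("`p_ruled_out_more_recent` cannot exceed `p_ruled_out_ever`",
          class = "asdsurv_config_error")
  }
  check_prob(iq_available_fraction, "iq_available_fraction")
  check_weights(iq_band_probs, "iq_band_probs", IQ_BANDS)
  check_age_dist(dx_age_months_distribution, "dx_age_months_distribution",
                 per_band = TRUE)
  check_age_dist(first_eval_age_months_distribution,
                 "first_eval_age_months_distribution", per_band = FALSE)
  check_prob(false_trigger_rate, "false_trigger_rate")

  structure(
    list(site_name = site_name,
         n_children = n_children,
         pct_male = pct_male,
         race_mix = race_mix[RACE_LEVELS],
         true_prevalence = true_prevalence,
         male_female_rate_ratio = male_female_rate_ratio,
         has_education_source = has_education_source,
         record_accessible_fraction = record_accessible_fraction,
         tract_count = tract_count,
         tract_mhi_range = as.numeric(tract_mhi_range),
         missing_tract_fraction = missing_tract_fraction,
         identification_mixture = identification_mixture[REGIONS],
         p_suspected_before_confirmed = p_suspected_before_confirmed,
         p_ruled_out_ever = p_ruled_out_ever,
         p_ruled_out_more_recent = p_ruled_out_more_recent,
         iq_available_fraction = iq_available_fraction,
         iq_band_probs = iq_band_probs[IQ_BANDS],
         dx_age_months_distribution = dx_age_months_distribution,
         first_eval_age_months_distribution = first_eval_age_months_distribution,
         false_trigger_rate = false_trigger_rate),
    class = "asdsurv_site_config")
}

check_age_dist <- function(d, what, per_band) {
  ok <- is.list(d) && identical(d$family, "lognormal") &&
    is.numeric(d$meanlog) && is.numeric(d$sdlog) && all(d$sdlog > 0)
  if (ok && per_band) ok <- identical(sort(names(d$meanlog)), sort(IQ_BANDS))
  if (ok && !per_band) ok <- length(d$meanlog) == 1L
  if (!ok) {
    abort(sprintf("`%s` must be list(family='lognormal', meanlog, sdlog)%s",
                  what, if (per_band) " with meanlog named per IQ band" else ""),
          class = "asdsurv_config_error")
  }
  invisible(d)
}

#' Network-wide race/ethnicity mix
#'
#' The all-sites denominator race/ethnicity distribution (proportions), with
#' the small remainder assigned to other/multiracial.
#' @return named numeric vector over the six categories, summing to 1.
#' @export
network_race_mix <- function() {
  w <- c("white-nh" = 0.516, "black-nh" = 0.212, "hispanic" = 0.205,
         "api-nh" = 0.060, "aian-nh" = 0.006, "other-multiracial" = 0.001)
  w / sum(w)
}

#' Network-wide identification-type mixture
#'
#' Seven-region mixture over the indicator combinations calibrated to the
#' published network shares: 75.8% of cases with any diagnostic statement,
#' 18.8% with special-education eligibility and no diagnostic statement, 5.4%
#' with an ICD code only, 73.5% with at least two identification types, and
#' marginal shares 66.7% (ICD) and 61.7% (special education).  Those
#' constraints leave one free region (special education + ICD without a
#' diagnostic statement), fixed at 0.10.
#' @return named numeric vector over the seven regions, summing to 1.
#' @export
network_identification_mixture <- function() {
  w <- c("dx-only" = 0.1228, "sped-only" = 0.0880, "icd-only" = 0.0538,
         "dx+sped" = 0.1219, "dx+icd" = 0.2060, "sped+icd" = 0.1000,
         "all-three" = 0.3071)
  w / sum(w)
}

#' Fit an identification mixture to marginal indicator shares
#'
#' Given the per-case marginal probabilities of carrying each of the three
#' indicators (diagnostic statement, special-education eligibility, ICD
#' code), finds the unique mixture over the seven non-empty combinations that
#' arises from independent indicators conditioned on at least one being
#' present.  Used to build site presets from published marginal shares.
#'
#' @param p_dx,p_sped,p_icd marginal shares among cases, each in (0, 1\];
#'   their sum must exceed 1 (every case carries at least one indicator).
#' @return named numeric vector over the seven regions, summing to 1.
#' @export
#' @examples
#' mixture_from_marginals(0.758, 0.617, 0.667)
mixture_from_marginals <- function(p_dx, p_sped, p_icd) {
  p <- c(dx = p_dx, sped = p_sped, icd = p_icd)
  for (nm in names(p)) check_prob(p[[nm]], nm, lo = 1e-9, hi = 1)
  if (sum(p) <= 1) {
    abort("marginal shares must sum to more than 1",
          class = "asdsurv_config_error")
  }
  # u = P(union) for unconditional Bernoulli(q_i) with q_i = p_i * u
  f <- function(u) 1 - prod(1 - p * u) - u
  u <- uniroot(f, c(1e-9, 1 - 1e-12), tol = 1e-14)$root
  q <- pmin(p * u, 1)
  combos <- list("dx-only" = c(1, 0, 0), "sped-only" = c(0, 1, 0),
                 "icd-only" = c(0, 0, 1), "dx+sped" = c(1, 1, 0),
                 "dx+icd" = c(1, 0, 1), "sped+icd" = c(0, 1, 1),
                 "all-three" = c(1, 1, 1))
  w <- vapply(combos, function(s) prod(ifelse(s == 1, q, 1 - q)) / u,
              numeric(1))
  w / sum(w)
}

#' Assemble a generator configuration
#'
#' @param sites a list of [site_config()] objects with unique names (a single
#'   site may be passed unwrapped).
#' @param global_seed integer base seed recorded with the configuration;
#'   generation functions also accept an explicit seed.
#' @param analysis_year surveillance year (fixed design: 2018).
#' @param birth_year birth cohort (fixed design: 2010).
#' @return a validated `asdsurv_generator_config` list.
#' @export
#' @examples
#' generator_config(site_config("demo", 1000), global_seed = 1)
generator_config <- function(sites, global_seed = 1L,
                             analysis_year = 2018L, birth_year = 2010L) {
  if (inherits(sites, "asdsurv_site_config")) sites <- list(sites)
  if (!is.list(sites) || length(sites) == 0L ||
      !all(vapply(sites, inherits, logical(1), "asdsurv_site_config"))) {
    abort("`sites` must be a non-empty list of site_config objects",
          class = "asdsurv_config_error")
  }
  nms <- vapply(sites, `[[`, character(1), "site_name")
  if (anyDuplicated(nms)) {
    abort("site names must be unique", class = "asdsurv_config_error")
  }
  global_seed <- check_count(global_seed, "global_seed")
  structure(
    list(sites = setNames(sites, nms),
         global_seed = global_seed,
         analysis_year = as.integer(analysis_year),
         birth_year = as.integer(birth_year)),
    class = "asdsurv_generator_config")
}

#' @export
print.asdsurv_generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d site(s), surveillance year %d, birth year %d\n",
              length(x$sites), x$analysis_year, x$birth_year))
  for (s in x$sites) {
    cat(sprintf("  %-12s n=%7d  true prev %.1f/1000  education=%s  accessible=%.1f%%\n",
                s$site_name, s$n_children, 1000 * s$true_prevalence,
                ifelse(s$has_education_source, "yes", "no"),
                100 * s$record_accessible_fraction))
  }
  invisible(x)
}
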