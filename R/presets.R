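# Site presets approximating the 11 surveillance sites of the 2018 ADDM
# Network year: population, %male, race mix, source availability, record
# accessibility, identification marginals, suspected/ruled-out shares, IQ
# availability and bands, and median ages feeding the evaluation- and
# diagnosis-age distributions.  Values are the published site-level summary
# statistics; mixtures are derived from the marginals via
# mixture_from_marginals().
preset_table <- function() {
  tibble::tribble(
    ~key,         ~n,     ~pmale, ~white, ~black, ~hisp, ~api, ~aian,
    ~prev1000, ~mf,  ~educ, ~access, ~m_icd, ~m_sped, ~m_dx,
    ~p_susp, ~p_ro, ~p_ro_recent, ~iq_avail, ~iq_le70, ~iq_7185, ~iq_gt85,
    ~dxage_le70, ~dxage_gt70, ~evalage,
    "arizona",    13313L, 0.511, 42.7, 7.2, 42.9, 3.8, 3.4,
    24.9, 3.4, TRUE,  1.000, 0.293, 0.843, 0.686,
    0.378, 0.154, 0.048, 0.876, 31.4, 23.8, 44.8, 55,   60,   41,
    "arkansas",   15435L, 0.515, 63.6, 25.0, 9.5, 1.4, 0.4,
    22.9, 4.5, TRUE,  0.981, 0.677, 0.663, 0.856,
    0.487, 0.153, 0.045, 0.887, 39.9, 25.2, 34.8, 49,   56,   40,
    "california", 15076L, 0.509, 24.3, 9.5, 51.8, 14.0, 0.4,
    38.9, 5.2, TRUE,  0.998, 0.587, 0.882, 0.770,
    0.200, 0.247, 0.125, 0.775, 20.5, 25.6, 54.0, 35.5, 36,   35,
    "georgia",    23580L, 0.509, 25.9, 40.5, 24.5, 8.9, 0.2,
    21.8, 4.5, TRUE,  0.666, 0.416, 0.728, 0.625,
    0.492, 0.056, 0.021, 0.687, 38.5, 18.4, 43.1, 46.5, 60,   37,
    "maryland",   20666L, 0.507, 55.3, 25.8, 8.9, 9.8, 0.3,
    20.5, 4.4, TRUE,  0.314, 0.539, 0.726, 0.548,
    0.324, 0.118, 0.045, 0.333, 44.7, 17.7, 37.6, 36,   38.5, 30,
    "minnesota",  10081L, 0.512, 51.1, 24.7, 14.3, 8.3, 1.7,
    27.5, 4.2, TRUE,  0.999, 0.610, 0.823, 0.635,
    0.184, 0.108, 0.036, 0.812, 28.9, 19.1, 52.0, 57,   72,   39,
    "missouri",   24481L, 0.513, 65.6, 25.2, 5.1, 3.8, 0.2,
    16.5, 3.3, FALSE, 1.000, 0.946, 0.264, 0.916,
    0.341, 0.106, 0.025, 0.321, 26.2, 24.6, 49.2, 54,   74,   43,
    "new-jersey", 17289L, 0.515, 28.0, 32.3, 33.8, 5.6, 0.3,
    28.4, 4.5, TRUE,  0.997, 0.680, 0.699, 0.941,
    0.255, 0.014, 0.004, 0.642, 34.6, 27.3, 38.1, 45,   44,   39,
    "tennessee",  25237L, 0.512, 62.8, 19.6, 13.9, 3.3, 0.3,
    22.7, 4.1, TRUE,  0.854, 0.771, 0.548, 0.743,
    0.330, 0.084, 0.040, 0.628, 52.5, 19.2, 28.3, 34,   61.5, 43,
    "utah",       25459L, 0.513, 71.1, 2.5, 21.2, 4.5, 0.6,
    21.5, 3.6, TRUE,  0.677, 0.828, 0.422, 0.719,
    0.321, 0.042, 0.024, 0.378, 27.1, 31.9, 41.1, 47,   59,   42,
    "wisconsin",  29664L, 0.509, 57.5, 19.4, 17.4, 5.2, 0.5,
    18.8, 4.2, TRUE,  1.000, 0.842, 0.336, 0.846,
    0.341, 0.129, 0.025, 0.393, 44.7, 20.5, 34.7, 42,   52,   39
  )
}

#' Names of the available scenario presets
#'
#' The 11 site presets plus `"network"` (all 11 sites combined).
#' @return character vector of valid preset names.
#' @export
site_preset_names <- function() c(preset_table()$key, "network")

preset_site_config <- function(row) {
  race <- c("white-nh" = row$white, "black-nh" = row$black,
            "hispanic" = row$hisp, "api-nh" = row$api, "aian-nh" = row$aian)
  race <- race / 100
  other <- max(0, 1 - sum(race))
  race <- c(race, "other-multiracial" = other)
  race <- race / sum(race)
  bands <- c("<=70" = row$iq_le70, "71-85" = row$iq_7185, ">85" = row$iq_gt85)
  bands <- bands / sum(bands)
  site_config(
    site_name = row$key,
    n_children = row$n,
    pct_male = row$pmale,
    race_mix = race,
    true_prevalence = row$prev1000 / 1000,
    male_female_rate_ratio = row$mf,
    has_education_source = row$educ,
    record_accessible_fraction = row$access,
    identification_mixture = mixture_from_marginals(row$m_dx, row$m_sped,
                                                    row$m_icd),
    p_suspected_before_confirmed = row$p_susp,
    p_ruled_out_ever = row$p_ro,
    p_ruled_out_more_recent = row$p_ro_recent,
    iq_available_fraction = row$iq_avail,
    iq_band_probs = bands,
    dx_age_months_distribution = list(
      family = "lognormal",
      meanlog = c("<=70" = log(row$dxage_le70), "71-85" = log(row$dxage_gt70),
                  ">85" = log(row$dxage_gt70)),
      sdlog = 0.35),
    first_eval_age_months_distribution = list(
      family = "lognormal", meanlog = log(row$evalage), sdlog = 0.40)
  )
}

#' Build a generator configuration from a named scenario preset
#'
#' Presets approximate the published profile of each of the 11 surveillance
#' sites (population, demographics, source availability, record
#' accessibility, identification-type marginals, cognitive-data availability,
#' median evaluation/diagnosis ages); `"network"` bundles all 11.
#'
#' @param name one of [site_preset_names()].
#' @param global_seed base seed stored in the configuration.
#' @return an [generator_config()] object.
#' @export
#' @examples
#' scenario_preset("missouri")$sites$missouri$has_education_source
#' scenario_preset("maryland")$sites$maryland$record_accessible_fraction
scenario_preset <- function(name, global_seed = 1L) {
  tab <- preset_table()
  if (identical(name, "network")) {
    sites <- lapply(seq_len(nrow(tab)),
                    function(i) preset_site_config(tab[i, ]))
    return(generator_config(sites, global_seed = global_seed))
  }
  i <- match(name, tab$key)
  if (is.na(i)) {
    abort(sprintf("unknown preset '%s'; valid presets: %s", name,
                  paste(site_preset_names(), collapse = ", ")),
          class = "asdsurv_lookup_error")
  }
  generator_config(list(preset_site_config(tab[i, ])),
                   global_seed = global_seed)
}
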