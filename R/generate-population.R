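#' Generate a synthetic surveillance population
#'
#' Draws a child-level population for every configured site, together with
#' the matching demographic denominator table and a census-tract frame.
#' Children carry a latent true-case flag drawn from the site's true
#' prevalence with the configured male:female rate ratio; tract median
#' household incomes are uniform over the configured range and tract child
#' counts (ages 5--9) follow a symmetric multinomial, so the estimated
#' 8-year-old tract denominators sum to the site population.
#'
#' The same `(config, seed)` pair always reproduces the identical population.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (defaults to the configuration's `global_seed`).
#' @return a list with class `asdsurv_population`:
#'   \describe{
#'     \item{children}{tibble: `child_id`, `site`, `sex`, `race_ethnicity`,
#'       `resident_in_year`, `census_tract` (`NA` when not geocodable),
#'       `is_true_case`.}
#'     \item{denominators}{a [denominator_table()] built from the children.}
#'     \item{tracts}{tibble: `tract_id`, `site`, `mhi_usd`, `n_age_5_9`,
#'       `est_age_8`.}
#'   }
#' @export
#' @examples
#' pop <- generate_population(generator_config(site_config("demo", 500)), seed = 7)
#' nrow(pop$children)
generate_population <- function(config, seed = config$global_seed) {
  if (!inherits(config, "asdsurv_generator_config")) {
    abort("`config` must be a generator_config()",
          class = "asdsurv_config_error")
  }
  with_seed(seed, {
    kids <- vector("list", length(config$sites))
    trs <- vector("list", length(config$sites))
    for (i in seq_along(config$sites)) {
      s <- config$sites[[i]]
      n <- s$n_children

      # tract frame: uniform MHI, symmetric multinomial 5-9 counts
      tract_id <- sprintf("%s-t%04d", s$site_name, seq_len(s$tract_count))
      mhi <- runif(s$tract_count, s$tract_mhi_range[1], s$tract_mhi_range[2])
      n59 <- as.vector(stats::rmultinom(1, size = 5L * n,
                                        prob = rep(1, s$tract_count)))
      trs[[i]] <- tibble::tibble(tract_id = tract_id, site = s$site_name,
                                 mhi_usd = mhi, n_age_5_9 = n59,
                                 est_age_8 = n59 / 5)

      sex <- ifelse(runif(n) < s$pct_male, "male", "female")
      race <- sample(RACE_LEVELS, n, replace = TRUE, prob = s$race_mix)
      tract <- sample(tract_id, n, replace = TRUE,
                      prob = if (sum(n59) > 0) n59 else rep(1, s$tract_count))
      tract[runif(n) < s$missing_tract_fraction] <- NA_character_

      # sex-specific prevalence from overall prevalence and the rate ratio:
      # p = m*pm + (1-m)*pf with pm = r*pf
      m <- s$pct_male
      r <- s$male_female_rate_ratio
      pf <- s$true_prevalence / (1 - m + r * m)
      pm <- min(1, r * pf)
      p_case <- ifelse(sex == "male", pm, pf)
      is_case <- runif(n) < p_case

      kids[[i]] <- tibble::tibble(
        child_id = sprintf("%s-c%06d", s$site_name, seq_len(n)),
        site = s$site_name,
        sex = sex,
        race_ethnicity = race,
        resident_in_year = TRUE,
        census_tract = tract,
        is_true_case = is_case)
    }
    children <- dplyr::bind_rows(kids)
    structure(list(children = children,
                   denominators = denominator_table(children),
                   tracts = dplyr::bind_rows(trs)),
              class = "asdsurv_population")
  })
}

#' @export
print.asdsurv_population <- function(x, ...) {
  cat(sprintf("<population> %d children across %d site(s); %d true cases; %d tracts\n",
              nrow(x$children), length(unique(x$children$site)),
              sum(x$children$is_true_case), nrow(x$tracts)))
  invisible(x)
}
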