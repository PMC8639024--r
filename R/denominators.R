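#' Build a population denominator table
#'
#' Tabulates children by site, sex, and race/ethnicity.  Race-specific
#' denominators exclude children coded other/multiracial; site and network
#' totals retain them.
#'
#' @param children tibble with `site`, `sex`, `race_ethnicity` (one row per
#'   child), or a pre-tabulated tibble with those columns plus `n`.
#' @return an `asdsurv_denominator_table`: tibble of cells
#'   (`site`, `sex`, `race_ethnicity`, `n`) with site and network totals as
#'   attributes.
#' @export
denominator_table <- function(children) {
  stopifnot(all(c("site", "sex", "race_ethnicity") %in% names(children)))
  cells <- if ("n" %in% names(children)) {
    dplyr::summarise(dplyr::group_by(children, .data$site, .data$sex,
                                     .data$race_ethnicity),
                     n = sum(.data$n), .groups = "drop")
  } else {
    dplyr::count(children, .data$site, .data$sex, .data$race_ethnicity)
  }
  if (any(cells$n < 0)) {
    abort("denominator counts must be nonnegative",
          class = "asdsurv_validation_error")
  }
  site_totals <- dplyr::summarise(dplyr::group_by(cells, .data$site),
                                  n = sum(.data$n), .groups = "drop")
  structure(cells,
            site_totals = site_totals,
            network_total = sum(cells$n),
            class = c("asdsurv_denominator_table", class(cells)))
}

#' @rdname denominator_table
#' @param x a denominator table.
#' @export
site_totals <- function(x) attr(x, "site_totals")

#' @rdname denominator_table
#' @export
network_total <- function(x) attr(x, "network_total")

#' Denominator for a site/sex/race margin
#'
#' Sums the requested cells; race-specific requests exclude
#' other/multiracial by construction (the category is simply not selected),
#' and `race = "all"` excludes it explicitly only when `race_specific` is
#' `TRUE`.
#'
#' @param x a [denominator_table()].
#' @param site site name or `"all"`.
#' @param sex `"male"`, `"female"`, or `"all"`.
#' @param race a race/ethnicity category or `"all"`.
#' @return a single count.
#' @export
denominator_for <- function(x, site = "all", sex = "all", race = "all") {
  d <- x
  if (!identical(site, "all")) d <- d[d$site %in% site, , drop = FALSE]
  if (!identical(sex, "all")) d <- d[d$sex %in% sex, , drop = FALSE]
  if (!identical(race, "all")) {
    d <- d[d$race_ethnicity %in% race, , drop = FALSE]
  }
  sum(d$n)
}

#' Estimate a census tract's population of 8-year-olds
#'
#' Tract denominators are estimated as one fifth of the tract's count of
#' children aged 5--9 years; fractional values are preserved.
#'
#' @param n_age_5_9 nonnegative count(s) of children aged 5--9.
#' @return numeric, `n_age_5_9 / 5`.
#' @export
#' @examples
#' estimate_tract_denominator(55)
estimate_tract_denominator <- function(n_age_5_9) {
  if (any(!is.finite(n_age_5_9)) || any(n_age_5_9 < 0)) {
    abort("`n_age_5_9` must be nonnegative",
          class = "asdsurv_validation_error")
  }
  n_age_5_9 / 5
}

#' Assign all-sites median-household-income tertiles to census tracts
#'
#' Tracts from all sites combined are ordered by MHI (ties broken by tract
#' id) and split into three approximately equal-population groups weighted
#' by each tract's estimated 8-year-old population.  Whole tracts are never
#' split: a tract is `low` when its cumulative population upper bound is at
#' most one third of the total, `high` when its lower bound is at least two
#' thirds, and `medium` otherwise.
#'
#' @param tracts tibble with `tract_id`, `site`, `mhi_usd`, and either
#'   `est_age_8` or `n_age_5_9`.
#' @return the tracts with a `tertile` column (`low`/`medium`/`high`), in
#'   the original row order.
#' @export
assign_tertiles <- function(tracts) {
  stopifnot(is.data.frame(tracts))
  if (!"est_age_8" %in% names(tracts)) {
    tracts$est_age_8 <- estimate_tract_denominator(tracts$n_age_5_9)
  }
  if (nrow(tracts) < 3) {
    abort("at least 3 tracts are required for tertile assignment",
          class = "asdsurv_validation_error")
  }
  total <- sum(tracts$est_age_8)
  if (total <= 0) {
    abort("total estimated tract population must be positive",
          class = "asdsurv_validation_error")
  }
  ord <- order(tracts$mhi_usd, tracts$tract_id)
  pop <- tracts$est_age_8[ord]
  upper <- cumsum(pop)
  lower <- upper - pop
  tert <- ifelse(upper <= total / 3 + 1e-9, "low",
                 ifelse(lower >= 2 * total / 3 - 1e-9, "high", "medium"))
  tracts$tertile <- NA_character_
  tracts$tertile[ord] <- tert
  tracts
}

#' Socioeconomic group of children from their census tract
#'
#' @param children tibble with `child_id` and `census_tract` (`NA` when the
#'   residence could not be geocoded).
#' @param tracts tract table with tertiles assigned
#'   (see [assign_tertiles()]).
#' @return character vector of tertiles aligned with `children`; `NA` for
#'   children without a tract (excluded from SES-stratified analyses but
#'   retained in overall prevalence).
#' @export
child_ses_group <- function(children, tracts) {
  if (!"tertile" %in% names(tracts) || any(is.na(tracts$tertile))) {
    abort("tracts must have tertiles assigned",
          class = "asdsurv_validation_error")
  }
  idx <- match(children$census_tract, tracts$tract_id)
  dangling <- !is.na(children$census_tract) & is.na(idx)
  if (any(dangling)) {
    abort(sprintf("child tract id not in tract table: %s",
                  children$census_tract[dangling][1]),
          class = "asdsurv_data_error")
  }
  tracts$tertile[idx]
}
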