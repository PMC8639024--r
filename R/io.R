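#' Read and write generator configurations
#'
#' Configurations are stored as YAML (or JSON, by file extension) with one
#' entry per site carrying the [site_config()] fields; named probability
#' vectors are stored as mappings.
#'
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return for the reader, a [generator_config()].
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "asdsurv_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  sites <- lapply(raw$sites, function(s) {
    s$race_mix <- unlist(s$race_mix)
    s$identification_mixture <- unlist(s$identification_mixture)
    s$iq_band_probs <- unlist(s$iq_band_probs)
    s$tract_mhi_range <- unlist(s$tract_mhi_range)
    d <- s$dx_age_months_distribution
    d$meanlog <- unlist(d$meanlog)
    d$sdlog <- unlist(d$sdlog)
    s$dx_age_months_distribution <- d
    f <- s$first_eval_age_months_distribution
    f$meanlog <- unlist(f$meanlog)
    f$sdlog <- unlist(f$sdlog)
    s$first_eval_age_months_distribution <- f
    do.call(site_config, s)
  })
  generator_config(sites,
                   global_seed = raw$global_seed %||% 1L,
                   analysis_year = raw$analysis_year %||% 2018L,
                   birth_year = raw$birth_year %||% 2010L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_generator_config
#' @param config a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "asdsurv_generator_config"))
  as_plain <- function(s) {
    s <- unclass(s)
    s$race_mix <- as.list(s$race_mix)
    s$identification_mixture <- as.list(s$identification_mixture)
    s$iq_band_probs <- as.list(s$iq_band_probs)
    d <- s$dx_age_months_distribution
    d$meanlog <- as.list(d$meanlog)
    s$dx_age_months_distribution <- d
    s
  }
  payload <- list(global_seed = config$global_seed,
                  analysis_year = config$analysis_year,
                  birth_year = config$birth_year,
                  sites = lapply(unname(config$sites), as_plain))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path, precision = 15)
  }
  invisible(path)
}

#' Write and read a record set as CSV tables
#'
#' One CSV per table (`records`, `icd`, `sped`, `evaluations`,
#' `cognitive`), each with a header row; ids are stable strings.
#'
#' @param rs an [record_set()].
#' @param dir output directory (created if needed).
#' @return for the reader, an [record_set()].
#' @export
write_record_set <- function(rs, dir) {
  stopifnot(inherits(rs, "asdsurv_record_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("records", "icd", "sped", "evaluations", "cognitive")) {
    readr::write_csv(rs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_record_set
#' @export
read_record_set <- function(dir) {
  read1 <- function(nm, template) {
    path <- file.path(dir, paste0(nm, ".csv"))
    spec <- do.call(readr::cols,
                    lapply(template, function(col) {
                      if (is.logical(col)) readr::col_logical()
                      else if (is.integer(col)) readr::col_integer()
                      else readr::col_character()
                    }))
    readr::read_csv(path, col_types = spec, progress = FALSE)
  }
  record_set(records = read1("records", empty_records()),
             icd = read1("icd", empty_icd()),
             sped = read1("sped", empty_sped()),
             evaluations = read1("evaluations", empty_evaluations()),
             cognitive = read1("cognitive", empty_cognitive()))
}

#' Write a record set as nested JSON, one object per child
#'
#' @param rs an [record_set()].
#' @param path output `.json` path.
#' @export
write_records_json <- function(rs, path) {
  stopifnot(inherits(rs, "asdsurv_record_set"))
  ids <- unique(rs$records$child_id)
  payload <- lapply(ids, function(cid) {
    recs <- child_records(rs, cid)
    list(child_id = cid,
         records = lapply(recs, function(r) {
           list(site = r$site,
                source_type = r$source_type, accessible = r$accessible,
                icd_codes = r$icd_codes[-1],
                sped = r$sped[-1],
                evaluations = r$evaluations[-1],
                cognitive = r$cognitive[-1])
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, null = "null")
  invisible(path)
}
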