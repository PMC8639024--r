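# Builders for hand-crafted source records and small record sets, plus
# independent oracles used across test files.

sr <- function(child_id, source_type = "health", accessible = TRUE,
               site = "s1", icd = NULL, sped = NULL, evaluations = NULL,
               cognitive = NULL) {
  list(child_id = child_id, site = site, source_type = source_type,
       accessible = accessible,
       icd_codes = icd %||% tibble::tibble(code = character(),
                                           age_months = integer()),
       sped = sped %||% tibble::tibble(classification = character(),
                                       age_months = integer()),
       evaluations = evaluations %||% tibble::tibble(
         age_months = integer(), conclusion = character(),
         by_qualified_professional = logical(),
         reported_prior_dx_age_months = integer()),
       cognitive = cognitive %||% tibble::tibble(
         age_months = integer(), kind = character(), iq_score = integer(),
         stated_band = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

icd_tbl <- function(codes, ages = 60L) {
  tibble::tibble(code = codes, age_months = as.integer(rep(ages,
                                                           length.out = length(codes))))
}

eval_tbl <- function(ages, conclusions, qualified = TRUE, reported = NA) {
  tibble::tibble(age_months = as.integer(ages), conclusion = conclusions,
                 by_qualified_professional = rep(qualified,
                                                 length.out = length(ages)),
                 reported_prior_dx_age_months =
                   as.integer(rep(reported, length.out = length(ages))))
}

sped_tbl <- function(classification = "autism-primary", age = 60L) {
  tibble::tibble(classification = classification,
                 age_months = as.integer(age))
}

cog_tbl <- function(ages, kinds, scores = NA, bands = NA) {
  tibble::tibble(age_months = as.integer(ages), kind = kinds,
                 iq_score = as.integer(rep(scores, length.out = length(ages))),
                 stated_band = as.character(rep(bands,
                                                length.out = length(ages))))
}

# Assemble a record_set (and matching children table) from source records.
rs_from <- function(records) {
  recs <- tibble::tibble(
    record_id = sprintf("r%03d", seq_along(records)),
    child_id = vapply(records, `[[`, character(1), "child_id"),
    site = vapply(records, `[[`, character(1), "site"),
    source_type = vapply(records, `[[`, character(1), "source_type"),
    accessible = vapply(records, `[[`, logical(1), "accessible"))
  bind_content <- function(field) {
    parts <- lapply(seq_along(records), function(i) {
      d <- records[[i]][[field]]
      if (nrow(d)) cbind(record_id = recs$record_id[i], d) else NULL
    })
    out <- do.call(rbind, parts)
    if (is.null(out)) NULL else tibble::as_tibble(out)
  }
  args <- list(records = recs)
  map <- c(icd_codes = "icd", sped = "sped", evaluations = "evaluations",
           cognitive = "cognitive")
  for (f in names(map)) {
    d <- bind_content(f)
    if (!is.null(d)) args[[map[[f]]]] <- d
  }
  do.call(record_set, args)
}

children_for <- function(rs, extra_ids = character()) {
  ids <- unique(c(rs$records$child_id, extra_ids))
  tibble::tibble(child_id = ids, site = "s1",
                 sex = rep_len(c("male", "female"), length(ids)),
                 race_ethnicity = "white-nh", resident_in_year = TRUE,
                 census_tract = NA_character_, is_true_case = TRUE)
}

# Independent brute-force case evaluation: loops over every record and
# entry, deliberately avoiding the package's merge path.
brute_force_case <- function(records, resident = TRUE, birth_year = 2010) {
  has_icd <- FALSE; has_sped <- FALSE; has_dx <- FALSE
  for (r in records) {
    for (code in r$icd_codes$code) {
      code <- toupper(trimws(code))
      if (grepl("^F84", code)) {
        rest <- sub("^F84\\.?", "", code)
        if (!startsWith(rest, "2")) has_icd <- TRUE
      } else if (grepl("^299(\\.|$)", code)) {
        v <- suppressWarnings(as.numeric(code))
        if (!is.na(v) && v >= 299 && v < 300) has_icd <- TRUE
      }
    }
    for (cl in r$sped$classification) {
      if (cl %in% c("autism-primary", "autism-eligibility-met")) {
        has_sped <- TRUE
      }
    }
    if (isTRUE(r$accessible)) {
      ev <- r$evaluations
      for (i in seq_len(nrow(ev))) {
        if (ev$conclusion[i] == "asd-diagnosis" &&
            isTRUE(ev$by_qualified_professional[i])) has_dx <- TRUE
        if (!is.na(ev$reported_prior_dx_age_months[i])) has_dx <- TRUE
      }
    }
  }
  resident && birth_year == 2010 && (has_icd || has_sped || has_dx)
}

# Score-test inversion of the Wilson interval by root finding: the bounds
# are the p0 where the score statistic equals +/- z.
wilson_oracle <- function(x, n, z = 1.959964) {
  phat <- x / n
  glow <- function(p0) (phat - p0) - z * sqrt(p0 * (1 - p0) / n)
  ghigh <- function(p0) (phat - p0) + z * sqrt(p0 * (1 - p0) / n)
  span <- c(1e-14, 1 - 1e-14)
  lo <- if (x == 0) 0 else uniroot(glow, span, tol = 1e-14)$root
  hi <- if (x == n) 1 else uniroot(ghigh, span, tol = 1e-14)$root
  c(lo, hi) * 1000
}

# Cumulative whole-tract tertile rule, reimplemented independently with an
# explicit loop.
tertile_oracle <- function(mhi, pop, ids = as.character(seq_along(mhi))) {
  ord <- order(mhi, ids)
  total <- sum(pop)
  out <- character(length(mhi))
  cum <- 0
  for (j in ord) {
    upper <- cum + pop[j]
    out[j] <- if (upper <= total / 3 + 1e-9) "low"
      else if (cum >= 2 * total / 3 - 1e-9) "high"
      else "medium"
    cum <- upper
  }
  out
}

quiet_records <- function(...) suppressWarnings(generate_records(...))
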