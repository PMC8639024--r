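#' Run the full surveillance pipeline
#'
#' Generates the synthetic population and records, ascertains cases,
#' assigns socioeconomic tertiles, builds the report tables and figure
#' data, and writes everything (plus a run manifest) to `outdir`.
#' Re-running with identical config and seed reproduces identical CSVs.
#'
#' @param config a [generator_config()], a preset name (see
#'   [site_preset_names()]), or a path to a YAML/JSON config file.
#' @param outdir output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed integer seed for all randomness.
#' @param figures also render the figure plots as PDFs (requires ggplot2).
#' @param cfg an [analysis_config()]; its permutation seed is derived from
#'   `seed` when omitted.
#' @return an `asdsurv_report_bundle` list: `population`, `records`,
#'   `statuses`, `tracts` (with tertiles), `table2` ... `table7`, `fig1`,
#'   `fig2`, `fig3`, `manifest` (invisible when writing).
#' @export
run_pipeline <- function(config, outdir = NULL, seed = 1L, figures = FALSE,
                         cfg = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) read_generator_config(config)
      else scenario_preset(config, global_seed = seed)
  }
  if (!inherits(config, "asdsurv_generator_config")) {
    abort("`config` must be a generator_config, preset name, or config path",
          class = "asdsurv_config_error")
  }
  if (is.null(cfg)) {
    cfg <- analysis_config(permutation_seed = derive_seed(seed, 101))
  }

  pop <- generate_population(config, seed = seed)
  rs <- generate_records(pop$children, config, seed = derive_seed(seed, 1))
  statuses <- ascertain_cases(pop$children, rs,
                              birth_year = config$birth_year,
                              cohort_birth_year = 2010L)
  tracts <- assign_tertiles(pop$tracts)

  bundle <- list(
    population = pop, records = rs, statuses = statuses, tracts = tracts,
    table2 = build_table2(statuses, pop$denominators, cfg),
    table3 = build_table3(statuses, pop$denominators, cfg),
    table4 = build_table4(statuses),
    table5 = build_table5(statuses),
    table6 = build_table6(statuses),
    table7 = build_table7(statuses, pop$denominators, cfg),
    fig1 = build_fig1(statuses, pop$children, tracts, cfg),
    fig2 = build_fig2(statuses),
    fig3 = build_fig3(statuses, pop$denominators, cfg),
    manifest = list(
      package = "asdsurv",
      version = as.character(utils::packageVersion("asdsurv")),
      seed = as.integer(seed),
      config_hash = hash(unclass_config(config)),
      analysis_year = config$analysis_year,
      birth_year = config$birth_year,
      sites = names(config$sites),
      n_children = nrow(pop$children),
      n_cases = sum(statuses$is_case)))
  class(bundle) <- "asdsurv_report_bundle"

  if (!is.null(outdir)) write_report_bundle(bundle, outdir, figures = figures)
  invisible(bundle)
}

unclass_config <- function(config) {
  rapply(unclass(config), unclass, how = "replace")
}

#' @export
print.asdsurv_report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d children, %d cases, %d site(s)\n",
              x$manifest$n_children, x$manifest$n_cases,
              length(x$manifest$sites)))
  total <- x$table2[x$table2$site == "total", ]
  if (nrow(total)) {
    cat(sprintf("  overall prevalence: %s per 1,000; M:F ratio %s\n",
                total$overall, total$mf_ratio))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Tables and figure data as UTF-8 CSV (suppressed cells as an em dash),
#' population/tract/status tables as CSV, records as CSV tables, and a
#' JSON run manifest.
#'
#' @param bundle an `asdsurv_report_bundle` from [run_pipeline()].
#' @param outdir output directory.
#' @param figures also render figure PDFs (requires ggplot2).
#' @export
write_report_bundle <- function(bundle, outdir, figures = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    readr::write_csv(tibble::as_tibble(x), file.path(outdir, name),
                     progress = FALSE)
  }
  wcsv(bundle$population$children, "children.csv")
  wcsv(bundle$population$denominators, "denominators.csv")
  wcsv(bundle$tracts, "tracts.csv")
  wcsv(bundle$statuses, "case_statuses.csv")
  write_record_set(bundle$records, file.path(outdir, "records"))
  for (nm in c(paste0("table", 2:7), paste0("fig", 1:3))) {
    wcsv(bundle[[nm]], paste0(nm, ".csv"))
  }
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (figures && requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggsave(file.path(outdir, "fig1.pdf"), plot_fig1(bundle$fig1),
                    width = 8, height = 6)
    ggplot2::ggsave(file.path(outdir, "fig3.pdf"), plot_fig3(bundle$fig3),
                    width = 8, height = 6)
  }
  invisible(outdir)
}

#' Figure: prevalence by socioeconomic tertile and site
#'
#' @param fig1 the `fig1` tibble from [run_pipeline()]/[build_fig1()].
#' @return a ggplot object.
#' @export
plot_fig1 <- function(fig1) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting", class = "asdsurv_io_error")
  }
  fig1$tertile <- factor(fig1$tertile, levels = c("low", "medium", "high"))
  ggplot2::ggplot(fig1, ggplot2::aes(x = .data$per_1000, y = .data$tertile)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = "ASD prevalence per 1,000 children aged 8 years",
                  y = "Median household income tertile") +
    ggplot2::theme_minimal()
}

#' Figure: prevalence by identification type and site
#'
#' @param fig3 the `fig3` tibble from [run_pipeline()]/[build_fig3()].
#' @return a ggplot object.
#' @export
plot_fig3 <- function(fig3) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting", class = "asdsurv_io_error")
  }
  ggplot2::ggplot(fig3, ggplot2::aes(x = .data$per_1000, y = .data$site,
                                     shape = .data$identification_type)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ASD prevalence per 1,000 children aged 8 years",
                  y = NULL, shape = "Identification type") +
    ggplot2::theme_minimal()
}
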