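#' Run the full costing pipeline
#'
#' Executes the whole chain on a CSV input bundle: facility costing of every
#' sampled facility, level summaries, the three network extrapolations,
#' normative costing with the sample-derived overhead rates, the gap report,
#' and the sensitivity tables. When `out_dir` is given, writes the report set
#' as CSV files plus a run manifest (`manifest.json`) with input digests.
#'
#' @param data_dir directory with `facilities.csv`, `staff.csv`, `items.csv`,
#'   `outputs.csv`, `regions.csv`, `utilization.csv`, `stp.csv`,
#'   `consumables.csv`, `labor.csv`.
#' @param config a [phc_config()].
#' @param out_dir optional output directory for the CSV report bundle.
#' @return a list of class `phc_run`: `costings`, `summary`, `estimates`
#'   (A1/A2/B), `capture`, `normative`, `gap`, `sensitivity`.
#' @export
run_all <- function(data_dir, config = phc_config(), out_dir = NULL) {
  survey <- read_facility_survey(data_dir)
  regions <- read_region_tables(file.path(data_dir, "regions.csv"),
                                file.path(data_dir, "utilization.csv"))
  stp <- read_stp_tables(file.path(data_dir, "stp.csv"),
                         file.path(data_dir, "consumables.csv"),
                         file.path(data_dir, "labor.csv"))
  run_pipeline(survey, regions, stp, config, out_dir = out_dir,
               data_dir = data_dir)
}

#' @rdname run_all
#' @param survey,regions,stp in-memory inputs (`phc_survey`, `phc_regions`,
#'   `phc_stp`), for running without a file bundle.
#' @param data_dir used only to digest the inputs into the manifest.
#' @export
run_pipeline <- function(survey, regions, stp, config = phc_config(),
                         out_dir = NULL, data_dir = NULL) {
  records <- facility_records(survey)
  costings <- lapply(records, facility_costing, config = config)
  summary <- level_summary(costings)

  norms <- config$catchment_norms
  pc_a1 <- per_capita_A(costings, "norm_midpoint", norms)
  pc_a2 <- per_capita_A(costings, "reported")
  est_a1 <- estimate_A(pc_a1, costings, regions, "A1")
  est_a2 <- estimate_A(pc_a2, costings, regions, "A2")
  weights <- department_weights(costings)
  est_b <- estimate_B(costings, regions, weights)
  capture <- sample_capture(costings, regions, weights)

  overhead <- overhead_rate(costings)
  normative <- normative_summary(stp, regions, overhead, config)

  estimates <- list(A1 = est_a1, A2 = est_a2, B = est_b)
  gap <- gap_report(estimates, normative, costings = costings)

  sens <- lapply(estimates, function(est) {
    one_way_table(cost_components(est), est$population,
                  config$sensitivity_actual) %>%
      mutate(series = est$estimator)
  })
  sens$normative <- one_way_table(cost_components(normative),
                                  normative$population,
                                  config$sensitivity_normative) %>%
    mutate(series = "normative")
  sensitivity <- bind_rows(sens) %>%
    select("series", dplyr::everything())

  run <- structure(
    list(costings = costings, summary = summary, estimates = estimates,
         capture = capture, overhead = overhead, normative = normative,
         gap = gap, sensitivity = sensitivity, config = config),
    class = "phc_run"
  )
  if (!is.null(out_dir)) write_reports(run, out_dir, data_dir = data_dir)
  run
}

estimate_table <- function(est) {
  est$totals %>%
    mutate(estimator = est$estimator,
           per_capita = .data$total / est$population) %>%
    select("estimator", "level", "clinical_labor", "drugs_supplies",
           "indirect", "total", "per_capita")
}

costing_table <- function(costings) {
  lapply(costings, function(cc) {
    tibble(
      id = cc$id, level = cc$level, region = cc$region,
      clinical_labor = cc$clinical_labor, drugs_supplies = cc$drugs_supplies,
      admin = cc$admin, other_indirect = cc$other_indirect,
      other_service = cc$other_service, total = cc$total,
      overall_unit_cost = cc$overall_unit_cost,
      productivity = cc$productivity
    )
  }) %>% bind_rows()
}

write_reports <- function(run, out_dir, data_dir = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(costing_table(run$costings),
                   file.path(out_dir, "facility_costing.csv"))
  readr::write_csv(run$summary, file.path(out_dir, "level_summary.csv"))
  unit <- lapply(run$costings, function(cc) {
    cc$unit_costs %>% mutate(id = cc$id, level = cc$level)
  }) %>% bind_rows()
  readr::write_csv(unit, file.path(out_dir, "unit_costs.csv"))
  est <- bind_rows(lapply(run$estimates, estimate_table))
  readr::write_csv(est, file.path(out_dir, "estimates.csv"))
  readr::write_csv(run$capture, file.path(out_dir, "sample_capture.csv"))
  norm <- run$normative$by_level
  readr::write_csv(norm, file.path(out_dir, "normative_summary.csv"))
  readr::write_csv(run$normative$services,
                   file.path(out_dir, "normative_by_service.csv"))
  readr::write_csv(run$gap, file.path(out_dir, "gap_report.csv"))
  readr::write_csv(run$sensitivity, file.path(out_dir, "sensitivity.csv"))
  jsonlite::write_json(
    list(estimates = est, normative = norm, gap = run$gap),
    file.path(out_dir, "reports.json"),
    dataframe = "rows", digits = NA
  )
  manifest <- list(
    timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("phccost")),
    input_digests = if (!is.null(data_dir)) {
      files <- sort(list.files(data_dir, pattern = "\\.csv$",
                               full.names = TRUE))
      as.list(setNames(unname(tools::md5sum(files)), basename(files)))
    } else {
      NULL
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(out_dir)
}

#' Published network cost reference, nine Ethiopian regions 2018/19
#'
#' Network-level actual cost totals (three extrapolation estimators) and
#' normative cost totals, in US$ millions by facility level and cost
#' component, for the nine-region Ethiopian PHC network in 2018/19, together
#' with the pooled population base. These published figures serve as
#' desk-scale inputs for per-capita, gap, and sensitivity computations.
#'
#' @return list with `costs` (tibble `series`, `level`, `clinical_labor`,
#'   `drugs_supplies`, `indirect`, `total`) and `population` (persons).
#' @export
reference_network_costs <- function() {
  costs <- readr::read_csv(
    system.file("extdata", "network_costs_2019.csv", package = "phccost",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE, comment = "#"
  )
  pop <- readr::read_csv(
    system.file("extdata", "network_population_2019.csv", package = "phccost",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE, comment = "#"
  )
  list(costs = costs, population = pop$population_million[1] * 1e6)
}
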