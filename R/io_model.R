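#' Facility survey container
#'
#' A facility survey is relational: one row per facility plus per-facility
#' staff rosters, expenditure line items, and service-output counts. The four
#' tables are carried together, validated as a unit, and tagged with the
#' currency all monetary columns are expressed in.
#'
#' Time-use fractions (`frac_*` columns on the staff table) cover the five
#' clinical departments plus other-service, administration, and unspecified
#' activity, and must sum to 1 for clinical staff at health centers and
#' primary hospitals. Health-post staff may omit them entirely: their costs
#' are not distributed across departments, and their indirect costs are held
#' at the associated health center.
#'
#' @param facilities tibble: `id`, `level`, `region`, `area_class`,
#'   `reported_catchment` (persons, may be `NA`).
#' @param staff tibble: `facility_id`, `cadre`, `is_clinical`,
#'   `annual_remuneration_etb`, and `frac_opd`, `frac_hiv`, `frac_mch`,
#'   `frac_del`, `frac_ipdor`, `frac_other_service`, `frac_admin`,
#'   `frac_unspecified`.
#' @param items tibble: `facility_id`, `category` (drug / medical_supply /
#'   operational), `description`, `annual_cost_etb`, `funding_source`
#'   (treasury / internal_revenue / donor), `department_tag` (clinical
#'   department or `NA`).
#' @param outputs tibble: `facility_id`, `department`, `patients`.
#' @param currency currency of all monetary columns (default `"ETB"`).
#' @return an object of class `phc_survey`.
#' @export
facility_survey <- function(facilities, staff, items, outputs,
                            currency = "ETB") {
  survey <- structure(
    list(
      facilities = as_tibble(facilities),
      staff = as_tibble(staff),
      items = as_tibble(items),
      outputs = as_tibble(outputs),
      currency = currency
    ),
    class = "phc_survey"
  )
  validate_survey(survey)
  survey
}

FRAC_COLS <- c(
  OPD = "frac_opd", HIV = "frac_hiv", MCH = "frac_mch", DEL = "frac_del",
  IPDOR = "frac_ipdor", OTHER_SERVICE = "frac_other_service",
  ADMIN = "frac_admin", UNSPECIFIED = "frac_unspecified"
)

fail_row <- function(file, row, field, msg) {
  abort(sprintf("%s, row %d, field `%s`: %s", file, row, field, msg))
}

require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  file, paste(missing, collapse = ", ")))
  }
}

validate_survey <- function(survey, tol = 1e-9) {
  fac <- survey$facilities
  require_cols(fac, c("id", "level", "region", "area_class",
                      "reported_catchment"), "facilities")
  if (anyDuplicated(fac$id)) abort("facilities: duplicate facility id.")
  for (i in seq_len(nrow(fac))) {
    if (!fac$level[i] %in% PHC_LEVELS) {
      fail_row("facilities", i, "level",
               paste0("must be one of ", paste(PHC_LEVELS, collapse = ", ")))
    }
    if (!fac$area_class[i] %in% AREA_CLASSES) {
      fail_row("facilities", i, "area_class",
               paste0("must be one of ", paste(AREA_CLASSES, collapse = ", ")))
    }
    rc <- fac$reported_catchment[i]
    if (!is.na(rc) && rc <= 0) {
      fail_row("facilities", i, "reported_catchment", "must be positive")
    }
  }

  stf <- survey$staff
  require_cols(stf, c("facility_id", "cadre", "is_clinical",
                      "annual_remuneration_etb", unname(FRAC_COLS)), "staff")
  level_of <- setNames(fac$level, fac$id)
  for (i in seq_len(nrow(stf))) {
    if (!stf$facility_id[i] %in% fac$id) {
      fail_row("staff", i, "facility_id", "unknown facility id")
    }
    if (is.na(stf$annual_remuneration_etb[i]) ||
        stf$annual_remuneration_etb[i] < 0) {
      fail_row("staff", i, "annual_remuneration_etb", "must be non-negative")
    }
    fr <- as.numeric(stf[i, unname(FRAC_COLS)])
    lvl <- level_of[[stf$facility_id[i]]]
    if (isTRUE(stf$is_clinical[i])) {
      if (all(is.na(fr))) {
        if (lvl != "health_post") {
          fail_row("staff", i, "frac_*",
                   "clinical staff at this level require time-use fractions")
        }
      } else {
        fr[is.na(fr)] <- 0
        if (any(fr < 0)) fail_row("staff", i, "frac_*", "fractions must be >= 0")
        if (abs(sum(fr) - 1) > tol) {
          fail_row("staff", i, "frac_*",
                   sprintf("time fractions sum to %.6g, expected 1", sum(fr)))
        }
      }
    } else {
      fr[is.na(fr)] <- 0
      if (any(fr != 0)) {
        fail_row("staff", i, "frac_*",
                 "non-clinical staff must not carry time fractions")
      }
    }
  }

  itm <- survey$items
  require_cols(itm, c("facility_id", "category", "description",
                      "annual_cost_etb", "funding_source", "department_tag"),
               "items")
  for (i in seq_len(nrow(itm))) {
    if (!itm$facility_id[i] %in% fac$id) {
      fail_row("items", i, "facility_id", "unknown facility id")
    }
    if (!itm$category[i] %in% ITEM_CATEGORIES) {
      fail_row("items", i, "category",
               paste0("must be one of ", paste(ITEM_CATEGORIES, collapse = ", ")))
    }
    if (is.na(itm$annual_cost_etb[i]) || itm$annual_cost_etb[i] < 0) {
      fail_row("items", i, "annual_cost_etb", "must be non-negative")
    }
    if (!itm$funding_source[i] %in% FUNDING_SOURCES) {
      fail_row("items", i, "funding_source",
               paste0("must be one of ", paste(FUNDING_SOURCES, collapse = ", ")))
    }
    tag <- itm$department_tag[i]
    if (!is.na(tag)) {
      if (!tag %in% CLINICAL_DEPARTMENTS) {
        fail_row("items", i, "department_tag",
                 "must be a clinical department or empty")
      }
      if (itm$category[i] == "operational") {
        fail_row("items", i, "department_tag",
                 "operational items cannot carry a clinical department tag")
      }
    }
  }

  out <- survey$outputs
  require_cols(out, c("facility_id", "department", "patients"), "outputs")
  for (i in seq_len(nrow(out))) {
    if (!out$facility_id[i] %in% fac$id) {
      fail_row("outputs", i, "facility_id", "unknown facility id")
    }
    if (!out$department[i] %in% CLINICAL_DEPARTMENTS) {
      fail_row("outputs", i, "department", "must be a clinical department")
    }
    p <- out$patients[i]
    if (is.na(p) || p < 0 || abs(p - round(p)) > 1e-9) {
      fail_row("outputs", i, "patients", "must be a non-negative integer")
    }
  }
  invisible(survey)
}

#' Read and write a facility survey
#'
#' `read_facility_survey()` reads `facilities.csv`, `staff.csv`, `items.csv`,
#' and `outputs.csv` from a directory and returns a validated [facility_survey()].
#' `write_facility_survey()` writes the same four files; a read of what was
#' written reproduces the survey field-for-field.
#'
#' @param dir directory containing (or to receive) the four CSV files.
#' @param survey a `phc_survey` object.
#' @return a `phc_survey` (reader); the input, invisibly (writer).
#' @export
read_facility_survey <- function(dir) {
  paths <- file.path(dir, c("facilities.csv", "staff.csv", "items.csv",
                            "outputs.csv"))
  for (p in paths) if (!file.exists(p)) abort(paste0("Missing input file: ", p))
  read1 <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                       progress = FALSE)
  facility_survey(
    facilities = read1(paths[1]),
    staff = read1(paths[2]),
    items = read1(paths[3]),
    outputs = read1(paths[4])
  )
}

#' @rdname read_facility_survey
#' @export
write_facility_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "phc_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(survey$facilities, file.path(dir, "facilities.csv"))
  readr::write_csv(survey$staff, file.path(dir, "staff.csv"))
  readr::write_csv(survey$items, file.path(dir, "items.csv"))
  readr::write_csv(survey$outputs, file.path(dir, "outputs.csv"))
  invisible(survey)
}

#' Extract single-facility records
#'
#' `facility_records()` splits a survey into a list of per-facility records,
#' the unit on which the actual-costing stage operates. Each record carries
#' the facility metadata, its staff roster, its line items, and a complete
#' named vector of service outputs over the five clinical departments
#' (departments without a row count as zero).
#'
#' @param survey a `phc_survey`.
#' @param id a facility id (for `facility_record()`).
#' @return a named list of `facility_record` objects, or a single one.
#' @export
facility_records <- function(survey) {
  stopifnot(inherits(survey, "phc_survey"))
  recs <- lapply(survey$facilities$id, function(id) facility_record(survey, id))
  names(recs) <- survey$facilities$id
  recs
}

#' @rdname facility_records
#' @export
facility_record <- function(survey, id) {
  stopifnot(inherits(survey, "phc_survey"))
  row <- survey$facilities[survey$facilities$id == id, ]
  if (nrow(row) != 1) abort(paste0("Unknown facility id: ", id))
  out <- setNames(numeric(length(CLINICAL_DEPARTMENTS)), CLINICAL_DEPARTMENTS)
  orows <- survey$outputs[survey$outputs$facility_id == id, ]
  if (nrow(orows) > 0) {
    agg <- tapply(orows$patients, orows$department, sum)
    out[names(agg)] <- agg
  }
  structure(
    list(
      id = id,
      level = row$level,
      region = row$region,
      area_class = row$area_class,
      reported_catchment = row$reported_catchment,
      staff = survey$staff[survey$staff$facility_id == id, ],
      items = survey$items[survey$items$facility_id == id, ],
      outputs = out,
      currency = survey$currency
    ),
    class = "facility_record"
  )
}

#' Read regional population and utilization tables
#'
#' Regions arrive as two CSVs: `regions.csv` (`region`, `population`) and
#' `utilization.csv` (`region`, `level`, `department`, `services`) holding
#' DHIS2-style region-wide service counts per facility level and clinical
#' department.
#'
#' @param regions_path,utilization_path CSV paths.
#' @return an object of class `phc_regions`: a list with tibbles `regions`
#'   and `utilization`.
#' @export
read_region_tables <- function(regions_path, utilization_path) {
  for (p in c(regions_path, utilization_path)) {
    if (!file.exists(p)) abort(paste0("Missing input file: ", p))
  }
  regions <- readr::read_csv(regions_path, show_col_types = FALSE,
                             progress = FALSE)
  util <- readr::read_csv(utilization_path, show_col_types = FALSE,
                          progress = FALSE)
  region_tables(regions, util)
}

#' @rdname read_region_tables
#' @param regions,utilization in-memory tibbles with the same columns.
#' @export
region_tables <- function(regions, utilization) {
  regions <- as_tibble(regions)
  utilization <- as_tibble(utilization)
  require_cols(regions, c("region", "population"), "regions")
  require_cols(utilization, c("region", "level", "department", "services"),
               "utilization")
  for (i in seq_len(nrow(regions))) {
    if (is.na(regions$population[i]) || regions$population[i] <= 0) {
      fail_row("regions", i, "population", "must be positive")
    }
  }
  for (i in seq_len(nrow(utilization))) {
    if (!utilization$region[i] %in% regions$region) {
      fail_row("utilization", i, "region", "unknown region")
    }
    if (!utilization$level[i] %in% PHC_LEVELS) {
      fail_row("utilization", i, "level", "unknown facility level")
    }
    if (!utilization$department[i] %in% CLINICAL_DEPARTMENTS) {
      fail_row("utilization", i, "department", "must be a clinical department")
    }
    if (is.na(utilization$services[i]) || utilization$services[i] < 0) {
      fail_row("utilization", i, "services", "must be non-negative")
    }
  }
  structure(list(regions = regions, utilization = utilization),
            class = "phc_regions")
}

#' Read standard treatment protocol (STP) tables
#'
#' A protocol bundle has three long-format CSVs: `stp.csv` (one row per
#' service: `service_id`, `level`, `department`, `target_pop_fraction`,
#' `rate`, `coverage_target`, `encounters`), `consumables.csv` (`service_id`,
#' `item`, `quantity`, `unit_price`), and `labor.csv` (`service_id`, `cadre`,
#' `minutes`, `wage_per_minute`). Prices and wages are in US$ unless
#' `currency` says otherwise.
#'
#' @param stp_path,consumables_path,labor_path CSV paths.
#' @return an object of class `phc_stp`.
#' @export
read_stp_tables <- function(stp_path, consumables_path, labor_path) {
  for (p in c(stp_path, consumables_path, labor_path)) {
    if (!file.exists(p)) abort(paste0("Missing input file: ", p))
  }
  stp_tables(
    services = readr::read_csv(stp_path, show_col_types = FALSE, progress = FALSE),
    consumables = readr::read_csv(consumables_path, show_col_types = FALSE,
                                  progress = FALSE),
    labor = readr::read_csv(labor_path, show_col_types = FALSE, progress = FALSE)
  )
}

#' @rdname read_stp_tables
#' @param services,consumables,labor in-memory tibbles with the same columns.
#' @param currency currency of prices and wages (default `"USD"`).
#' @export
stp_tables <- function(services, consumables, labor, currency = "USD") {
  services <- as_tibble(services)
  consumables <- as_tibble(consumables)
  labor <- as_tibble(labor)
  require_cols(services, c("service_id", "level", "department",
                           "target_pop_fraction", "rate", "coverage_target",
                           "encounters"), "stp")
  require_cols(consumables, c("service_id", "item", "quantity", "unit_price"),
               "consumables")
  require_cols(labor, c("service_id", "cadre", "minutes", "wage_per_minute"),
               "labor")
  if (anyDuplicated(services$service_id)) abort("stp: duplicate service_id.")
  for (i in seq_len(nrow(services))) {
    s <- services[i, ]
    if (!s$level %in% PHC_LEVELS) fail_row("stp", i, "level", "unknown level")
    if (!s$department %in% CLINICAL_DEPARTMENTS) {
      fail_row("stp", i, "department", "must be a clinical department")
    }
    for (f in c("target_pop_fraction", "rate", "encounters")) {
      if (is.na(s[[f]]) || s[[f]] < 0) fail_row("stp", i, f, "must be >= 0")
    }
    if (is.na(s$coverage_target) || s$coverage_target < 0 ||
        s$coverage_target > 1) {
      fail_row("stp", i, "coverage_target", "must lie in [0, 1]")
    }
    has_labor <- s$service_id %in% labor$service_id
    if (has_labor && s$encounters < 1) {
      fail_row("stp", i, "encounters",
               "must be >= 1 for services with labor minutes")
    }
  }
  for (i in seq_len(nrow(consumables))) {
    if (!consumables$service_id[i] %in% services$service_id) {
      fail_row("consumables", i, "service_id", "unknown service")
    }
    if (is.na(consumables$quantity[i]) || consumables$quantity[i] < 0) {
      fail_row("consumables", i, "quantity", "must be >= 0")
    }
    if (is.na(consumables$unit_price[i]) || consumables$unit_price[i] < 0) {
      fail_row("consumables", i, "unit_price", "must be >= 0")
    }
  }
  for (i in seq_len(nrow(labor))) {
    if (!labor$service_id[i] %in% services$service_id) {
      fail_row("labor", i, "service_id", "unknown service")
    }
    if (is.na(labor$minutes[i]) || labor$minutes[i] < 0) {
      fail_row("labor", i, "minutes", "must be >= 0")
    }
    if (is.na(labor$wage_per_minute[i]) || labor$wage_per_minute[i] < 0) {
      fail_row("labor", i, "wage_per_minute", "must be >= 0")
    }
  }
  structure(
    list(services = services, consumables = consumables, labor = labor,
         currency = currency),
    class = "phc_stp"
  )
}
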