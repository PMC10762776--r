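#' Pipeline configuration
#'
#' Assembles the run configuration: the exchange rate used to convert survey
#' amounts to US$, reference catchment-population norms per facility level,
#' the working-days divisor for staff-productivity metrics, the interpretation
#' of protocol labor minutes, and the sensitivity-analysis multipliers.
#'
#' Defaults: exchange rate 28.44 ETB per US$ (the 2018/19 rate); catchment
#' norm midpoints of 5,000 / 25,000 / 100,000 persons for health posts,
#' health centers, and primary hospitals — editable placeholders standing in
#' for the official reference norms, which are not shipped here; 365 working
#' days; protocol labor minutes read as per-encounter. Sensitivity defaults:
#' for actual costs, clinical labor varies by 10% and drugs, medical supplies,
#' and indirect costs by 20%; for normative costs, labor, drugs, and supplies
#' vary by 10% and indirect costs by 20%; population varies by 5% on both
#' sides.
#'
#' @param exchange_rate local currency units per US$ (> 0).
#' @param catchment_norms data frame with columns `level`, `min`, `max`
#'   (persons); the midpoint `(min + max) / 2` is the estimator-A1 divisor.
#' @param working_days_per_year divisor for services-per-clinical-staff-per-day.
#' @param stp_minutes_per `"encounter"` (labor minutes are per encounter,
#'   multiplied by encounters per episode) or `"episode"`.
#' @param sensitivity_actual,sensitivity_normative sensitivity specifications,
#'   see [sensitivity_spec()].
#' @return an object of class `phc_config`.
#' @export
phc_config <- function(exchange_rate = 28.44,
                       catchment_norms = default_catchment_norms(),
                       working_days_per_year = 365,
                       stp_minutes_per = c("encounter", "episode"),
                       sensitivity_actual = sensitivity_spec(
                         clinical_labor = 0.10, drugs = 0.20,
                         medical_supplies = 0.20, indirect = 0.20,
                         population = 0.05
                       ),
                       sensitivity_normative = sensitivity_spec(
                         clinical_labor = 0.10, drugs = 0.10,
                         medical_supplies = 0.10, indirect = 0.20,
                         population = 0.05
                       )) {
  stp_minutes_per <- match.arg(stp_minutes_per)
  if (!is.numeric(exchange_rate) || exchange_rate <= 0) {
    abort("`exchange_rate` must be positive.")
  }
  norms <- as_tibble(catchment_norms)
  required <- c("level", "min", "max")
  if (!all(required %in% names(norms))) {
    abort("`catchment_norms` needs columns level, min, max.")
  }
  if (!all(norms$level %in% PHC_LEVELS)) {
    abort("`catchment_norms$level` must be one of the facility levels.")
  }
  if (any(norms$min <= 0) || any(norms$max < norms$min)) {
    abort("Catchment norms require 0 < min <= max.")
  }
  norms$midpoint <- (norms$min + norms$max) / 2
  if (!is.numeric(working_days_per_year) || working_days_per_year <= 0) {
    abort("`working_days_per_year` must be positive.")
  }
  structure(
    list(
      exchange_rate = exchange_rate,
      catchment_norms = norms,
      working_days_per_year = working_days_per_year,
      stp_minutes_per = stp_minutes_per,
      sensitivity_actual = sensitivity_actual,
      sensitivity_normative = sensitivity_normative
    ),
    class = "phc_config"
  )
}

default_catchment_norms <- function() {
  tibble(
    level = PHC_LEVELS,
    min = c(2500, 15000, 60000),
    max = c(7500, 35000, 140000)
  )
}

#' Sensitivity-analysis specification
#'
#' One-way and scenario sensitivity adjustments: each multiplier is a relative
#' adjustment applied symmetrically (`+m` and `-m`) to its cost component, and
#' `population` is the relative adjustment to the population denominator.
#'
#' @param clinical_labor,drugs,medical_supplies,indirect relative adjustments
#'   in `(-1, Inf)`, e.g. `0.10` for plus/minus 10%.
#' @param population relative population adjustment.
#' @return an object of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(clinical_labor = 0.10, drugs = 0.20,
                             medical_supplies = 0.20, indirect = 0.20,
                             population = 0.05) {
  vals <- c(
    clinical_labor = clinical_labor, drugs = drugs,
    medical_supplies = medical_supplies, indirect = indirect,
    population = population
  )
  if (any(!is.finite(vals)) || any(vals <= -1)) {
    abort("Sensitivity adjustments must be finite and greater than -1.")
  }
  structure(
    list(
      multipliers = vals[setdiff(names(vals), "population")],
      population_adjustment = unname(vals[["population"]])
    ),
    class = "sensitivity_spec"
  )
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over the defaults of
#' [phc_config()]. Unknown top-level keys trigger a warning; missing keys take
#' their defaults.
#'
#' @param path path to a YAML/JSON config file.
#' @return a `phc_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(
    "exchange_rate", "catchment_norms", "working_days_per_year",
    "stp_minutes_per", "sensitivity"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  args <- list()
  for (key in c("exchange_rate", "working_days_per_year", "stp_minutes_per")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$catchment_norms)) {
    cn <- raw$catchment_norms
    args$catchment_norms <- tibble(
      level = names(cn),
      min = vapply(cn, function(x) as.numeric(x$min), numeric(1)),
      max = vapply(cn, function(x) as.numeric(x$max), numeric(1))
    )
  }
  if (!is.null(raw$sensitivity)) {
    for (side in c("actual", "normative")) {
      blk <- raw$sensitivity[[side]]
      if (!is.null(blk)) {
        args[[paste0("sensitivity_", side)]] <- do.call(sensitivity_spec, blk)
      }
    }
  }
  do.call(phc_config, args)
}
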