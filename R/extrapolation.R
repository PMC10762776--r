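#' Per-capita cost of sampled facilities from catchment populations
#'
#' For each sampled facility, annual total cost is divided by a catchment
#' population: the midpoint of the reference catchment norm for its level
#' (`"norm_midpoint"`, estimator A1) or the facility-reported catchment
#' (`"reported"`, estimator A2). The level figure is the simple, unweighted
#' mean over facilities. Facilities lacking a reported catchment are dropped
#' from A2 with a warning.
#'
#' @param costings list of `facility_costing` objects.
#' @param source `"norm_midpoint"` or `"reported"`.
#' @param norms catchment norms tibble (from a [phc_config()]), with
#'   `level` and `midpoint` columns; required for `"norm_midpoint"`.
#' @return tibble `level`, `per_capita`, `n`; facility-wise values in
#'   attribute `"facility"`.
#' @export
per_capita_A <- function(costings, source = c("norm_midpoint", "reported"),
                         norms = NULL) {
  source <- match.arg(source)
  rows <- lapply(costings, function(cc) {
    catchment <- if (source == "norm_midpoint") {
      if (is.null(norms)) abort("Catchment norms required for norm_midpoint.")
      norms$midpoint[match(cc$level, norms$level)]
    } else {
      cc$reported_catchment
    }
    tibble(id = cc$id, level = cc$level, catchment = as.numeric(catchment),
           total = cc$total)
  }) %>% bind_rows()
  if (source == "reported" && any(is.na(rows$catchment))) {
    dropped <- rows$id[is.na(rows$catchment)]
    warn(paste0("Facilities without reported catchment excluded from A2: ",
                paste(dropped, collapse = ", ")))
    rows <- rows[!is.na(rows$catchment), ]
  }
  rows$per_capita <- rows$total / rows$catchment
  out <- rows %>%
    group_by(.data$level) %>%
    summarise(per_capita = mean(.data$per_capita), n = dplyr::n(),
              .groups = "drop")
  attr(out, "facility") <- rows
  out
}

# Sample-wide component shares per level (used to split a per-capita scalar
# into clinical labor / drugs & supplies / indirect).
level_component_shares <- function(costings) {
  lapply(costings, function(cc) {
    tibble(level = cc$level, clinical_labor = cc$clinical_labor,
           drugs_supplies = cc$drugs_supplies, indirect = cc$indirect,
           total = cc$total)
  }) %>%
    bind_rows() %>%
    group_by(.data$level) %>%
    summarise(across(c("clinical_labor", "drugs_supplies", "indirect",
                       "total"), sum), .groups = "drop") %>%
    mutate(
      clinical_labor = ifelse(.data$total > 0, .data$clinical_labor / .data$total, 0),
      drugs_supplies = ifelse(.data$total > 0, .data$drugs_supplies / .data$total, 0),
      indirect = ifelse(.data$total > 0, .data$indirect / .data$total, 0)
    ) %>%
    select(-"total")
}

new_estimate <- function(estimator, totals, population, meta = list()) {
  totals <- totals %>% arrange(match(.data$level, PHC_LEVELS))
  per_capita <- totals %>%
    mutate(per_capita = .data$total / population) %>%
    select("level", "per_capita")
  structure(
    list(
      estimator = estimator,
      totals = totals,
      population = population,
      per_capita = per_capita,
      per_capita_overall = sum(totals$total) / population,
      meta = meta
    ),
    class = "phc_estimate"
  )
}

#' @export
print.phc_estimate <- function(x, ...) {
  cat(sprintf("<phc_estimate %s>  population %.1f M, per-capita US$ %.2f\n",
              x$estimator, x$population / 1e6, x$per_capita_overall))
  print(x$totals)
  invisible(x)
}

#' Catchment-based network estimates (A1, A2)
#'
#' Multiplies level-wise mean per-capita costs by the total population of the
#' regions in scope to obtain network totals per level; components are split
#' in proportion to the sample's component shares at that level.
#'
#' @param pc level per-capita tibble from [per_capita_A()].
#' @param costings list of `facility_costing` (for component shares).
#' @param regions a `phc_regions` object.
#' @param estimator label, `"A1"` or `"A2"`.
#' @return a `phc_estimate`.
#' @export
estimate_A <- function(pc, costings, regions, estimator = "A1") {
  population <- sum(regions$regions$population)
  shares <- level_component_shares(costings)
  totals <- pc %>%
    left_join(shares, by = "level") %>%
    mutate(
      total = .data$per_capita * population,
      clinical_labor = .data$total * .data$clinical_labor,
      drugs_supplies = .data$total * .data$drugs_supplies,
      indirect = .data$total * .data$indirect
    ) %>%
    select("level", "clinical_labor", "drugs_supplies", "indirect", "total")
  new_estimate(estimator, totals, population)
}

#' Department weights from sample unit costs
#'
#' Weights for comparing utilization across departments: a department's
#' weight at a level is the mean of its unit cost over sampled facilities of
#' that level where the unit cost is defined. Health posts, which have no
#' department unit costs, get a single uniform weight equal to the mean
#' overall unit cost, so their weighted utilization reduces to total services
#' times that weight. A display-normalized column (`weight_rel`, OPD = 1) is
#' included; the utilization-expansion estimator is invariant to weight
#' rescaling.
#'
#' @param costings list of `facility_costing`.
#' @return tibble `level`, `department`, `weight`, `weight_rel`.
#' @export
department_weights <- function(costings) {
  rows <- lapply(costings, function(cc) {
    if (cc$level == "health_post") {
      tibble(level = cc$level, department = CLINICAL_DEPARTMENTS,
             unit_cost = cc$overall_unit_cost)
    } else {
      tibble(level = cc$level, department = cc$unit_costs$department,
             unit_cost = cc$unit_costs$unit_cost)
    }
  }) %>% bind_rows()
  w <- rows %>%
    filter(!is.na(.data$unit_cost)) %>%
    group_by(.data$level, .data$department) %>%
    summarise(weight = mean(.data$unit_cost), .groups = "drop")
  absent <- tidyr::expand_grid(level = unique(w$level),
                               department = CLINICAL_DEPARTMENTS) %>%
    anti_join(w, by = c("level", "department"))
  if (nrow(absent) > 0) {
    warn(paste0(
      "Departments without sample unit costs (their utilization is excluded): ",
      paste(paste(absent$level, absent$department, sep = "/"), collapse = ", ")
    ))
  }
  opd <- w %>% filter(.data$department == "OPD") %>%
    select("level", opd_w = "weight")
  w %>%
    left_join(opd, by = "level") %>%
    mutate(weight_rel = .data$weight / .data$opd_w) %>%
    select(-"opd_w")
}

# Sampled utilization per region x level x department, from facility outputs.
sample_utilization <- function(costings) {
  lapply(costings, function(cc) {
    tibble(region = cc$region, level = cc$level,
           department = CLINICAL_DEPARTMENTS,
           services = as.numeric(cc$outputs[CLINICAL_DEPARTMENTS]))
  }) %>%
    bind_rows() %>%
    group_by(.data$region, .data$level, .data$department) %>%
    summarise(services = sum(.data$services), .groups = "drop")
}

weighted_sum <- function(util, weights) {
  util %>%
    dplyr::inner_join(weights, by = c("level", "department")) %>%
    group_by(.data$region, .data$level) %>%
    summarise(weighted = sum(.data$services * .data$weight), .groups = "drop")
}

#' Utilization expansion factors
#'
#' For each region and facility level, the expansion factor is the ratio of
#' total weighted region-wide utilization to total weighted utilization in
#' the sampled facilities of that region and level. Region-level combinations
#' with regional utilization but no sampled facility borrow the level's
#' pooled factor (total weighted regional over total weighted sample
#' utilization across sampled regions), with a warning.
#'
#' @param regions a `phc_regions` object.
#' @param costings list of `facility_costing` (supplies sampled utilization
#'   and region assignments).
#' @param weights department weights from [department_weights()].
#' @return tibble `region`, `level`, `factor`, `weighted_region`,
#'   `weighted_sample`, `borrowed`.
#' @export
expansion_factors <- function(regions, costings, weights) {
  samp <- weighted_sum(sample_utilization(costings), weights)
  reg <- weighted_sum(regions$utilization, weights)
  joined <- reg %>%
    rename(weighted_region = "weighted") %>%
    left_join(samp %>% rename(weighted_sample = "weighted"),
              by = c("region", "level"))
  pooled <- joined %>%
    filter(!is.na(.data$weighted_sample) & .data$weighted_sample > 0) %>%
    group_by(.data$level) %>%
    summarise(pooled_factor = sum(.data$weighted_region) /
                sum(.data$weighted_sample), .groups = "drop")
  out <- joined %>%
    left_join(pooled, by = "level") %>%
    mutate(
      borrowed = is.na(.data$weighted_sample) | .data$weighted_sample <= 0,
      factor = ifelse(.data$borrowed, .data$pooled_factor,
                      .data$weighted_region / .data$weighted_sample)
    ) %>%
    select("region", "level", "factor", "weighted_region", "weighted_sample",
           "borrowed")
  if (any(out$borrowed)) {
    b <- out[out$borrowed, ]
    warn(paste0(
      "No sampled facilities for: ",
      paste(paste(b$region, b$level, sep = "/"), collapse = ", "),
      "; borrowing the level's pooled expansion factor."
    ))
  }
  out
}

#' Utilization-weighted network estimate (B)
#'
#' Network cost per region and level is the sampled cost in that region and
#' level multiplied by its expansion factor; components scale by the same
#' factor. Regions with utilization but no sample at a level contribute their
#' weighted utilization times the level's pooled cost per weighted service
#' unit (equivalently, the borrowed pooled factor applied to a proportional
#' cost share). Per-capita is the grand total over the summed regional
#' population.
#'
#' @inheritParams expansion_factors
#' @param factors optionally precomputed [expansion_factors()].
#' @return a `phc_estimate` with per-region detail in `meta`.
#' @export
estimate_B <- function(costings, regions, weights = department_weights(costings),
                       factors = NULL) {
  if (is.null(factors)) {
    factors <- suppressWarnings(expansion_factors(regions, costings, weights))
  }
  samp_cost <- lapply(costings, function(cc) {
    tibble(region = cc$region, level = cc$level,
           clinical_labor = cc$clinical_labor,
           drugs_supplies = cc$drugs_supplies,
           indirect = cc$indirect, total = cc$total)
  }) %>%
    bind_rows() %>%
    group_by(.data$region, .data$level) %>%
    summarise(across(c("clinical_labor", "drugs_supplies", "indirect",
                       "total"), sum), .groups = "drop")

  sampled <- factors %>%
    filter(!.data$borrowed) %>%
    left_join(samp_cost, by = c("region", "level")) %>%
    mutate(across(c("clinical_labor", "drugs_supplies", "indirect", "total"),
                  ~ .x * .data$factor))

  # Pooled cost per weighted network service unit, and pooled component
  # shares, for region/level combinations with no sample.
  pooled <- sampled %>%
    group_by(.data$level) %>%
    summarise(
      cost_per_wu = sum(.data$total) / sum(.data$weighted_region),
      share_labor = sum(.data$clinical_labor) / sum(.data$total),
      share_ds = sum(.data$drugs_supplies) / sum(.data$total),
      share_ind = sum(.data$indirect) / sum(.data$total),
      .groups = "drop"
    )
  unsampled <- factors %>%
    filter(.data$borrowed) %>%
    left_join(pooled, by = "level") %>%
    mutate(
      total = .data$weighted_region * .data$cost_per_wu,
      clinical_labor = .data$total * .data$share_labor,
      drugs_supplies = .data$total * .data$share_ds,
      indirect = .data$total * .data$share_ind
    )

  by_region <- bind_rows(
    sampled %>% select("region", "level", "clinical_labor", "drugs_supplies",
                       "indirect", "total"),
    unsampled %>% select("region", "level", "clinical_labor", "drugs_supplies",
                         "indirect", "total")
  )
  totals <- by_region %>%
    group_by(.data$level) %>%
    summarise(across(c("clinical_labor", "drugs_supplies", "indirect",
                       "total"), sum), .groups = "drop")
  new_estimate("B", totals, sum(regions$regions$population),
               meta = list(factors = factors, by_region = by_region,
                           weights = weights))
}

#' Share of network services captured by the sample
#'
#' Per facility level, the ratio of total weighted sampled utilization to
#' total weighted region-wide utilization, reported as a percentage.
#'
#' @inheritParams expansion_factors
#' @return tibble `level`, `capture_pct`.
#' @export
sample_capture <- function(costings, regions, weights = department_weights(costings)) {
  samp <- weighted_sum(sample_utilization(costings), weights) %>%
    group_by(.data$level) %>%
    summarise(sample = sum(.data$weighted), .groups = "drop")
  reg <- weighted_sum(regions$utilization, weights) %>%
    group_by(.data$level) %>%
    summarise(network = sum(.data$weighted), .groups = "drop")
  samp %>%
    left_join(reg, by = "level") %>%
    mutate(capture_pct = 100 * .data$sample / .data$network) %>%
    select("level", "capture_pct")
}
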