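#' Population in need of a service
#'
#' Expected annual episodes: population times the fraction of the population
#' eligible for the service times the episode rate (incidence or prevalence,
#' episodes per eligible person-year).
#'
#' @param population persons.
#' @param target_pop_fraction fraction of the population eligible.
#' @param rate episodes per eligible person-year.
#' @return expected episodes per year (vectorized).
#' @export
population_in_need <- function(population, target_pop_fraction, rate) {
  stopifnot(all(population > 0), all(target_pop_fraction >= 0), all(rate >= 0))
  population * target_pop_fraction * rate
}

#' Direct cost of one service episode
#'
#' Consumables cost is the sum over protocol items of quantity per episode
#' times unit price. Labor cost is minutes per cadre times the cadre wage per
#' minute, summed over cadres and — under the default per-encounter reading —
#' multiplied by the number of encounters per episode (`minutes_per =
#' "episode"` skips that multiplier).
#'
#' @param stp a `phc_stp` bundle.
#' @param minutes_per `"encounter"` or `"episode"`.
#' @return tibble `service_id`, `labor`, `consumables`.
#' @export
episode_cost <- function(stp, minutes_per = c("encounter", "episode")) {
  stopifnot(inherits(stp, "phc_stp"))
  minutes_per <- match.arg(minutes_per)
  cons <- stp$consumables %>%
    group_by(.data$service_id) %>%
    summarise(consumables = sum(.data$quantity * .data$unit_price),
              .groups = "drop")
  lab <- stp$labor %>%
    group_by(.data$service_id) %>%
    summarise(labor_per_encounter = sum(.data$minutes * .data$wage_per_minute),
              .groups = "drop")
  stp$services %>%
    select("service_id", "encounters") %>%
    left_join(cons, by = "service_id") %>%
    left_join(lab, by = "service_id") %>%
    mutate(
      consumables = ifelse(is.na(.data$consumables), 0, .data$consumables),
      labor_per_encounter = ifelse(is.na(.data$labor_per_encounter), 0,
                                   .data$labor_per_encounter),
      labor = if (minutes_per == "encounter") {
        .data$encounters * .data$labor_per_encounter
      } else {
        .data$labor_per_encounter
      }
    ) %>%
    select("service_id", "labor", "consumables")
}

#' Annual normative cost per service
#'
#' For each protocol service: population in need over the pooled regional
#' population, times the coverage target, times the direct episode cost,
#' attributed to the service's facility level and department.
#'
#' @param stp a `phc_stp` bundle.
#' @param regions a `phc_regions` object (populations are pooled).
#' @param minutes_per passed to [episode_cost()].
#' @return tibble with per-service episodes, covered episodes, and annual
#'   labor, consumables, and total direct cost.
#' @export
service_total <- function(stp, regions, minutes_per = "encounter") {
  population <- sum(regions$regions$population)
  ec <- episode_cost(stp, minutes_per = minutes_per)
  stp$services %>%
    left_join(ec, by = "service_id") %>%
    mutate(
      episodes = population_in_need(population, .data$target_pop_fraction,
                                    .data$rate),
      covered_episodes = .data$episodes * .data$coverage_target,
      labor_cost = .data$covered_episodes * .data$labor,
      consumables_cost = .data$covered_episodes * .data$consumables,
      direct_cost = .data$labor_cost + .data$consumables_cost
    ) %>%
    select("service_id", "level", "department", "episodes",
           "covered_episodes", "labor_cost", "consumables_cost", "direct_cost")
}

#' Overhead rate of the actual sample
#'
#' Per facility level, indirect costs (administration plus other indirect)
#' divided by total costs, over all sampled facilities of that level. Health
#' posts are pinned to zero: their indirect costs are carried by the health
#' centers they are attached to.
#'
#' @param costings list of `facility_costing`.
#' @return tibble `level`, `rate`.
#' @export
overhead_rate <- function(costings) {
  rows <- lapply(costings, function(cc) {
    tibble(level = cc$level, indirect = cc$indirect, total = cc$total)
  }) %>%
    bind_rows() %>%
    group_by(.data$level) %>%
    summarise(rate = sum(.data$indirect) / sum(.data$total), .groups = "drop")
  rows$rate[rows$level == "health_post"] <- 0
  rows
}

#' Apply an overhead uplift to direct costs
#'
#' With the overhead rate defined as indirect over *total* cost, the uplift
#' consistent with that definition is `total = direct / (1 - r)`, which
#' guarantees `indirect / total = r` exactly (a `direct * (1 + r)` markup
#' would not).
#'
#' @param direct direct cost (vectorized).
#' @param r overhead rate(s) in `[0, 1)`.
#' @return tibble `direct`, `indirect`, `total`.
#' @export
apply_overhead <- function(direct, r) {
  stopifnot(all(direct >= 0))
  if (any(r < 0) || any(r >= 1)) {
    abort("Overhead rate must lie in [0, 1).")
  }
  total <- direct / (1 - r)
  tibble(direct = direct, indirect = total - direct, total = total)
}

#' Normative cost summary
#'
#' Aggregates per-service normative costs by facility level and department,
#' applies the level overhead uplift, and derives per-capita figures over the
#' pooled regional population. The department view allocates the level's
#' indirect cost in proportion to department direct cost.
#'
#' @param stp a `phc_stp` bundle.
#' @param regions a `phc_regions` object.
#' @param overhead tibble `level`, `rate` from [overhead_rate()] (or any
#'   rates in `[0, 1)`).
#' @param config a [phc_config()]; supplies the labor-minutes interpretation.
#' @return an object of class `phc_normative` with elements `by_level`,
#'   `by_department`, `population`, `per_capita_overall`, `services`.
#' @export
normative_summary <- function(stp, regions, overhead, config = phc_config()) {
  population <- sum(regions$regions$population)
  services <- service_total(stp, regions, minutes_per = config$stp_minutes_per)
  lvl <- services %>%
    group_by(.data$level) %>%
    summarise(clinical_labor = sum(.data$labor_cost),
              drugs_supplies = sum(.data$consumables_cost),
              direct = sum(.data$direct_cost), .groups = "drop") %>%
    left_join(overhead, by = "level")
  if (any(is.na(lvl$rate))) {
    abort(paste0("No overhead rate for level(s): ",
                 paste(lvl$level[is.na(lvl$rate)], collapse = ", ")))
  }
  up <- apply_overhead(lvl$direct, lvl$rate)
  by_level <- lvl %>%
    mutate(indirect = up$indirect, total = up$total,
           per_capita = .data$total / population) %>%
    select("level", "clinical_labor", "drugs_supplies", "indirect", "total",
           "per_capita") %>%
    arrange(match(.data$level, PHC_LEVELS))
  by_department <- services %>%
    group_by(.data$level, .data$department) %>%
    summarise(direct = sum(.data$direct_cost), .groups = "drop") %>%
    group_by(.data$level) %>%
    mutate(direct_share = .data$direct / sum(.data$direct)) %>%
    ungroup() %>%
    left_join(by_level %>% select("level", "indirect"), by = "level") %>%
    mutate(indirect = .data$indirect * .data$direct_share,
           total = .data$direct + .data$indirect,
           per_capita = .data$total / population) %>%
    select("level", "department", "direct", "indirect", "total", "per_capita")
  structure(
    list(
      by_level = by_level,
      by_department = by_department,
      population = population,
      per_capita_overall = sum(by_level$total) / population,
      services = services
    ),
    class = "phc_normative"
  )
}

#' @export
print.phc_normative <- function(x, ...) {
  cat(sprintf("<phc_normative>  population %.1f M, per-capita US$ %.2f\n",
              x$population / 1e6, x$per_capita_overall))
  print(x$by_level)
  invisible(x)
}
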