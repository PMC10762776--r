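#' Actual-versus-normative resource gap
#'
#' Per facility level and overall: absolute gap is normative minus actual
#' per-capita cost; percent gap is the absolute gap as a share of the
#' normative value, rounded half-up to an integer for display (computation
#' stays unrounded). Negative gaps — actual spending above the normative
#' requirement — are reported as negative and flagged as `excess`. A zero
#' normative value with nonzero actual leaves the percent gap undefined
#' (`NA`) and flagged.
#'
#' When `costings` is supplied, department-level rows are added for levels
#' with department data: actual department per-capita splits the level total
#' in proportion to the sample's department direct costs (with other-service
#' and indirect rows), and normative department rows carry direct cost only,
#' with indirect as its own row — matching how the two sides are reported.
#'
#' @param actual a `phc_estimate` or a list of them.
#' @param normative a `phc_normative`.
#' @param costings optional list of `facility_costing` to enable the
#'   department breakdown.
#' @return tibble with `estimator`, `level`, `department`, `actual_pc`,
#'   `normative_pc`, `gap_abs`, `gap_pct`, `gap_pct_display`, `excess`.
#' @export
gap_report <- function(actual, normative, costings = NULL) {
  stopifnot(inherits(normative, "phc_normative"))
  if (inherits(actual, "phc_estimate")) actual <- list(actual)
  rows <- lapply(actual, function(est) {
    if (abs(est$population - normative$population) >
        1e-6 * normative$population) {
      abort("Actual and normative estimates use different population bases.")
    }
    lvl <- est$per_capita %>%
      left_join(normative$by_level %>% select("level", normative_pc = "per_capita"),
                by = "level") %>%
      rename(actual_pc = "per_capita") %>%
      mutate(estimator = est$estimator, department = "ALL")
    tot <- tibble(
      estimator = est$estimator, level = "total", department = "ALL",
      actual_pc = est$per_capita_overall,
      normative_pc = normative$per_capita_overall
    )
    out <- bind_rows(lvl, tot)
    if (!is.null(costings)) {
      out <- bind_rows(department_gap_rows(est, normative, costings), out)
    }
    out
  })
  bind_rows(rows) %>%
    mutate(
      gap_abs = .data$normative_pc - .data$actual_pc,
      gap_pct = ifelse(.data$normative_pc > 0,
                       100 * .data$gap_abs / .data$normative_pc, NA_real_),
      gap_pct_display = round_half_up(.data$gap_pct),
      excess = !is.na(.data$gap_abs) & .data$gap_abs < 0,
      undefined = .data$normative_pc <= 0 & .data$actual_pc > 0
    ) %>%
    select("estimator", "level", "department", "actual_pc", "normative_pc",
           "gap_abs", "gap_pct", "gap_pct_display", "excess", "undefined")
}

department_gap_rows <- function(est, normative, costings) {
  shares <- lapply(costings, function(cc) {
    if (cc$level == "health_post") return(NULL)
    dept_direct <- cc$labor[CLINICAL_DEPARTMENTS] +
      cc$drugs[CLINICAL_DEPARTMENTS]
    tibble(
      level = cc$level,
      department = c(CLINICAL_DEPARTMENTS, "OTHER_SERVICE", "INDIRECT"),
      cost = c(as.numeric(dept_direct), cc$other_service, cc$indirect),
      total = cc$total
    )
  }) %>%
    bind_rows()
  if (nrow(shares) == 0) return(tibble())
  shares <- shares %>%
    group_by(.data$level, .data$department) %>%
    summarise(cost = sum(.data$cost), .groups = "drop") %>%
    group_by(.data$level) %>%
    mutate(share = .data$cost / sum(.data$cost)) %>%
    ungroup()
  lvl_tot <- est$totals %>% select("level", "total")
  norm_dept <- normative$by_department %>%
    mutate(normative_pc = .data$direct / normative$population) %>%
    select("level", "department", "normative_pc")
  norm_ind <- normative$by_level %>%
    mutate(department = "INDIRECT",
           normative_pc = .data$indirect / normative$population) %>%
    select("level", "department", "normative_pc")
  shares %>%
    left_join(lvl_tot, by = "level") %>%
    mutate(actual_pc = .data$share * .data$total / est$population,
           estimator = est$estimator) %>%
    left_join(bind_rows(norm_dept, norm_ind), by = c("level", "department")) %>%
    mutate(normative_pc = ifelse(is.na(.data$normative_pc), 0,
                                 .data$normative_pc)) %>%
    select("estimator", "level", "department", "actual_pc", "normative_pc")
}

# Resolve signed component adjustments against the supplied components,
# merging the drug and medical-supply adjustments when the input carries them
# as one combined component.
adjusted_components <- function(components, adjustments) {
  if (any(adjustments <= -1)) abort("Adjustments must be greater than -1.")
  out <- components
  for (nm in names(adjustments)) {
    a <- adjustments[[nm]]
    if (nm %in% names(out)) {
      out[[nm]] <- out[[nm]] * (1 + a)
    } else if (nm %in% c("drugs", "medical_supplies") &&
               "drugs_supplies" %in% names(out)) {
      other <- setdiff(c("drugs", "medical_supplies"), nm)
      if (!other %in% names(adjustments) ||
          adjustments[[other]] != a) {
        abort(paste0(
          "Components carry drugs and medical supplies merged; their ",
          "adjustments must be supplied and equal to apply to the merged value."
        ))
      }
      if (nm == "drugs") {  # apply once for the pair
        out[["drugs_supplies"]] <- out[["drugs_supplies"]] * (1 + a)
      }
    } else if (!nm %in% c("drugs", "medical_supplies")) {
      abort(paste0("Adjustment for unknown component: ", nm))
    }
  }
  out
}

#' Evaluate one sensitivity scenario
#'
#' Applies signed relative adjustments to cost components and the population
#' denominator and returns the resulting per-capita cost. Components may be
#' named `clinical_labor`, `drugs`, `medical_supplies` (or merged
#' `drugs_supplies`), and `indirect`.
#'
#' @param components named non-negative numeric of cost components (absolute
#'   money, any fixed currency).
#' @param population persons (> 0).
#' @param adjustments named numeric of signed relative adjustments (e.g.
#'   `c(clinical_labor = 0.1)`); components not named are unadjusted.
#' @param population_adjustment signed relative population adjustment.
#' @param label scenario label.
#' @return one-row tibble: `scenario`, adjusted total, population,
#'   `per_capita`, `delta` versus the unadjusted baseline.
#' @export
scenario <- function(components, population, adjustments = numeric(0),
                     population_adjustment = 0, label = "scenario") {
  stopifnot(all(components >= 0), population > 0)
  if (population_adjustment <= -1) {
    abort("Population adjustment must be greater than -1.")
  }
  adj <- adjusted_components(components, adjustments)
  pop <- population * (1 + population_adjustment)
  baseline <- sum(components) / population
  pc <- sum(adj) / pop
  tibble(
    scenario = label,
    total = sum(adj),
    population = pop,
    per_capita = pc,
    delta = pc - baseline
  )
}

signed_spec <- function(spec, components, sign_cost, sign_pop) {
  mult <- spec$multipliers
  keep <- names(mult) %in% names(components) |
    (names(mult) %in% c("drugs", "medical_supplies") &
       "drugs_supplies" %in% names(components))
  list(adjustments = sign_cost * mult[keep],
       population_adjustment = sign_pop * spec$population_adjustment)
}

#' Best- and worst-case scenarios
#'
#' The worst case for a cost-gap reading raises every cost component by its
#' full adjustment while lowering the population denominator; the best case
#' is the mirror image.
#'
#' @inheritParams scenario
#' @param spec a [sensitivity_spec()].
#' @return two-row tibble (best, worst) in the shape of [scenario()].
#' @export
scenario_bounds <- function(components, population, spec) {
  stopifnot(inherits(spec, "sensitivity_spec"))
  worst <- signed_spec(spec, components, +1, -1)
  best <- signed_spec(spec, components, -1, +1)
  bind_rows(
    scenario(components, population, best$adjustments,
             best$population_adjustment, label = "best"),
    scenario(components, population, worst$adjustments,
             worst$population_adjustment, label = "worst")
  )
}

#' One-way sensitivity table
#'
#' One row per single-parameter adjustment in each direction, plus the
#' baseline and the best/worst scenarios, suitable for tornado-style
#' reporting.
#'
#' @inheritParams scenario_bounds
#' @return tibble of [scenario()] rows.
#' @export
one_way_table <- function(components, population, spec) {
  stopifnot(inherits(spec, "sensitivity_spec"))
  rows <- list(scenario(components, population, label = "baseline"))
  mult <- spec$multipliers
  merged <- "drugs_supplies" %in% names(components)
  done_merged <- FALSE
  for (nm in names(mult)) {
    applies <- nm %in% names(components) ||
      (nm %in% c("drugs", "medical_supplies") && merged)
    if (!applies) next
    if (nm %in% c("drugs", "medical_supplies") && merged) {
      if (done_merged) next
      done_merged <- TRUE
      adj_hi <- c(drugs = mult[[nm]], medical_supplies = mult[[nm]])
      adj_lo <- -adj_hi
      base_label <- "drugs_supplies"
    } else {
      adj_hi <- setNames(mult[[nm]], nm)
      adj_lo <- -adj_hi
      base_label <- nm
    }
    rows <- c(rows, list(
      scenario(components, population, adj_hi,
               label = sprintf("%s +%g%%", base_label, 100 * mult[[nm]])),
      scenario(components, population, adj_lo,
               label = sprintf("%s -%g%%", base_label, 100 * mult[[nm]]))
    ))
  }
  p <- spec$population_adjustment
  rows <- c(rows, list(
    scenario(components, population, population_adjustment = +p,
             label = sprintf("population +%g%%", 100 * p)),
    scenario(components, population, population_adjustment = -p,
             label = sprintf("population -%g%%", 100 * p))
  ))
  bind_rows(bind_rows(rows), scenario_bounds(components, population, spec))
}

#' Cost components of an estimate or normative result
#'
#' Extracts the merged component vector (`clinical_labor`, `drugs_supplies`,
#' `indirect`) summed over facility levels, ready for [scenario()] and
#' [one_way_table()].
#'
#' @param x a `phc_estimate` or `phc_normative`.
#' @return named numeric of components.
#' @export
cost_components <- function(x) {
  tab <- if (inherits(x, "phc_estimate")) {
    x$totals
  } else if (inherits(x, "phc_normative")) {
    x$by_level
  } else {
    abort("Expected a phc_estimate or phc_normative.")
  }
  c(
    clinical_labor = sum(tab$clinical_labor),
    drugs_supplies = sum(tab$drugs_supplies),
    indirect = sum(tab$indirect)
  )
}
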