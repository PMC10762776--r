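#' Allocate clinical labor cost by staff time use
#'
#' Splits each clinical staff member's annual remuneration across the five
#' clinical departments, other-service work, and administration in proportion
#' to their reported time-use fractions, then sums over staff. Time reported
#' as unspecified is pooled with administration: both end up in the indirect
#' administration bucket downstream.
#'
#' @param record a `facility_record`.
#' @param exchange_rate local currency units per US$ applied to remuneration
#'   (default 1, i.e. amounts returned in the record's own currency).
#' @return named numeric over `OPD, HIV, MCH, DEL, IPDOR, OTHER_SERVICE,
#'   ADMIN`.
#' @export
allocate_clinical_labor <- function(record, exchange_rate = 1) {
  stopifnot(inherits(record, "facility_record"))
  buckets <- c(CLINICAL_DEPARTMENTS, "OTHER_SERVICE", "ADMIN")
  alloc <- setNames(numeric(length(buckets)), buckets)
  clin <- record$staff[which(record$staff$is_clinical), ]
  for (i in seq_len(nrow(clin))) {
    fr <- as.numeric(clin[i, unname(FRAC_COLS)])
    names(fr) <- names(FRAC_COLS)
    if (all(is.na(fr))) {
      abort(sprintf(
        "Facility %s: clinical staff `%s` has no time-use fractions; %s",
        record$id, clin$cadre[i],
        "department allocation requires them (health posts are not allocated)."
      ))
    }
    fr[is.na(fr)] <- 0
    rem <- clin$annual_remuneration_etb[i] / exchange_rate
    split <- rem * fr
    split[["ADMIN"]] <- split[["ADMIN"]] + split[["UNSPECIFIED"]]
    alloc <- alloc + split[buckets]
  }
  alloc
}

#' Allocate drug and medical-supply costs to departments
#'
#' Items tagged with a department go wholly to that department; untagged
#' drugs and supplies are split across the five clinical departments in
#' proportion to each department's share of clinical labor cost (shares over
#' clinical departments only — administrative and other-service labor are not
#' an allocation basis).
#'
#' @param record a `facility_record`.
#' @param labor_by_dept allocation from [allocate_clinical_labor()] (same
#'   currency as requested here).
#' @param exchange_rate local currency units per US$ applied to item costs.
#' @return named numeric over the five clinical departments.
#' @export
allocate_drugs_supplies <- function(record, labor_by_dept, exchange_rate = 1) {
  stopifnot(inherits(record, "facility_record"))
  alloc <- setNames(numeric(length(CLINICAL_DEPARTMENTS)), CLINICAL_DEPARTMENTS)
  ds <- record$items[record$items$category %in% c("drug", "medical_supply"), ]
  if (nrow(ds) == 0) return(alloc)
  dept_labor <- labor_by_dept[CLINICAL_DEPARTMENTS]
  untagged_total <- 0
  for (i in seq_len(nrow(ds))) {
    cost <- ds$annual_cost_etb[i] / exchange_rate
    tag <- ds$department_tag[i]
    if (!is.na(tag)) {
      alloc[[tag]] <- alloc[[tag]] + cost
    } else {
      untagged_total <- untagged_total + cost
    }
  }
  if (untagged_total > 0) {
    basis <- sum(dept_labor)
    if (basis <= 0) {
      abort(sprintf(
        "Facility %s: untagged drug/supply items but no clinical labor cost in any department to allocate against.",
        record$id
      ))
    }
    alloc <- alloc + untagged_total * dept_labor / basis
  }
  alloc
}

#' Indirect costs of a facility
#'
#' Administration cost is non-clinical staff remuneration plus clinical labor
#' reported against administrative or unspecified activity; other indirect
#' cost is operational spending (utilities and similar) carrying no clinical
#' department tag.
#'
#' @inheritParams allocate_drugs_supplies
#' @return list with `admin` and `other_indirect`.
#' @export
compute_indirect <- function(record, labor_by_dept, exchange_rate = 1) {
  stopifnot(inherits(record, "facility_record"))
  nonclin <- record$staff[!record$staff$is_clinical, ]
  admin <- sum(nonclin$annual_remuneration_etb) / exchange_rate +
    labor_by_dept[["ADMIN"]]
  oper <- record$items[record$items$category == "operational" &
                         is.na(record$items$department_tag), ]
  other_indirect <- sum(oper$annual_cost_etb) / exchange_rate
  list(admin = unname(admin), other_indirect = other_indirect)
}

#' Activity-based costing of one facility
#'
#' Assembles the full cost picture of one facility in US$: clinical labor and
#' drug/supply costs by department, other-service labor, administration and
#' other indirect costs, component and funding-source shares, department and
#' overall unit costs, and staff productivity.
#'
#' Health posts are costed in totals only: their staff time use is not
#' collected, so no department allocation is attempted, and their indirect
#' costs are held at the associated health center (so `admin` and
#' `other_indirect` carry only what the health-post record itself contains,
#' typically nothing).
#'
#' Component conventions: `clinical_labor` is clinical remuneration spent on
#' the five departments plus other-service work; clinical time on
#' administration counts toward `indirect` together with non-clinical labor
#' and untagged operational spending.
#'
#' @param record a `facility_record` (monetary fields in local currency).
#' @param config a [phc_config()] supplying the exchange rate and working-days
#'   divisor.
#' @return an object of class `facility_costing`.
#' @export
facility_costing <- function(record, config = phc_config()) {
  stopifnot(inherits(record, "facility_record"))
  if (identical(record$currency, "USD")) {
    abort("Facility record is already in US$; expected local-currency input.")
  }
  rate <- config$exchange_rate
  is_hp <- record$level == "health_post"

  if (is_hp) {
    labor <- setNames(numeric(7), c(CLINICAL_DEPARTMENTS, "OTHER_SERVICE",
                                    "ADMIN"))
    clin <- record$staff[which(record$staff$is_clinical), ]
    clin_total <- sum(clin$annual_remuneration_etb) / rate
    drugs <- setNames(numeric(5), CLINICAL_DEPARTMENTS)
    ds <- record$items[record$items$category %in% c("drug", "medical_supply"), ]
    drugs_total <- sum(ds$annual_cost_etb) / rate
    nonclin <- record$staff[!record$staff$is_clinical, ]
    oper <- record$items[record$items$category == "operational", ]
    ind <- list(admin = sum(nonclin$annual_remuneration_etb) / rate,
                other_indirect = sum(oper$annual_cost_etb) / rate)
    clinical_labor <- clin_total
  } else {
    labor <- allocate_clinical_labor(record, exchange_rate = rate)
    drugs <- allocate_drugs_supplies(record, labor, exchange_rate = rate)
    drugs_total <- sum(drugs)
    ind <- compute_indirect(record, labor, exchange_rate = rate)
    clinical_labor <- sum(labor[CLINICAL_DEPARTMENTS]) + labor[["OTHER_SERVICE"]]
  }

  indirect <- ind$admin + ind$other_indirect
  total <- clinical_labor + drugs_total + indirect

  # Funding sources: labor is treasury-financed; items carry their own source.
  staff_total <- sum(record$staff$annual_remuneration_etb) / rate
  src_all <- setNames(numeric(3), FUNDING_SOURCES)
  src_all[["treasury"]] <- staff_total
  src_ds <- setNames(numeric(3), FUNDING_SOURCES)
  for (i in seq_len(nrow(record$items))) {
    cost <- record$items$annual_cost_etb[i] / rate
    src <- record$items$funding_source[i]
    src_all[[src]] <- src_all[[src]] + cost
    if (record$items$category[i] %in% c("drug", "medical_supply")) {
      src_ds[[src]] <- src_ds[[src]] + cost
    }
  }

  costing <- structure(
    list(
      id = record$id,
      level = record$level,
      region = record$region,
      currency = "USD",
      labor = labor,
      drugs = drugs,
      other_service = labor[["OTHER_SERVICE"]],
      admin = ind$admin,
      other_indirect = ind$other_indirect,
      clinical_labor = unname(clinical_labor),
      drugs_supplies = drugs_total,
      indirect = unname(indirect),
      total = unname(total),
      outputs = record$outputs,
      reported_catchment = record$reported_catchment,
      n_clinical_staff = sum(record$staff$is_clinical),
      funding_total = if (total > 0) src_all / total else src_all,
      funding_drugs = if (drugs_total > 0) src_ds / drugs_total else src_ds,
      component_shares = if (total > 0) {
        c(clinical_labor = unname(clinical_labor) / total,
          drugs_supplies = drugs_total / total,
          indirect = unname(indirect) / total)
      } else {
        c(clinical_labor = 0, drugs_supplies = 0, indirect = 0)
      }
    ),
    class = "facility_costing"
  )
  costing$unit_costs <- department_unit_costs(costing)
  costing$overall_unit_cost <-
    if (sum(record$outputs) > 0) total / sum(record$outputs) else NA_real_
  costing$productivity <- staff_productivity(record, config$working_days_per_year)
  costing
}

#' Department and overall unit costs
#'
#' A department's cost for unit-cost purposes is its clinical labor plus its
#' drugs and supplies plus a share of other indirect costs (utilities and the
#' like) allocated in proportion to department labor. Administration costs
#' and other-service staff costs are excluded from department unit costs but
#' included in the overall unit cost. Departments with zero patients but
#' nonzero cost are flagged and reported as undefined rather than infinite.
#'
#' @param costing a `facility_costing`.
#' @return tibble with `department`, `cost`, `patients`, `unit_cost`,
#'   `flagged`.
#' @export
department_unit_costs <- function(costing) {
  stopifnot(inherits(costing, "facility_costing"))
  if (costing$level == "health_post") {
    return(tibble(
      department = CLINICAL_DEPARTMENTS, cost = NA_real_,
      patients = as.numeric(costing$outputs[CLINICAL_DEPARTMENTS]),
      unit_cost = NA_real_, flagged = FALSE
    ))
  }
  dept_labor <- costing$labor[CLINICAL_DEPARTMENTS]
  basis <- sum(dept_labor)
  oi_share <- if (basis > 0) {
    costing$other_indirect * dept_labor / basis
  } else {
    setNames(numeric(5), CLINICAL_DEPARTMENTS)
  }
  cost <- dept_labor + costing$drugs[CLINICAL_DEPARTMENTS] + oi_share
  patients <- as.numeric(costing$outputs[CLINICAL_DEPARTMENTS])
  unit <- ifelse(patients > 0, cost / patients, NA_real_)
  flagged <- patients == 0 & cost > 0
  tibble(
    department = CLINICAL_DEPARTMENTS,
    cost = as.numeric(cost),
    patients = patients,
    unit_cost = as.numeric(unit),
    flagged = flagged
  )
}

#' Services per clinical staff per working day
#'
#' @param record a `facility_record`.
#' @param working_days working days per year used as the daily divisor.
#' @return services per clinical staff per day; `NA` (with a warning) when
#'   the facility reports no clinical staff.
#' @export
staff_productivity <- function(record, working_days = 365) {
  stopifnot(inherits(record, "facility_record"), working_days > 0)
  n_clin <- sum(record$staff$is_clinical)
  if (n_clin == 0) {
    warn(sprintf("Facility %s has no clinical staff; productivity undefined.",
                 record$id))
    return(NA_real_)
  }
  sum(record$outputs) / n_clin / working_days
}

#' Summary statistics by facility level
#'
#' Mean, median (midpoint-of-two-central-values convention), and range of
#' total and component costs, unit costs, and productivity across sampled
#' facilities, per facility level.
#'
#' @param costings list of `facility_costing` objects.
#' @return tibble with `level`, `metric`, `n`, `mean`, `median`, `min`, `max`.
#' @export
level_summary <- function(costings) {
  stopifnot(length(costings) > 0)
  rows <- lapply(costings, function(cc) {
    units <- setNames(cc$unit_costs$unit_cost, cc$unit_costs$department)
    tibble(
      level = cc$level,
      metric = c("total", "clinical_labor", "drugs_supplies", "indirect",
                 paste0("unit_cost_", CLINICAL_DEPARTMENTS),
                 "overall_unit_cost", "productivity"),
      value = c(cc$total, cc$clinical_labor, cc$drugs_supplies, cc$indirect,
                as.numeric(units[CLINICAL_DEPARTMENTS]),
                cc$overall_unit_cost, cc$productivity)
    )
  })
  bind_rows(rows) %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$level, .data$metric) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      median = stats::median(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
}
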