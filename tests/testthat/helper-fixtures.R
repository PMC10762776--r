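# Hand-built minimal fixtures, constructed in code at test time.

frac_row <- function(opd = 0, hiv = 0, mch = 0, del = 0, ipdor = 0,
                     other_service = 0, admin = 0, unspecified = 0) {
  tibble::tibble(
    frac_opd = opd, frac_hiv = hiv, frac_mch = mch, frac_del = del,
    frac_ipdor = ipdor, frac_other_service = other_service,
    frac_admin = admin, frac_unspecified = unspecified
  )
}

na_fracs <- function() frac_row()[0, ][1, ]  # one row of all-NA fractions

staff_row <- function(facility_id, cadre, remuneration, is_clinical = TRUE,
                      fracs = NULL) {
  base <- tibble::tibble(
    facility_id = facility_id, cadre = cadre, is_clinical = is_clinical,
    annual_remuneration_etb = remuneration
  )
  if (is.null(fracs)) fracs <- na_fracs()
  dplyr::bind_cols(base, fracs)
}

item_row <- function(facility_id, category, cost, source = "treasury",
                     tag = NA_character_, description = "item") {
  tibble::tibble(
    facility_id = facility_id, category = category, description = description,
    annual_cost_etb = cost, funding_source = source, department_tag = tag
  )
}

# One health center with a two-person roster, a small basket of items, and
# outputs in two departments. All amounts in ETB at rate 1 unless stated.
mini_survey <- function(rate = 1) {
  facility_survey(
    facilities = tibble::tibble(
      id = "HC1", level = "health_center", region = "Testland",
      area_class = "agrarian", reported_catchment = 30000
    ),
    staff = dplyr::bind_rows(
      staff_row("HC1", "nurse", 10000 * rate,
                fracs = frac_row(opd = 0.5, mch = 0.3, admin = 0.2)),
      staff_row("HC1", "midwife", 6000 * rate,
                fracs = frac_row(mch = 0.8, other_service = 0.2)),
      staff_row("HC1", "cleaner", 2000 * rate, is_clinical = FALSE)
    ),
    items = dplyr::bind_rows(
      item_row("HC1", "drug", 500 * rate, source = "donor", tag = "HIV"),
      item_row("HC1", "drug", 100 * rate, source = "donor"),
      item_row("HC1", "operational", 300 * rate, description = "electricity")
    ),
    outputs = tibble::tibble(
      facility_id = "HC1", department = c("OPD", "MCH"),
      patients = c(1000, 500)
    )
  )
}

# A two-region world with one health center per region, used for estimator-B
# identities: utilization can be set to an exact multiple of the sample.
two_region_world <- function(util_multiplier = 1) {
  survey <- facility_survey(
    facilities = tibble::tibble(
      id = c("HC1", "HC2"), level = "health_center",
      region = c("North", "South"), area_class = "agrarian",
      reported_catchment = c(20000, 40000)
    ),
    staff = dplyr::bind_rows(
      staff_row("HC1", "nurse", 30000, fracs = frac_row(opd = 0.6, mch = 0.4)),
      staff_row("HC2", "nurse", 40000, fracs = frac_row(opd = 0.5, mch = 0.5))
    ),
    items = dplyr::bind_rows(
      item_row("HC1", "drug", 10000, tag = "OPD"),
      item_row("HC2", "drug", 12000, tag = "MCH")
    ),
    outputs = tibble::tibble(
      facility_id = c("HC1", "HC1", "HC2", "HC2"),
      department = c("OPD", "MCH", "OPD", "MCH"),
      patients = c(2000, 1000, 1500, 2500)
    )
  )
  util <- survey$outputs |>
    dplyr::left_join(
      tibble::tibble(facility_id = c("HC1", "HC2"),
                     region = c("North", "South")),
      by = "facility_id"
    ) |>
    dplyr::transmute(region, level = "health_center", department,
                     services = patients * util_multiplier)
  regions <- region_tables(
    regions = tibble::tibble(region = c("North", "South"),
                             population = c(1e6, 2e6)),
    utilization = util
  )
  list(survey = survey, regions = regions)
}

costings_for <- function(survey, config = phc_config()) {
  lapply(facility_records(survey), facility_costing, config = config)
}

# hand-built fixtures quote amounts that should pass through unconverted
cfg_unit <- function() phc_config(exchange_rate = 1)
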