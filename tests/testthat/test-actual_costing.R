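record_of <- function(survey, id = survey$facilities$id[1]) {
  facility_record(survey, id)
}

test_that("clinical labor splits proportionally to time use", {
  s <- mini_survey()
  rec <- record_of(s)
  alloc <- allocate_clinical_labor(rec)
  expect_equal(alloc[["OPD"]], 5000)
  expect_equal(alloc[["MCH"]], 3000 + 4800)     # nurse 0.3 + midwife 0.8
  expect_equal(alloc[["ADMIN"]], 2000)
  expect_equal(alloc[["OTHER_SERVICE"]], 1200)
})

test_that("labor conversion lands in US$ at the configured rate", {
  fac <- tibble::tibble(id = "HC1", level = "health_center", region = "R",
                        area_class = "urban", reported_catchment = 25000)
  staff <- staff_row("HC1", "nurse", 28440, fracs = frac_row(opd = 1))
  s <- facility_survey(fac, staff, item_row("HC1", "drug", 0)[0, ],
                       tibble::tibble(facility_id = "HC1",
                                      department = "OPD", patients = 1))
  alloc <- allocate_clinical_labor(record_of(s), exchange_rate = 28.44)
  expect_equal(alloc[["OPD"]], 1000)
})

test_that("labor allocation matches a brute-force per-staff loop", {
  set.seed(31)
  fracs <- t(vapply(1:12, function(i) {
    x <- rgamma(8, 1); x / sum(x)
  }, numeric(8)))
  colnames(fracs) <- c("frac_opd", "frac_hiv", "frac_mch", "frac_del",
                       "frac_ipdor", "frac_other_service", "frac_admin",
                       "frac_unspecified")
  remun <- runif(12, 5000, 90000)
  staff <- dplyr::bind_cols(
    tibble::tibble(facility_id = "HC1", cadre = "nurse", is_clinical = TRUE,
                   annual_remuneration_etb = remun),
    tibble::as_tibble(fracs)
  )
  fac <- tibble::tibble(id = "HC1", level = "health_center", region = "R",
                        area_class = "urban", reported_catchment = 25000)
  s <- facility_survey(fac, staff, item_row("HC1", "drug", 0)[0, ],
                       tibble::tibble(facility_id = "HC1",
                                      department = "OPD", patients = 1))
  alloc <- allocate_clinical_labor(record_of(s))
  brute <- setNames(numeric(7), c("OPD", "HIV", "MCH", "DEL", "IPDOR",
                                  "OTHER_SERVICE", "ADMIN"))
  for (i in 1:12) {
    brute[1:5] <- brute[1:5] + remun[i] * fracs[i, 1:5]
    brute["OTHER_SERVICE"] <- brute[["OTHER_SERVICE"]] + remun[i] * fracs[i, 6]
    brute["ADMIN"] <- brute[["ADMIN"]] + remun[i] * (fracs[i, 7] + fracs[i, 8])
  }
  expect_equal(alloc, brute, tolerance = 1e-9)
})

test_that("drugs and supplies follow tags, then labor shares", {
  s <- mini_survey()
  rec <- record_of(s)
  labor <- allocate_clinical_labor(rec)
  ds <- allocate_drugs_supplies(rec, labor)
  expect_equal(ds[["HIV"]], 500)                      # tagged directly
  dept_labor <- labor[c("OPD", "HIV", "MCH", "DEL", "IPDOR")]
  expect_equal(unname(ds[c("OPD", "MCH")]),
               unname(100 * dept_labor[c("OPD", "MCH")] / sum(dept_labor)))
  expect_equal(sum(ds), 600)
})

test_that("a mixed basket allocates identically to an item-wise loop", {
  set.seed(41)
  s <- generate_sample(generator_spec(seed = 41))
  rec <- facility_record(s$survey, "HC_03")
  labor <- allocate_clinical_labor(rec)
  ds <- allocate_drugs_supplies(rec, labor)
  depts <- c("OPD", "HIV", "MCH", "DEL", "IPDOR")
  shares <- labor[depts] / sum(labor[depts])
  brute <- setNames(numeric(5), depts)
  basket <- rec$items[rec$items$category %in% c("drug", "medical_supply"), ]
  for (i in seq_len(nrow(basket))) {
    if (is.na(basket$department_tag[i])) {
      brute <- brute + basket$annual_cost_etb[i] * shares
    } else {
      tag <- basket$department_tag[i]
      brute[tag] <- brute[[tag]] + basket$annual_cost_etb[i]
    }
  }
  expect_equal(ds, brute, tolerance = 1e-9)
  expect_error(
    allocate_drugs_supplies(rec, setNames(numeric(7), names(labor))),
    "no clinical labor"
  )
})

test_that("indirect costs pool admin labor and untagged operational spend", {
  s <- mini_survey()
  rec <- record_of(s)
  labor <- allocate_clinical_labor(rec)
  ind <- compute_indirect(rec, labor)
  expect_equal(ind$admin, 2000 + 2000)   # cleaner + nurse admin time
  expect_equal(ind$other_indirect, 300)
})

test_that("money is conserved through facility costing", {
  # every birr of remuneration and line items lands in exactly one bucket
  for (seed in c(3, 17)) {
    s <- generate_sample(generator_spec(seed = seed))
    cfg <- phc_config()
    for (rec in facility_records(s$survey)) {
      cc <- facility_costing(rec, cfg)
      brute <- (sum(rec$staff$annual_remuneration_etb) +
                  sum(rec$items$annual_cost_etb)) / cfg$exchange_rate
      expect_lt(abs(cc$total - brute) / brute, 1e-6)
      parts <- sum(cc$labor[c("OPD", "HIV", "MCH", "DEL", "IPDOR")]) +
        sum(cc$drugs) + cc$other_service + cc$admin + cc$other_indirect
      if (rec$level != "health_post") {
        expect_lt(abs(parts - cc$total) / cc$total, 1e-6)
      }
    }
  }
})

test_that("costing is scale-equivariant and permutation-invariant", {
  s <- mini_survey()
  k <- 3.7
  scaled <- facility_survey(
    s$facilities,
    dplyr::mutate(s$staff, annual_remuneration_etb = annual_remuneration_etb * k),
    dplyr::mutate(s$items, annual_cost_etb = annual_cost_etb * k),
    s$outputs
  )
  shuffled <- facility_survey(
    s$facilities, s$staff[c(3, 1, 2), ], s$items[c(2, 3, 1), ], s$outputs
  )
  base <- facility_costing(facility_record(s, "HC1"))
  cs <- facility_costing(facility_record(scaled, "HC1"))
  cp <- facility_costing(facility_record(shuffled, "HC1"))
  expect_equal(cs$total, base$total * k, tolerance = 1e-12)
  expect_equal(cs$labor, base$labor * k, tolerance = 1e-12)
  expect_equal(cs$funding_total, base$funding_total, tolerance = 1e-12)
  expect_equal(cp$total, base$total, tolerance = 1e-12)
  expect_equal(cp$unit_costs$unit_cost, base$unit_costs$unit_cost,
               tolerance = 1e-12)
})

test_that("unit costs split shared indirect by labor and exclude admin", {
  fac <- tibble::tibble(id = "HC1", level = "health_center", region = "R",
                        area_class = "urban", reported_catchment = 25000)
  staff <- dplyr::bind_rows(
    staff_row("HC1", "nurse", 1000, fracs = frac_row(opd = 1)),
    staff_row("HC1", "nurse", 1000, fracs = frac_row(mch = 1))
  )
  items <- item_row("HC1", "operational", 100, description = "utilities")
  outputs <- tibble::tibble(facility_id = "HC1",
                            department = c("OPD", "MCH"),
                            patients = c(10, 10))
  s <- facility_survey(fac, staff, items, outputs)
  cc <- facility_costing(facility_record(s, "HC1"), cfg_unit())
  uc <- cc$unit_costs
  # equal labor: the 100 of utilities splits 50/50
  expect_equal(uc$cost[uc$department == "OPD"], 1000 + 50)
  expect_equal(uc$cost[uc$department == "MCH"], 1000 + 50)
  expect_equal(uc$unit_cost[uc$department == "OPD"], 105)
  # overall unit cost includes everything
  expect_equal(cc$overall_unit_cost, 2100 / 20)
})

test_that("unit costs match a brute-force recomputation on generated data", {
  s <- generate_sample(generator_spec(seed = 13))
  cfg <- phc_config()
  rec <- facility_record(s$survey, "PH_02")
  cc <- facility_costing(rec, cfg)
  labor <- allocate_clinical_labor(rec, cfg$exchange_rate)
  drugs <- allocate_drugs_supplies(rec, labor, cfg$exchange_rate)
  ind <- compute_indirect(rec, labor, cfg$exchange_rate)
  depts <- c("OPD", "HIV", "MCH", "DEL", "IPDOR")
  for (d in depts) {
    expected <- labor[[d]] + drugs[[d]] +
      ind$other_indirect * labor[[d]] / sum(labor[depts])
    got <- cc$unit_costs$cost[cc$unit_costs$department == d]
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("unit costs stay finite and flagged at zero patients", {
  fac <- tibble::tibble(id = "HC1", level = "health_center", region = "R",
                        area_class = "urban", reported_catchment = 25000)
  staff <- staff_row("HC1", "nurse", 1000, fracs = frac_row(opd = 0.5, del = 0.5))
  outputs <- tibble::tibble(facility_id = "HC1", department = "OPD",
                            patients = 10)
  s <- facility_survey(fac, staff, item_row("HC1", "drug", 0)[0, ], outputs)
  cc <- facility_costing(facility_record(s, "HC1"))
  uc <- cc$unit_costs
  expect_true(is.na(uc$unit_cost[uc$department == "DEL"]))
  expect_true(uc$flagged[uc$department == "DEL"])
  expect_false(any(is.infinite(uc$unit_cost), na.rm = TRUE))
})

test_that("splitting a line item leaves department unit costs unchanged", {
  s <- mini_survey()
  split_items <- dplyr::bind_rows(
    s$items[2:3, ],
    item_row("HC1", "drug", 200, source = "donor", tag = "HIV"),
    item_row("HC1", "drug", 300, source = "donor", tag = "HIV")
  )
  s2 <- facility_survey(s$facilities, s$staff, split_items, s$outputs)
  base <- facility_costing(facility_record(s, "HC1"))
  alt <- facility_costing(facility_record(s2, "HC1"))
  expect_equal(alt$unit_costs$unit_cost, base$unit_costs$unit_cost,
               tolerance = 1e-12)
})

test_that("staff productivity follows its closed form", {
  fac <- tibble::tibble(id = "HC1", level = "health_center", region = "R",
                        area_class = "urban", reported_catchment = 25000)
  staff <- dplyr::bind_rows(
    staff_row("HC1", "nurse", 1000, fracs = frac_row(opd = 1)),
    staff_row("HC1", "nurse", 1000, fracs = frac_row(opd = 1))
  )
  outputs <- tibble::tibble(facility_id = "HC1", department = "OPD",
                            patients = 7300)
  s <- facility_survey(fac, staff, item_row("HC1", "drug", 0)[0, ], outputs)
  rec <- facility_record(s, "HC1")
  expect_equal(staff_productivity(rec, 365), 10)
  expect_equal(staff_productivity(rec, 365 / 2), 20)  # halving days doubles
  zero_out <- tibble::tibble(facility_id = "HC1", department = "OPD",
                             patients = 0)
  s0 <- facility_survey(fac, staff, item_row("HC1", "drug", 0)[0, ], zero_out)
  expect_equal(staff_productivity(facility_record(s0, "HC1"), 365), 0)
})

test_that("level summaries use the midpoint median convention", {
  s <- mini_survey()
  cc <- facility_costing(facility_record(s, "HC1"))
  one <- level_summary(list(cc))
  row <- one[one$metric == "total", ]
  expect_equal(row$mean, row$median)
  expect_equal(row$min, row$max)
  expect_equal(median(c(1, 2, 3, 4)), 2.5)  # convention used throughout
  s4 <- generate_sample(generator_spec(seed = 2))
  cost <- costings_for(s4$survey)
  summ <- level_summary(cost)
  hc_total <- summ[summ$level == "health_center" & summ$metric == "total", ]
  vals <- vapply(Filter(function(x) x$level == "health_center", cost),
                 function(x) x$total, numeric(1))
  expect_equal(hc_total$mean, mean(vals))
  expect_equal(hc_total$median, median(vals))
  expect_equal(c(hc_total$min, hc_total$max), range(vals))
})
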