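test_that("catchment per-capita is a simple unweighted mean", {
  w <- two_region_world()
  cost <- costings_for(w$survey, cfg_unit())
  # facility per-capita from reported catchments: totals 40000, 52000
  pc <- per_capita_A(cost, "reported")
  fac <- attr(pc, "facility")
  expect_equal(sort(fac$per_capita), sort(c(40000 / 20000, 52000 / 40000)))
  expect_equal(pc$per_capita, mean(c(2.0, 1.3)))
  # single facility arithmetic
  one <- per_capita_A(cost[1],
                      "norm_midpoint",
                      tibble::tibble(level = "health_center", min = 5000,
                                     max = 15000, midpoint = 10000))
  expect_equal(one$per_capita, 40000 / 10000)
})

test_that("larger reported catchments make A2 no larger than A1 facility-wise", {
  s <- generate_sample(generator_spec(seed = 19))
  # force reported catchments above the norm midpoints
  cfg <- phc_config()
  norms <- cfg$catchment_norms
  fac <- s$survey$facilities
  mid <- norms$midpoint[match(fac$level, norms$level)]
  fac$reported_catchment <- pmax(fac$reported_catchment, mid * 1.25)
  s2 <- facility_survey(fac, s$survey$staff, s$survey$items, s$survey$outputs)
  cost <- costings_for(s2)
  a1 <- attr(per_capita_A(cost, "norm_midpoint", norms), "facility")
  a2 <- attr(per_capita_A(cost, "reported"), "facility")
  joined <- dplyr::left_join(a1, a2, by = "id", suffix = c("_a1", "_a2"))
  expect_true(all(joined$per_capita_a2 <= joined$per_capita_a1 + 1e-12))
})

test_that("estimate A scales per-capita means by pooled population", {
  w <- two_region_world()
  cost <- costings_for(w$survey, cfg_unit())
  pc <- per_capita_A(cost, "reported")
  est <- estimate_A(pc, cost, w$regions, "A2")
  expect_equal(est$totals$total, mean(c(2.0, 1.3)) * 3e6)
  comp_sum <- est$totals$clinical_labor + est$totals$drugs_supplies +
    est$totals$indirect
  expect_equal(comp_sum, est$totals$total, tolerance = 1e-9)
  expect_equal(est$per_capita$per_capita * est$population, est$totals$total,
               tolerance = 1e-9)
})

test_that("department weights are sample means and estimator B ignores their scale", {
  w <- two_region_world()
  cost <- costings_for(w$survey)
  wt <- suppressWarnings(department_weights(cost))
  # brute-force mean over facilities with defined unit costs
  for (d in c("OPD", "MCH")) {
    per_fac <- vapply(cost, function(cc) {
      cc$unit_costs$unit_cost[cc$unit_costs$department == d]
    }, numeric(1))
    expect_equal(wt$weight[wt$department == d], mean(per_fac, na.rm = TRUE))
  }
  est1 <- estimate_B(cost, w$regions, wt)
  wt10 <- dplyr::mutate(wt, weight = weight * 10)
  est2 <- estimate_B(cost, w$regions, wt10)
  expect_equal(est1$totals$total, est2$totals$total, tolerance = 1e-12)
})

test_that("identical unit costs give identical weights", {
  fac <- tibble::tibble(id = "HC1", level = "health_center", region = "R",
                        area_class = "urban", reported_catchment = 25000)
  staff <- dplyr::bind_rows(
    staff_row("HC1", "nurse", 1000, fracs = frac_row(opd = 0.5, mch = 0.5))
  )
  outputs <- tibble::tibble(facility_id = "HC1",
                            department = c("OPD", "MCH"), patients = c(50, 50))
  s <- facility_survey(fac, staff, item_row("HC1", "drug", 0)[0, ], outputs)
  wt <- suppressWarnings(department_weights(costings_for(s)))
  expect_equal(wt$weight[wt$department == "OPD"],
               wt$weight[wt$department == "MCH"])
})

test_that("expansion factors reduce to ratios of weighted utilization", {
  w1 <- two_region_world(util_multiplier = 1)
  cost <- costings_for(w1$survey)
  wt <- suppressWarnings(department_weights(cost))
  f1 <- expansion_factors(w1$regions, cost, wt)
  expect_true(all(abs(f1$factor - 1) < 1e-12))
  w2 <- two_region_world(util_multiplier = 2)
  f2 <- expansion_factors(w2$regions, cost, wt)
  expect_true(all(abs(f2$factor - 2) < 1e-12))
})

test_that("expansion factors match a brute-force double loop", {
  set.seed(77)
  for (rep in 1:10) {
    s <- generate_sample(generator_spec(seed = 100 + rep))
    cost <- costings_for(s$survey)
    wt <- suppressWarnings(department_weights(cost))
    fac <- suppressWarnings(expansion_factors(s$regions, cost, wt))
    su <- s$survey$outputs |>
      dplyr::left_join(s$survey$facilities[, c("id", "level", "region")],
                       by = c(facility_id = "id"))
    checked <- 0
    for (i in seq_len(nrow(fac))) {
      if (fac$borrowed[i]) next
      num <- 0; den <- 0
      for (d in c("OPD", "HIV", "MCH", "DEL", "IPDOR")) {
        wgt <- wt$weight[wt$level == fac$level[i] & wt$department == d]
        if (length(wgt) == 0) next
        u <- s$regions$utilization
        num <- num + wgt * sum(u$services[u$region == fac$region[i] &
                                            u$level == fac$level[i] &
                                            u$department == d])
        den <- den + wgt * sum(su$patients[su$region == fac$region[i] &
                                             su$level == fac$level[i] &
                                             su$department == d])
      }
      expect_equal(fac$factor[i], num / den, tolerance = 1e-12)
      checked <- checked + 1
    }
    expect_gt(checked, 0)
  }
})

test_that("estimator B with unit factors reproduces the sample cost", {
  w <- two_region_world(util_multiplier = 1)
  cost <- costings_for(w$survey)
  est <- suppressWarnings(estimate_B(cost, w$regions))
  expect_equal(sum(est$totals$total),
               sum(vapply(cost, function(x) x$total, numeric(1))),
               tolerance = 1e-12)
})

test_that("estimator B recovers the constructed network totals exactly", {
  kt <- generate_known_truth(generator_spec(seed = 55))
  cost <- costings_for(kt$sample$survey)
  est <- suppressWarnings(estimate_B(cost, kt$sample$regions))
  truth <- kt$truth$network
  got <- est$totals$total[match(truth$level, est$totals$level)]
  expect_true(all(abs(got - truth$total) / truth$total < 1e-6))
  f <- est$meta$factors
  ef_truth <- kt$truth$expansion
  joined <- dplyr::inner_join(f, ef_truth, by = c("region", "level"),
                              suffix = c("", "_truth"))
  expect_true(all(abs(joined$factor - joined$factor_truth) /
                    joined$factor_truth < 1e-9))
})

test_that("sample capture reports the constructed percentages", {
  w <- two_region_world(util_multiplier = 1)
  cost <- costings_for(w$survey)
  cap <- suppressWarnings(sample_capture(cost, w$regions))
  expect_equal(cap$capture_pct, 100)
  kt <- generate_known_truth(generator_spec(seed = 23))
  cost2 <- costings_for(kt$sample$survey)
  wt <- suppressWarnings(department_weights(cost2))
  cap2 <- suppressWarnings(sample_capture(cost2, kt$sample$regions, wt))
  expect_equal(cap2$capture_pct[cap2$level == "health_center"], 2.3,
               tolerance = 1e-9)
  expect_equal(cap2$capture_pct[cap2$level == "health_post"], 0.1,
               tolerance = 1e-9)
  # capture times the pooled expansion factor is one without heterogeneity
  f <- suppressWarnings(expansion_factors(kt$sample$regions, cost2, wt))
  pooled <- sum(f$weighted_region[f$level == "health_center"]) /
    sum(f$weighted_sample[f$level == "health_center"])
  expect_equal(pooled * cap2$capture_pct[cap2$level == "health_center"] / 100,
               1, tolerance = 1e-9)
})

test_that("all estimators are money- and population-equivariant", {
  w <- two_region_world()
  cost <- costings_for(w$survey)
  k <- 2.5
  scaled_survey <- facility_survey(
    w$survey$facilities,
    dplyr::mutate(w$survey$staff,
                  annual_remuneration_etb = annual_remuneration_etb * k),
    dplyr::mutate(w$survey$items, annual_cost_etb = annual_cost_etb * k),
    w$survey$outputs
  )
  cost_k <- costings_for(scaled_survey)
  norms <- tibble::tibble(level = "health_center", min = 5000, max = 15000,
                          midpoint = 10000)
  a1 <- estimate_A(per_capita_A(cost, "norm_midpoint", norms), cost,
                   w$regions, "A1")
  a1k <- estimate_A(per_capita_A(cost_k, "norm_midpoint", norms), cost_k,
                    w$regions, "A1")
  expect_equal(a1k$totals$total, a1$totals$total * k, tolerance = 1e-9)
  b <- suppressWarnings(estimate_B(cost, w$regions))
  bk <- suppressWarnings(estimate_B(cost_k, w$regions))
  expect_equal(bk$totals$total, b$totals$total * k, tolerance = 1e-9)
})
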