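toy_stp <- function() {
  stp_tables(
    services = tibble::tibble(
      service_id = c("s1", "s2"),
      level = "health_center",
      department = c("OPD", "MCH"),
      target_pop_fraction = c(0.04, 1.0),
      rate = c(0.5, 0.2),
      coverage_target = c(1.0, 0.5),
      encounters = c(1, 2)
    ),
    consumables = tibble::tibble(
      service_id = c("s1", "s2"), item = c("drugA", "drugB"),
      quantity = c(2, 1), unit_price = c(3, 4)
    ),
    labor = tibble::tibble(
      service_id = c("s1", "s2"), cadre = "nurse",
      minutes = c(30, 15), wage_per_minute = 0.1
    )
  )
}

toy_regions <- function(pop = 1e6) {
  region_tables(
    tibble::tibble(region = "R", population = pop),
    tibble::tibble(region = "R", level = "health_center",
                   department = "OPD", services = 1)
  )
}

test_that("population in need is multiplicative and additive over regions", {
  expect_equal(population_in_need(1e6, 0.04, 0.5), 20000)
  expect_equal(population_in_need(1e6, 0.04, 0), 0)
  pops <- c(3e5, 7e5)
  expect_equal(sum(population_in_need(pops, 0.04, 0.5)),
               population_in_need(sum(pops), 0.04, 0.5))
})

test_that("episode costs combine consumables and per-encounter labor", {
  ec <- episode_cost(toy_stp())
  s1 <- ec[ec$service_id == "s1", ]
  expect_equal(s1$consumables, 6)            # 2 x 3
  expect_equal(s1$labor, 3)                  # 1 encounter x 30 min x 0.1
  s2 <- ec[ec$service_id == "s2", ]
  expect_equal(s2$labor, 2 * 15 * 0.1)       # encounters multiply labor
  expect_equal(s2$consumables, 4)            # ...but not consumables
  ep <- episode_cost(toy_stp(), minutes_per = "episode")
  expect_equal(ep$labor[ep$service_id == "s2"], 15 * 0.1)
})

test_that("episode costs equal a brute-force loop on a generated package", {
  stp <- generate_sample(generator_spec(seed = 4))$stp
  ec <- episode_cost(stp)
  for (sid in stp$services$service_id) {
    cons <- stp$consumables[stp$consumables$service_id == sid, ]
    lab <- stp$labor[stp$labor$service_id == sid, ]
    enc <- stp$services$encounters[stp$services$service_id == sid]
    brute_cons <- sum(cons$quantity * cons$unit_price)
    brute_lab <- enc * sum(lab$minutes * lab$wage_per_minute)
    expect_equal(ec$consumables[ec$service_id == sid], brute_cons)
    expect_equal(ec$labor[ec$service_id == sid], brute_lab)
  }
})

test_that("service totals scale with coverage and add across services", {
  st <- service_total(toy_stp(), toy_regions())
  s1 <- st[st$service_id == "s1", ]
  expect_equal(s1$episodes, 20000)
  expect_equal(s1$direct_cost, 20000 * 1.0 * 9)      # coverage 1, cost 6+3
  zero_cov <- toy_stp()
  zero_cov$services$coverage_target <- 0
  expect_true(all(service_total(zero_cov, toy_regions())$direct_cost == 0))
  expect_equal(sum(st$direct_cost),
               st$direct_cost[1] + st$direct_cost[2])
})

test_that("overhead rates are indirect over total, zero for health posts", {
  s <- generate_sample(generator_spec(seed = 6))
  cost <- costings_for(s$survey)
  ov <- overhead_rate(cost)
  expect_equal(ov$rate[ov$level == "health_post"], 0)
  expect_true(all(ov$rate >= 0 & ov$rate < 1))
  hc <- Filter(function(x) x$level == "health_center", cost)
  brute <- sum(vapply(hc, function(x) x$indirect, numeric(1))) /
    sum(vapply(hc, function(x) x$total, numeric(1)))
  expect_equal(ov$rate[ov$level == "health_center"], brute, tolerance = 1e-12)
})

test_that("the overhead uplift preserves the indirect-over-total ratio", {
  up0 <- apply_overhead(100, 0)
  expect_equal(up0$indirect, 0)
  expect_equal(up0$total, 100)
  set.seed(8)
  direct <- runif(20, 1, 1e6)
  r <- runif(20, 0, 0.9)
  up <- apply_overhead(direct, r)
  expect_equal(up$indirect / up$total, r, tolerance = 1e-9)
  expect_equal(up$direct + up$indirect, up$total, tolerance = 1e-9)
  expect_error(apply_overhead(100, 1), "\\[0, 1\\)")
})

test_that("normative summary aggregates services and applies overhead", {
  stp <- toy_stp()
  regions <- toy_regions()
  ov <- tibble::tibble(level = "health_center", rate = 0.25)
  ns <- normative_summary(stp, regions, ov)
  st <- service_total(stp, regions)
  direct <- sum(st$direct_cost)
  expect_equal(ns$by_level$total, direct / 0.75, tolerance = 1e-9)
  expect_equal(ns$by_level$indirect / ns$by_level$total, 0.25,
               tolerance = 1e-9)
  expect_equal(ns$by_level$per_capita, ns$by_level$total / 1e6)
  # department view: indirect allocated by direct shares, sums conserved
  expect_equal(sum(ns$by_department$direct), direct, tolerance = 1e-9)
  expect_equal(sum(ns$by_department$indirect), ns$by_level$indirect,
               tolerance = 1e-9)
  # doubling population doubles totals (linearity)
  ns2 <- normative_summary(stp, toy_regions(2e6), ov)
  expect_equal(ns2$by_level$total, 2 * ns$by_level$total, tolerance = 1e-9)
  expect_equal(ns2$by_level$per_capita, ns$by_level$per_capita,
               tolerance = 1e-9)
})

test_that("normative totals match brute-force per-service accumulation", {
  sample <- generate_sample(generator_spec(seed = 12))
  cost <- costings_for(sample$survey)
  ov <- overhead_rate(cost)
  ns <- normative_summary(sample$stp, sample$regions, ov)
  st <- service_total(sample$stp, sample$regions)
  for (lv in unique(st$level)) {
    direct <- sum(st$direct_cost[st$level == lv])
    r <- ov$rate[ov$level == lv]
    expect_equal(ns$by_level$total[ns$by_level$level == lv],
                 direct / (1 - r), tolerance = 1e-9)
  }
})
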