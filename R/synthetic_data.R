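#' Specification for the synthetic facility-data generator
#'
#' Encodes the study conditions the generator emulates: 20 health posts, 25
#' health centers, and 8 primary hospitals spread over nine regions totalling
#' 92.4 million people, right-skewed (log-normal) cost components per level
#' calibrated to the observed sample medians and means, staffing and service
#' volumes in the observed ranges, and a sample that captures roughly 0.1%,
#' 2.3%, and 10.4% of network utilization at the three levels.
#'
#' Cost calibration is order-of-magnitude: location parameters are the logs
#' of the observed sample medians and scale parameters reproduce the observed
#' mean/median skew.
#'
#' @param seed integer seed; the generator uses a single pseudo-random stream
#'   with a documented draw order (see [generate_sample()]).
#' @param n_facilities named counts per facility level.
#' @param exchange_rate ETB per US$ used to emit survey amounts in ETB.
#' @param sample_capture named fractions of network utilization captured by
#'   the sample, per level, in `(0, 1]`.
#' @param utilization_noise_sd log-normal jitter (sdlog) on the scale-up part
#'   of region utilization; `0` makes region tables an exact `1/capture`
#'   scale-up of the sample.
#' @param cost_calibration tibble `level`, `component`, `meanlog`, `sdlog`
#'   (US$ scale) for clinical labor, drugs & supplies, and indirect costs.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1,
                           n_facilities = c(health_post = 20,
                                            health_center = 25,
                                            primary_hospital = 8),
                           exchange_rate = 28.44,
                           sample_capture = c(health_post = 0.001,
                                              health_center = 0.023,
                                              primary_hospital = 0.104),
                           utilization_noise_sd = 0.15,
                           cost_calibration = default_cost_calibration()) {
  stopifnot(all(PHC_LEVELS %in% names(n_facilities)),
            all(n_facilities >= 0))
  if (any(sample_capture <= 0) || any(sample_capture > 1)) {
    abort("`sample_capture` fractions must lie in (0, 1].")
  }
  cal <- as_tibble(cost_calibration)
  if (any(cal$sdlog < 0)) abort("Cost dispersions must be non-negative.")
  structure(
    list(
      seed = as.integer(seed),
      n_facilities = n_facilities[PHC_LEVELS],
      exchange_rate = exchange_rate,
      sample_capture = sample_capture[PHC_LEVELS],
      utilization_noise_sd = utilization_noise_sd,
      cost_calibration = cal,
      regions = default_region_frame(),
      staffing = list(
        # median clinical staff and lognormal spread, clamp range; share of
        # non-clinical staff relative to clinical
        health_post = list(median = 2, sdlog = 0.45, range = c(1, 5),
                           nonclin_ratio = 0),
        health_center = list(median = 27, sdlog = 0.5, range = c(6, 82),
                             nonclin_ratio = 1.0),
        primary_hospital = list(median = 78, sdlog = 0.2, range = c(41, 124),
                                nonclin_ratio = 1.17)
      ),
      services = list(  # total annual services per facility
        health_post = list(meanlog = log(6592), sdlog = 0.9),
        health_center = list(meanlog = log(47852), sdlog = 0.66),
        primary_hospital = list(meanlog = log(76027), sdlog = 0.5)
      ),
      dept_shares = list(  # service-output mix per level
        health_post = c(OPD = 0.44, HIV = 0.005, MCH = 0.55, DEL = 0.005,
                        IPDOR = 0),
        health_center = c(OPD = 0.35, HIV = 0.12, MCH = 0.45, DEL = 0.07,
                          IPDOR = 0.01),
        primary_hospital = c(OPD = 0.40, HIV = 0.15, MCH = 0.25, DEL = 0.08,
                             IPDOR = 0.12)
      ),
      time_use = list(  # clinical time-use Dirichlet base shares
        health_center = c(OPD = 0.25, HIV = 0.15, MCH = 0.18, DEL = 0.07,
                          IPDOR = 0.03, OTHER_SERVICE = 0.10, ADMIN = 0.15,
                          UNSPECIFIED = 0.07),
        primary_hospital = c(OPD = 0.22, HIV = 0.08, MCH = 0.08, DEL = 0.05,
                             IPDOR = 0.19, OTHER_SERVICE = 0.08, ADMIN = 0.22,
                             UNSPECIFIED = 0.08)
      ),
      catchment = list(  # reported catchment (persons)
        health_post = list(meanlog = log(6009), sdlog = 0.30),
        health_center = list(meanlog = log(28914), sdlog = 0.50),
        primary_hospital = list(meanlog = log(172852), sdlog = 0.35)
      ),
      drug_funding = list(  # funding-source mix of drug/supply items
        health_post = c(treasury = 0, internal_revenue = 0, donor = 1),
        health_center = c(treasury = 0.16, internal_revenue = 0.12,
                          donor = 0.72),
        primary_hospital = c(treasury = 0.29, internal_revenue = 0.28,
                             donor = 0.43)
      )
    ),
    class = "generator_spec"
  )
}

default_cost_calibration <- function() {
  tibble(
    level = rep(PHC_LEVELS, each = 3),
    component = rep(COST_COMPONENTS, times = 3),
    meanlog = log(c(2711, 2092, 1,        # health post (indirect unused)
                    61092, 68316, 40159,  # health center
                    313624, 83957, 198186)),
    sdlog = c(1.00, 1.50, 0,
              0.88, 0.87, 0.97,
              0.20, 0.86, 0.28)
  )
}

# Nine regions: populations (persons) sum to 92.4 million; facility quotas
# follow the study's sample layout per level.
default_region_frame <- function() {
  tibble(
    region = c("Amhara", "Oromia", "Sidama", "SNNPR", "Afar", "Somali",
               "Addis Ababa", "Dire Dawa", "Harari"),
    area_class = c("agrarian", "agrarian", "agrarian", "agrarian", "pastoral",
                   "pastoral", "urban", "urban", "urban"),
    population = c(21.5, 35.3, 4.3, 19.4, 1.9, 5.7, 3.6, 0.45, 0.25) * 1e6,
    health_post = c(4, 3, 2, 4, 2, 2, 0, 1, 2),
    health_center = c(4, 4, 2, 4, 2, 2, 3, 2, 2),
    primary_hospital = c(2, 2, 1, 2, 1, 0, 0, 0, 0)
  )
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

draw_lognorm <- function(meanlog, sdlog, clamp = NULL) {
  x <- rlnorm(1, meanlog, sdlog)
  if (!is.null(clamp)) x <- min(max(x, clamp[1]), clamp[2])
  x
}

region_assignment <- function(spec, level) {
  quota <- spec$regions[[level]]
  n <- spec$n_facilities[[level]]
  if (sum(quota) == n) {
    rep(spec$regions$region, times = quota)
  } else {
    # non-default facility counts: allocate proportionally to the quota
    # profile (plus a floor so zero-quota regions stay possible)
    probs <- (quota + 0.1) / sum(quota + 0.1)
    sample(spec$regions$region, n, replace = TRUE, prob = probs)
  }
}

build_facility <- function(spec, level, idx, region) {
  rate <- spec$exchange_rate
  cal <- spec$cost_calibration
  getcal <- function(comp) cal[cal$level == level & cal$component == comp, ]
  id <- sprintf("%s_%02d", c(health_post = "HP", health_center = "HC",
                             primary_hospital = "PH")[[level]], idx)

  # (1) component cost targets, US$
  lab_c <- getcal("clinical_labor")
  labor_target <- draw_lognorm(lab_c$meanlog, lab_c$sdlog)
  ds_c <- getcal("drugs_supplies")
  drugs_target <- draw_lognorm(ds_c$meanlog, ds_c$sdlog)
  ind_c <- getcal("indirect")
  indirect_target <- if (level == "health_post") 0 else {
    draw_lognorm(ind_c$meanlog, ind_c$sdlog)
  }

  # (2) staffing counts
  stf <- spec$staffing[[level]]
  n_clin <- round(draw_lognorm(log(stf$median), stf$sdlog, stf$range))
  n_clin <- max(1, n_clin)
  n_nonclin <- round(n_clin * stf$nonclin_ratio)

  # clinical remuneration gross of admin/unspecified time, so that the
  # labor component (departments + other service) lands near its target
  if (level == "health_post") {
    clin_total <- labor_target
    admin_share <- 0
  } else {
    tu <- spec$time_use[[level]]
    admin_share <- tu[["ADMIN"]] + tu[["UNSPECIFIED"]]
    clin_total <- labor_target / (1 - admin_share)
  }

  # (3) remuneration weights, (4) time-use fractions
  w <- rgamma(n_clin, shape = 6, rate = 1)
  remun <- clin_total * w / sum(w)
  frac_mat <- matrix(NA_real_, nrow = n_clin, ncol = length(FRAC_COLS),
                     dimnames = list(NULL, unname(FRAC_COLS)))
  if (level != "health_post") {
    tu <- spec$time_use[[level]]
    for (i in seq_len(n_clin)) {
      frac_mat[i, ] <- rdirichlet1(tu[names(FRAC_COLS)] * 25)
    }
  }
  cadres <- c("physician", "nurse", "midwife", "health_officer",
              "health_extension_worker")
  staff <- tibble(
    facility_id = id,
    cadre = if (level == "health_post") {
      rep("health_extension_worker", n_clin)
    } else {
      cadres[1 + (seq_len(n_clin) - 1) %% length(cadres)]
    },
    is_clinical = TRUE,
    annual_remuneration_etb = remun * rate
  )
  staff <- dplyr::bind_cols(staff, as_tibble(frac_mat))
  # the indirect calibration target covers total indirect cost; net out the
  # expected clinical admin/unspecified labor, which lands there too
  clin_admin_expected <- labor_target * admin_share / (1 - admin_share)
  indirect_resid <- max(indirect_target - clin_admin_expected,
                        0.2 * indirect_target)
  if (n_nonclin > 0) {
    wn <- rgamma(n_nonclin, shape = 6, rate = 1)
    nonclin_total <- indirect_resid * 0.6
    ncl <- tibble(
      facility_id = id,
      cadre = rep(c("administrator", "cleaner", "guard"),
                  length.out = n_nonclin),
      is_clinical = FALSE,
      annual_remuneration_etb = nonclin_total * wn / sum(wn) * rate
    )
    ncl <- dplyr::bind_cols(
      ncl,
      as_tibble(matrix(NA_real_, n_nonclin, length(FRAC_COLS),
                       dimnames = list(NULL, unname(FRAC_COLS))))
    )
    staff <- bind_rows(staff, ncl)
  }

  # (5) line items: tagged drugs per department, untagged drugs/supplies,
  # operational spending
  fund <- spec$drug_funding[[level]]
  draw_source <- function() {
    sample(names(fund), 1, prob = fund)
  }
  items <- list()
  if (level == "health_post") {
    split <- rdirichlet1(c(3, 2))
    items <- list(
      tibble(facility_id = id, category = "drug",
             description = "program drugs",
             annual_cost_etb = drugs_target * split[1] * rate,
             funding_source = "donor", department_tag = NA_character_),
      tibble(facility_id = id, category = "medical_supply",
             description = "medical supplies",
             annual_cost_etb = drugs_target * split[2] * rate,
             funding_source = "donor", department_tag = NA_character_)
    )
  } else {
    tagged_frac <- 0.6
    shares <- rdirichlet1(spec$dept_shares[[level]] * 10 + 0.2)
    for (d in seq_along(CLINICAL_DEPARTMENTS)) {
      amt <- drugs_target * tagged_frac * shares[d]
      if (amt <= 0) next
      items <- c(items, list(tibble(
        facility_id = id, category = "drug",
        description = paste0("program drugs ", CLINICAL_DEPARTMENTS[d]),
        annual_cost_etb = amt * rate,
        funding_source = draw_source(),
        department_tag = CLINICAL_DEPARTMENTS[d]
      )))
    }
    untagged <- drugs_target * (1 - tagged_frac)
    usplit <- rdirichlet1(c(4, 3))
    items <- c(items, list(
      tibble(facility_id = id, category = "drug",
             description = "essential drugs",
             annual_cost_etb = untagged * usplit[1] * rate,
             funding_source = draw_source(),
             department_tag = NA_character_),
      tibble(facility_id = id, category = "medical_supply",
             description = "supplies and reagents",
             annual_cost_etb = untagged * usplit[2] * rate,
             funding_source = draw_source(),
             department_tag = NA_character_)
    ))
    oper_total <- indirect_resid * 0.4
    osplit <- rdirichlet1(c(3, 2, 2))
    items <- c(items, list(tibble(
      facility_id = id, category = "operational",
      description = c("electricity", "water", "maintenance"),
      annual_cost_etb = oper_total * osplit * rate,
      funding_source = "treasury",
      department_tag = NA_character_
    )))
  }
  items <- bind_rows(items)

  # (6) service outputs
  sv <- spec$services[[level]]
  total_services <- draw_lognorm(sv$meanlog, sv$sdlog)
  base <- spec$dept_shares[[level]]
  alpha <- ifelse(base > 0, base * 30, 0)
  sh <- numeric(length(base))
  pos <- alpha > 0
  sh[pos] <- rdirichlet1(alpha[pos])
  counts <- round(total_services * sh)
  outputs <- tibble(
    facility_id = id,
    department = CLINICAL_DEPARTMENTS,
    patients = counts
  ) %>% filter(.data$patients > 0)

  # (7) reported catchment
  ct <- spec$catchment[[level]]
  catchment <- round(draw_lognorm(ct$meanlog, ct$sdlog))

  area <- spec$regions$area_class[match(region, spec$regions$region)]
  list(
    facility = tibble(id = id, level = level, region = region,
                      area_class = area, reported_catchment = catchment),
    staff = staff, items = items, outputs = outputs
  )
}

# Per-facility truth components in US$, computed with plain loops directly
# from the generated micro-records (independent of the costing code path).
truth_components <- function(fac, staff, items, rate) {
  clin <- staff[staff$is_clinical, ]
  dept_labor <- setNames(numeric(5), CLINICAL_DEPARTMENTS)
  other_service <- 0
  admin_labor <- 0
  for (i in seq_len(nrow(clin))) {
    fr <- as.numeric(clin[i, unname(FRAC_COLS)])
    names(fr) <- names(FRAC_COLS)
    rem <- clin$annual_remuneration_etb[i] / rate
    if (!all(is.na(fr))) {  # health-post labor stays undistributed
      fr[is.na(fr)] <- 0
      for (d in CLINICAL_DEPARTMENTS) {
        dept_labor[d] <- dept_labor[[d]] + rem * fr[[d]]
      }
      other_service <- other_service + rem * fr[["OTHER_SERVICE"]]
      admin_labor <- admin_labor + rem * (fr[["ADMIN"]] + fr[["UNSPECIFIED"]])
    }
  }
  clin_remun <- sum(clin$annual_remuneration_etb) / rate
  nonclin_remun <- sum(staff$annual_remuneration_etb[!staff$is_clinical]) / rate
  ds <- items[items$category %in% c("drug", "medical_supply"), ]
  oper <- items[items$category == "operational", ]
  clinical_labor <- if (fac$level == "health_post") {
    clin_remun
  } else {
    sum(dept_labor) + other_service
  }
  indirect <- nonclin_remun + admin_labor + sum(oper$annual_cost_etb) / rate
  drugs_supplies <- sum(ds$annual_cost_etb) / rate
  tibble(
    id = fac$id, level = fac$level, region = fac$region,
    clinical_labor = clinical_labor,
    drugs_supplies = drugs_supplies,
    indirect = indirect,
    dept_labor = list(dept_labor),
    other_service = other_service,
    total = clinical_labor + drugs_supplies + indirect
  )
}

#' Generate a synthetic facility sample, region tables, and protocol bundle
#'
#' Deterministic given the spec seed. A single pseudo-random stream is used
#' with a fixed draw order: facilities in level order (health posts, health
#' centers, primary hospitals) and within level by index; for each facility,
#' component cost targets, staffing counts, remuneration weights, time-use
#' fractions, line items, service outputs, then reported catchment; then the
#' region-utilization jitters; then the protocol tables.
#'
#' Region utilization is constructed as the sampled department counts scaled
#' by the reciprocal of the level's sample-capture fraction, the scale-up
#' part jittered by a non-negative log-normal factor — so region utilization
#' is never below sampled utilization and expansion factors are at least 1.
#' Regions without sampled facilities at a level receive utilization scaled
#' from the sampled regions by population.
#'
#' @param spec a [generator_spec()].
#' @return a list of class `phc_sample`: `survey` (a `phc_survey` in ETB),
#'   `regions` (a `phc_regions`), `stp` (a `phc_stp`), and the `spec`.
#' @export
generate_sample <- function(spec = generator_spec()) {
  generate_internal(spec, truth = FALSE)$sample
}

#' Generate inputs with known ground truth
#'
#' Noise-free variant of [generate_sample()] for parameter-recovery tests:
#' region utilization is exactly the sample scaled by `1 / capture` (regions
#' without sampled facilities at a level carry none), so the network totals,
#' expansion factors, and capture fractions implied by construction are known
#' exactly.
#'
#' @param spec a [generator_spec()].
#' @return list with `sample` (as [generate_sample()]) and `truth`: tibbles
#'   `facilities` (per-facility US$ components computed by direct summation),
#'   `network` (per-level network totals), `expansion` (region-level factors),
#'   and `capture` (per-level capture percentages).
#' @export
generate_known_truth <- function(spec = generator_spec()) {
  spec$utilization_noise_sd <- 0
  generate_internal(spec, truth = TRUE)
}

generate_internal <- function(spec, truth = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  facs <- list(); staffs <- list(); itemss <- list(); outs <- list()
  truths <- list()
  for (level in PHC_LEVELS) {
    n <- spec$n_facilities[[level]]
    if (n == 0) next
    regions <- region_assignment(spec, level)
    for (i in seq_len(n)) {
      f <- build_facility(spec, level, i, regions[i])
      facs <- c(facs, list(f$facility))
      staffs <- c(staffs, list(f$staff))
      itemss <- c(itemss, list(f$items))
      outs <- c(outs, list(f$outputs))
      truths <- c(truths, list(
        truth_components(f$facility, f$staff, f$items, spec$exchange_rate)
      ))
    }
  }
  survey <- facility_survey(
    facilities = bind_rows(facs),
    staff = bind_rows(staffs),
    items = bind_rows(itemss),
    outputs = bind_rows(outs)
  )
  truth_fac <- bind_rows(truths)

  # region utilization: sample counts scaled by 1/capture (+ jitter)
  samp_util <- survey$outputs %>%
    left_join(survey$facilities %>% select("id", "level", "region"),
              by = c(facility_id = "id")) %>%
    group_by(.data$region, .data$level, .data$department) %>%
    summarise(sampled = sum(.data$patients), .groups = "drop")
  util_rows <- list()
  for (level in PHC_LEVELS) {
    cap <- spec$sample_capture[[level]]
    lv <- samp_util %>% filter(.data$level == !!level)
    if (nrow(lv) == 0) next
    jitter <- if (spec$utilization_noise_sd > 0) {
      rlnorm(nrow(lv), 0, spec$utilization_noise_sd)
    } else {
      rep(1, nrow(lv))
    }
    scaled <- lv %>%
      mutate(services = .data$sampled +
               (.data$sampled / cap - .data$sampled) * jitter) %>%
      select("region", "level", "department", "services")
    util_rows <- c(util_rows, list(scaled))
    if (!truth) {
      # regions without sampled facilities at this level
      sampled_regions <- unique(lv$region)
      missing <- setdiff(spec$regions$region, sampled_regions)
      if (length(missing) > 0) {
        per_capita_u <- scaled %>%
          left_join(spec$regions %>% select("region", "population"),
                    by = "region") %>%
          group_by(.data$department) %>%
          summarise(rate = sum(.data$services) / sum(.data$population),
                    .groups = "drop")
        for (rg in missing) {
          pop <- spec$regions$population[spec$regions$region == rg]
          jit <- rlnorm(nrow(per_capita_u), 0,
                        max(spec$utilization_noise_sd, 0.05))
          util_rows <- c(util_rows, list(tibble(
            region = rg, level = level,
            department = per_capita_u$department,
            services = per_capita_u$rate * pop * jit
          )))
        }
      }
    }
  }
  regions <- region_tables(
    regions = spec$regions %>% select("region", "population"),
    utilization = bind_rows(util_rows)
  )

  stp <- generate_stp(spec)

  sample <- structure(
    list(survey = survey, regions = regions, stp = stp, spec = spec),
    class = "phc_sample"
  )
  if (!truth) return(list(sample = sample))

  network <- truth_fac %>%
    group_by(.data$level) %>%
    summarise(across(c("clinical_labor", "drugs_supplies", "indirect",
                       "total"), sum), .groups = "drop") %>%
    mutate(capture = as.numeric(spec$sample_capture[.data$level]),
           across(c("clinical_labor", "drugs_supplies", "indirect", "total"),
                  ~ .x / .data$capture)) %>%
    select(-"capture")
  expansion <- truth_fac %>%
    distinct(.data$region, .data$level) %>%
    mutate(factor = 1 / as.numeric(spec$sample_capture[.data$level]))
  capture <- tibble(level = PHC_LEVELS,
                    capture_pct = 100 * as.numeric(spec$sample_capture))
  list(sample = sample,
       truth = list(facilities = truth_fac, network = network,
                    expansion = expansion, capture = capture))
}

generate_stp <- function(spec) {
  # small illustrative benefit package: a handful of services per level
  menu <- list(
    health_post = list(
      c("hp_opd_acute", "OPD", 1.00, 0.60), c("hp_malaria", "OPD", 1.00, 0.15),
      c("hp_anc", "MCH", 0.035, 1.00), c("hp_immunization", "MCH", 0.13, 1.00),
      c("hp_fp", "MCH", 0.24, 0.60), c("hp_hiv_test", "HIV", 0.50, 0.10)
    ),
    health_center = list(
      c("hc_opd_acute", "OPD", 1.00, 0.80), c("hc_tb", "OPD", 1.00, 0.02),
      c("hc_anc", "MCH", 0.035, 1.00), c("hc_delivery", "DEL", 0.032, 0.90),
      c("hc_art", "HIV", 0.009, 1.00), c("hc_ipd_minor", "IPDOR", 1.00, 0.01)
    ),
    primary_hospital = list(
      c("ph_opd_referral", "OPD", 1.00, 0.25), c("ph_anc_complicated", "MCH",
                                                 0.035, 0.25),
      c("ph_delivery_cemonc", "DEL", 0.032, 0.25), c("ph_art", "HIV", 0.009,
                                                     0.30),
      c("ph_surgery", "IPDOR", 1.00, 0.015), c("ph_ipd", "IPDOR", 1.00, 0.03)
    )
  )
  svc <- list(); cons <- list(); lab <- list()
  wages <- c(physician = 0.25, nurse = 0.10, midwife = 0.11, other = 0.06)
  for (level in PHC_LEVELS) {
    for (m in menu[[level]]) {
      sid <- m[1]; dept <- m[2]
      tpf <- as.numeric(m[3]); rate <- as.numeric(m[4])
      coverage <- runif(1, 0.7, 0.95)
      encounters <- sample(1:4, 1)
      svc <- c(svc, list(tibble(
        service_id = sid, level = level, department = dept,
        target_pop_fraction = tpf, rate = rate, coverage_target = coverage,
        encounters = encounters
      )))
      n_items <- sample(2:4, 1)
      cons <- c(cons, list(tibble(
        service_id = sid,
        item = paste0(sid, "_item", seq_len(n_items)),
        quantity = round(runif(n_items, 1, 3)),
        unit_price = round(runif(n_items, 0.2, 3.0), 2)
      )))
      cadres <- if (level == "primary_hospital") {
        c("physician", "nurse")
      } else if (level == "health_center") {
        c("nurse", "midwife")
      } else {
        c("other")
      }
      lab <- c(lab, list(tibble(
        service_id = sid, cadre = cadres,
        minutes = round(runif(length(cadres), 10, 30)),
        wage_per_minute = as.numeric(wages[cadres])
      )))
    }
  }
  stp_tables(bind_rows(svc), bind_rows(cons), bind_rows(lab))
}

#' Write a generated bundle to CSV files
#'
#' Writes the full relational CSV bundle (survey, regions, utilization,
#' protocol tables) and, when truth is supplied, `truth.json`.
#'
#' @param sample a `phc_sample` (or the list returned by
#'   [generate_known_truth()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample_bundle <- function(sample, dir) {
  truth <- NULL
  if (!inherits(sample, "phc_sample") && !is.null(sample$sample)) {
    truth <- sample$truth
    sample <- sample$sample
  }
  stopifnot(inherits(sample, "phc_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_facility_survey(sample$survey, dir)
  readr::write_csv(sample$regions$regions, file.path(dir, "regions.csv"))
  readr::write_csv(sample$regions$utilization,
                   file.path(dir, "utilization.csv"))
  readr::write_csv(sample$stp$services, file.path(dir, "stp.csv"))
  readr::write_csv(sample$stp$consumables, file.path(dir, "consumables.csv"))
  readr::write_csv(sample$stp$labor, file.path(dir, "labor.csv"))
  if (!is.null(truth)) {
    tf <- truth$facilities
    tf$dept_labor <- NULL
    jsonlite::write_json(
      list(facilities = tf, network = truth$network,
           expansion = truth$expansion, capture = truth$capture),
      file.path(dir, "truth.json"),
      dataframe = "rows", digits = NA
    )
  }
  invisible(dir)
}
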