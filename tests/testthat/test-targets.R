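test_that("Wilson tolerance intervals match prop.test and limit behaviour", {
  ti <- tolerance_intervals(0.0032, 40674)
  expect_equal(ti$lower_final, 0.00272, tolerance = 1e-2)
  expect_equal(ti$upper_final, 0.00377, tolerance = 1e-2)
  # independent route: prop.test without continuity correction
  pt <- stats::prop.test(130, 40674, correct = FALSE)$conf.int
  ti2 <- tolerance_intervals(130 / 40674, 40674)
  expect_equal(ti2$lower_final, pt[1], tolerance = 1e-10)
  expect_equal(ti2$upper_final, pt[2], tolerance = 1e-10)
  # vanishing standard error collapses the final interval onto the value
  big <- tolerance_intervals(0.5, 1e12)
  expect_equal(big$lower_final, 0.5, tolerance = 1e-5)
  expect_equal(big$upper_final, 0.5, tolerance = 1e-5)
  # no inflation: the initial interval equals the final interval
  ti3 <- tolerance_intervals(0.3, 500, inflation = 1)
  expect_equal(ti3$lower_init, ti3$lower_final)
  expect_equal(ti3$upper_init, ti3$upper_final)
  expect_error(tolerance_intervals(0.5, 0), "positive")
})

test_that("target tables validate interval nesting and round-trip as CSV", {
  tg <- target_set(c("a", "b"), c(0.2, 0.4), c(100, 200), c("s1", "s1"))
  expect_true(all(tg$lower_init <= tg$lower_final))
  expect_true(all(tg$upper_final <= tg$upper_init))
  f <- withr::local_tempfile(fileext = ".csv")
  write_targets_csv(tg, f)
  tg2 <- read_targets_csv(f)
  expect_equal(as.data.frame(tg2), as.data.frame(tg))
  expect_error(target_set("a", 0.9, 100, "s1",
                          intervals = tibble::tibble(
                            lower_init = 0, upper_init = 1,
                            lower_final = 0.1, upper_final = 0.2)),
               "observed_value")
})

test_that("size bins use the half-open operationalisation", {
  expect_equal(as.character(crcabc:::size_bin(c(4, 5.5, 9.4, 9.5, 30))),
               c("small", "medium", "medium", "large", "large"))
})

test_that("the MC-error guard flags unresolvable targets", {
  tg <- target_set("a", 0.003, 20000, "s1")
  chk <- check_target_mc_error(tg, c(s1 = 500))
  expect_false(chk$ok)
  chk2 <- check_target_mc_error(tg, c(s1 = 5e6))
  expect_true(chk2$ok)
})

test_that("simulated target statistics are consistent and invariant", {
  sc <- make_default_scenario(seed = 5)
  p <- sc$truth
  spc <- study_spec("col", 1500, 50, 75, 0.5, "colonoscopy")
  pop <- simulate_population(spc, p, seed = 99)
  st <- crcabc:::prevalence_from_population(pop)
  pct <- st$value[grep("^pct_", st$name)]
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  det <- crcabc:::screen_detection_from_population(pop)
  r <- det$value[match(c("screen_detect_men", "screen_detect_women",
                         "screen_detect_overall"), det$name)]
  expect_gte(r[3], min(r[1:2]))
  expect_lte(r[3], max(r[1:2]))
  # overall equals the person-weighted mean of the sex-specific rates
  expect_equal(r[3], stats::weighted.mean(r[1:2], det$n[1:2]))
  # partitioning the same covariate roster into two batches (with the
  # matching agent-index offsets) reproduces the full run exactly
  cov <- crcabc:::spec_covariates(spc)
  m <- sensitivity_model()
  lt <- life_table()
  run_batch <- function(rows, offset) {
    crcabc:::.simulate_population_cpp(
      unlist(unclass(p)), cov$female[rows], cov$index_age[rows], 0.25,
      lt$breaks, lt$hazards, lt$max_age, 1L,
      m$anchors$size, m$anchors$sensitivity, m$preclin_floor,
      m$sigmoid_colon_reach, 100, 99, as.integer(offset))
  }
  raw_a <- run_batch(1:750, 0)
  raw_b <- run_batch(751:1500, 750)
  expect_equal(c(raw_a$clinical_age, raw_b$clinical_age),
               pop$agents$clinical_age)
  expect_equal(c(raw_a$n_det_preclin, raw_b$n_det_preclin),
               pop$agents$n_det_preclin)
  expect_equal(c(raw_a$lesion_size, raw_b$lesion_size), pop$lesions$size)
})

test_that("overall trial detection rate is the person-weighted combination", {
  expect_equal(round(combine_rates(c(0.0046, 0.0017), c(20519, 20155)), 4),
               0.0032)
  expect_equal(combine_rates(c(0.3, 0.3), c(10, 99)), 0.3)
})

test_that("incidence target matches a straight-loop reference simulation", {
  sc <- make_default_scenario(seed = 5)
  p <- sc$truth
  spc <- study_spec("inc", 4000, 55, 80, 0.5, "none")
  bands <- tibble::tibble(name = "all", lower = 55, upper = 80)
  fast <- simulate_incidence_target(spc, p, seed = 7, age_bands = bands)
  # independent straight-loop re-implementation via the R reference agent
  cov <- crcabc:::spec_covariates(spc)
  set.seed(1234)
  n_el <- 0; n_ev <- 0
  for (i in seq_len(spc$n_agents)) {
    h <- simulate_agent(cov$female[i], p)
    if (h$death_age > cov$index_age[i] && h$clinical_age > cov$index_age[i]) {
      n_el <- n_el + 1
      if (h$clinical_age <= cov$index_age[i] + 1) n_ev <- n_ev + 1
    }
  }
  ref_rate <- 1e5 * n_ev / n_el
  pr <- (fast$n_events + n_ev) / (fast$n_eligible + n_el)
  se <- 1e5 * sqrt(pr * (1 - pr) * (1 / fast$n_eligible + 1 / n_el))
  expect_lt(abs(fast$value - ref_rate), 3 * se)
  # degenerate cases
  p0 <- nh_params(A = -50)
  z <- simulate_incidence_target(spc, p0, seed = 7, age_bands = bands)
  expect_equal(z$value, 0)
})
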