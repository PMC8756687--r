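test_that("effective sample size identities hold", {
  expect_equal(ess(rep(0.2, 5)), 5)
  expect_equal(ess(rep(1, 100)), 100)
  w <- c(1, rep(1e-12, 50))
  expect_lt(ess(w), 1.01)
  for (i in 1:10) {
    w <- stats::runif(20)
    expect_gte(ess(w), 1)
    expect_lte(ess(w), 20)
    # invariant to rescaling
    expect_equal(ess(w), ess(7 * w))
  }
})

test_that("prior sampling and density agree for both families", {
  pr <- prior_spec(c("u", "t"), c("uniform", "truncnorm"),
                   mean = c(NA, 1), sd = c(NA, 0.5),
                   lower = c(0, 0), upper = c(2, 2))
  set.seed(1)
  th <- sample_prior(pr, 5000)
  expect_true(all(th$u >= 0 & th$u <= 2))
  expect_true(all(th$t >= 0 & th$t <= 2))
  # truncated-normal mean by quadrature
  f <- function(x) x * stats::dnorm(x, 1, 0.5) /
    (stats::pnorm(2, 1, 0.5) - stats::pnorm(0, 1, 0.5))
  m <- stats::integrate(f, 0, 2)$value
  expect_lt(abs(mean(th$t) - m), 3 * stats::sd(th$t) / sqrt(5000))
  lp <- log_prior_density(pr, tibble::tibble(u = c(1, 3), t = c(1, 1)))
  expect_equal(lp[1], -log(2) + stats::dnorm(1, 1, 0.5, log = TRUE) -
                 log(stats::pnorm(2, 1, 0.5) - stats::pnorm(0, 1, 0.5)))
  expect_identical(lp[2], -Inf)
})

test_that("initialisation from the prior accepts at the analytic rate", {
  pr <- prior_spec("x", "uniform", lower = 0, upper = 1)
  tg <- manual_target("x", 0.5, 0, 1, 0.4, 0.6)
  # with the current interval at (0.4, 0.6) at init, acceptance is 0.2
  tg$lower_init <- 0.4; tg$upper_init <- 0.6
  cfg <- imabc_config(n_init = 1e4, target_ess = 1e9, max_iterations = 0,
                      mc_guard = "off")
  st <- init_from_prior(pr, tg, identity_simulator, cfg, seed = 3)
  frac <- nrow(st$draws) / 1e4
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 1e4))
  expect_equal(st$ess, nrow(st$draws))  # uniform weights at init
  # impossible intervals error out
  tg2 <- manual_target("x", 0.5, 0.4, 0.6, 0.4, 0.6)
  tg2$lower_init <- 2; tg2$upper_init <- 3
  tg2$lower_final <- 2; tg2$upper_final <- 3
  tg2$observed_value <- 2.5
  expect_error(init_from_prior(pr, tg2, identity_simulator, cfg, seed = 3),
               "no prior draws")
})

test_that("importance weights are prior over proposal, zeroed outside bands", {
  pr <- prior_spec("x", "uniform", lower = 0, upper = 1)
  tg <- manual_target("x", 0.5, 0, 1, 0.4, 0.6)
  cfg <- imabc_config(n_init = 200, target_ess = 1e9, max_iterations = 0,
                      mc_guard = "off")
  st <- init_from_prior(pr, tg, identity_simulator, cfg, seed = 5)
  # proposal is the prior: weights uniform
  expect_true(all(abs(st$weights - 1 / nrow(st$draws)) < 1e-12))
  # shrinking to the final band zeroes draws outside it before pruning
  st2 <- shrink_intervals(st)
  expect_true(all(st2$sim_values$x >= st2$targets$current_lower &
                  st2$sim_values$x <= st2$targets$current_upper))
  expect_equal(sum(st2$weights), 1)
})

test_that("mixture components centre on the highest-weight accepted draws", {
  pr <- prior_spec(c("a", "b"), "uniform", lower = c(0, 0), upper = c(1, 1))
  tg <- manual_target("s", 1, 0, 2, 0.8, 1.2)
  cfg <- imabc_config(n_init = 300, target_ess = 1e9, max_iterations = 0,
                      n_centers = 2, mc_guard = "off")
  st <- init_from_prior(pr, tg, quad_simulator, cfg, seed = 9)
  st2 <- add_mixture_components(st, 2)
  gauss <- Filter(function(s) s$type == "gaussian", st2$stages)
  expect_length(gauss, 2)
  theta <- crcabc:::state_theta(st)
  for (g in gauss) {
    # centres coincide with accepted draw locations
    d <- apply(theta, 1, function(r) sum(abs(r - g$center)))
    expect_lt(min(d), 1e-12)
    expect_true(all(eigen(g$cov, symmetric = TRUE)$values > 0))
  }
  # proposal density is higher at a centre than far away
  st2$stages[[2]]$n_sampled <- 100
  c1 <- gauss[[1]]$center
  far <- c1 + 10
  ld <- crcabc:::log_proposal_density(
    st2, rbind(c1, far))
  expect_gt(ld[1], ld[2])
})

test_that("interval narrowing honours the retained-draw floor", {
  pr <- prior_spec("x", "uniform", lower = 0, upper = 1)
  tg <- manual_target("x", 0.5, 0, 1, 0.499, 0.501)
  cfg <- imabc_config(n_init = 500, target_ess = 1e9, max_iterations = 0,
                      shrink_factor = 1, min_draws_retained = 50,
                      mc_guard = "off")
  st <- init_from_prior(pr, tg, identity_simulator, cfg, seed = 11)
  st2 <- shrink_intervals(st)
  # jumping straight to the final band would keep ~1 draw: step is skipped
  expect_equal(st2$shrink_skipped, "x")
  expect_equal(st2$targets$current_lower, 0)
  # with a reachable band, a unit step lands exactly on the final interval
  tg3 <- manual_target("x", 0.5, 0, 1, 0.3, 0.7)
  st3 <- init_from_prior(pr, tg3, identity_simulator, cfg, seed = 11)
  st4 <- shrink_intervals(st3)
  expect_equal(st4$targets$current_lower, 0.3)
  expect_equal(st4$targets$current_upper, 0.7)
  # fixed point: shrinking at the final interval changes nothing
  st5 <- shrink_intervals(st4)
  expect_equal(st5$targets$current_lower, 0.3)
})

test_that("calibration matches the analytic ABC posterior on the toy", {
  pr <- prior_spec("x", "uniform", lower = 0, upper = 1)
  tg <- manual_target("x", 0.5, 0.1, 0.9, 0.45, 0.55)
  cfg <- imabc_config(n_init = 1500, n_centers = 3, batch_size = 100,
                      target_ess = 500, max_iterations = 30,
                      mc_guard = "off")
  st <- run_calibration(pr, tg, identity_simulator, cfg, seed = 17)
  expect_true(st$converged)
  expect_gte(st$ess, 500)
  expect_true(all(st$sim_values$x >= 0.45 & st$sim_values$x <= 0.55))
  # weighted posterior CDF vs the truncated prior (uniform on the band)
  ks <- weighted_ks(st$draws$x, st$weights,
                    function(x) pmin(1, pmax(0, (x - 0.45) / 0.1)))
  expect_lt(ks, 0.05)
})

test_that("a satisfied target short-circuits without mixture iterations", {
  pr <- prior_spec("x", "uniform", lower = 0, upper = 1)
  tg <- manual_target("x", 0.5, 0, 1, 0.2, 0.8)
  cfg <- imabc_config(n_init = 400, target_ess = 100, max_iterations = 30,
                      mc_guard = "off")
  st <- run_calibration(pr, tg, identity_simulator, cfg, seed = 19)
  expect_true(st$converged)
  expect_equal(st$iteration, 0L)
  expect_equal(st$sim_calls, 400)
  # ESS target 1 converges immediately as well
  cfg1 <- imabc_config(n_init = 5, target_ess = 1, max_iterations = 30,
                       mc_guard = "off")
  st1 <- run_calibration(pr, tg, identity_simulator, cfg1, seed = 19)
  expect_true(st1$converged)
})

test_that("unconverged runs are flagged, not silently truncated", {
  pr <- prior_spec("x", "uniform", lower = 0, upper = 1)
  tg <- manual_target("x", 0.5, 0.1, 0.9, 0.45, 0.55)
  cfg <- imabc_config(n_init = 200, target_ess = 1e5, max_iterations = 2,
                      mc_guard = "off")
  st <- run_calibration(pr, tg, identity_simulator, cfg, seed = 23)
  expect_false(st$converged)
  expect_equal(st$iteration, 2L)
})

test_that("warm start with vacuous new targets changes nothing material", {
  pr <- prior_spec("x", "uniform", lower = 0, upper = 1)
  tg <- manual_target("x", 0.5, 0.1, 0.9, 0.4, 0.6)
  cfg <- imabc_config(n_init = 1000, n_centers = 3, batch_size = 80,
                      target_ess = 150, max_iterations = 30, mc_guard = "off")
  two_sim <- function(theta, seeds, target_names) {
    tibble::tibble(x = theta[[1]], x2 = theta[[1]])[, target_names,
                                                    drop = FALSE]
  }
  st <- run_calibration(pr, tg, two_sim, cfg, seed = 29)
  expect_true(st$converged)
  z <- manual_target("x2", 0.5, -Inf, Inf, -Inf, Inf)
  st2 <- warm_start_recalibration(st, z, two_sim)
  expect_true(st2$converged)
  expect_equal(st2$draws$x, st$draws$x)
  expect_equal(st2$weights, st$weights)
  expect_true("x2" %in% names(st2$sim_values))
  # disjointness and degenerate-restart errors
  expect_error(warm_start_recalibration(st, tg, two_sim), "disjoint")
  z_bad <- manual_target("x2", 0.99, 0.98, 1, 0.985, 0.995)
  expect_error(warm_start_recalibration(st, z_bad, two_sim), "no stored draw")
})

test_that("the acceptance invariant holds through a full run", {
  pr <- prior_spec(c("a", "b"), "uniform", lower = c(0, 0), upper = c(1, 1))
  tg <- manual_target(c("s", "d"), c(1, 0.05), c(0, 0), c(2, 1),
                      c(0.9, 0), c(1.1, 0.1))
  cfg <- imabc_config(n_init = 800, n_centers = 3, batch_size = 80,
                      target_ess = 200, max_iterations = 30, mc_guard = "off")
  st <- run_calibration(pr, tg, quad_simulator, cfg, seed = 31)
  expect_true(st$converged)
  v <- as.matrix(st$sim_values[, c("s", "d")])
  expect_true(all(v[, 1] >= 0.9 & v[, 1] <= 1.1))
  expect_true(all(v[, 2] >= 0 & v[, 2] <= 0.1))
  expect_equal(sum(st$weights), 1)
})

test_that("states save, load and resume bit-for-bit", {
  pr <- prior_spec("x", "uniform", lower = 0, upper = 1)
  tg <- manual_target("x", 0.5, 0.1, 0.9, 0.45, 0.55)
  cfg_stop <- imabc_config(n_init = 600, n_centers = 3, batch_size = 80,
                           target_ess = 400, max_iterations = 2,
                           mc_guard = "off")
  cfg_full <- imabc_config(n_init = 600, n_centers = 3, batch_size = 80,
                           target_ess = 400, max_iterations = 20,
                           mc_guard = "off")
  st_partial <- run_calibration(pr, tg, identity_simulator, cfg_stop, seed = 37)
  f <- withr::local_tempfile(fileext = ".json")
  save_state(st_partial, f)
  st_re <- load_state(f)
  expect_equal(st_re$draws$x, st_partial$draws$x)
  expect_equal(st_re$weights, st_partial$weights, tolerance = 1e-12)
  st_re$config <- cfg_full
  resumed <- resume_calibration(st_re, identity_simulator)
  full <- run_calibration(pr, tg, identity_simulator, cfg_full, seed = 37)
  expect_true(resumed$converged && full$converged)
  expect_equal(resumed$draws$x, full$draws$x)
  expect_equal(resumed$weights, full$weights, tolerance = 1e-10)
  expect_equal(resumed$sim_calls, full$sim_calls)
})
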