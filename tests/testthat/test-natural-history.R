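test_that("log adenoma risk follows the piecewise-linear form", {
  p <- nh_params(alpha20 = 0.03, alpha50 = 0.01, alpha60 = 0, alpha70 = 0)
  # all age terms vanish at 20; female effect is additive
  expect_equal(adenoma_log_risk(20, 0, p$A, p), p$A)
  expect_equal(adenoma_log_risk(20, 1, p$A, p), p$A + p$alpha1)
  # hand-evaluated piecewise sum at age 55
  expect_equal(adenoma_log_risk(55, 0, -6, p), -6 + 30 * 0.03 + 5 * 0.01)
  # independent scalar evaluation of the same form on a grid
  ref <- function(a, f, a0, q) {
    if (a < 20) return(-Inf)
    a0 + q$alpha1 * f + min(a - 20, 30) * q$alpha20 +
      max(min(a - 50, 10), 0) * q$alpha50 +
      max(min(a - 60, 10), 0) * q$alpha60 + max(a - 70, 0) * q$alpha70
  }
  q <- nh_params(alpha20 = 0.04, alpha50 = -0.01, alpha60 = 0.02,
                 alpha70 = 0.005)
  for (a in c(0, 19.9, 20, 35, 50, 57, 60, 66, 70, 85, 100)) {
    expect_equal(adenoma_log_risk(a, 1, -4.5, q), ref(a, 1, -4.5, q))
  }
  expect_identical(adenoma_log_risk(19, 0, p$A, p), -Inf)
})

test_that("Frechet CDF, quantile and sampler agree", {
  expect_equal(frechet_cdf(10, 2, 10), exp(-1))
  expect_equal(frechet_cdf(0, 2, 10), 0)
  expect_equal(frechet_cdf(1e9, 2, 10), 1, tolerance = 1e-6)
  # median by inversion
  expect_equal(frechet_quantile(0.5, 2, 10), 10 * log(2)^(-1 / 2),
               tolerance = 1e-12)
  expect_error(frechet_cdf(1, -1, 10))
  # sampler-vs-CDF agreement: KS below the 1% critical value at n = 1e5
  p <- nh_params(beta1_colon = 2, beta2_colon = 10)
  set.seed(11)
  x <- sample_t10mm(rep("colon", 1e5), p)
  ks <- suppressWarnings(stats::ks.test(x, function(t) frechet_cdf(t, 2, 10)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e5))
})

test_that("Richards growth endpoints and the solved growth rate are exact", {
  for (pg in c(0.5, 1, 2.7)) {
    p <- nh_params(p_growth = pg)
    lam <- solve_growth_rate(8, p)
    expect_gt(lam, 0)
    expect_equal(richards_diameter(0, lam, p), 1, tolerance = 1e-9)
    expect_equal(richards_diameter(1e6, lam, p), 50, tolerance = 1e-9)
    expect_equal(richards_diameter(8, lam, p), 10, tolerance = 1e-9)
    # rate scales as 1 / t_10mm
    expect_equal(solve_growth_rate(16, p), lam / 2, tolerance = 1e-12)
    # strictly increasing trajectory within [d0, d_infinity)
    d <- richards_diameter(seq(0, 60, by = 0.5), lam, p)
    expect_true(all(diff(d) > 0))
    expect_true(all(d >= 1 - 1e-9 & d < 50))
  }
  expect_equal(solve_growth_rate(1, nh_params(p_growth = 1)),
               -log(0.8 / 0.98), tolerance = 1e-9)
  expect_error(solve_growth_rate(1, nh_params(d0 = 12)), "d0")
})

test_that("transition size follows the lognormal with the age-decade coding", {
  p0 <- nh_params(gamma0 = 2, gamma1 = 0, gamma2 = 0, gamma3 = 0,
                  gamma4 = 0, gamma5 = 0, sigma_gamma = 0)
  expect_equal(sample_transition_size(0, 0, 50, p0), exp(2))
  # Monte-Carlo mean matches the lognormal mean identity
  p1 <- nh_params(gamma0 = 2, gamma1 = 0, gamma2 = 0, gamma3 = 0,
                  gamma4 = 0, gamma5 = 0, sigma_gamma = 0.5)
  set.seed(21)
  x <- sample_transition_size(rep(0, 1e5), 0, 50, p1)
  mu_true <- exp(2 + 0.25 / 2)
  se <- sqrt((exp(0.25) - 1)) * mu_true / sqrt(1e5)
  expect_lt(abs(mean(x) - mu_true), 3 * se)
  # covariate coding: age in decades centred at 50
  p2 <- nh_params(gamma0 = 2, gamma4 = -0.1, gamma5 = 0.02, sigma_gamma = 0)
  expect_equal(sample_transition_size(0, 0, 70, p2),
               exp(2 - 0.1 * 2 + 0.02 * 4))
})

test_that("transition probability increases with attainable diameter", {
  p <- nh_params()
  set.seed(31)
  tsize <- sample_transition_size(rep(0, 2e4), 0, 55, p)
  frac <- vapply(c(5, 10, 20, 35, 49.9), function(dmax) mean(tsize <= dmax),
                 numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("sojourn sampler matches its Weibull law and closed-form mean", {
  p <- nh_params(lambda1 = 3.77, lambda2 = 2.38, lambda3 = 0.87)
  # survival at t = scale is exp(-1)
  set.seed(41)
  x <- sample_sojourn_time(rep("colon", 1e5), p)
  expect_equal(mean(x > 3.77), exp(-1), tolerance = 0.01)
  ks <- suppressWarnings(stats::ks.test(x, stats::pweibull,
                                        shape = 2.38, scale = 3.77))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e5))
  # closed-form MST values
  expect_equal(mean_sojourn_time(p, "colon"), 3.77 * gamma(1 + 1 / 2.38))
  expect_equal(mean_sojourn_time(p, "colon"), 3.342, tolerance = 1e-3)
  expect_equal(mean_sojourn_time(p, "rectum"),
               mean_sojourn_time(p, "colon") * exp(0.87))
  expect_equal(mean_sojourn_time(p, "rectum"), 7.98, tolerance = 1e-2)
  # zero location effect: identical distributions
  p0 <- nh_params(lambda3 = 0)
  expect_equal(mean_sojourn_time(p0, "rectum"), mean_sojourn_time(p0, "colon"))
  # MC mean within 3 standard errors, both locations
  for (loc in c("colon", "rectum")) {
    set.seed(43)
    x <- sample_sojourn_time(rep(loc, 1e5), p)
    expect_lt(abs(mean(x) - mean_sojourn_time(p, loc)),
              3 * stats::sd(x) / sqrt(1e5))
  }
  # increasing the scale stochastically increases draws (shared stream)
  set.seed(47)
  a <- sample_sojourn_time(rep("colon", 1000), nh_params(lambda1 = 3))
  set.seed(47)
  b <- sample_sojourn_time(rep("colon", 1000), nh_params(lambda1 = 4))
  expect_true(all(b > a))
})

test_that("initiation process matches the integrated intensity", {
  # homogeneous special case: flat risk 0.1/yr from 20 to 70
  p <- nh_params(A = log(0.1), sigma_alpha = 0, alpha1 = 0, alpha20 = 0,
                 alpha50 = 0, alpha60 = 0, alpha70 = 0)
  set.seed(51)
  counts <- replicate(400, nrow(sample_adenoma_initiations(0, log(0.1), p,
                                                           horizon = 70)))
  expect_lt(abs(mean(counts) - 5), 3 * stats::sd(counts) / sqrt(400))
  # zero risk before 20
  expect_equal(nrow(sample_adenoma_initiations(0, log(0.1), p, horizon = 20)), 0)
  # piecewise intensity vs quadrature of the integrated risk
  q <- nh_params(A = -4, sigma_alpha = 0, alpha20 = 0.05, alpha50 = 0,
                 alpha60 = 0, alpha70 = 0)
  lam <- stats::integrate(function(a) exp(adenoma_log_risk(a, 0, -4, q)),
                          20, 70)$value
  set.seed(53)
  counts <- replicate(400, nrow(sample_adenoma_initiations(0, -4, q,
                                                           horizon = 70)))
  expect_lt(abs(mean(counts) - lam), 3 * stats::sd(counts) / sqrt(400))
})

test_that("life table draws respect the piecewise hazards and the cap", {
  lt <- life_table()
  set.seed(61)
  d <- sample_death_age(2e4, lt)
  expect_true(all(d > 0 & d <= 100))
  # survival to 60 matches exp(-H(60))
  H60 <- sum(c(40, 10, 10) * lt$hazards[1:3])
  expect_equal(mean(d > 60), exp(-H60), tolerance = 0.015)
  # conditioning on survival shifts support
  d2 <- sample_death_age(1000, lt, min_age = 55)
  expect_true(all(d2 > 55))
})

test_that("single-agent histories respect the event plumbing", {
  p <- nh_params()
  # no risk: no adenomas
  p_none <- nh_params(A = -50)
  set.seed(71)
  h <- simulate_agent(0, p_none)
  expect_equal(nrow(h$adenomas), 0)
  expect_identical(h$clinical_age, Inf)
  # transition size far above the maximum diameter: no transitions ever
  p_big <- nh_params(A = -3, gamma0 = log(1000), sigma_gamma = 0)
  set.seed(72)
  h <- simulate_agent(0, p_big)
  expect_true(all(is.na(h$adenomas$transition_age)))
  # clinical age is transition age plus sojourn for each lesion
  set.seed(73)
  for (i in 1:20) {
    h <- simulate_agent(1, nh_params(A = -3))
    a <- h$adenomas[!is.na(h$adenomas$transition_age), ]
    if (nrow(a)) {
      expect_equal(a$clinical_age, a$transition_age + a$sojourn_time)
    }
    if (is.finite(h$clinical_age)) {
      expect_lt(h$clinical_age, min(h$death_age, 100))
    }
  }
  expect_s3_class(tidy(h), "tbl_df")
})
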