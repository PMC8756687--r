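test_that("weighted quantiles invert the right-continuous weighted CDF", {
  s <- posterior_sample(tibble::tibble(x = 1:100))
  expect_equal(unname(credible_interval(s, "x", 0.95)), c(3, 98))
  # point mass
  s0 <- posterior_sample(tibble::tibble(x = rep(4, 5)))
  expect_equal(unname(credible_interval(s0, "x")), c(4, 4))
  # invariant to weight rescaling
  x <- stats::rnorm(50)
  w <- stats::runif(50)
  a <- credible_interval(tibble::tibble(x = x, weight = w / sum(w)), "x")
  b <- credible_interval(tibble::tibble(x = x, weight = 5 * w), "x")
  expect_equal(a, b)
})

test_that("credible-interval overlap reproduces its defining cases", {
  expect_equal(ci_overlap(c(1, 2), c(1, 2)), 1)
  expect_equal(ci_overlap(c(0, 1), c(2, 3)), 0)
  # symmetry and affine invariance
  i1 <- c(0.3, 1.9); i2 <- c(1.1, 2.5)
  expect_equal(ci_overlap(i1, i2), ci_overlap(i2, i1))
  expect_equal(ci_overlap(10 + 2 * i1, 10 + 2 * i2), ci_overlap(i1, i2))
  # hand-checked value: intersection (1.1, 1.9)
  expect_equal(ci_overlap(i1, i2), 0.5 * 0.8 / 1.6 + 0.5 * 0.8 / 1.4)
  expect_error(ci_overlap(c(1, 1), c(0, 2)), "degenerate")
})

test_that("density overlap and Hellinger match Gaussian closed forms", {
  set.seed(101)
  a <- posterior_sample(tibble::tibble(x = stats::rnorm(4000)))
  b <- posterior_sample(tibble::tibble(x = stats::rnorm(4000, 1)))
  # overlap of N(0,1) and N(1,1) is 2*pnorm(-1/2)
  expect_equal(area_overlap(a, b, "x"), 2 * stats::pnorm(-0.5),
               tolerance = 0.03)
  expect_equal(hellinger_distance(a, b, "x"), sqrt(1 - exp(-1 / 8)),
               tolerance = 0.03)
  # self-comparison and disjoint supports
  expect_gt(area_overlap(a, a, "x"), 0.98)
  expect_lt(hellinger_distance(a, a, "x"), 0.02)
  far <- posterior_sample(tibble::tibble(x = stats::rnorm(4000, 100)))
  expect_lt(area_overlap(a, far, "x"), 0.01)
  expect_gt(hellinger_distance(a, far, "x"), 0.99)
  expect_error(area_overlap(
    posterior_sample(tibble::tibble(x = rep(1, 20))), a, "x"), "degenerate")
})

test_that("overlap and Hellinger are permutation- and scale-invariant", {
  set.seed(103)
  x <- stats::rnorm(500); w <- stats::runif(500)
  y <- stats::rnorm(500, 0.3)
  s1 <- tibble::tibble(x = x, weight = w / sum(w))
  s2 <- tibble::tibble(x = y, weight = rep(1 / 500, 500))
  perm <- sample(500)
  s1p <- tibble::tibble(x = x[perm], weight = (w / sum(w))[perm])
  s1w <- tibble::tibble(x = x, weight = 3 * w)
  expect_equal(area_overlap(s1, s2, "x"), area_overlap(s1p, s2, "x"))
  expect_equal(hellinger_distance(s1, s2, "x"),
               hellinger_distance(s1w, s2, "x"))
  # near-identical distributions: overlap ~ 1 iff hellinger ~ 0
  expect_gt(area_overlap(s1, s1w, "x"), 0.98)
  expect_lt(hellinger_distance(s1, s1w, "x"), 0.02)
})

test_that("standardized mean difference uses weighted reference moments", {
  s1 <- tibble::tibble(x = c(1, 2, 3, 4, 5), weight = c(0.1, 0.2, 0.4, 0.2, 0.1))
  s2 <- tibble::tibble(x = c(2, 3, 4, 5, 6), weight = c(0.1, 0.2, 0.4, 0.2, 0.1))
  m1 <- sum(s1$x * s1$weight)
  sd1 <- sqrt(sum(s1$weight * (s1$x - m1)^2))
  expect_equal(standardized_mean_difference(s1, s2, "x"), 1 / sd1)
  expect_equal(standardized_mean_difference(s1, s1, "x"), 0)
  # a shift of exactly one reference sd gives 1
  s3 <- tibble::tibble(x = s1$x + sd1, weight = s1$weight)
  expect_equal(standardized_mean_difference(s1, s3, "x"), 1)
  expect_error(standardized_mean_difference(
    tibble::tibble(x = rep(1, 5), weight = rep(0.2, 5)), s2, "x"), "zero")
})

test_that("posterior mean sojourn time transforms draws, not means", {
  single <- posterior_sample(tibble::tibble(lambda1 = 3.77, lambda2 = 2.38,
                                            lambda3 = 0.87))
  m <- mst_posterior(single)
  expect_equal(m$mean[m$location == "colon"], 3.342, tolerance = 1e-3)
  expect_equal(m$mean[m$location == "rectum"], 7.98, tolerance = 1e-2)
  # zero location effect: identical colon and rectum distributions
  set.seed(107)
  s0 <- posterior_sample(tibble::tibble(lambda1 = stats::runif(100, 2, 5),
                                        lambda2 = stats::runif(100, 1.5, 3),
                                        lambda3 = 0))
  m0 <- mst_posterior(s0)
  expect_equal(m0$mean[1], m0$mean[2])
  # Jensen check on a dispersed sample: mean of transform != transform of mean
  set.seed(109)
  disp <- posterior_sample(tibble::tibble(
    lambda1 = stats::runif(100, 1, 8), lambda2 = stats::runif(100, 1.2, 4),
    lambda3 = stats::rnorm(100, 0.5, 0.5)))
  md <- mst_posterior(disp)
  w <- disp$weight
  at_mean <- mean_sojourn_time(nh_params(
    lambda1 = sum(w * disp$lambda1), lambda2 = sum(w * disp$lambda2),
    lambda3 = sum(w * disp$lambda3)), "rectum")
  brute <- sum(w * disp$lambda1 * exp(disp$lambda3) *
                 gamma(1 + 1 / disp$lambda2))
  expect_equal(md$mean[md$location == "rectum"], brute)
  expect_gt(brute, at_mean)  # convexity in lambda3 pushes the draw-mean up
  expect_error(mst_posterior(posterior_sample(
    tibble::tibble(lambda1 = -1, lambda2 = 2, lambda3 = 0))), "non-positive")
})

test_that("compare_posteriors emits the four metrics per parameter", {
  set.seed(113)
  s1 <- posterior_sample(tibble::tibble(a = stats::rnorm(500),
                                        b = stats::rnorm(500, 2)), label = "one")
  s2 <- posterior_sample(tibble::tibble(a = stats::rnorm(500, 0.2),
                                        b = stats::rnorm(500, 2.1)), label = "two")
  cmp <- compare_posteriors(s1, s2)
  expect_equal(cmp$parameter, c("a", "b"))
  expect_named(cmp, c("parameter", "ci_overlap", "area_overlap", "smd",
                      "hellinger"))
  expect_true(all(cmp$ci_overlap >= 0 & cmp$ci_overlap <= 1))
  expect_true(all(cmp$hellinger >= 0 & cmp$hellinger <= 1))
  p <- autoplot(s1, s2, parameter = "a")
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_comparison(cmp), "ggplot")
})
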