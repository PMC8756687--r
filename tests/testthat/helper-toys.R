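# shared toy fixtures for engine tests

# identity simulator: one parameter x, reported directly as target "x"
identity_simulator <- function(theta, seeds, target_names = "x") {
  tibble::tibble(x = theta[[1]])
}

# deterministic quadratic 2-parameter simulator
quad_simulator <- function(theta, seeds, target_names = c("s", "d")) {
  tibble::tibble(s = theta[[1]] + theta[[2]],
                 d = (theta[[1]] - theta[[2]])^2)[, target_names, drop = FALSE]
}

# target table with explicit intervals (skipping the Wilson recipe)
manual_target <- function(name, value, lower_init, upper_init,
                          lower_final, upper_final, spec = "toy") {
  n <- length(name)
  target_set(name, value, sample_size = rep_len(1000, n),
             study_spec_id = rep_len(spec, n),
             intervals = tibble::tibble(
               lower_init = lower_init, upper_init = upper_init,
               lower_final = lower_final, upper_final = upper_final))
}

# weighted Kolmogorov-Smirnov statistic against a reference CDF
weighted_ks <- function(x, w, cdf) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  f <- cdf(x[o])
  max(abs(cw - f), abs(c(0, cw[-length(cw)]) - f))
}

# small scenario + toy engine config reused across slow tests
toy_engine_config <- function(...) {
  imabc_config(n_init = 400, n_centers = 5, batch_size = 60,
               target_ess = 200, max_iterations = 25, mc_guard = "off", ...)
}
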