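#' Wilson tolerance intervals for a calibration target
#'
#' Calibration proceeds against accept bands around each observed target
#' value: a wide *initial* interval that the engine narrows stepwise to a
#' *final* interval. The final interval is the Wilson score interval at
#' `level` for the observed proportion at its sample size; the initial
#' interval widens the final one about the observed value by `inflation`,
#' truncated to the target's natural range. Rates (e.g. per 100,000) are
#' handled on the proportion scale and rescaled by `scale`.
#'
#' @param observed_value Observed proportion (or rate = proportion * scale).
#' @param sample_size Number of trials behind the observation (> 0).
#' @param level Confidence level of the final interval.
#' @param inflation Widening factor for the initial interval.
#' @param scale Scale of the reported value (1 for proportions, 1e5 for
#'   rates per 100,000).
#' @param range Natural range of the reported value (after scaling).
#' @return A tibble with one row: `lower_init`, `upper_init`,
#'   `lower_final`, `upper_final`.
#' @export
#' @examples
#' tolerance_intervals(0.0032, 40674) # final ~ (0.00272, 0.00377)
tolerance_intervals <- function(observed_value, sample_size, level = 0.95,
                                inflation = 10, scale = 1,
                                range = c(0, scale)) {
  if (sample_size <= 0) stop("sample_size must be positive")
  p <- observed_value / scale
  stopifnot(p >= 0, p <= 1)
  fin <- wilson_interval(p, sample_size, level) * scale
  lo_i <- max(range[1], observed_value - inflation * (observed_value - fin[1]))
  hi_i <- min(range[2], observed_value + inflation * (fin[2] - observed_value))
  tibble::tibble(lower_init = lo_i, upper_init = hi_i,
                 lower_final = fin[1], upper_final = fin[2])
}

# Wilson score interval (closed form; no continuity correction)
wilson_interval <- function(p, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  z2 <- z^2
  centre <- (p + z2 / (2 * n)) / (1 + z2 / n)
  half <- z * sqrt(p * (1 - p) / n + z2 / (4 * n^2)) / (1 + z2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Assemble a calibration-target table
#'
#' @param name Target names (unique).
#' @param observed_value Observed values on their natural scale.
#' @param sample_size Observation sample sizes.
#' @param intervals Data frame from [tolerance_intervals()] (one row per
#'   target) or `NULL` to compute with the defaults.
#' @param study_spec_id Which study population each target is computed from.
#' @param scale Value scale per target (see [tolerance_intervals()]).
#' @return A `target_set`: a tibble with one row per target.
#' @export
target_set <- function(name, observed_value, sample_size, study_spec_id,
                       intervals = NULL, scale = 1) {
  n <- length(name)
  stopifnot(!anyDuplicated(name), length(observed_value) == n,
            length(sample_size) == n, length(study_spec_id) == n)
  scale <- rep_len(scale, n)
  if (is.null(intervals)) {
    intervals <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      tolerance_intervals(observed_value[i], sample_size[i], scale = scale[i])
    }))
  }
  out <- tibble::tibble(name = name, observed_value = observed_value,
                        sample_size = sample_size, scale = scale,
                        study_spec_id = study_spec_id)
  out <- dplyr::bind_cols(out, tibble::as_tibble(intervals))
  stopifnot(all(out$lower_init < out$upper_init),
            all(out$lower_final < out$upper_final),
            all(out$lower_init <= out$lower_final + 1e-12),
            all(out$upper_final <= out$upper_init + 1e-12),
            all(out$observed_value >= out$lower_final - 1e-12),
            all(out$observed_value <= out$upper_final + 1e-12))
  class(out) <- c("target_set", class(out))
  out
}

#' Read or write a target table as CSV
#'
#' Columns: `name, observed_value, sample_size, scale, study_spec_id,
#' lower_init, upper_init, lower_final, upper_final`.
#'
#' @param targets A `target_set` tibble.
#' @param path File path.
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(format_full_precision(targets), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_targets_csv
#' @export
read_targets_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  target_set(df$name, df$observed_value, df$sample_size, df$study_spec_id,
             intervals = df[, c("lower_init", "upper_init",
                                "lower_final", "upper_final")],
             scale = df$scale)
}

#' Monte-Carlo error guard for simulated targets
#'
#' Compares each target's simulation binomial standard error (at the agents
#' allocated to it) against its final tolerance half-width. Targets whose
#' simulation SE exceeds `threshold` times the half-width cannot be resolved
#' reliably at that simulation size.
#'
#' @param targets A [target_set()].
#' @param n_agents Named vector: agents simulated per study spec id.
#' @param threshold Maximum allowed ratio of MC SE to final half-width.
#' @return Tibble with per-target `mc_se`, `half_width`, `ratio`, `ok`.
#' @export
check_target_mc_error <- function(targets, n_agents, threshold = 0.2) {
  n_sim <- n_agents[targets$study_spec_id]
  p <- targets$observed_value / targets$scale
  mc_se <- sqrt(p * (1 - p) / n_sim) * targets$scale
  hw <- (targets$upper_final - targets$lower_final) / 2
  tibble::tibble(name = targets$name, mc_se = mc_se, half_width = hw,
                 ratio = mc_se / hw, ok = mc_se <= threshold * hw)
}

size_bin <- function(size) {
  # reported size categories <=5 / 6-9 / >=10 mm operationalised as
  # [1, 5.5), [5.5, 9.5), [9.5, Inf)
  cut(size, breaks = c(1, 5.5, 9.5, Inf), right = FALSE,
      labels = c("small", "medium", "large"))
}

#' Simulate an incidence calibration target
#'
#' Annual clinically-detected colorectal cancer incidence per 100,000, among
#' agents free of clinically detected cancer (and alive) at their entry age:
#' the proportion with a first clinical cancer within the following year,
#' rescaled.
#'
#' @param spec A [study_spec()] (no screening test).
#' @param params An [nh_params()] object.
#' @param seed Population seed.
#' @param age_bands Data frame with columns `name`, `lower`, `upper`
#'   (entry-age bands, `[lower, upper)`), or `NULL` for a single overall band.
#' @param sex `"both"`, `"male"` or `"female"`.
#' @param ... Passed to [simulate_population()].
#' @return Tibble with `name`, `value` (per 100,000 per year),
#'   `n_eligible`, `n_events`.
#' @export
simulate_incidence_target <- function(spec, params, seed, age_bands = NULL,
                                      sex = "both", ...) {
  pop <- simulate_population(spec, params, seed, ...)
  incidence_from_population(pop, age_bands, sex)
}

incidence_from_population <- function(pop, age_bands = NULL, sex = "both") {
  a <- pop$agents
  if (sex == "male") a <- a[a$female == 0L, ]
  if (sex == "female") a <- a[a$female == 1L, ]
  if (is.null(age_bands)) {
    age_bands <- tibble::tibble(name = "incidence_all",
                                lower = pop$spec$age_lower,
                                upper = pop$spec$age_upper)
  }
  st <- stat_incidence(a$index_age, a$eligible, a$clinical_age, age_bands)
  if (anyNA(st$value)) {
    stop("empty eligible stratum for ",
         paste(st$name[is.na(st$value)], collapse = ", "))
  }
  st
}

# base-R statistic kernels shared by the user-facing functions and the
# calibration hot path; NA values signal undefined statistics

stat_incidence <- function(index_age, eligible, clinical_age, age_bands) {
  value <- n_el <- n_ev <- numeric(nrow(age_bands))
  for (i in seq_len(nrow(age_bands))) {
    el <- eligible & index_age >= age_bands$lower[i] &
      index_age < age_bands$upper[i]
    n_el[i] <- sum(el)
    n_ev[i] <- sum(clinical_age[el] <= index_age[el] + 1)
    value[i] <- if (n_el[i] > 0) 1e5 * n_ev[i] / n_el[i] else NA_real_
  }
  tibble::tibble(name = age_bands$name, value = value,
                 n_eligible = n_el, n_events = n_ev)
}

stat_prevalence <- function(female, eligible, n_det_adenoma, n_det_preclin,
                            lesion_size, lesion_preclin) {
  any_det <- (n_det_adenoma + n_det_preclin) > 0
  men <- eligible & female == 0L
  women <- eligible & female == 1L
  n_men <- sum(men); n_women <- sum(women)
  aden_size <- lesion_size[!lesion_preclin]
  bin <- findInterval(lesion_size, c(5.5, 9.5)) + 1L  # 1 small 2 medium 3 large
  aden_bin <- bin[!lesion_preclin]
  n_aden <- length(aden_size)
  pct <- if (n_aden > 0) 100 * tabulate(aden_bin, 3) / n_aden else
    rep(NA_real_, 3)
  per1000 <- vapply(2:3, function(b) {
    nb <- sum(bin == b)
    if (nb > 0) 1000 * sum(lesion_preclin[bin == b]) / nb else NA_real_
  }, numeric(1))
  tibble::tibble(
    name = c("adenoma_prev_men", "adenoma_prev_women",
             paste0("pct_adenomas_", c("small", "medium", "large")),
             paste0("preclin_per1000_", c("medium", "large"))),
    value = c(if (n_men > 0) mean(any_det[men]) else NA_real_,
              if (n_women > 0) mean(any_det[women]) else NA_real_,
              pct, per1000),
    n = c(n_men, n_women, rep(n_aden, 3), sum(bin == 2), sum(bin == 3))
  )
}

stat_screen_detect <- function(female, eligible, n_det_preclin) {
  men <- eligible & female == 0L
  women <- eligible & female == 1L
  n_men <- sum(men); n_women <- sum(women)
  r_men <- if (n_men > 0) mean(n_det_preclin[men] > 0) else NA_real_
  r_women <- if (n_women > 0) mean(n_det_preclin[women] > 0) else NA_real_
  overall <- if (n_men + n_women > 0) {
    sum(n_det_preclin[men | women] > 0) / (n_men + n_women)
  } else NA_real_
  tibble::tibble(
    name = c("screen_detect_men", "screen_detect_women",
             "screen_detect_overall"),
    value = c(r_men, r_women, overall),
    n = c(n_men, n_women, n_men + n_women)
  )
}

#' Simulate adenoma-prevalence and lesion-size calibration targets
#'
#' From a colonoscopy study population: detected-lesion prevalence by sex,
#' the percentage of detected adenomas falling in the reported size
#' categories (operationalised as `[1, 5.5)`, `[5.5, 9.5)` and `>= 9.5` mm),
#' and detected preclinical cancers per 1000 detected lesions in the medium
#' and large size bins.
#'
#' @inheritParams simulate_incidence_target
#' @return Tibble with `name`, `value`, `n` (denominator).
#' @export
simulate_prevalence_and_size_targets <- function(spec, params, seed, ...) {
  stopifnot(spec$test == "colonoscopy")
  pop <- simulate_population(spec, params, seed, ...)
  prevalence_from_population(pop)
}

prevalence_from_population <- function(pop) {
  a <- pop$agents
  if (nrow(pop$lesions) == 0) {
    stop("zero detected lesions; size targets undefined")
  }
  stat_prevalence(a$female, a$eligible, a$n_det_adenoma, a$n_det_preclin,
                  pop$lesions$size, pop$lesions$is_preclinical)
}

#' Simulate screen-detection calibration targets
#'
#' Proportion of screened agents with at least one preclinical cancer
#' detected, by sex and overall (person-count weighted).
#'
#' @inheritParams simulate_incidence_target
#' @return Tibble with `name`, `value`, `n`.
#' @export
simulate_screen_detection_target <- function(spec, params, seed, ...) {
  stopifnot(spec$test != "none")
  pop <- simulate_population(spec, params, seed, ...)
  screen_detection_from_population(pop)
}

screen_detection_from_population <- function(pop) {
  a <- pop$agents
  st <- stat_screen_detect(a$female, a$eligible, a$n_det_preclin)
  present <- unique(a$female)
  need <- c(0L %in% present, 1L %in% present)
  if (anyNA(st$value[c(need, TRUE)])) stop("empty sex stratum")
  st[c(need, TRUE), ]
}

#' Person-weighted combination of stratum rates
#'
#' @param rates Stratum rates.
#' @param n Stratum person counts.
#' @return The overall rate: the count-weighted mean.
#' @export
#' @examples
#' combine_rates(c(0.0046, 0.0017), c(20519, 20155)) # ~0.0032
combine_rates <- function(rates, n) {
  stats::weighted.mean(rates, n)
}
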