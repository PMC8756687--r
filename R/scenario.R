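#' Default synthetic calibration scenario
#'
#' Builds a fully self-contained calibration experiment around a known
#' ground-truth parameter vector: three free sojourn-time parameters
#' (`lambda1`, `lambda2`, `lambda3`, truth 3.77 / 2.38 / 0.87, all other
#' parameters fixed at truth), three simulated study populations, an
#' original target set `y` spanning the usual target kinds (annual clinical
#' incidence by age band, detected-adenoma prevalence by sex, detected-size
#' percentages, preclinical cancers per 1000 large lesions, and one
#' imprecise overall screen-detection rate), and a held-out new target set
#' `z` of two precisely estimated sex-specific screen-detection rates from
#' a large one-time sigmoidoscopy trial (observed sample sizes 20,519 men
#' and 20,155 women). Event rates are scaled up relative to real registry
#' data so that desk-scale populations carry signal; see the package
#' vignette.
#'
#' @param seed Master seed; the scenario (including the synthetic observed
#'   targets) is byte-identical across calls with the same seed.
#' @param n_eval_agents Total agents per simulator evaluation, split across
#'   the study populations.
#' @param truth_multiplier Population-size multiplier used when simulating
#'   the ground truth to generate observed target values.
#' @return An object of class `crc_scenario`.
#' @export
make_default_scenario <- function(seed = 1, n_eval_agents = 2000,
                                  truth_multiplier = 25) {
  truth <- default_nh_params()  # lambda truth 3.77 / 2.38 / 0.87
  prior <- prior_spec(
    name = c("lambda1", "lambda2", "lambda3"),
    family = "truncnorm",
    mean = c(3.0, 2.5, 0.5), sd = c(1.5, 1.0, 1.0),
    lower = c(0.5, 1.0, -1.5), upper = c(8.0, 5.0, 2.0)
  )
  n_inc <- round(0.4 * n_eval_agents)
  n_col <- round(0.3 * n_eval_agents)
  n_sig <- n_eval_agents - n_inc - n_col
  specs <- list(
    incidence = study_spec("incidence", n_inc, 40, 90, 0.5, "none"),
    colo_study = study_spec("colo_study", n_col, 50, 75, 0.5, "colonoscopy"),
    sigmoid_trial = study_spec("sigmoid_trial", n_sig, 55, 64, 0.496,
                               "sigmoidoscopy")
  )
  age_bands <- tibble::tibble(name = c("incidence_50_69", "incidence_70_90"),
                              lower = c(50, 70), upper = c(70, 90))
  defs <- tibble::tibble(
    name = c("incidence_50_69", "incidence_70_90",
             "adenoma_prev_men", "adenoma_prev_women",
             "pct_adenomas_small", "pct_adenomas_medium", "pct_adenomas_large",
             "preclin_per1000_large", "screen_detect_overall",
             "screen_detect_men", "screen_detect_women"),
    spec_id = c("incidence", "incidence",
                "colo_study", "colo_study",
                "colo_study", "colo_study", "colo_study",
                "colo_study", "colo_study",
                "sigmoid_trial", "sigmoid_trial"),
    set = c(rep("y", 9), "z", "z"),
    # observation sample sizes of the synthetic "published studies"
    n_obs = c(50000, 50000, 2500, 2500, 1500, 1500, 1500, 800, 1994,
              20519, 20155),
    scale = c(1e5, 1e5, 1, 1, 100, 100, 100, 1000, 1, 1, 1),
    # the legacy screen-detection target is deliberately imprecise: its
    # final tolerance band is widened, mirroring a small early study
    final_widen = c(rep(1, 8), 4, 1, 1)
  )
  sc <- structure(list(
    truth = truth, prior = prior, specs = specs, defs = defs,
    age_bands = age_bands, seed = seed,
    n_eval_agents = n_eval_agents, truth_multiplier = truth_multiplier,
    model = sensitivity_model(), lt = life_table(), p_rectum = 0.25
  ), class = "crc_scenario")
  tg <- generate_observed_targets(sc)
  sc$targets_y <- tg$y
  sc$targets_z <- tg$z
  sc$truth_values <- tg$truth_values
  sc
}

#' @export
print.crc_scenario <- function(x, ...) {
  cat("<crc_scenario> seed", x$seed, "|", nrow(x$defs), "targets (",
      sum(x$defs$set == "y"), "original +", sum(x$defs$set == "z"),
      "new ) |", x$n_eval_agents, "agents per evaluation\n")
  invisible(x)
}

# simulate all target statistics for one parameter set at a given
# population scale; returns named vector over all defined targets
scenario_target_values <- function(scenario, params, seed, multiplier = 1,
                                   which_specs = NULL) {
  out <- list()
  denom <- list()
  for (k in seq_along(scenario$specs)) {
    sp <- scenario$specs[[k]]
    if (!is.null(which_specs) && !(sp$id %in% which_specs)) next
    if (multiplier != 1) {
      sp <- study_spec(sp$id, sp$n_agents * multiplier, sp$age_lower,
                       sp$age_upper, sp$fraction_female, sp$test)
    }
    pop <- simulate_population(sp, params,
                               seed = (seed + 104729 * k) %% 2147483647,
                               model = scenario$model, lt = scenario$lt,
                               p_rectum = scenario$p_rectum)
    st <- switch(sp$id,
      incidence = incidence_from_population(pop, scenario$age_bands),
      colo_study = {
        a <- tryCatch(prevalence_from_population(pop), error = function(e) NULL)
        b <- screen_detection_from_population(pop)
        if (is.null(a)) b else dplyr::bind_rows(a, b)
      },
      sigmoid_trial = screen_detection_from_population(pop)
    )
    st$key <- paste0(sp$id, ".", st$name)
    out[[sp$id]] <- st
  }
  st <- dplyr::bind_rows(out)
  denoms <- if ("n" %in% names(st)) st$n else rep(NA_real_, nrow(st))
  if ("n_eligible" %in% names(st)) {
    denoms <- ifelse(is.na(denoms), st$n_eligible, denoms)
  }
  # resolve each defined target against the stats of its own study spec
  defs <- scenario$defs
  hit <- match(paste0(defs$spec_id, ".", defs$name), st$key)
  list(values = stats::setNames(st$value[hit], defs$name),
       denoms = stats::setNames(denoms[hit], defs$name))
}

#' Generate synthetic observed targets from the ground truth
#'
#' Simulates the scenario's model at the ground-truth parameters with a
#' large population (`truth_multiplier` times the evaluation size), then
#' perturbs each target by binomial (or multinomial, for the size-bin
#' percentages) sampling noise at its declared observation sample size, and
#' constructs tolerance intervals: the final interval is a Wilson score
#' interval at an effective sample size `1 / (1/n_obs + 1/n_sim)` that
#' folds the simulator's own Monte-Carlo noise at evaluation scale into
#' the tolerance band, times the target's `final_widen` factor; the
#' initial interval widens the final one about the observed value tenfold.
#'
#' @param scenario A `crc_scenario` (fields before target generation).
#' @return A list with `target_set`s `y` and `z` and the noiseless
#'   `truth_values`.
#' @export
generate_observed_targets <- function(scenario) {
  set.seed(iter_seed_for(scenario$seed, 999983))
  big <- scenario_target_values(scenario, scenario$truth,
                                seed = scenario$seed,
                                multiplier = scenario$truth_multiplier)
  truth_v <- big$values
  if (any(!is.finite(truth_v))) {
    stop("ground-truth simulation produced undefined targets: ",
         paste(names(truth_v)[!is.finite(truth_v)], collapse = ", "))
  }
  defs <- scenario$defs
  # expected per-evaluation denominators (for the MC-noise part of the band)
  n_sim <- pmax(1, big$denoms[defs$name] / scenario$truth_multiplier)

  obs <- numeric(nrow(defs))
  # multinomial noise for the size-bin percentages so they still sum to 100
  pct_i <- grep("^pct_adenomas_", defs$name)
  p_bins <- truth_v[defs$name[pct_i]] / 100
  n_pct <- defs$n_obs[pct_i[1]]
  obs[pct_i] <- 100 * as.vector(stats::rmultinom(1, n_pct, p_bins)) / n_pct
  for (i in seq_len(nrow(defs))[-pct_i]) {
    p <- truth_v[defs$name[i]] / defs$scale[i]
    obs[i] <- defs$scale[i] * stats::rbinom(1, defs$n_obs[i], p) / defs$n_obs[i]
  }

  rows <- lapply(seq_len(nrow(defs)), function(i) {
    n_eff <- 1 / (1 / defs$n_obs[i] + 1 / n_sim[i])
    p_obs <- obs[i] / defs$scale[i]
    fin <- wilson_interval(p_obs, n_eff) * defs$scale[i]
    # widen about the observed value, then the tenfold initial band
    hw_lo <- (obs[i] - fin[1]) * defs$final_widen[i]
    hw_hi <- (fin[2] - obs[i]) * defs$final_widen[i]
    lo_f <- max(0, obs[i] - hw_lo)
    hi_f <- min(defs$scale[i], obs[i] + hw_hi)
    tibble::tibble(lower_init = max(0, obs[i] - 10 * (obs[i] - lo_f)),
                   upper_init = min(defs$scale[i], obs[i] + 10 * (hi_f - obs[i])),
                   lower_final = lo_f, upper_final = hi_f)
  })
  intervals <- dplyr::bind_rows(rows)
  sets <- lapply(c(y = "y", z = "z"), function(s) {
    sel <- defs$set == s
    target_set(defs$name[sel], obs[sel], defs$n_obs[sel], defs$spec_id[sel],
               intervals = intervals[sel, ], scale = defs$scale[sel])
  })
  list(y = sets$y, z = sets$z, truth_values = truth_v)
}

#' Build the simulator function for a scenario
#'
#' Returns the function handed to the calibration engine: it takes a data
#' frame of free-parameter draws, a vector of per-draw seeds and the names
#' of the targets required, simulates only the study populations those
#' targets need, and returns one row of target values per draw. Per-draw
#' seeds make results independent of evaluation order and batch
#' partitioning.
#'
#' @param scenario A `crc_scenario`.
#' @return A function `f(theta_df, seeds, target_names)`, with an
#'   `n_agents` attribute (agents per study spec) for the Monte-Carlo
#'   error guard.
#' @export
make_target_simulator <- function(scenario) {
  defs <- scenario$defs
  # precompute per-spec covariates and fixed simulator arguments once
  base_vec <- unlist(unclass(scenario$truth))
  free <- scenario$prior$name
  lt <- scenario$lt
  model <- scenario$model
  pre <- lapply(scenario$specs, function(sp) {
    cov <- spec_covariates(sp)
    list(id = sp$id, female = cov$female, index_age = cov$index_age,
         test = test_code(sp$test))
  })
  f <- function(theta, seeds, target_names = defs$name) {
    specs_needed <- unique(defs$spec_id[defs$name %in% target_names])
    theta <- as.matrix(as.data.frame(theta))
    m <- matrix(NA_real_, nrow(theta), length(target_names),
                dimnames = list(NULL, target_names))
    for (i in seq_len(nrow(theta))) {
      pv <- base_vec
      pv[free] <- theta[i, free]
      if (pv[["lambda1"]] <= 0 || pv[["lambda2"]] <= 0) next
      st <- vector("list", length(pre))
      for (k in seq_along(pre)) {
        pk <- pre[[k]]
        if (!(pk$id %in% specs_needed)) next
        raw <- .simulate_population_cpp(
          pv, pk$female, pk$index_age, scenario$p_rectum,
          lt$breaks, lt$hazards, lt$max_age, pk$test,
          model$anchors$size, model$anchors$sensitivity,
          model$preclin_floor, model$sigmoid_colon_reach, 100,
          (seeds[i] + 104729 * k) %% 2147483647)
        st[[k]] <- switch(pk$id,
          incidence = stat_incidence(pk$index_age, raw$eligible == 1L,
                                     raw$clinical_age, scenario$age_bands),
          colo_study = rbind(
            stat_prevalence(pk$female, raw$eligible == 1L, raw$n_det_adenoma,
                            raw$n_det_preclin, raw$lesion_size,
                            raw$lesion_preclin == 1L),
            stat_screen_detect(pk$female, raw$eligible == 1L,
                               raw$n_det_preclin)),
          sigmoid_trial = stat_screen_detect(pk$female, raw$eligible == 1L,
                                             raw$n_det_preclin))
        st[[k]] <- data.frame(key = paste0(pk$id, ".", st[[k]]$name),
                              value = st[[k]]$value)
      }
      st <- do.call(rbind, st)
      want <- paste0(defs$spec_id[match(target_names, defs$name)], ".",
                     target_names)
      m[i, ] <- st$value[match(want, st$key)]
    }
    tibble::as_tibble(as.data.frame(m))
  }
  attr(f, "n_agents") <- stats::setNames(
    vapply(scenario$specs, function(s) s$n_agents, numeric(1)),
    vapply(scenario$specs, function(s) s$id, character(1)))
  f
}

#' Run the two-arm recalibration experiment
#'
#' Arm 1 (sequential) calibrates to the original targets `y`, then
#' warm-starts from the converged state when the new targets `z` arrive.
#' Arm 2 (scratch) calibrates to the combined set `{y, z}` from the prior.
#' The report compares the two posteriors parameter by parameter with the
#' four agreement metrics, summarises mean sojourn time under each, and
#' accounts simulator calls per arm (the sequential arm's post-restart
#' calls versus the scratch arm's total).
#'
#' @param scenario A `crc_scenario`.
#' @param config An [imabc_config()] (toy-scale values recommended).
#' @param seed Master seed for both arms.
#' @return A list of class `two_arm_report`: states `orig`, `seq`,
#'   `scratch`; `comparison` (tibble of metrics); `mst` (per arm);
#'   `sim_calls` (named counts); `converged` flags.
#' @export
run_two_arm_experiment <- function(scenario, config, seed = scenario$seed) {
  sim <- make_target_simulator(scenario)
  s_orig <- run_calibration(scenario$prior, scenario$targets_y, sim, config,
                            seed)
  s_seq <- warm_start_recalibration(s_orig, scenario$targets_z, sim)
  s_scr <- run_calibration(scenario$prior,
                           dplyr::bind_rows(scenario$targets_y,
                                            scenario$targets_z),
                           sim, config, seed + 500009)
  p_seq <- as_posterior_sample(s_seq, "seq")
  p_scr <- as_posterior_sample(s_scr, "scratch")
  comparison <- compare_posteriors(p_seq, p_scr,
                                   parameters = scenario$prior$name)
  mst <- dplyr::bind_rows(
    dplyr::mutate(mst_posterior(p_seq), run = "seq"),
    dplyr::mutate(mst_posterior(p_scr), run = "scratch")
  )
  structure(list(
    orig = s_orig, seq = s_seq, scratch = s_scr,
    comparison = comparison, mst = mst,
    sim_calls = c(seq_post_restart = s_seq$sim_calls - s_orig$sim_calls,
                  seq_total = s_seq$sim_calls,
                  scratch_total = s_scr$sim_calls),
    converged = c(orig = s_orig$converged, seq = s_seq$converged,
                  scratch = s_scr$converged)
  ), class = "two_arm_report")
}

#' @export
print.two_arm_report <- function(x, ...) {
  cat("<two_arm_report> converged:",
      paste(names(x$converged), x$converged, collapse = ", "), "\n")
  cat("simulator draws: sequential post-restart",
      x$sim_calls[["seq_post_restart"]], "vs scratch total",
      x$sim_calls[["scratch_total"]], "\n")
  print(x$comparison)
  invisible(x)
}

#' Write scenario fixtures to a directory
#'
#' Writes `prior.yaml`, `study_specs.yaml`, `targets_y.csv`,
#' `targets_z.csv` and `truth.yaml` for a scenario.
#'
#' @param scenario A `crc_scenario`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario_fixtures <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  yaml::write_yaml(lapply(seq_len(nrow(scenario$prior)), function(i)
    as.list(scenario$prior[i, ])), file.path(dir, "prior.yaml"))
  yaml::write_yaml(lapply(scenario$specs, unclass),
                   file.path(dir, "study_specs.yaml"))
  write_targets_csv(scenario$targets_y, file.path(dir, "targets_y.csv"))
  write_targets_csv(scenario$targets_z, file.path(dir, "targets_z.csv"))
  write_params_yaml(scenario$truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
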