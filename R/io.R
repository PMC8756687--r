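#' Save or restore a calibration state
#'
#' The resumable state is serialized as a JSON document (configuration,
#' prior, targets with current tolerance intervals, mixture components,
#' counters) plus a companion CSV of accepted draws (parameter columns,
#' weight, per-target simulated values, per-draw seed) written with
#' 17-significant-digit floats so values round-trip exactly. Files are
#' written atomically (temp file, then rename). A reloaded state resumed
#' with the same configuration reproduces an uninterrupted run bit for
#' bit, because all engine randomness is re-derived from the master seed
#' and the iteration counter.
#'
#' @param state An `imabc_state`.
#' @param path Path of the JSON file; the draws CSV is written alongside
#'   with suffix `_draws.csv`.
#' @return `save_state()`: `path`, invisibly. `load_state()`: the state.
#' @export
save_state <- function(state, path) {
  draws_path <- paste0(sub("\\.json$", "", path), "_draws.csv")
  doc <- list(
    config = unclass(state$config),
    prior = as.data.frame(state$prior),
    targets = as.data.frame(state$targets),
    stages = lapply(state$stages, function(s) {
      if (s$type == "prior") list(type = "prior", n_sampled = s$n_sampled)
      else list(type = "gaussian", center = as.numeric(s$center),
                cov = as.numeric(s$cov), d = nrow(s$cov),
                n_sampled = s$n_sampled, iteration = s$iteration)
    }),
    iteration = state$iteration, next_draw_id = state$next_draw_id,
    sim_calls = state$sim_calls, ess = state$ess,
    converged = state$converged, master_seed = state$master_seed,
    draws_file = basename(draws_path)
  )
  atomic_write(function(p) jsonlite::write_json(
    doc, p, auto_unbox = TRUE, digits = NA, null = "null"), path)
  sims <- state$sim_values[, state$targets$name, drop = FALSE]
  names(sims) <- paste0("sim_", names(sims))  # avoid parameter-name clashes
  tab <- dplyr::bind_cols(state$draws, sims,
                          tibble::tibble(weight = state$weights))
  atomic_write(function(p) utils::write.csv(format_full_precision(tab), p,
                                            row.names = FALSE, quote = FALSE),
               draws_path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  num_col <- function(rows, nm) {
    vapply(rows, function(r) {
      v <- r[[nm]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  chr_col <- function(rows, nm) {
    vapply(rows, function(r) as.character(r[[nm]]), character(1))
  }
  prior <- prior_spec(chr_col(doc$prior, "name"), chr_col(doc$prior, "family"),
                      num_col(doc$prior, "mean"), num_col(doc$prior, "sd"),
                      num_col(doc$prior, "lower"), num_col(doc$prior, "upper"))
  targets <- tibble::tibble(
    name = chr_col(doc$targets, "name"),
    observed_value = num_col(doc$targets, "observed_value"),
    sample_size = num_col(doc$targets, "sample_size"),
    scale = num_col(doc$targets, "scale"),
    study_spec_id = chr_col(doc$targets, "study_spec_id"),
    lower_init = num_col(doc$targets, "lower_init"),
    upper_init = num_col(doc$targets, "upper_init"),
    lower_final = num_col(doc$targets, "lower_final"),
    upper_final = num_col(doc$targets, "upper_final"),
    current_lower = num_col(doc$targets, "current_lower"),
    current_upper = num_col(doc$targets, "current_upper"))
  cfg <- lapply(doc$config, function(x) if (is.list(x)) unlist(x) else x)
  cfg$knn <- if (is.null(cfg$knn)) NULL else cfg$knn
  config <- imabc_config(cfg$n_init, cfg$n_centers, cfg$batch_size,
                         cfg$target_ess, cfg$max_iterations,
                         cfg$shrink_factor, cfg$min_draws_retained,
                         cfg$defensive_weight, cfg$cov_reg, cfg$knn,
                         cfg$mc_guard, cfg$mc_threshold)
  stages <- lapply(doc$stages, function(s) {
    if (s$type == "prior") {
      list(type = "prior", n_sampled = as.numeric(s$n_sampled))
    } else {
      list(type = "gaussian",
           center = stats::setNames(as.numeric(unlist(s$center)), prior$name),
           cov = matrix(as.numeric(unlist(s$cov)), s$d, s$d),
           n_sampled = as.numeric(s$n_sampled),
           iteration = as.integer(s$iteration))
    }
  })
  tab <- utils::read.csv(file.path(dirname(path), doc$draws_file),
                         check.names = FALSE)
  for (nm in c(prior$name, paste0("sim_", targets$name), "seed", "weight")) {
    tab[[nm]] <- as.double(tab[[nm]])
  }
  tab <- tibble::as_tibble(tab)
  sim_values <- tab[, c("draw_id", paste0("sim_", targets$name))]
  names(sim_values) <- c("draw_id", targets$name)
  state <- structure(list(
    prior = prior, targets = targets, config = config,
    master_seed = doc$master_seed,
    draws = tab[, c("draw_id", prior$name, "stage", "seed")],
    sim_values = sim_values,
    weights = tab$weight,
    stages = stages,
    iteration = as.integer(doc$iteration),
    next_draw_id = as.integer(doc$next_draw_id),
    sim_calls = doc$sim_calls, ess = doc$ess, converged = doc$converged
  ), class = "imabc_state")
  assert_state_invariants(state)
  state
}

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Command-line dispatch
#'
#' Entry point behind the `inst/cli/crcabc` script. Subcommands:
#' `simulate` (write a population event table), `calibrate`, `recalibrate`,
#' `compare` (Table-style metric report for two draw CSVs) and
#' `make-fixtures` (write the default scenario's files). Outputs are
#' written atomically. Exit status: 0 on success, 2 for an unconverged
#' calibration, 1 for usage or input errors.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status, invisibly.
#' @export
cli_dispatch <- function(argv) {
  if (length(argv) < 1) {
    message("usage: crcabc <simulate|calibrate|recalibrate|compare|make-fixtures> ...")
    return(invisible(1L))
  }
  cmd <- argv[1]
  args <- parse_kv_args(argv[-1])
  status <- tryCatch({
    switch(cmd,
      "make-fixtures" = {
        sc <- make_default_scenario(seed = as.integer(args$seed %||% 1))
        write_scenario_fixtures(sc, args$out %||% "fixtures")
        0L
      },
      "simulate" = {
        sc <- make_default_scenario(seed = as.integer(args$seed %||% 1))
        pop <- simulate_population(sc$specs$colo_study, sc$truth,
                                   seed = as.integer(args$seed %||% 1))
        atomic_write(function(p) utils::write.csv(tidy(pop), p,
                                                  row.names = FALSE),
                     args$out %||% "population.csv")
        0L
      },
      "calibrate" = {
        sc <- make_default_scenario(seed = as.integer(args$seed %||% 1))
        cfg <- toy_config(args)
        st <- run_calibration(sc$prior, sc$targets_y,
                              make_target_simulator(sc), cfg,
                              as.integer(args$seed %||% 1))
        save_state(st, args$out %||% "state.json")
        if (st$converged) 0L else 2L
      },
      "recalibrate" = {
        st <- load_state(args$`resume-from`)
        sc <- make_default_scenario(seed = as.integer(args$seed %||%
                                                        st$master_seed))
        zt <- if (!is.null(args$`new-targets`)) {
          read_targets_csv(args$`new-targets`)
        } else sc$targets_z
        st2 <- warm_start_recalibration(st, zt, make_target_simulator(sc))
        save_state(st2, args$out %||% "state2.json")
        if (st2$converged) 0L else 2L
      },
      "compare" = {
        a <- posterior_sample(read_draws_csv(args$`run-a`), label = "a")
        b <- posterior_sample(read_draws_csv(args$`run-b`), label = "b")
        rep <- compare_posteriors(a, b)
        atomic_write(function(p) utils::write.csv(rep, p, row.names = FALSE),
                     args$out %||% "report.csv")
        0L
      },
      {
        message("unknown subcommand: ", cmd)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

toy_config <- function(args) {
  imabc_config(
    n_init = as.integer(args$n_init %||% 400),
    n_centers = as.integer(args$n_centers %||% 5),
    batch_size = as.integer(args$batch_size %||% 60),
    target_ess = as.numeric(args$target_ess %||% 200),
    max_iterations = as.integer(args$max_iterations %||% 25),
    mc_guard = "warn"
  )
}

parse_kv_args <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (i + 1 <= length(argv) && !startsWith(argv[i + 1], "--")) {
      out[[key]] <- argv[i + 1]; i <- i + 2
    } else {
      out[[key]] <- TRUE; i <- i + 1
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
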