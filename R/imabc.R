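#' Prior specification for calibrated parameters
#'
#' Independent truncated-normal or uniform priors, one row per free
#' parameter, with bounded support. These are the families used for the
#' natural-history model's calibrated parameters.
#'
#' @param name Parameter names.
#' @param family `"truncnorm"` or `"uniform"` per parameter.
#' @param mean,sd Hyperparameters (ignored for uniform).
#' @param lower,upper Support bounds (finite).
#' @return A `prior_spec` tibble.
#' @export
prior_spec <- function(name, family, mean = NA_real_, sd = NA_real_,
                       lower, upper) {
  n <- length(name)
  out <- tibble::tibble(name = name, family = rep_len(family, n),
                        mean = rep_len(mean, n), sd = rep_len(sd, n),
                        lower = rep_len(lower, n), upper = rep_len(upper, n))
  stopifnot(all(out$family %in% c("truncnorm", "uniform")),
            all(is.finite(out$lower)), all(is.finite(out$upper)),
            all(out$lower < out$upper),
            all(is.finite(out$sd[out$family == "truncnorm"])),
            all(out$sd[out$family == "truncnorm"] > 0))
  class(out) <- c("prior_spec", class(out))
  out
}

#' Sample from / evaluate the prior
#'
#' Truncated normals are drawn by inverse-CDF; densities are normalised over
#' the truncation interval. Parameters are a priori independent.
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @return `sample_prior()`: an `n` x `n_params` tibble.
#'   `log_prior_density()`: a numeric vector (`-Inf` outside the support).
#' @export
sample_prior <- function(prior, n) {
  cols <- lapply(seq_len(nrow(prior)), function(i) {
    u <- stats::runif(n)
    if (prior$family[i] == "uniform") {
      prior$lower[i] + u * (prior$upper[i] - prior$lower[i])
    } else {
      pa <- stats::pnorm(prior$lower[i], prior$mean[i], prior$sd[i])
      pb <- stats::pnorm(prior$upper[i], prior$mean[i], prior$sd[i])
      stats::qnorm(pa + u * (pb - pa), prior$mean[i], prior$sd[i])
    }
  })
  names(cols) <- prior$name
  tibble::as_tibble(cols)
}

#' @rdname sample_prior
#' @param theta Data frame (or matrix) of parameter values, columns named.
#' @export
log_prior_density <- function(prior, theta) {
  theta <- as.data.frame(theta)
  lp <- numeric(nrow(theta))
  for (i in seq_len(nrow(prior))) {
    x <- theta[[prior$name[i]]]
    inb <- x >= prior$lower[i] & x <= prior$upper[i]
    if (prior$family[i] == "uniform") {
      d <- -log(prior$upper[i] - prior$lower[i])
      lp <- lp + ifelse(inb, d, -Inf)
    } else {
      pa <- stats::pnorm(prior$lower[i], prior$mean[i], prior$sd[i])
      pb <- stats::pnorm(prior$upper[i], prior$mean[i], prior$sd[i])
      d <- stats::dnorm(x, prior$mean[i], prior$sd[i], log = TRUE) - log(pb - pa)
      lp <- lp + ifelse(inb, d, -Inf)
    }
  }
  lp
}

#' IMABC engine configuration
#'
#' Defaults are sized for production runs (target effective sample size
#' 5000); toy problems should scale down `n_init`, `batch_size` and
#' `target_ess`.
#'
#' @param n_init Prior draws in the initial stage.
#' @param n_centers New mixture components added per iteration.
#' @param batch_size Draws sampled per component per iteration.
#' @param target_ess Stop once the effective sample size at the final
#'   tolerance intervals reaches this.
#' @param max_iterations Iteration cap; exceeding it returns an unconverged
#'   state.
#' @param shrink_factor Fraction of the remaining gap between current and
#'   final interval endpoints closed per iteration (1 jumps straight to the
#'   final intervals).
#' @param min_draws_retained An interval-narrowing step is skipped when it
#'   would leave fewer accepted draws than this.
#' @param defensive_weight Probability that a proposal draw comes from the
#'   prior rather than the Gaussian components (defensive mixture).
#' @param cov_reg Diagonal regularisation of component covariances, as a
#'   multiple of the trace.
#' @param knn Neighbourhood size for local component covariances (`NULL`:
#'   automatic).
#' @param mc_guard `"refuse"`, `"warn"` or `"off"`: reaction when a target's
#'   simulation Monte-Carlo error is too large relative to its final
#'   tolerance half-width (see [check_target_mc_error()]).
#' @param mc_threshold Threshold for that check.
#' @return A list of class `imabc_config`.
#' @export
imabc_config <- function(n_init = 5000, n_centers = 5, batch_size = 100,
                         target_ess = 5000, max_iterations = 50,
                         shrink_factor = 0.5, min_draws_retained = 50,
                         defensive_weight = 0.1, cov_reg = 1e-8, knn = NULL,
                         mc_guard = c("refuse", "warn", "off"),
                         mc_threshold = 0.2) {
  stopifnot(n_init >= 1, n_centers >= 1, batch_size >= 1, target_ess >= 1,
            max_iterations >= 0, shrink_factor > 0, shrink_factor <= 1,
            min_draws_retained >= 1, defensive_weight >= 0,
            defensive_weight < 1)
  structure(list(n_init = n_init, n_centers = n_centers,
                 batch_size = batch_size, target_ess = target_ess,
                 max_iterations = max_iterations,
                 shrink_factor = shrink_factor,
                 min_draws_retained = min_draws_retained,
                 defensive_weight = defensive_weight, cov_reg = cov_reg,
                 knn = knn, mc_guard = match.arg(mc_guard),
                 mc_threshold = mc_threshold),
            class = "imabc_config")
}

#' Effective sample size of importance weights
#'
#' `ess(w) = (sum w)^2 / sum(w^2)`; equals `length(w)` for equal weights and
#' tends to 1 when one weight dominates.
#'
#' @param w Non-negative weights (need not be normalised).
#' @return A scalar in `[1, length(w)]` (0 for empty/all-zero weights).
#' @export
ess <- function(w) {
  s <- sum(w)
  if (s <= 0) return(0)
  s^2 / sum(w^2)
}

# deterministic seed splitting ----------------------------------------------

draw_seed_for <- function(master_seed, draw_id) {
  (as.numeric(master_seed) * 48271 + as.numeric(draw_id) * 16807) %% 2147483647
}

iter_seed_for <- function(master_seed, iteration) {
  as.integer((as.numeric(master_seed) * 69069 + 7919 * iteration) %% 2147483647)
}

# state internals ------------------------------------------------------------

new_imabc_state <- function(prior, targets, config, master_seed) {
  targets$current_lower <- targets$lower_init
  targets$current_upper <- targets$upper_init
  structure(list(
    prior = prior, targets = targets, config = config,
    master_seed = master_seed,
    draws = NULL,            # tibble: draw_id, params..., stage, seed
    sim_values = NULL,       # tibble: draw_id + one column per target
    weights = numeric(0),
    stages = list(list(type = "prior", n_sampled = 0)),
    iteration = 0L, next_draw_id = 1L,
    sim_calls = 0, ess = 0, converged = FALSE
  ), class = "imabc_state")
}

state_theta <- function(state) {
  as.matrix(state$draws[, state$prior$name, drop = FALSE])
}

log_sum_exp <- function(m) {
  # rowwise log-sum-exp of a matrix
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# mixture proposal density under the balance heuristic: each sampling stage
# (prior, or one Gaussian component) contributes with weight proportional to
# the number of draws actually sampled from it
log_proposal_density <- function(state, theta) {
  theta <- as.matrix(theta)
  ns <- vapply(state$stages, function(s) s$n_sampled, numeric(1))
  keep <- ns > 0
  ns <- ns[keep]
  stages <- state$stages[keep]
  logn <- log(ns) - log(sum(ns))
  comp <- matrix(-Inf, nrow(theta), length(stages))
  for (k in seq_along(stages)) {
    s <- stages[[k]]
    comp[, k] <- logn[k] + if (s$type == "prior") {
      log_prior_density(state$prior, theta)
    } else {
      mvtnorm::dmvnorm(theta, mean = s$center, sigma = s$cov, log = TRUE)
    }
  }
  log_sum_exp(comp)
}

draw_in_intervals <- function(state, sim_values,
                              lower = state$targets$current_lower,
                              upper = state$targets$current_upper) {
  v <- as.matrix(sim_values[, state$targets$name, drop = FALSE])
  ok <- is.finite(v) & sweep(v, 2, lower, ">=") & sweep(v, 2, upper, "<=")
  rowSums(ok) == ncol(v)
}

#' Importance weights of the accepted draws
#'
#' `w_i` proportional to `prior(theta_i) / q(theta_i)` for draws inside
#' every current tolerance interval and zero otherwise, normalised to sum
#' to one. `q` is the defensive mixture of the prior and all Gaussian
#' components, combined with weights proportional to the number of draws
#' sampled from each.
#'
#' @param state An `imabc_state`.
#' @return The state with updated `weights` and `ess`.
#' @export
importance_weights <- function(state) {
  if (is.null(state$draws) || nrow(state$draws) == 0) {
    state$weights <- numeric(0); state$ess <- 0
    return(state)
  }
  theta <- state_theta(state)
  lw <- log_prior_density(state$prior, theta) -
    log_proposal_density(state, theta)
  ok <- draw_in_intervals(state, state$sim_values)
  lw[!ok] <- -Inf
  if (all(lw == -Inf)) stop("all importance weights are zero")
  w <- exp(lw - max(lw[is.finite(lw)]))
  state$weights <- w / sum(w)
  state$ess <- ess(state$weights)
  state
}

# drop draws outside the current intervals and renormalise
prune_to_intervals <- function(state) {
  if (is.null(state$draws) || nrow(state$draws) == 0) return(state)
  ok <- draw_in_intervals(state, state$sim_values)
  state$draws <- state$draws[ok, , drop = FALSE]
  state$sim_values <- state$sim_values[ok, , drop = FALSE]
  state$weights <- state$weights[ok]
  if (sum(state$weights) > 0) state$weights <- state$weights / sum(state$weights)
  state$ess <- ess(state$weights)
  state
}

assert_state_invariants <- function(state) {
  if (!is.null(state$draws) && nrow(state$draws) > 0) {
    stopifnot(all(draw_in_intervals(state, state$sim_values)))
    if (length(state$weights)) {
      stopifnot(all(state$weights >= 0),
                abs(sum(state$weights) - 1) < 1e-8)
    }
  }
  stopifnot(all(state$targets$current_lower <= state$targets$lower_final + 1e-12),
            all(state$targets$current_upper >= state$targets$upper_final - 1e-12))
  invisible(state)
}

#' Initialise a calibration from the prior
#'
#' Draws `n_init` parameter vectors from the prior, simulates every target
#' for each draw, and retains the draws falling inside all initial tolerance
#' intervals with uniform weights.
#'
#' @param prior A [prior_spec()].
#' @param targets A [target_set()].
#' @param simulator Function `f(theta_df, seeds, target_names)` returning a
#'   data frame with one row per draw and one column per requested target.
#' @param config An [imabc_config()].
#' @param seed Master seed.
#' @return An `imabc_state`.
#' @export
init_from_prior <- function(prior, targets, simulator, config, seed) {
  state <- new_imabc_state(prior, targets, config, seed)
  set.seed(iter_seed_for(seed, 0))
  theta <- sample_prior(prior, config$n_init)
  ids <- seq_len(config$n_init)
  seeds <- draw_seed_for(seed, ids)
  vals <- simulator(theta, seeds, targets$name)
  state$stages[[1]]$n_sampled <- config$n_init
  state$sim_calls <- state$sim_calls + config$n_init
  state$next_draw_id <- config$n_init + 1L
  draws <- dplyr::bind_cols(tibble::tibble(draw_id = ids), theta)
  draws$stage <- 1L
  draws$seed <- seeds
  sim_values <- dplyr::bind_cols(tibble::tibble(draw_id = ids),
                                 tibble::as_tibble(vals))
  ok <- draw_in_intervals(
    structure(list(targets = state$targets), class = "imabc_state"),
    sim_values)
  if (!any(ok)) {
    stop("no prior draws fall inside the initial tolerance intervals")
  }
  state$draws <- draws[ok, , drop = FALSE]
  state$sim_values <- sim_values[ok, , drop = FALSE]
  state$weights <- rep(1 / sum(ok), sum(ok))
  state$ess <- ess(state$weights)
  assert_state_invariants(state)
  state
}

#' Add adaptive mixture components
#'
#' Centres `n_centers` new multivariate-normal proposal components at the
#' highest-weight accepted draws (stable tie-break: weight descending, then
#' draw id ascending). Each component's covariance is the sample covariance
#' of the centre's nearest accepted draws (in coordinates standardised by
#' the accepted sample's spread), regularised by adding `cov_reg * trace`
#' to the diagonal.
#'
#' @param state An `imabc_state` with accepted draws.
#' @param n_centers Number of components to add.
#' @return The state with new components appended (not yet sampled from).
#' @export
add_mixture_components <- function(state, n_centers = state$config$n_centers) {
  n_acc <- nrow(state$draws)
  if (n_acc < 1) stop("no accepted draws to centre components on")
  n_centers <- min(n_centers, n_acc)
  ord <- order(-state$weights, state$draws$draw_id)
  centers_idx <- ord[seq_len(n_centers)]
  theta <- state_theta(state)
  d <- ncol(theta)
  sdev <- apply(theta, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  std <- sweep(theta, 2, sdev, "/")
  k <- state$config$knn
  if (is.null(k)) k <- min(n_acc, max(2 * (d + 1), 25))
  for (ci in centers_idx) {
    dist2 <- colSums((t(std) - std[ci, ])^2)
    nb <- order(dist2)[seq_len(k)]
    S <- if (length(nb) >= 2) stats::cov(theta[nb, , drop = FALSE]) else
      diag(sdev^2, d)
    S <- regularize_cov(S, state$config$cov_reg, sdev)
    state$stages[[length(state$stages) + 1]] <-
      list(type = "gaussian", center = theta[ci, ], cov = S, n_sampled = 0,
           iteration = state$iteration + 1L)
  }
  state
}

regularize_cov <- function(S, reg, sdev) {
  d <- nrow(S)
  tr <- sum(diag(S))
  if (!is.finite(tr) || tr <= 0) tr <- sum(sdev^2)
  S <- S + diag(reg * tr, d)
  for (i in 1:8) {
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (ok) return(S)
    S <- S + diag(max(reg, 1e-10) * tr * 10^i, d)
  }
  stop("component covariance singular after regularisation")
}

sample_from_mixture <- function(state, components_idx, n_total) {
  d <- nrow(state$prior)
  from_prior <- stats::runif(n_total) < state$config$defensive_weight
  n_p <- sum(from_prior)
  theta <- matrix(NA_real_, n_total, d,
                  dimnames = list(NULL, state$prior$name))
  stage_id <- integer(n_total)
  if (n_p > 0) {
    theta[from_prior, ] <- as.matrix(sample_prior(state$prior, n_p))
    stage_id[from_prior] <- 1L
  }
  idx_g <- which(!from_prior)
  if (length(idx_g)) {
    pick <- components_idx[1 + (seq_along(idx_g) - 1) %% length(components_idx)]
    for (ci in unique(pick)) {
      rows <- idx_g[pick == ci]
      s <- state$stages[[ci]]
      theta[rows, ] <- mvtnorm::rmvnorm(length(rows), mean = s$center,
                                        sigma = s$cov)
      stage_id[rows] <- ci
    }
  }
  list(theta = tibble::as_tibble(as.data.frame(theta)), stage_id = stage_id)
}

#' Narrow tolerance intervals one step
#'
#' Moves each target's current interval endpoints a fraction
#' `shrink_factor` of the remaining way toward the final interval, one
#' target at a time, skipping (with a log record in
#' `state$shrink_skipped`) any step that would leave fewer than
#' `min_draws_retained` accepted draws inside all intervals. Draws outside
#' the updated intervals are dropped and weights renormalised.
#'
#' @param state An `imabc_state`.
#' @return The updated state.
#' @export
shrink_intervals <- function(state) {
  cfg <- state$config
  tg <- state$targets
  skipped <- character(0)
  for (i in seq_len(nrow(tg))) {
    new_lo <- tg$current_lower[i] +
      cfg$shrink_factor * (tg$lower_final[i] - tg$current_lower[i])
    new_hi <- tg$current_upper[i] +
      cfg$shrink_factor * (tg$upper_final[i] - tg$current_upper[i])
    cand <- tg
    cand$current_lower[i] <- new_lo
    cand$current_upper[i] <- new_hi
    n_in <- sum(draw_in_intervals(
      structure(list(targets = cand), class = "imabc_state"),
      state$sim_values))
    if (n_in >= cfg$min_draws_retained) {
      tg <- cand
    } else {
      skipped <- c(skipped, tg$name[i])
    }
  }
  state$targets <- tg
  state$shrink_skipped <- skipped
  state <- prune_to_intervals(state)
  state
}

at_final_intervals <- function(state) {
  all(abs(state$targets$current_lower - state$targets$lower_final) < 1e-12 &
      abs(state$targets$current_upper - state$targets$upper_final) < 1e-12)
}

# if the draws inside the *final* intervals already carry enough effective
# sample size, jump the intervals to final and finish
try_finalize <- function(state) {
  if (is.null(state$draws) || nrow(state$draws) == 0) return(state)
  theta <- state_theta(state)
  lw <- log_prior_density(state$prior, theta) -
    log_proposal_density(state, theta)
  ok <- draw_in_intervals(state, state$sim_values,
                          lower = state$targets$lower_final,
                          upper = state$targets$upper_final)
  lw[!ok] <- -Inf
  if (!any(is.finite(lw))) return(state)
  w <- exp(lw - max(lw[is.finite(lw)]))
  if (ess(w) >= state$config$target_ess) {
    state$targets$current_lower <- state$targets$lower_final
    state$targets$current_upper <- state$targets$upper_final
    state <- importance_weights(state)
    state <- prune_to_intervals(state)
    state$converged <- TRUE
  }
  state
}

apply_mc_guard <- function(targets, simulator, config) {
  n_agents <- attr(simulator, "n_agents")
  if (is.null(n_agents) || config$mc_guard == "off") return(invisible())
  chk <- check_target_mc_error(targets, n_agents, config$mc_threshold)
  if (any(!chk$ok)) {
    msg <- paste0("target MC error exceeds ", config$mc_threshold,
                  " x final half-width: ",
                  paste(chk$name[!chk$ok], collapse = ", "))
    if (config$mc_guard == "refuse") stop(msg) else warning(msg, call. = FALSE)
  }
  invisible()
}

#' Run an IMABC calibration
#'
#' Iterates: add mixture components at the highest-weight accepted draws,
#' sample a batch from the defensive mixture, simulate the targets for each
#' draw, accept draws inside all current tolerance intervals, narrow the
#' intervals toward their final widths, reweight, and recompute the
#' effective sample size — until the ESS at the final intervals reaches
#' `target_ess` or `max_iterations` is hit (returning an unconverged state).
#'
#' @inheritParams init_from_prior
#' @param seed Master seed; all engine randomness and per-draw simulator
#'   seeds derive from it, so reruns are exactly reproducible.
#' @return A converged (or flagged-unconverged) `imabc_state`.
#' @export
run_calibration <- function(prior, targets, simulator, config, seed) {
  apply_mc_guard(targets, simulator, config)
  state <- init_from_prior(prior, targets, simulator, config, seed)
  state <- try_finalize(state)
  state <- resume_calibration(state, simulator)
  state
}

#' Resume a calibration from a (possibly reloaded) state
#'
#' Continues the iteration loop from `state$iteration`. Because every
#' source of engine randomness is re-derived from the master seed and the
#' iteration counter, resuming a saved state reproduces an uninterrupted
#' run exactly.
#'
#' @param state An `imabc_state` (e.g. from [load_state()]).
#' @param simulator The simulator function used for the original run.
#' @return The continued `imabc_state`.
#' @export
resume_calibration <- function(state, simulator) {
  cfg <- state$config
  while (!state$converged && state$iteration < cfg$max_iterations) {
    it <- state$iteration + 1L
    set.seed(iter_seed_for(state$master_seed, it))
    state <- add_mixture_components(state)
    new_idx <- which(vapply(state$stages, function(s)
      !is.null(s$iteration) && s$iteration == it, logical(1)))
    n_batch <- cfg$n_centers * cfg$batch_size
    prop <- sample_from_mixture(state, new_idx, n_batch)
    ids <- state$next_draw_id - 1L + seq_len(n_batch)
    seeds <- draw_seed_for(state$master_seed, ids)
    vals <- tibble::as_tibble(simulator(prop$theta, seeds,
                                        state$targets$name))
    state$sim_calls <- state$sim_calls + n_batch
    state$next_draw_id <- state$next_draw_id + n_batch
    for (si in unique(prop$stage_id)) {
      state$stages[[si]]$n_sampled <-
        state$stages[[si]]$n_sampled + sum(prop$stage_id == si)
    }
    # keep draws inside the prior support and all current intervals
    sim_values <- dplyr::bind_cols(tibble::tibble(draw_id = ids), vals)
    in_support <- is.finite(log_prior_density(state$prior, prop$theta))
    ok <- in_support & draw_in_intervals(state, sim_values)
    if (any(ok)) {
      add <- dplyr::bind_cols(tibble::tibble(draw_id = ids[ok]),
                              prop$theta[ok, , drop = FALSE])
      add$stage <- prop$stage_id[ok]
      add$seed <- seeds[ok]
      state$draws <- dplyr::bind_rows(state$draws, add)
      state$sim_values <- dplyr::bind_rows(state$sim_values, sim_values[ok, ])
    }
    state <- importance_weights(state)
    state <- shrink_intervals(state)
    state <- importance_weights(state)
    state$iteration <- it
    log_line("iteration", it, "accepted", nrow(state$draws),
             "ess", round(state$ess, 1), "sim_calls", state$sim_calls,
             "at_final", at_final_intervals(state))
    if (at_final_intervals(state) && state$ess >= cfg$target_ess) {
      state$converged <- TRUE
    } else {
      state <- try_finalize(state)
    }
    assert_state_invariants(state)
  }
  state
}

#' Warm-start recalibration with new targets
#'
#' Resumes a converged calibration when new targets `z` arrive: every stored
#' accepted draw's new-target statistics are simulated by reusing the stored
#' per-draw seed (so the original targets' simulated values are unchanged
#' and need not be recomputed), acceptance is re-applied against the
#' combined target set with the new targets starting at their initial
#' tolerance intervals, the existing mixture components are retained, and
#' the iteration loop resumes (iteration counter continuing) until the ESS
#' target is reached at the final intervals of all targets.
#'
#' @param state A converged `imabc_state` (targets `y`).
#' @param new_targets A [target_set()] with names disjoint from `y`'s.
#' @param simulator Simulator covering both old and new target names.
#' @param config Optionally a new [imabc_config()] (default: the saved one,
#'   with the iteration cap extended by its own `max_iterations`).
#' @return An `imabc_state` calibrated to the combined targets.
#' @export
warm_start_recalibration <- function(state, new_targets, simulator,
                                     config = NULL) {
  if (!state$converged) stop("saved state is not converged")
  if (any(new_targets$name %in% state$targets$name)) {
    stop("new target names must be disjoint from the existing ones")
  }
  if (is.null(config)) {
    config <- state$config
    config$max_iterations <- state$iteration + config$max_iterations
  }
  state$config <- config
  # simulate only the new targets for the stored draws, reusing stored seeds
  z_vals <- tibble::as_tibble(
    simulator(state$draws[, state$prior$name, drop = FALSE],
              state$draws$seed, new_targets$name))
  state$sim_calls <- state$sim_calls + nrow(state$draws)
  new_targets$current_lower <- new_targets$lower_init
  new_targets$current_upper <- new_targets$upper_init
  state$targets <- dplyr::bind_rows(state$targets, new_targets)
  state$sim_values <- dplyr::bind_cols(state$sim_values,
                                       z_vals[, new_targets$name, drop = FALSE])
  ok <- draw_in_intervals(state, state$sim_values)
  if (!any(ok)) {
    stop("no stored draw satisfies the new targets' initial intervals; ",
         "widen them or start from scratch")
  }
  state$converged <- FALSE
  state <- importance_weights(state)
  state <- prune_to_intervals(state)
  state <- try_finalize(state)
  state <- resume_calibration(state, simulator)
  state
}

#' @export
print.imabc_state <- function(x, ...) {
  cat("<imabc_state>", if (x$converged) "converged" else "NOT converged",
      "| iteration", x$iteration, "| accepted", nrow(x$draws),
      "| ESS", round(x$ess, 1), "| simulated draws", x$sim_calls, "\n")
  invisible(x)
}

#' Posterior draws of a calibration as a tibble
#'
#' @param x An `imabc_state`.
#' @param ... Unused.
#' @return Tibble of accepted draws: parameter columns, `weight`, `seed`
#'   and the simulated target values.
#' @export
tidy.imabc_state <- function(x, ...) {
  out <- dplyr::bind_cols(
    x$draws[, c("draw_id", x$prior$name), drop = FALSE],
    tibble::tibble(weight = x$weights, seed = x$draws$seed),
    x$sim_values[, setdiff(names(x$sim_values), "draw_id"), drop = FALSE]
  )
  tibble::as_tibble(out)
}

#' One-row summary of a calibration
#'
#' @param x An `imabc_state`.
#' @param ... Unused.
#' @return Tibble with `converged`, `iterations`, `n_accepted`, `ess`,
#'   `sim_calls`.
#' @export
glance.imabc_state <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iteration,
                 n_accepted = nrow(x$draws), ess = x$ess,
                 sim_calls = x$sim_calls)
}

log_line <- function(...) {
  kv <- list(...)
  if (isTRUE(getOption("crcabc.verbose", FALSE))) {
    msg <- paste(vapply(seq(1, length(kv), by = 2), function(i)
      paste0(kv[[i]], "=", kv[[i + 1]]), character(1)), collapse = " ")
    message(msg)
  }
  invisible()
}
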