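#' Log instantaneous adenoma risk
#'
#' Piecewise-linear log-risk in age with knots at 50, 60 and 70 years and
#' zero risk (log-risk `-Inf`) before age 20:
#' \deqn{\ln\psi_i(a) = \alpha_{0i} + \alpha_1 female_i
#'   + \min(a-20,30)\,\alpha_{20} + \min((a-50)_+,10)\,\alpha_{50}
#'   + \min((a-60)_+,10)\,\alpha_{60} + (a-70)_+\,\alpha_{70}.}
#' At age 20 all age terms vanish, so the baseline risk is
#' \eqn{\exp(\alpha_{0i} + \alpha_1 female_i)}.
#'
#' @param age Age in years (vectorised).
#' @param female 0/1 indicator (vectorised).
#' @param alpha0 Person-level intercept \eqn{\alpha_{0i}} (drawn
#'   `N(A, sigma_alpha)` across agents).
#' @param params An [nh_params()] object.
#' @return Log instantaneous risk per year; `-Inf` below age 20.
#' @export
#' @examples
#' p <- nh_params()
#' adenoma_log_risk(20, female = 0, alpha0 = p$A, params = p) # == p$A
adenoma_log_risk <- function(age, female, alpha0, params) {
  stopifnot(all(age >= 0))
  lr <- alpha0 + params$alpha1 * female +
    pmin(pmax(age - 20, 0), 30) * params$alpha20 +
    pmin(pmax(age - 50, 0), 10) * params$alpha50 +
    pmin(pmax(age - 60, 0), 10) * params$alpha60 +
    pmax(age - 70, 0) * params$alpha70
  lr[age < 20] <- -Inf
  lr
}

#' Sample adenoma initiation ages from the risk process
#'
#' Adenomas arise according to a non-homogeneous Poisson process with
#' intensity \eqn{\psi_i(a)} from [adenoma_log_risk()]. Sampling uses
#' thinning with a per-segment constant majorant: the log-intensity is
#' piecewise linear, so the maximum over each segment between knots
#' (20, 50, 60, 70, horizon) is attained at an endpoint and the thinning
#' proposal is exact with no discretisation bias. Each event is assigned a
#' location (colon or rectum) independently.
#'
#' @param female,alpha0 Agent covariates, see [adenoma_log_risk()].
#' @param params An [nh_params()] object.
#' @param horizon Upper age limit (years) for initiations.
#' @param p_rectum Probability an adenoma arises in the rectum.
#' @return A tibble with columns `init_age` (sorted) and `location`.
#' @export
sample_adenoma_initiations <- function(female, alpha0, params, horizon = 100,
                                       p_rectum = 0.25) {
  stopifnot(horizon <= 100 + 1e-9)
  if (horizon <= 20) {
    return(tibble::tibble(init_age = numeric(0), location = character(0)))
  }
  knots <- sort(unique(c(20, 50, 60, 70, horizon)))
  knots <- knots[knots <= horizon]
  if (knots[length(knots)] < horizon) knots <- c(knots, horizon)
  ages <- numeric(0)
  for (k in seq_len(length(knots) - 1)) {
    a0 <- knots[k]; a1 <- knots[k + 1]
    lmax <- max(adenoma_log_risk(c(a0, a1), female, alpha0, params))
    if (!is.finite(lmax)) {
      if (lmax == -Inf) next
      stop("non-finite adenoma intensity on [", a0, ", ", a1, "]")
    }
    m <- exp(lmax)
    n_cand <- stats::rpois(1, m * (a1 - a0))
    if (n_cand == 0) next
    cand <- stats::runif(n_cand, a0, a1)
    keep <- stats::runif(n_cand) <
      exp(adenoma_log_risk(cand, female, alpha0, params) - lmax)
    ages <- c(ages, cand[keep])
  }
  ages <- sort(ages)
  tibble::tibble(
    init_age = ages,
    location = ifelse(stats::runif(length(ages)) < p_rectum, "rectum", "colon")
  )
}

#' Frechet distribution of time to reach 10 mm
#'
#' The hypothetical time for an adenoma to reach 10 mm diameter follows a
#' Frechet distribution with CDF \eqn{F(t) = \exp(-(t/\beta_2)^{-\beta_1})},
#' with separate shape/scale pairs for colon and rectum.
#'
#' @param t Time in years (`t >= 0`).
#' @param shape,scale Frechet shape \eqn{\beta_1} and scale \eqn{\beta_2},
#'   both strictly positive.
#' @return `frechet_cdf()`: probabilities; `frechet_quantile()`: years.
#' @export
frechet_cdf <- function(t, shape, scale) {
  stopifnot(all(t >= 0), shape > 0, scale > 0)
  ifelse(t == 0, 0, exp(-(t / scale)^(-shape)))
}

#' @rdname frechet_cdf
#' @param p Probability in (0, 1).
#' @export
frechet_quantile <- function(p, shape, scale) {
  stopifnot(all(p > 0), all(p < 1), shape > 0, scale > 0)
  scale * (-log(p))^(-1 / shape)
}

#' @rdname frechet_cdf
#' @param location `"colon"` or `"rectum"`; selects the parameter pair.
#' @param params An [nh_params()] object.
#' @param n Number of draws.
#' @export
sample_t10mm <- function(location, params, n = 1) {
  shape <- ifelse(location == "rectum", params$beta1_rectum, params$beta1_colon)
  scale <- ifelse(location == "rectum", params$beta2_rectum, params$beta2_colon)
  frechet_quantile(stats::runif(max(n, length(location))), shape, scale)
}

#' Richards growth curve for adenoma diameter
#'
#' Diameter at time `t` after initiation:
#' \deqn{d(t) = d_\infty\bigl[1 + ((d_0/d_\infty)^{1/p} - 1)e^{-\lambda t}\bigr]^p,}
#' strictly increasing from `d0` at `t = 0` toward `d_infinity`.
#'
#' @param t Years since initiation (`t >= 0`, vectorised).
#' @param growth_rate Per-adenoma rate \eqn{\lambda_{ij}} (per year).
#' @param params An [nh_params()] object (supplies `d0`, `d_infinity`,
#'   `p_growth`).
#' @return Diameter in mm.
#' @export
richards_diameter <- function(t, growth_rate, params) {
  stopifnot(all(t >= 0))
  p <- params$p_growth
  dinf <- params$d_infinity
  dinf * (1 + ((params$d0 / dinf)^(1 / p) - 1) * exp(-growth_rate * t))^p
}

#' Growth rate from the time-to-10mm draw
#'
#' Inverts the Richards curve at `d = 10` mm:
#' \deqn{\lambda = -\ln\frac{(10/d_\infty)^{1/p} - 1}{(d_0/d_\infty)^{1/p} - 1}
#'   \big/ t_{10mm}.}
#'
#' @param t_10mm Time to reach 10 mm (years, `> 0`, vectorised).
#' @param params An [nh_params()] object.
#' @return Growth rate per year (`> 0`).
#' @export
solve_growth_rate <- function(t_10mm, params) {
  stopifnot(all(t_10mm > 0))
  p <- params$p_growth
  dinf <- params$d_infinity
  if (params$d0 >= 10 || dinf <= 10) {
    stop("growth-rate inversion requires d0 < 10 mm < d_infinity")
  }
  ratio <- ((10 / dinf)^(1 / p) - 1) / ((params$d0 / dinf)^(1 / p) - 1)
  -log(ratio) / t_10mm
}

# time for the Richards curve to reach diameter `d`; Inf if d >= d_infinity
time_to_diameter <- function(d, growth_rate, params) {
  p <- params$p_growth
  dinf <- params$d_infinity
  out <- rep(Inf, length(d))
  reach <- d < dinf
  gr <- rep_len(growth_rate, length(d))
  ratio <- ((pmin(d, dinf * (1 - 1e-12)) / dinf)^(1 / p) - 1) /
    ((params$d0 / dinf)^(1 / p) - 1)
  out[reach] <- pmax(0, -log(ratio[reach]) / gr[reach])
  out
}

#' Size at transition to preclinical cancer
#'
#' Lognormal draw with log-scale mean
#' \deqn{\mu_{ij} = \gamma_0 + \gamma_1 female + \gamma_2 rectum
#'   + \gamma_3 female \cdot rectum + \gamma_4 age + \gamma_5 age^2,}
#' where `age` is the age at adenoma initiation in decades centred at 50
#' (i.e. `(init_age - 50)/10`), and log-scale sd `sigma_gamma`. An adenoma
#' transitions if and only if its diameter trajectory reaches this size
#' before the simulation horizon, so the transition probability increases
#' with attained size.
#'
#' @param female,rectum 0/1 indicators (vectorised).
#' @param init_age Age at adenoma initiation in years (vectorised).
#' @param params An [nh_params()] object.
#' @return Transition size in mm.
#' @export
sample_transition_size <- function(female, rectum, init_age, params) {
  ag <- (init_age - 50) / 10
  mu <- params$gamma0 + params$gamma1 * female + params$gamma2 * rectum +
    params$gamma3 * female * rectum + params$gamma4 * ag + params$gamma5 * ag^2
  n <- max(length(female), length(rectum), length(init_age))
  exp(stats::rnorm(n, mu, params$sigma_gamma))
}

#' Sojourn time from preclinical to clinical cancer
#'
#' Colon sojourn times are Weibull with survival
#' \eqn{S(t) = \exp(-(t/\lambda_1)^{\lambda_2})} (scale `lambda1`, shape
#' `lambda2`). Rectal cancers use the same shape with scale
#' \eqn{\lambda_1 e^{\lambda_3}} (accelerated-scale convention), so that the
#' closed-form means are \eqn{\lambda_1\Gamma(1+1/\lambda_2)} for the colon
#' and \eqn{\lambda_1 e^{\lambda_3}\Gamma(1+1/\lambda_2)} for the rectum.
#'
#' @param location `"colon"` or `"rectum"` (vectorised).
#' @param params An [nh_params()] object.
#' @param n Number of draws.
#' @return Sojourn times in years.
#' @export
sample_sojourn_time <- function(location, params, n = 1) {
  n <- max(n, length(location))
  scale <- params$lambda1 * ifelse(location == "rectum", exp(params$lambda3), 1)
  stats::rweibull(n, shape = params$lambda2, scale = scale)
}

#' Closed-form mean sojourn time
#'
#' @inheritParams sample_sojourn_time
#' @return Mean sojourn time in years: \eqn{\lambda_1\Gamma(1+1/\lambda_2)}
#'   (colon) or \eqn{\lambda_1 e^{\lambda_3}\Gamma(1+1/\lambda_2)} (rectum).
#' @export
#' @examples
#' mean_sojourn_time(nh_params(lambda1 = 3.77, lambda2 = 2.38), "colon")
mean_sojourn_time <- function(params, location = c("colon", "rectum")) {
  location <- match.arg(location, several.ok = TRUE)
  base <- params$lambda1 * gamma(1 + 1 / params$lambda2)
  ifelse(location == "rectum", base * exp(params$lambda3), base)
}

#' Synthetic other-cause life table
#'
#' Piecewise-constant all-cause (non-CRC) mortality hazards rising with age.
#' This is a synthetic stand-in with the structure (not the values) of a
#' national life table; it exists to impose realistic censoring on the
#' natural-history trajectories.
#'
#' @param breaks Ascending age breakpoints starting at 0.
#' @param hazards Hazard per year on each interval (length
#'   `length(breaks) - 1` if the last break is the terminal age, else
#'   `length(breaks)` with the last hazard extending upward).
#' @param max_age All survivors die by this age.
#' @return An object of class `life_table`.
#' @export
life_table <- function(breaks = c(0, 40, 50, 60, 70, 80, 90),
                       hazards = c(0.0015, 0.004, 0.008, 0.018, 0.045, 0.10, 0.22),
                       max_age = 100) {
  stopifnot(length(hazards) == length(breaks), all(diff(breaks) > 0),
            all(hazards > 0), max_age > max(breaks))
  structure(list(breaks = breaks, hazards = hazards, max_age = max_age),
            class = "life_table")
}

#' Sample ages at death from other causes
#'
#' Piecewise-exponential inversion, truncated at `max_age`.
#'
#' @param n Number of draws.
#' @param lt A [life_table()].
#' @param min_age Condition on survival to this age (default 0).
#' @return Ages at death in years, all in `(min_age, max_age]`.
#' @export
sample_death_age <- function(n, lt = life_table(), min_age = 0) {
  edges <- c(lt$breaks, lt$max_age)
  haz <- lt$hazards
  # cumulative hazard at segment edges
  cumh <- c(0, cumsum(haz * diff(edges)))
  h_min <- piecewise_cumhaz(min_age, edges, haz, cumh)
  u <- stats::runif(n)
  # conditional on survival to min_age: H(t) = h_min - log(1-u)
  target <- h_min - log1p(-u)
  idx <- findInterval(target, cumh, rightmost.closed = TRUE)
  idx <- pmin(idx, length(haz))
  age <- edges[idx] + (target - cumh[idx]) / haz[idx]
  pmin(age, lt$max_age)
}

piecewise_cumhaz <- function(a, edges, haz, cumh) {
  i <- min(max(findInterval(a, edges), 1), length(haz))
  cumh[i] + (a - edges[i]) * haz[i]
}

#' Simulate one agent's full event history (reference implementation)
#'
#' A readable straight-loop implementation of the natural-history plumbing:
#' draws the person intercept, other-cause death age, adenoma initiations,
#' and for each adenoma the time-to-10mm, growth rate, transition size/age,
#' sojourn time and clinical-detection age. The first clinical colorectal
#' cancer is the minimum clinical age over adenomas, censored by other-cause
#' death and the simulation horizon. The compiled population simulator
#' ([simulate_population()]) is the fast path; this function is its
#' independent counterpart used for inspection and cross-checking.
#'
#' @param female 0/1 indicator.
#' @param params An [nh_params()] object.
#' @param horizon Maximum simulated age (years, `<= 100`).
#' @param lt A [life_table()].
#' @param p_rectum Rectal location probability.
#' @param alpha0 Optional fixed person intercept; drawn from
#'   `N(A, sigma_alpha)` if `NULL`.
#' @return A list of class `agent_history` with elements `female`, `alpha0`,
#'   `death_age`, `clinical_age` (`Inf` if none), and `adenomas` (tibble).
#' @export
simulate_agent <- function(female, params, horizon = 100, lt = life_table(),
                           p_rectum = 0.25, alpha0 = NULL) {
  stopifnot(horizon <= 100 + 1e-9)
  if (is.null(alpha0)) alpha0 <- stats::rnorm(1, params$A, params$sigma_alpha)
  death_age <- sample_death_age(1, lt)
  inits <- sample_adenoma_initiations(female, alpha0, params,
                                      horizon = min(horizon, death_age),
                                      p_rectum = p_rectum)
  n <- nrow(inits)
  if (n == 0) {
    aden <- tibble::tibble(
      init_age = numeric(0), location = character(0), t_10mm = numeric(0),
      growth_rate = numeric(0), transition_size = numeric(0),
      transition_age = numeric(0), sojourn_time = numeric(0),
      clinical_age = numeric(0)
    )
    return(structure(list(female = female, alpha0 = alpha0,
                          death_age = death_age, clinical_age = Inf,
                          adenomas = aden), class = "agent_history"))
  }
  t10 <- sample_t10mm(inits$location, params)
  lam <- solve_growth_rate(t10, params)
  tsize <- sample_transition_size(female, as.integer(inits$location == "rectum"),
                                  inits$init_age, params)
  t_trans <- time_to_diameter(tsize, lam, params)
  transition_age <- inits$init_age + t_trans
  transition_age[transition_age > horizon] <- NA_real_
  sojourn <- ifelse(is.na(transition_age), NA_real_,
                    sample_sojourn_time(inits$location, params, n))
  clinical_age <- transition_age + sojourn
  aden <- tibble::tibble(
    init_age = inits$init_age, location = inits$location,
    t_10mm = t10, growth_rate = lam, transition_size = tsize,
    transition_age = transition_age, sojourn_time = sojourn,
    clinical_age = clinical_age
  )
  cl <- suppressWarnings(min(clinical_age, na.rm = TRUE))
  if (!is.finite(cl) || cl >= min(death_age, horizon)) cl <- Inf
  structure(list(female = female, alpha0 = alpha0, death_age = death_age,
                 clinical_age = cl, adenomas = aden),
            class = "agent_history")
}

#' @export
print.agent_history <- function(x, ...) {
  cat("<agent_history> female =", x$female,
      "| death (other cause) at", round(x$death_age, 1),
      "| clinical CRC:",
      if (is.finite(x$clinical_age)) round(x$clinical_age, 1) else "none", "\n")
  print(x$adenomas)
  invisible(x)
}

#' Tidy export of an agent history
#'
#' One row per event (initiation, transition, clinical detection, death) for
#' debugging and plotting.
#'
#' @param x An `agent_history`.
#' @param ... Unused.
#' @return A tibble with columns `event`, `age`, `location`, `size`.
#' @export
tidy.agent_history <- function(x, ...) {
  a <- x$adenomas
  ev <- dplyr::bind_rows(
    tibble::tibble(event = "initiation", age = a$init_age,
                   location = a$location, size = rep(1, nrow(a))),
    tibble::tibble(event = "transition",
                   age = a$transition_age, location = a$location,
                   size = a$transition_size)[!is.na(a$transition_age), ],
    tibble::tibble(event = "clinical_crc", age = x$clinical_age,
                   location = NA_character_, size = NA_real_)[is.finite(x$clinical_age), ],
    tibble::tibble(event = "death_other_cause", age = x$death_age,
                   location = NA_character_, size = NA_real_)
  )
  dplyr::arrange(ev, .data$age)
}
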