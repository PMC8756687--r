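#' Define a simulated study population
#'
#' A study population matches the design of the study a calibration target
#' comes from: number of agents, entry-age range, sex mix and the one-time
#' screening test (if any). Agents are assumed free of clinically detected
#' colorectal cancer at entry and never previously screened; agents who die
#' or present clinically before their entry age are excluded from the
#' eligible set when targets are computed. Entry ages and sexes are assigned
#' deterministically (stratified over the age range and the sex mix), so all
#' Monte-Carlo variation comes from the natural-history draws.
#'
#' @param id Identifier string.
#' @param n_agents Number of simulated agents (> 0).
#' @param age_lower,age_upper Entry-age range in years.
#' @param fraction_female Fraction of female agents, in `[0, 1]`.
#' @param test `"none"`, `"colonoscopy"` or `"sigmoidoscopy"`.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(id, n_agents, age_lower, age_upper,
                       fraction_female = 0.5,
                       test = c("none", "colonoscopy", "sigmoidoscopy")) {
  test <- match.arg(test)
  stopifnot(n_agents > 0, age_lower >= 20, age_upper <= 100,
            age_lower < age_upper,
            fraction_female >= 0, fraction_female <= 1)
  structure(list(id = id, n_agents = as.integer(n_agents),
                 age_lower = age_lower, age_upper = age_upper,
                 fraction_female = fraction_female, test = test),
            class = "study_spec")
}

# deterministic covariates: sexes interleaved to hit fraction_female exactly
# (up to rounding), ages stratified uniformly over the range within sex
spec_covariates <- function(spec) {
  n <- spec$n_agents
  nf <- round(n * spec$fraction_female)
  female <- c(rep(1L, nf), rep(0L, n - nf))
  age <- numeric(n)
  for (s in c(1L, 0L)) {
    i <- which(female == s)
    if (length(i)) {
      age[i] <- spec$age_lower +
        (spec$age_upper - spec$age_lower) * (seq_along(i) - 0.5) / length(i)
    }
  }
  list(female = female, index_age = age)
}

test_code <- function(test) {
  c(none = 0L, colonoscopy = 1L, sigmoidoscopy = 2L)[[test]]
}

#' Simulate a study population
#'
#' Runs the compiled natural-history core for every agent in a
#' [study_spec()], including the one-time screen (if any) at each agent's
#' entry age. Each agent owns an independent random stream derived from
#' `seed` and the agent index, so results are invariant to agent ordering
#' and to batch partitioning.
#'
#' @param spec A [study_spec()].
#' @param params An [nh_params()] object.
#' @param seed Integer seed for the population.
#' @param model A [sensitivity_model()].
#' @param lt A [life_table()].
#' @param p_rectum Rectal location probability for new adenomas.
#' @param horizon Maximum simulated age in years.
#' @param agent_offset Offset added to agent indices when deriving their
#'   random streams; lets a population be simulated in batches whose
#'   concatenation is identical to one full run.
#' @return An object of class `crc_population`: a list with tibbles
#'   `agents` (per-agent entry age, sex, death age, clinical-cancer age,
#'   eligibility and detected-lesion counts) and `lesions` (one row per
#'   lesion detected at the screen).
#' @export
simulate_population <- function(spec, params, seed, model = sensitivity_model(),
                                lt = life_table(), p_rectum = 0.25,
                                horizon = 100, agent_offset = 0) {
  cov <- spec_covariates(spec)
  raw <- .simulate_population_cpp(
    unlist(unclass(params)), cov$female, cov$index_age, p_rectum,
    lt$breaks, lt$hazards, lt$max_age,
    test_code(spec$test),
    model$anchors$size, model$anchors$sensitivity, model$preclin_floor,
    model$sigmoid_colon_reach, horizon, as.double(seed %% 2^31),
    as.integer(agent_offset)
  )
  agents <- tibble::tibble(
    agent = seq_along(cov$female),
    female = cov$female,
    index_age = cov$index_age,
    death_age = raw$death_age,
    clinical_age = raw$clinical_age,
    eligible = raw$eligible == 1L,
    n_det_adenoma = raw$n_det_adenoma,
    n_det_preclin = raw$n_det_preclin
  )
  lesions <- tibble::tibble(
    agent = raw$lesion_agent,
    size = raw$lesion_size,
    is_preclinical = raw$lesion_preclin == 1L,
    location = ifelse(raw$lesion_rectum == 1L, "rectum", "colon")
  )
  structure(list(spec = spec, agents = agents, lesions = lesions),
            class = "crc_population")
}

#' @export
print.crc_population <- function(x, ...) {
  cat("<crc_population>", x$spec$id, "-", nrow(x$agents), "agents,",
      sum(x$agents$eligible), "eligible,", nrow(x$lesions),
      "detected lesions\n")
  invisible(x)
}

#' Export agent histories as a tidy event table
#'
#' @param x A `crc_population`.
#' @param ... Unused.
#' @return Tibble with one row per agent-level event.
#' @export
tidy.crc_population <- function(x, ...) {
  a <- x$agents
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(agent = a$agent, event = "entry", age = a$index_age),
    tibble::tibble(agent = a$agent, event = "clinical_crc",
                   age = a$clinical_age)[is.finite(a$clinical_age), ],
    tibble::tibble(agent = a$agent, event = "death_other_cause",
                   age = a$death_age)
  ), .data$agent, .data$age)
}
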