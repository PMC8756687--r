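#' Natural-history parameter set
#'
#' Constructs the full parameter set of the colorectal-cancer natural-history
#' model: 22 calibrated parameters plus two fixed inputs (the minimum and
#' maximum adenoma diameters `d0` and `d_infinity`). Calibrated parameters
#' cover adenoma risk (`A`, `sigma_alpha`, `alpha1`, and the piecewise-linear
#' age slopes `alpha20`, `alpha50`, `alpha60`, `alpha70`), adenoma growth
#' (Frechet shape/scale pairs for colon and rectum plus the Richards shape
#' `p_growth`), size at transition to preclinical cancer (`gamma0`..`gamma5`,
#' `sigma_gamma`), and sojourn time (`lambda1`, `lambda2`, `lambda3`).
#'
#' @param ... Named parameter values overriding the defaults returned by
#'   [default_nh_params()].
#' @param .values Optionally, a named list or named numeric vector of
#'   parameter values (merged after `...`).
#'
#' @return An object of class `nh_params`: a named list of 24 numeric scalars.
#' @export
#' @examples
#' p <- nh_params(lambda1 = 3.77, lambda2 = 2.38, lambda3 = 0.87)
#' mean_sojourn_time(p, "colon")
nh_params <- function(..., .values = NULL) {
  p <- default_nh_params()
  ov <- c(list(...), as.list(.values))
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) {
      stop("unknown natural-history parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(ov)] <- vapply(ov, as.numeric, numeric(1))
  }
  validate_nh_params(p)
}

#' @rdname nh_params
#' @export
default_nh_params <- function() {
  structure(list(
    A = -5.0, sigma_alpha = 0.55, alpha1 = -0.25,
    alpha20 = 0.04, alpha50 = 0.025, alpha60 = 0.015, alpha70 = 0.01,
    beta1_colon = 2.0, beta2_colon = 11.0,
    beta1_rectum = 2.0, beta2_rectum = 9.0,
    p_growth = 1.0,
    gamma0 = 3.1, gamma1 = -0.1, gamma2 = 0.1, gamma3 = 0.0,
    gamma4 = -0.1, gamma5 = 0.0, sigma_gamma = 0.6,
    lambda1 = 3.77, lambda2 = 2.38, lambda3 = 0.87,
    d0 = 1.0, d_infinity = 50.0
  ), class = "nh_params")
}

#' Names of the 22 calibrated parameters
#'
#' `d0` and `d_infinity` are fixed model inputs and are never sampled or
#' calibrated.
#'
#' @return Character vector of length 22.
#' @export
calibrated_param_names <- function() {
  c("A", "sigma_alpha", "alpha1", "alpha20", "alpha50", "alpha60", "alpha70",
    "beta1_colon", "beta2_colon", "beta1_rectum", "beta2_rectum",
    "p_growth", "gamma0", "gamma1", "gamma2", "gamma3", "gamma4", "gamma5",
    "sigma_gamma", "lambda1", "lambda2", "lambda3")
}

validate_nh_params <- function(p) {
  stopifnot(is.list(p))
  need <- c(calibrated_param_names(), "d0", "d_infinity")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  pos <- c("sigma_alpha", "beta1_colon", "beta2_colon", "beta1_rectum",
           "beta2_rectum", "p_growth", "sigma_gamma", "lambda1", "lambda2")
  strict <- c("beta1_colon", "beta2_colon", "beta1_rectum", "beta2_rectum",
              "p_growth", "lambda1", "lambda2")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.finite(v) || v < 0 || (nm %in% strict && v <= 0)) {
      stop("parameter ", nm, " must be positive, got ", v)
    }
  }
  if (!(p$d0 > 0 && p$d0 < p$d_infinity)) {
    stop("require 0 < d0 < d_infinity")
  }
  class(p) <- "nh_params"
  p
}

#' @export
print.nh_params <- function(x, ...) {
  cat("<nh_params> 22 calibrated parameters + fixed d0 =", x$d0,
      "mm, d_infinity =", x$d_infinity, "mm\n")
  print(unlist(x[calibrated_param_names()]))
  invisible(x)
}

#' Convert a parameter set to / from a one-row tibble
#'
#' @param x An `nh_params` object.
#' @param ... Unused.
#' @return `tidy.nh_params()` returns a tibble with columns `term` and
#'   `estimate` (24 rows).
#' @export
tidy.nh_params <- function(x, ...) {
  tibble::tibble(term = names(x), estimate = unlist(x, use.names = FALSE))
}

#' Merge free-parameter values into a base parameter set
#'
#' @param base An `nh_params` object.
#' @param theta Named numeric vector (or one-row data frame) of values for a
#'   subset of the calibrated parameters.
#' @return An `nh_params` object.
#' @export
set_params <- function(base, theta) {
  if (is.data.frame(theta)) theta <- unlist(theta[1, , drop = FALSE])
  nh_params(.values = utils::modifyList(unclass(base), as.list(theta)))
}

#' Read or write parameter sets
#'
#' A single named parameter set round-trips through YAML; a table of draws
#' (one row per draw, named columns) round-trips through CSV.
#'
#' @param path File path.
#' @param params An `nh_params` object (`write_params_yaml`) or data frame of
#'   draws (`write_draws_csv`).
#' @return `read_params_yaml()` returns an `nh_params`; `read_draws_csv()` a
#'   tibble.
#' @export
write_params_yaml <- function(params, path) {
  yaml::write_yaml(lapply(unclass(params), as.numeric), path, precision = 15)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  nh_params(.values = yaml::read_yaml(path))
}

#' @rdname write_params_yaml
#' @export
write_draws_csv <- function(params, path) {
  utils::write.csv(format_full_precision(params), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_draws_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  # draw tables are numeric throughout; whole numbers come back as double
  df[] <- lapply(df, function(x) if (is.integer(x)) as.double(x) else x)
  tibble::as_tibble(df)
}

# floats with 17 significant digits so CSV round-trips exactly
format_full_precision <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}
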