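#' Size-dependent screening-test sensitivity model
#'
#' Colonoscopy sensitivity for adenomas is a monotone piecewise-linear
#' function of lesion diameter through the anchor points
#' (5 mm, 0.81), (10 mm, 0.92), (15 mm, 0.98), extended with a configurable
#' sensitivity `s_min` at the 1 mm minimum diameter and 1.0 at 20 mm and
#' above. For preclinical cancers the sensitivity is the maximum of a floor
#' (default 0.95) and the size-based adenoma sensitivity, so it equals 0.95
#' for preclinical cancers of 12 mm or smaller and exceeds 0.95 for larger
#' ones. A reach model covers tests that do not examine the whole colon:
#' flexible sigmoidoscopy examines all rectal lesions and a configurable
#' fraction of colon lesions (a distal-colon stand-in); colonoscopy reaches
#' everything.
#'
#' @param anchors Data frame with columns `size` (mm, ascending) and
#'   `sensitivity` (non-decreasing, in `[0, 1]`).
#' @param s_min Sensitivity at the 1 mm minimum diameter.
#' @param preclin_floor Sensitivity floor for preclinical cancers.
#' @param s_max Sensitivity at 20 mm and above.
#' @param sigmoid_colon_reach Fraction of colon lesions within reach of
#'   flexible sigmoidoscopy.
#' @return An object of class `sensitivity_model`.
#' @export
#' @examples
#' m <- sensitivity_model()
#' adenoma_sensitivity(10, m)     # 0.92
#' preclinical_sensitivity(12, m) # 0.95
sensitivity_model <- function(anchors = NULL, s_min = 0.70, s_max = 1.0,
                              preclin_floor = 0.95,
                              sigmoid_colon_reach = 0.4) {
  if (is.null(anchors)) {
    anchors <- tibble::tibble(size = c(5, 10, 15), sensitivity = c(0.81, 0.92, 0.98))
  }
  anchors <- tibble::as_tibble(anchors)
  full <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(size = 1, sensitivity = s_min),
    anchors[anchors$size > 1 & anchors$size < 20, ],
    tibble::tibble(size = 20, sensitivity = s_max)
  ), .data$size)
  stopifnot(all(diff(full$sensitivity) >= 0),
            all(full$sensitivity >= 0 & full$sensitivity <= 1),
            preclin_floor >= 0, preclin_floor <= 1,
            sigmoid_colon_reach >= 0, sigmoid_colon_reach <= 1)
  structure(list(anchors = full, preclin_floor = preclin_floor,
                 sigmoid_colon_reach = sigmoid_colon_reach),
            class = "sensitivity_model")
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat("<sensitivity_model> preclinical floor", x$preclin_floor,
      "| sigmoidoscopy colon reach", x$sigmoid_colon_reach, "\n")
  print(x$anchors)
  invisible(x)
}

#' Test sensitivity by lesion size
#'
#' @param size Lesion diameter in mm (`>= 1`, vectorised).
#' @param model A [sensitivity_model()].
#' @return Detection probability in `[0, 1]`; exact at the anchor points.
#' @export
adenoma_sensitivity <- function(size, model = sensitivity_model()) {
  if (any(size < 1)) stop("lesion size below the 1 mm minimum diameter")
  stats::approx(model$anchors$size, model$anchors$sensitivity, xout = size,
                rule = 2)$y
}

#' @rdname adenoma_sensitivity
#' @export
preclinical_sensitivity <- function(size, model = sensitivity_model()) {
  pmax(model$preclin_floor, adenoma_sensitivity(size, model))
}

#' Simulate a one-time screening exam for one agent
#'
#' Each lesion present at `screen_age` (adenomas at their current Richards
#' diameter; preclinical cancers not yet clinically detected) is detected
#' independently with its size-based sensitivity multiplied by the test's
#' reach probability for its location. Detected lesions are removed (no
#' recurrence is modelled); the screen is one-time.
#'
#' @param history An `agent_history` from [simulate_agent()].
#' @param screen_age Age at the screen; must precede clinical cancer and
#'   other-cause death.
#' @param test `"colonoscopy"` or `"sigmoidoscopy"`.
#' @param params The [nh_params()] used to simulate `history`.
#' @param model A [sensitivity_model()].
#' @return A tibble (one row per lesion present) with columns `location`,
#'   `size`, `is_preclinical`, `detected`, plus attribute
#'   `cancer_detected` (any preclinical cancer detected).
#' @export
simulate_screen <- function(history, screen_age,
                            test = c("colonoscopy", "sigmoidoscopy"),
                            params, model = sensitivity_model()) {
  test <- match.arg(test)
  if (screen_age >= history$death_age || screen_age >= history$clinical_age) {
    stop("screen_age after clinical CRC or death; exclude such agents upstream")
  }
  a <- history$adenomas
  present <- a$init_age <= screen_age &
    (is.na(a$clinical_age) | a$clinical_age > screen_age)
  a <- a[present, , drop = FALSE]
  if (nrow(a) == 0) {
    out <- tibble::tibble(location = character(0), size = numeric(0),
                          is_preclinical = logical(0), detected = logical(0))
    attr(out, "cancer_detected") <- FALSE
    return(out)
  }
  size <- richards_diameter(screen_age - a$init_age, a$growth_rate, params)
  is_pre <- !is.na(a$transition_age) & a$transition_age <= screen_age
  sens <- ifelse(is_pre, preclinical_sensitivity(size, model),
                 adenoma_sensitivity(size, model))
  reach <- if (test == "sigmoidoscopy") {
    ifelse(a$location == "rectum", 1, model$sigmoid_colon_reach)
  } else 1
  detected <- stats::runif(nrow(a)) < sens * reach
  out <- tibble::tibble(location = a$location, size = size,
                        is_preclinical = is_pre, detected = detected)
  attr(out, "cancer_detected") <- any(is_pre & detected)
  out
}

#' Serialize a sensitivity model to / from YAML
#'
#' Makes experiments with alternative sensitivity assumptions a
#' configuration change rather than a code change.
#'
#' @param model A [sensitivity_model()].
#' @param path File path.
#' @export
write_sensitivity_yaml <- function(model, path) {
  yaml::write_yaml(list(
    anchors = lapply(seq_len(nrow(model$anchors)), function(i)
      list(size = model$anchors$size[i],
           sensitivity = model$anchors$sensitivity[i])),
    preclin_floor = model$preclin_floor,
    sigmoid_colon_reach = model$sigmoid_colon_reach
  ), path)
  invisible(path)
}

#' @rdname write_sensitivity_yaml
#' @export
read_sensitivity_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  anchors <- dplyr::bind_rows(lapply(y$anchors, tibble::as_tibble))
  # the stored anchor list already includes the endpoint anchors
  m <- sensitivity_model(anchors[anchors$size > 1 & anchors$size < 20, ],
                         s_min = anchors$sensitivity[which.min(anchors$size)],
                         s_max = anchors$sensitivity[which.max(anchors$size)],
                         preclin_floor = y$preclin_floor,
                         sigmoid_colon_reach = y$sigmoid_colon_reach)
  m
}
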