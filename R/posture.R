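#' Rigid-body center-of-pressure shift for a platform tilt
#'
#' A rigid body with its centre of mass at height `com_height_m` shifts its
#' centre of pressure laterally by `100 * com_height_m * tan(tilt)` cm when
#' tilted.
#'
#' @param com_height_m Centre-of-mass height in metres (> 0); half body
#'   height is the usual approximation.
#' @param platform_tilt_deg Platform tilt in degrees, `|tilt| < 90`.
#' @return COP shift in cm (vectorised over `platform_tilt_deg`).
#' @examples
#' expected_cop_shift(0.93, 3)
#' @export
expected_cop_shift <- function(com_height_m, platform_tilt_deg) {
  if (com_height_m <= 0) {
    stop("expected_cop_shift: `com_height_m` must be positive", call. = FALSE)
  }
  if (any(abs(platform_tilt_deg) >= 90)) {
    stop("expected_cop_shift: |tilt| must be < 90 degrees", call. = FALSE)
  }
  100 * com_height_m * tan(platform_tilt_deg * pi / 180)
}

#' Convert a COP shift back to an equivalent body tilt
#'
#' Inverse of [expected_cop_shift()]: `atan(shift / (100 * com_height))` in
#' degrees. A 0.5 cm shift at a 0.93 m centre of mass corresponds to about
#' 0.3 degrees of body tilt.
#'
#' @param shift_cm COP shift in cm (vectorised).
#' @param com_height_m Centre-of-mass height in metres (> 0).
#' @return Equivalent body tilt in degrees.
#' @examples
#' cop_shift_to_tilt(0.5, 0.93)
#' @export
cop_shift_to_tilt <- function(shift_cm, com_height_m) {
  if (com_height_m <= 0) {
    stop("cop_shift_to_tilt: `com_height_m` must be positive", call. = FALSE)
  }
  atan(shift_cm / (100 * com_height_m)) * 180 / pi
}

#' Counteraction slope: measured vs rigid-body COP
#'
#' Ordinary least-squares regression of measured COP on the rigid-body
#' expectation. A slope of 1 means the body follows the platform rigidly; a
#' slope below 1 means the stance counteracts a fraction `1 - slope` of the
#' tilt.
#'
#' @param measured_cop,expected_cop Equal-length numeric series (cm), n >= 2;
#'   `expected_cop` must not be constant.
#' @return A list with `slope`, `intercept`, `n`.
#' @examples
#' counteraction_slope(c(-2, 0, 2) * 0.73, c(-2, 0, 2))
#' @export
counteraction_slope <- function(measured_cop, expected_cop) {
  if (length(measured_cop) != length(expected_cop)) {
    stop("counteraction_slope: series must have equal length", call. = FALSE)
  }
  if (length(measured_cop) < 2) {
    stop("counteraction_slope: need at least 2 observations", call. = FALSE)
  }
  if (stats::sd(expected_cop) == 0) {
    stop("counteraction_slope: `expected_cop` is constant", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, expected_cop), measured_cop)
  list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    n = length(measured_cop)
  )
}

#' Estimate postural counteraction from a trial table
#'
#' Computes the rigid-body expected COP for the head-upright RFT trials
#' (where the platform stays tilted for the whole trial), centres both the
#' measured and expected series within each participant to remove
#' idiosyncratic offsets, and regresses measured on expected by OLS.
#'
#' @param trials A trial tibble with `cop_y_cm` filled.
#' @param body_height_m Body height in metres; the centre of mass is taken at
#'   half this height.
#' @param task,block Which trials to use (defaults: RFT, head upright).
#' @return A list with `slope`, `intercept`, `n`, `counteraction`
#'   (`1 - slope`), and `per_participant`, a tibble of per-participant slopes.
#' @export
estimate_counteraction <- function(trials, body_height_m = 1.86,
                                   task = "RFT", block = "upright") {
  sub <- trials[trials$task == task & trials$block == block, , drop = FALSE]
  if (nrow(sub) < 2) {
    stop("estimate_counteraction: not enough trials after filtering", call. = FALSE)
  }
  if (all(is.na(sub$cop_y_cm))) {
    stop("estimate_counteraction: `cop_y_cm` is empty", call. = FALSE)
  }
  com <- body_height_m / 2
  sub$expected_cop <- expected_cop_shift(com, sub$platform_tilt_deg)
  centred <- sub |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      m_c = .data$cop_y_cm - mean(.data$cop_y_cm),
      e_c = .data$expected_cop - mean(.data$expected_cop)
    ) |>
    dplyr::ungroup()
  overall <- counteraction_slope(centred$m_c, centred$e_c)
  per_participant <- centred |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      slope = counteraction_slope(.data$m_c, .data$e_c)$slope,
      n = dplyr::n(),
      .groups = "drop"
    )
  list(
    slope = overall$slope,
    intercept = overall$intercept,
    n = overall$n,
    counteraction = 1 - overall$slope,
    per_participant = per_participant
  )
}
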