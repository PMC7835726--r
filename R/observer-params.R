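#' Observer model parameters
#'
#' Bundles the coefficients of the verticality observer model for one
#' participant. The five core parameters are the effective neck tilt
#' `neck_tilt_deg` (degrees; contributes only in head-tilted blocks), the
#' somatosensory noise `sigma_som`, the neck-proprioceptive noise `sigma_pro`,
#' the baseline noise of the combined visual-vestibular head-tilt channel
#' `sigma_com0` (all standard deviations in degrees), and the eccentricity
#' gain `k_com` (degrees of extra head-channel noise per degree of visual
#' tilt). Optional extensions: `omega_hisd`/`omega_bisd` are the direct-path
#' weights used by the `"free"` variant (in the open interval (0, 1));
#' `k_som` is a gain on platform tilt in the somatosensory channel (default
#' 1); `spv_neck_offset_deg` is an additive offset on the predicted
#' postural-vertical setting in head-tilted blocks (default 0).
#'
#' @param neck_tilt_deg Effective head-on-body tilt in degrees.
#' @param sigma_som,sigma_pro,sigma_com0 Channel noise SDs in degrees (> 0).
#' @param k_com Eccentricity gain on the head-channel noise (>= 0).
#' @param omega_hisd,omega_bisd Direct-path weights for the `"free"` variant,
#'   each in (0, 1); leave `NA` for the `"fixed"` and `"mle"` variants.
#' @param k_som Somatosensory gain on platform tilt (default 1).
#' @param spv_neck_offset_deg Additive SPV offset in head-tilted blocks (deg).
#' @return An object of class `observer_params` (a named list).
#' @examples
#' observer_params(9.416, 0.811, 9.276, 8.572, 0.249)
#' @export
observer_params <- function(neck_tilt_deg,
                            sigma_som,
                            sigma_pro,
                            sigma_com0,
                            k_com,
                            omega_hisd = NA_real_,
                            omega_bisd = NA_real_,
                            k_som = 1,
                            spv_neck_offset_deg = 0) {
  p <- list(
    neck_tilt_deg = as.numeric(neck_tilt_deg),
    sigma_som = as.numeric(sigma_som),
    sigma_pro = as.numeric(sigma_pro),
    sigma_com0 = as.numeric(sigma_com0),
    k_com = as.numeric(k_com),
    omega_hisd = as.numeric(omega_hisd),
    omega_bisd = as.numeric(omega_bisd),
    k_som = as.numeric(k_som),
    spv_neck_offset_deg = as.numeric(spv_neck_offset_deg)
  )
  validate_observer_params(p)
  structure(p, class = "observer_params")
}

validate_observer_params <- function(p) {
  scalar_fields <- c(
    "neck_tilt_deg", "sigma_som", "sigma_pro", "sigma_com0", "k_com",
    "omega_hisd", "omega_bisd", "k_som", "spv_neck_offset_deg"
  )
  for (f in scalar_fields) {
    if (length(p[[f]]) != 1L) {
      stop("observer_params: `", f, "` must be a single value", call. = FALSE)
    }
  }
  finite_fields <- setdiff(scalar_fields, c("omega_hisd", "omega_bisd"))
  for (f in finite_fields) {
    if (!is.finite(p[[f]])) {
      stop("observer_params: `", f, "` must be finite", call. = FALSE)
    }
  }
  for (f in c("sigma_som", "sigma_pro", "sigma_com0")) {
    if (p[[f]] <= 0) {
      stop("observer_params: `", f, "` must be strictly positive", call. = FALSE)
    }
  }
  if (p$k_com < 0) stop("observer_params: `k_com` must be >= 0", call. = FALSE)
  for (f in c("omega_hisd", "omega_bisd")) {
    w <- p[[f]]
    if (!is.na(w) && (w <= 0 || w >= 1)) {
      stop("observer_params: `", f, "` must lie in the open interval (0, 1)",
        call. = FALSE
      )
    }
  }
  invisible(p)
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf(
    "  neck_tilt_deg = %.3f, sigma_som = %.3f, sigma_pro = %.3f\n",
    x$neck_tilt_deg, x$sigma_som, x$sigma_pro
  ))
  cat(sprintf("  sigma_com0 = %.3f, k_com = %.3f\n", x$sigma_com0, x$k_com))
  if (!is.na(x$omega_hisd) || !is.na(x$omega_bisd)) {
    cat(sprintf(
      "  omega_hisd = %.3f, omega_bisd = %.3f\n",
      x$omega_hisd, x$omega_bisd
    ))
  }
  if (x$k_som != 1) cat(sprintf("  k_som = %.3f\n", x$k_som))
  if (x$spv_neck_offset_deg != 0) {
    cat(sprintf("  spv_neck_offset_deg = %.3f\n", x$spv_neck_offset_deg))
  }
  invisible(x)
}

#' Coerce a one-row data frame or named list to observer parameters
#'
#' @param x A named list, one-row data frame, or `observer_params` object with
#'   at least the five core parameter fields.
#' @return An `observer_params` object.
#' @export
as_observer_params <- function(x) {
  if (inherits(x, "observer_params")) {
    return(x)
  }
  x <- as.list(x)
  grab <- function(field, default) {
    v <- x[[field]]
    if (is.null(v)) default else v
  }
  observer_params(
    neck_tilt_deg = x$neck_tilt_deg,
    sigma_som = x$sigma_som,
    sigma_pro = x$sigma_pro,
    sigma_com0 = x$sigma_com0,
    k_com = x$k_com,
    omega_hisd = grab("omega_hisd", NA_real_),
    omega_bisd = grab("omega_bisd", NA_real_),
    k_som = grab("k_som", 1),
    spv_neck_offset_deg = grab("spv_neck_offset_deg", 0)
  )
}

check_variant <- function(variant) {
  match.arg(variant, c("mle", "fixed", "free"))
}

check_variant_params <- function(params, variant) {
  if (variant == "free" && (is.na(params$omega_hisd) || is.na(params$omega_bisd))) {
    stop("variant \"free\" requires `omega_hisd` and `omega_bisd`", call. = FALSE)
  }
  invisible(params)
}
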