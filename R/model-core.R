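#' Visual tilt produced by a stimulus combination
#'
#' The tilt of the visual scene relative to gravity is the sum of platform
#' tilt, neck tilt and the commanded camera tilt of the see-through display.
#' All angles are in degrees; positive is clockwise from the participant's
#' perspective.
#'
#' @param platform_tilt_deg,neck_tilt_deg,ar_tilt_deg Tilt angles in degrees
#'   (vectorised; recycled to a common length).
#' @return Visual tilt in degrees.
#' @examples
#' visual_tilt(3, 15, -36)
#' @export
visual_tilt <- function(platform_tilt_deg, neck_tilt_deg, ar_tilt_deg) {
  args <- vctrs_recycle(
    platform_tilt_deg = platform_tilt_deg,
    neck_tilt_deg = neck_tilt_deg,
    ar_tilt_deg = ar_tilt_deg
  )
  if (!all(vapply(args, function(a) all(is.finite(a)), logical(1)))) {
    stop("visual_tilt: all angles must be finite", call. = FALSE)
  }
  args$platform_tilt_deg + args$neck_tilt_deg + args$ar_tilt_deg
}

# base-R recycling with a common-length check
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, integer(1)))
  bad <- vapply(args, function(a) !(length(a) %in% c(1L, n)), logical(1))
  if (any(bad)) {
    stop(
      "arguments must have length 1 or ", n, ": ",
      paste(names(args)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  lapply(args, rep_len, length.out = n)
}

#' Means and noise levels of the three sensory channels
#'
#' Maps stimulus conditions to the Gaussian signals of the observer model:
#' the somatosensory channel senses body (platform) tilt, the neck
#' proprioceptive channel senses head-on-body tilt, and a combined
#' visual-vestibular channel senses head-in-space tilt. The combined channel's
#' noise grows linearly with the eccentricity of the commanded visual tilt:
#' `sigma_com = k_com * |ar_tilt| + sigma_com0`.
#'
#' @param params An [observer_params] object.
#' @param platform_tilt_deg,ar_tilt_deg Stimulus tilts in degrees (vectorised).
#' @param head_tilted 0/1 (or logical) indicator of the head-tilted block.
#' @return A tibble with one row per condition and columns
#'   `som_mean`, `som_sd`, `pro_mean`, `pro_sd`, `com_mean`, `com_sd`
#'   (all degrees).
#' @examples
#' p <- median_observer()
#' sensory_channels(p, platform_tilt_deg = 0, head_tilted = 0, ar_tilt_deg = 36)
#' @export
sensory_channels <- function(params, platform_tilt_deg, head_tilted, ar_tilt_deg) {
  params <- as_observer_params(params)
  args <- vctrs_recycle(
    platform_tilt_deg = platform_tilt_deg,
    head_tilted = as.numeric(head_tilted),
    ar_tilt_deg = ar_tilt_deg
  )
  ok <- vapply(args, function(a) all(is.finite(a)), logical(1))
  if (!all(ok)) stop("sensory_channels: all stimuli must be finite", call. = FALSE)
  neck <- params$neck_tilt_deg * args$head_tilted
  som_mean <- params$k_som * args$platform_tilt_deg
  tibble::tibble(
    som_mean = som_mean,
    som_sd = params$sigma_som,
    pro_mean = neck,
    pro_sd = params$sigma_pro,
    com_mean = som_mean + neck + args$ar_tilt_deg,
    com_sd = params$k_com * abs(args$ar_tilt_deg) + params$sigma_com0
  )
}

#' Indirect body-in-space and head-in-space representations
#'
#' The indirect body-in-space estimate corrects the head-channel signal for
#' neck tilt (`x_com - x_pro`); the indirect head-in-space estimate adds neck
#' tilt to the body signal (`x_som + x_pro`). Differences/sums of independent
#' Gaussians: means subtract/add, variances add.
#'
#' @param channels A tibble as returned by [sensory_channels()].
#' @return A tibble with columns `mean` and `sd` (degrees), one row per
#'   condition.
#' @examples
#' ch <- sensory_channels(median_observer(), 0, 0, 0)
#' indirect_bis(ch)
#' indirect_his(ch)
#' @export
indirect_bis <- function(channels) {
  tibble::tibble(
    mean = channels$com_mean - channels$pro_mean,
    sd = sqrt(channels$com_sd^2 + channels$pro_sd^2)
  )
}

#' @rdname indirect_bis
#' @export
indirect_his <- function(channels) {
  tibble::tibble(
    mean = channels$som_mean + channels$pro_mean,
    sd = sqrt(channels$som_sd^2 + channels$pro_sd^2)
  )
}

#' Reliability-based (MLE) weights for the direct representations
#'
#' Under maximum-likelihood cue combination the weight on each estimate is
#' inversely proportional to its variance: the direct weight equals the
#' indirect variance divided by the sum of the two variances.
#'
#' @param var_hisd,var_hisi Variances (deg^2) of the direct and indirect
#'   head-in-space estimates.
#' @param var_bisd,var_bisi Variances (deg^2) of the direct and indirect
#'   body-in-space estimates.
#' @return A tibble with columns `omega_hisd` and `omega_bisd`.
#' @examples
#' mle_weights(4, 4, 1, 9)
#' @export
mle_weights <- function(var_hisd, var_hisi, var_bisd, var_bisi) {
  args <- vctrs_recycle(
    var_hisd = var_hisd, var_hisi = var_hisi,
    var_bisd = var_bisd, var_bisi = var_bisi
  )
  if (any(unlist(args) <= 0, na.rm = FALSE) || !all(is.finite(unlist(args)))) {
    stop("mle_weights: all variances must be finite and > 0", call. = FALSE)
  }
  if (any(args$var_hisd + args$var_hisi == 0) ||
    any(args$var_bisd + args$var_bisi == 0)) {
    stop("mle_weights: degenerate zero total variance", call. = FALSE)
  }
  tibble::tibble(
    omega_hisd = args$var_hisi / (args$var_hisd + args$var_hisi),
    omega_bisd = args$var_bisi / (args$var_bisd + args$var_bisi)
  )
}

#' Direct-path weights of an observer across visual-tilt eccentricities
#'
#' Convenience wrapper evaluating [mle_weights()] for an observer at given
#' commanded visual tilts: the head-channel noise, and hence both weights,
#' depend on `|ar_tilt_deg|`.
#'
#' @param params An [observer_params] object.
#' @param ar_tilt_deg Commanded visual tilt(s) in degrees.
#' @return A tibble with columns `ar_tilt_deg`, `omega_hisd`, `omega_bisd`.
#' @examples
#' observer_weights(median_observer(), c(0, 36))
#' @export
observer_weights <- function(params, ar_tilt_deg) {
  params <- as_observer_params(params)
  ch <- sensory_channels(params, 0, 0, ar_tilt_deg)
  w <- mle_weights(
    var_hisd = ch$com_sd^2,
    var_hisi = ch$som_sd^2 + ch$pro_sd^2,
    var_bisd = ch$som_sd^2,
    var_bisi = ch$com_sd^2 + ch$pro_sd^2
  )
  dplyr::bind_cols(tibble::tibble(ar_tilt_deg = rep_len(ar_tilt_deg, nrow(ch))), w)
}

#' Convex combination of two Gaussian estimates
#'
#' Combines a direct and an indirect Gaussian estimate with weight
#' `omega_direct` on the direct one: the mean is the weighted average and the
#' variance is `omega^2 * sd_d^2 + (1 - omega)^2 * sd_i^2`.
#'
#' @param mean_direct,sd_direct Mean and SD of the direct estimate (degrees).
#' @param mean_indirect,sd_indirect Mean and SD of the indirect estimate.
#' @param omega_direct Weight on the direct estimate, in `[0, 1]`.
#' @return A tibble with columns `mean` and `sd`.
#' @examples
#' combine_estimates(10, 2, 0, 2, 0.5)
#' @export
combine_estimates <- function(mean_direct, sd_direct,
                              mean_indirect, sd_indirect,
                              omega_direct) {
  args <- vctrs_recycle(
    mean_direct = mean_direct, sd_direct = sd_direct,
    mean_indirect = mean_indirect, sd_indirect = sd_indirect,
    omega_direct = omega_direct
  )
  w <- args$omega_direct
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("combine_estimates: `omega_direct` must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    mean = w * args$mean_direct + (1 - w) * args$mean_indirect,
    sd = sqrt(w^2 * args$sd_direct^2 + (1 - w)^2 * args$sd_indirect^2)
  )
}

# Direct-path weights per condition for a given variant: 1 for "fixed",
# the fitted constants for "free", reliability-based per condition for "mle".
variant_weights <- function(params, channels, variant) {
  n <- nrow(channels)
  if (variant == "fixed") {
    return(tibble::tibble(omega_hisd = rep(1, n), omega_bisd = rep(1, n)))
  }
  if (variant == "free") {
    return(tibble::tibble(
      omega_hisd = rep(params$omega_hisd, n),
      omega_bisd = rep(params$omega_bisd, n)
    ))
  }
  mle_weights(
    var_hisd = channels$com_sd^2,
    var_hisi = channels$som_sd^2 + channels$pro_sd^2,
    var_bisd = channels$som_sd^2,
    var_bisi = channels$com_sd^2 + channels$pro_sd^2
  )
}

#' Predictive response distributions for the two verticality tasks
#'
#' `predict_rft()` returns the Gaussian predictive distribution of the rod
#' setting: the rod is counter-rotated against the perceived head-in-space
#' tilt, so its mean is minus the mean of the combined head-in-space estimate
#' and its SD is that estimate's SD. `predict_spv()` returns the distribution
#' of the platform setting at which the body is perceived upright; its closed
#' form is `-(1 - omega_bisd) * ar_tilt_deg` (plus the optional head-tilted
#' offset) with SD equal to the somatosensory noise. For the `"mle"` variant
#' the weights are re-evaluated per condition because the head-channel noise
#' grows with `|ar_tilt_deg|` — this is what bends the mean response into a
#' sigmoid across visual-tilt levels.
#'
#' @param params An [observer_params] object.
#' @param platform_tilt_deg,ar_tilt_deg Stimulus tilts in degrees (vectorised).
#' @param head_tilted 0/1 indicator of the head-tilted block.
#' @param variant One of `"mle"`, `"fixed"`, `"free"`.
#' @return A tibble with columns `mean` and `sd` (degrees).
#' @examples
#' p <- median_observer()
#' predict_rft(p, 0, 0, 36, variant = "mle")
#' predict_spv(p, 0, 0, 36, variant = "mle")
#' @export
predict_rft <- function(params, platform_tilt_deg, head_tilted, ar_tilt_deg,
                        variant = c("mle", "fixed", "free")) {
  params <- as_observer_params(params)
  variant <- check_variant(variant)
  check_variant_params(params, variant)
  ch <- sensory_channels(params, platform_tilt_deg, head_tilted, ar_tilt_deg)
  his_i <- indirect_his(ch)
  w <- variant_weights(params, ch, variant)
  his_hat <- combine_estimates(
    mean_direct = ch$com_mean, sd_direct = ch$com_sd,
    mean_indirect = his_i$mean, sd_indirect = his_i$sd,
    omega_direct = w$omega_hisd
  )
  tibble::tibble(mean = -his_hat$mean, sd = his_hat$sd)
}

#' @rdname predict_rft
#' @export
predict_spv <- function(params, platform_tilt_deg, head_tilted, ar_tilt_deg,
                        variant = c("mle", "fixed", "free")) {
  params <- as_observer_params(params)
  variant <- check_variant(variant)
  check_variant_params(params, variant)
  ch <- sensory_channels(params, platform_tilt_deg, head_tilted, ar_tilt_deg)
  w <- variant_weights(params, ch, variant)
  args <- vctrs_recycle(
    platform_tilt_deg = platform_tilt_deg,
    head_tilted = as.numeric(head_tilted),
    ar_tilt_deg = ar_tilt_deg
  )
  tibble::tibble(
    mean = -(1 - w$omega_bisd) * args$ar_tilt_deg +
      params$spv_neck_offset_deg * args$head_tilted,
    sd = rep_len(params$sigma_som, nrow(ch))
  )
}

#' Predictive distribution for every trial of a tidy trial table
#'
#' Adds the model's predictive mean and SD to each row of a trial table,
#' dispatching on the `task` column (`"RFT"` or `"SPV"`).
#'
#' @param trials A trial tibble with columns `task`, `platform_tilt_deg`,
#'   `head_tilted`, `ar_tilt_deg` (see [build_design()]).
#' @param params An [observer_params] object.
#' @param variant One of `"mle"`, `"fixed"`, `"free"`.
#' @return `trials` with columns `pred_mean_deg` and `pred_sd_deg` appended.
#' @export
predict_trials <- function(trials, params, variant = c("mle", "fixed", "free")) {
  variant <- check_variant(variant)
  params <- as_observer_params(params)
  check_variant_params(params, variant)
  stopifnot(all(c("task", "platform_tilt_deg", "head_tilted", "ar_tilt_deg")
  %in% names(trials)))
  is_rft <- trials$task == "RFT"
  pred_mean <- numeric(nrow(trials))
  pred_sd <- numeric(nrow(trials))
  if (any(is_rft)) {
    pr <- predict_rft(
      params, trials$platform_tilt_deg[is_rft],
      trials$head_tilted[is_rft], trials$ar_tilt_deg[is_rft], variant
    )
    pred_mean[is_rft] <- pr$mean
    pred_sd[is_rft] <- pr$sd
  }
  if (any(!is_rft)) {
    ps <- predict_spv(
      params, trials$platform_tilt_deg[!is_rft],
      trials$head_tilted[!is_rft], trials$ar_tilt_deg[!is_rft], variant
    )
    pred_mean[!is_rft] <- ps$mean
    pred_sd[!is_rft] <- ps$sd
  }
  trials$pred_mean_deg <- pred_mean
  trials$pred_sd_deg <- pred_sd
  trials
}
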