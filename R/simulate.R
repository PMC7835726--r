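# Evaluate `expr` under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

exclusion_levels <- c("none", "training", "mistake", "cop_quality")

#' Build the crossed experimental design for one participant
#'
#' Fully crosses the commanded visual-tilt levels with the platform-tilt
#' levels, repeated `reps_upright` times in the head-upright block and
#' `reps_tilted` times in the head-tilted block, for each requested task.
#' With the defaults this yields the study design: 7 x 3 x 3 = 63 upright and
#' 7 x 3 x 2 = 42 tilted trials per task.
#'
#' @param participant_id Identifier stored in the `participant_id` column.
#' @param ar_levels Commanded visual tilts in degrees.
#' @param platform_levels Platform tilts in degrees.
#' @param reps_upright,reps_tilted Repetitions per cell in each head block
#'   (`reps_tilted` may be 0 to drop the head-tilted block).
#' @param tasks Character subset of `c("RFT", "SPV")`.
#' @param seed Optional integer; when given, trial order is shuffled within
#'   each task x block, reproducibly.
#' @return A trial tibble with empty `response_deg` and `cop_y_cm` columns.
#' @examples
#' nrow(build_design("p1")) # 210
#' @export
build_design <- function(participant_id = "p1",
                         ar_levels = c(-36, -13, -5, 0, 5, 13, 36),
                         platform_levels = c(-3, 0, 3),
                         reps_upright = 3,
                         reps_tilted = 2,
                         tasks = c("RFT", "SPV"),
                         seed = NULL) {
  if (length(ar_levels) == 0 || length(platform_levels) == 0) {
    stop("build_design: level lists must be non-empty", call. = FALSE)
  }
  if (reps_upright < 1) stop("build_design: `reps_upright` must be >= 1", call. = FALSE)
  if (reps_tilted < 0) stop("build_design: `reps_tilted` must be >= 0", call. = FALSE)
  tasks <- match.arg(tasks, c("RFT", "SPV"), several.ok = TRUE)

  one_block <- function(task, block, reps) {
    if (reps < 1) {
      return(NULL)
    }
    tidyr::expand_grid(
      task = task,
      block = block,
      ar_tilt_deg = ar_levels,
      platform_tilt_deg = platform_levels,
      rep = seq_len(reps)
    )
  }
  design <- dplyr::bind_rows(
    lapply(tasks, function(tk) {
      dplyr::bind_rows(
        one_block(tk, "upright", reps_upright),
        one_block(tk, "tilted", reps_tilted)
      )
    })
  )
  design <- design |>
    dplyr::mutate(
      participant_id = as.character(participant_id),
      head_tilted = as.integer(.data$block == "tilted"),
      response_deg = NA_real_,
      cop_y_cm = NA_real_,
      valid = TRUE,
      exclusion_reason = "none"
    ) |>
    dplyr::select(
      "participant_id", "task", "block", "head_tilted",
      "platform_tilt_deg", "ar_tilt_deg", "rep",
      "response_deg", "cop_y_cm", "valid", "exclusion_reason"
    )
  if (!is.null(seed)) {
    design <- with_seed(seed, {
      design |>
        dplyr::group_by(.data$task, .data$block) |>
        dplyr::slice_sample(prop = 1) |>
        dplyr::ungroup()
    })
  }
  design
}

#' Sample task responses from the observer model
#'
#' Draws each trial's response independently from the model's Gaussian
#' predictive distribution for that trial's task and condition.
#'
#' @param design A trial tibble from [build_design()] (responses empty).
#' @param params An [observer_params] object (the generating truth).
#' @param variant Weighting regime used to generate: `"mle"`, `"fixed"`, or
#'   `"free"`.
#' @param seed Integer seed; identical inputs and seed give identical tables.
#' @return The design with `response_deg` filled in.
#' @export
sample_responses <- function(design, params,
                             variant = c("mle", "fixed", "free"),
                             seed = NULL) {
  variant <- check_variant(variant)
  pred <- predict_trials(design, params, variant)
  with_seed(seed, {
    design$response_deg <- stats::rnorm(nrow(design), pred$pred_mean_deg, pred$pred_sd_deg)
  })
  design
}

#' Sample lateral center-of-pressure positions
#'
#' Static rigid-body COP with a postural counteraction gain and a small
#' visually driven lean. The COP of a rigid body with its centre of mass at
#' half body height shifts by `100 * (height/2) * tan(tilt)` cm. Standing
#' participants counteract part of the platform tilt, so the effective tilt is
#' `counteraction_gain * platform_tilt`; in SPV trials the platform has been
#' returned to upright by the response, so the platform term is zero. Visual
#' tilt adds a lean of `visual_lean_deg_per_deg * ar_tilt` degrees. The
#' default lean (-0.00856 deg/deg) is calibrated so that 36 deg of commanded
#' visual tilt shifts the COP by about -0.5 cm (about 0.3 deg of body tilt at
#' a 0.93 m centre of mass).
#'
#' @param design A trial tibble.
#' @param body_height_m Body height in metres (> 0); centre of mass at half.
#' @param counteraction_gain Fraction of platform tilt transmitted to the body
#'   (1 = rigid body, default 0.73 = 27% counteraction).
#' @param visual_lean_deg_per_deg Degrees of body lean per degree of commanded
#'   visual tilt.
#' @param noise_sd_cm SD of additive Gaussian measurement noise (cm).
#' @param seed Integer seed.
#' @return The design with `cop_y_cm` filled in.
#' @export
sample_cop <- function(design,
                       body_height_m = 1.86,
                       counteraction_gain = 0.73,
                       visual_lean_deg_per_deg = -0.00856,
                       noise_sd_cm = 0.3,
                       seed = NULL) {
  if (body_height_m <= 0) {
    stop("sample_cop: `body_height_m` must be positive", call. = FALSE)
  }
  com_cm <- 100 * body_height_m / 2
  platform_eff <- ifelse(design$task == "SPV", 0, design$platform_tilt_deg)
  mean_cop <- com_cm * tan(counteraction_gain * platform_eff * pi / 180) +
    com_cm * tan(visual_lean_deg_per_deg * design$ar_tilt_deg * pi / 180)
  with_seed(seed, {
    design$cop_y_cm <- mean_cop + stats::rnorm(nrow(design), 0, noise_sd_cm)
  })
  design
}

#' Default between-participant dispersions for cohort simulation
#'
#' Noise SDs vary multiplicatively (log-normal), the neck tilt and the
#' eccentricity gain vary additively (normal, the gain truncated at 0). The
#' defaults keep simulated parameters within the observed range of
#' [reference_parameters()].
#'
#' @param neck_tilt_sd Normal SD of the neck tilt (deg).
#' @param sigma_som_sdlog,sigma_pro_sdlog,sigma_com0_sdlog Log-scale SDs of
#'   the three noise parameters.
#' @param k_com_sd Normal SD of the eccentricity gain.
#' @return A named list of dispersions.
#' @export
cohort_spread <- function(neck_tilt_sd = 5,
                          sigma_som_sdlog = 0.3,
                          sigma_pro_sdlog = 0.6,
                          sigma_com0_sdlog = 0.6,
                          k_com_sd = 0.12) {
  spread <- list(
    neck_tilt_sd = neck_tilt_sd,
    sigma_som_sdlog = sigma_som_sdlog,
    sigma_pro_sdlog = sigma_pro_sdlog,
    sigma_com0_sdlog = sigma_com0_sdlog,
    k_com_sd = k_com_sd
  )
  if (any(unlist(spread) < 0)) {
    stop("cohort_spread: dispersions must be >= 0", call. = FALSE)
  }
  spread
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a cohort of observers with ground truth
#'
#' Draws per-participant parameters around `parameter_center`, builds the full
#' crossed design for each participant, samples responses from the generating
#' variant and COP from the rigid-body posture model, and optionally flags a
#' small fraction of trials for exclusion (to exercise preprocessing).
#'
#' @param n_participants Number of observers (>= 1).
#' @param parameter_center An [observer_params] object; cohort centre
#'   (default: [median_observer()]).
#' @param spread Dispersions from [cohort_spread()]; pass
#'   `cohort_spread(0, 0, 0, 0, 0)` for an exact-replica cohort.
#' @param generating_variant Variant used to generate responses.
#' @param exclusion_rate Expected fraction of trials flagged for exclusion
#'   (default 0.04; reasons are drawn among training / mistake / cop-quality).
#' @param seed Integer seed driving all sampling.
#' @param ... Passed to [build_design()] (levels, repetitions, tasks).
#' @param body_height_m,counteraction_gain,visual_lean_deg_per_deg,noise_sd_cm
#'   Posture-generator settings, see [sample_cop()].
#' @return A list with `trials` (one tibble for the whole cohort) and `truth`
#'   (one row of generating parameters per participant).
#' @examples
#' coh <- make_cohort(n_participants = 2, seed = 1)
#' nrow(coh$trials) # 420
#' @export
make_cohort <- function(n_participants = 10,
                        parameter_center = median_observer(),
                        spread = cohort_spread(),
                        generating_variant = c("mle", "fixed", "free"),
                        exclusion_rate = 0.04,
                        seed = 1,
                        ...,
                        body_height_m = 1.86,
                        counteraction_gain = 0.73,
                        visual_lean_deg_per_deg = -0.00856,
                        noise_sd_cm = 0.3) {
  if (n_participants < 1) stop("make_cohort: need >= 1 participant", call. = FALSE)
  generating_variant <- check_variant(generating_variant)
  centre <- as_observer_params(parameter_center)

  truth <- with_seed(seed, {
    tibble::tibble(
      participant_id = sprintf("p%02d", seq_len(n_participants)),
      neck_tilt_deg = clamp(
        stats::rnorm(n_participants, centre$neck_tilt_deg, spread$neck_tilt_sd), -45, 45
      ),
      sigma_som = clamp(
        centre$sigma_som * stats::rlnorm(n_participants, 0, spread$sigma_som_sdlog), 0.05, 30
      ),
      sigma_pro = clamp(
        centre$sigma_pro * stats::rlnorm(n_participants, 0, spread$sigma_pro_sdlog), 0.1, 60
      ),
      sigma_com0 = clamp(
        centre$sigma_com0 * stats::rlnorm(n_participants, 0, spread$sigma_com0_sdlog), 0.1, 60
      ),
      k_com = clamp(
        stats::rnorm(n_participants, centre$k_com, spread$k_com_sd), 0, 2
      ),
      omega_hisd = centre$omega_hisd,
      omega_bisd = centre$omega_bisd
    )
  })

  trials <- purrr::map_dfr(seq_len(n_participants), function(i) {
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    p <- as_observer_params(truth[i, ])
    design <- build_design(participant_id = truth$participant_id[i], ..., seed = sub_seed)
    design <- sample_responses(design, p, generating_variant, seed = sub_seed + 1L)
    design <- sample_cop(
      design, body_height_m, counteraction_gain,
      visual_lean_deg_per_deg, noise_sd_cm,
      seed = sub_seed + 2L
    )
    if (exclusion_rate > 0) {
      design <- with_seed(sub_seed + 3L, {
        flagged <- stats::runif(nrow(design)) < exclusion_rate
        reasons <- sample(c("training", "mistake", "cop_quality"),
          size = nrow(design), replace = TRUE,
          prob = c(72, 3, 10) / 85
        )
        design$exclusion_reason <- ifelse(flagged, reasons, "none")
        design$valid <- !flagged
        design
      })
    }
    design
  })
  list(trials = trials, truth = truth)
}
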