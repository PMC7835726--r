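# Shared fixtures: observers and small trial tables built in code.

ref_observer <- function() median_observer()

# a small but well-conditioned low-noise observer for identifiability checks
quiet_observer <- function() {
  observer_params(
    neck_tilt_deg = 12,
    sigma_som = 1e-3,
    sigma_pro = 1e-3,
    sigma_com0 = 1e-3,
    k_com = 0
  )
}

# bounds wide enough to contain the quiet observer's noise levels
quiet_bounds <- list(
  sigma_som = c(1e-4, 30),
  sigma_pro = c(1e-4, 60),
  sigma_com0 = c(1e-4, 60)
)

# one simulated participant at the reference medians, preprocessed
simulate_participant <- function(seed, params = ref_observer(), variant = "mle",
                                 ...) {
  d <- build_design(participant_id = "p1", ..., seed = seed)
  d <- sample_responses(d, params, variant, seed = seed + 1L)
  mean_correct(d)$trials
}

# hand-built minimal trial table
tiny_trials <- function(task = "RFT",
                        response = c(1, 2, 3),
                        block = "upright",
                        platform = 0, ar = 0) {
  tibble::tibble(
    participant_id = "p1",
    task = task,
    block = block,
    head_tilted = as.integer(block == "tilted"),
    platform_tilt_deg = platform,
    ar_tilt_deg = ar,
    rep = seq_along(response),
    response_deg = response,
    cop_y_cm = NA_real_,
    valid = TRUE,
    exclusion_reason = "none"
  )
}
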