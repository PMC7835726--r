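trial_schema <- c(
  "participant_id", "task", "block", "head_tilted",
  "platform_tilt_deg", "ar_tilt_deg", "rep",
  "response_deg", "cop_y_cm", "valid", "exclusion_reason"
)

#' Read and write tidy trial tables
#'
#' Trial tables are plain CSV (UTF-8, "." decimal) with one header row;
#' angles are in degrees and COP in cm, with units embedded in the column
#' names. Unknown extra columns are preserved.
#'
#' @param path File path.
#' @return `read_trials()` returns a validated trial tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("read_trials: no such file: ", path, call. = FALSE)
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(
    "participant_id", "task", "block", "head_tilted",
    "platform_tilt_deg", "ar_tilt_deg", "response_deg"
  )
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stop(
      "read_trials: missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  numeric_cols <- c("head_tilted", "platform_tilt_deg", "ar_tilt_deg", "response_deg")
  for (col in numeric_cols) {
    if (!is.numeric(trials[[col]])) {
      stop("read_trials: column `", col, "` is not numeric", call. = FALSE)
    }
  }
  if (!all(trials$task %in% c("RFT", "SPV"))) {
    stop("read_trials: `task` must be RFT or SPV", call. = FALSE)
  }
  trials$participant_id <- as.character(trials$participant_id)
  if (!"valid" %in% names(trials)) trials$valid <- TRUE
  if (!"exclusion_reason" %in% names(trials)) trials$exclusion_reason <- "none"
  if (!"cop_y_cm" %in% names(trials)) trials$cop_y_cm <- NA_real_
  if (!"rep" %in% names(trials)) trials$rep <- NA_integer_
  trials
}

#' @param trials A trial tibble.
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Assemble or load a pipeline configuration
#'
#' A configuration is a named list with a `data` block (either
#' `source = "simulate"` plus cohort settings, or `source = "csv"` plus a
#' `path`), a `fit` block (n_starts, variants, extensions), a `posture` block
#' (body_height_m), an `out_dir`, and a `seed` that drives every stochastic
#' stage. YAML or JSON files with the same structure are accepted.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_pipeline_config: no such file: ", path, call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  default_pipeline_config(cfg)
}

#' @param config A partial configuration list; missing entries are filled with
#'   defaults.
#' @rdname read_pipeline_config
#' @export
default_pipeline_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    data = list(
      source = "simulate",
      path = NULL,
      n_participants = 10,
      generating_variant = "mle",
      exclusion_rate = 0.04
    ),
    fit = list(
      variants = c("fixed", "free", "mle"),
      n_starts = 20,
      fit_k_som = FALSE,
      fit_spv_offset = FALSE
    ),
    posture = list(body_height_m = 1.86)
  )
  merge_lists <- function(base, extra) {
    for (nm in names(extra)) {
      if (is.list(base[[nm]]) && is.list(extra[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], extra[[nm]])
      } else {
        base[[nm]] <- extra[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(defaults, config)
  if (!cfg$data$source %in% c("simulate", "csv")) {
    stop("pipeline config: `data$source` must be \"simulate\" or \"csv\"",
      call. = FALSE
    )
  }
  if (identical(cfg$data$source, "csv") && is.null(cfg$data$path)) {
    stop("pipeline config: data source \"csv\" needs a `path`", call. = FALSE)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) trials, exclude flagged trials, apply the head-upright
#' mean correction, fit the requested model variants to every participant,
#' compare variants by BIC, summarise the cohort, and estimate the postural
#' counteraction slope. All stages are seeded from `config$seed`. When
#' `config$out_dir` is set, tables are written as CSV, reports as JSON, and a
#' run manifest (configuration hash plus a hash of all numeric outputs) is
#' saved alongside.
#'
#' @param config A configuration list (see [default_pipeline_config()]).
#' @return A list with `trials` (preprocessed), `preprocess` (exclusion report
#'   and offsets), `fits` (tibble from [fit_cohort()]), `comparison` (per
#'   participant best variant and BIC deltas), `summary` (from
#'   [cohort_summary()], on the best-BIC variant's fits), `posture`, `truth`
#'   (when simulated), and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- default_pipeline_config(config)

  truth <- NULL
  if (identical(cfg$data$source, "simulate")) {
    cohort <- make_cohort(
      n_participants = cfg$data$n_participants,
      generating_variant = cfg$data$generating_variant,
      exclusion_rate = cfg$data$exclusion_rate,
      seed = cfg$seed
    )
    raw <- cohort$trials
    truth <- cohort$truth
  } else {
    raw <- read_trials(cfg$data$path)
  }

  pre <- preprocess_trials(raw)

  opts <- fit_options(
    n_starts = cfg$fit$n_starts,
    seed = cfg$seed,
    fit_k_som = cfg$fit$fit_k_som,
    fit_spv_offset = cfg$fit$fit_spv_offset
  )
  fits <- fit_cohort(pre$trials, variants = cfg$fit$variants, options = opts)

  comparison <- fits |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      delta_bic = .data$bic - min(.data$bic),
      evidence = evidence_category(.data$delta_bic),
      best = .data$delta_bic == 0
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "participant_id", "variant", "loglik", "k_params", "n_trials",
      "bic", "delta_bic", "evidence", "best", "r_squared", "converged"
    )

  best_variant <- comparison |>
    dplyr::count(.data$variant, wt = .data$best, name = "n_best") |>
    dplyr::arrange(dplyr::desc(.data$n_best)) |>
    dplyr::pull(.data$variant) |>
    utils::head(1)
  summary <- cohort_summary(fits$fit[fits$variant == best_variant])

  posture <- tryCatch(
    estimate_counteraction(pre$trials, body_height_m = cfg$posture$body_height_m),
    error = function(e) NULL
  )

  result <- list(
    trials = pre$trials,
    preprocess = list(report = pre$report, offsets = pre$offsets),
    fits = fits,
    comparison = comparison,
    summary = summary,
    best_variant = best_variant,
    posture = posture,
    truth = truth
  )
  result$manifest <- pipeline_manifest(cfg, result)

  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(result, cfg$out_dir)
  }
  result
}

pipeline_manifest <- function(cfg, result) {
  numeric_outputs <- list(
    comparison = as.data.frame(result$comparison[
      , c("participant_id", "variant", "loglik", "bic")
    ]),
    params = as.data.frame(result$summary$params),
    weights = as.data.frame(result$summary$weights),
    posture_slope = if (!is.null(result$posture)) result$posture$slope else NA_real_
  )
  list(
    config_hash = rlang::hash(cfg),
    output_hash = rlang::hash(numeric_outputs),
    seed = cfg$seed,
    n_trials = nrow(result$trials),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("uprightr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(result$trials, file.path(out_dir, "trials_preprocessed.csv"))
  readr::write_csv(result$comparison, file.path(out_dir, "model_comparison.csv"),
    progress = FALSE
  )
  readr::write_csv(result$summary$params, file.path(out_dir, "cohort_parameters.csv"),
    progress = FALSE
  )
  readr::write_csv(result$summary$weights, file.path(out_dir, "cohort_weights.csv"),
    progress = FALSE
  )
  fit_rows <- purrr::map(result$fits$fit, function(f) {
    c(
      list(
        participant_id = f$participant_id, variant = f$variant,
        loglik = f$loglik, bic = f$bic, r_squared = f$r_squared,
        n_trials = f$n_trials, k_params = f$k_params, converged = f$converged
      ),
      as.list(f$estimates)
    )
  })
  jsonlite::write_json(fit_rows, file.path(out_dir, "fits.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(result$preprocess$report,
    file.path(out_dir, "preprocess_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(result$posture)) {
    jsonlite::write_json(
      result$posture[c("slope", "intercept", "n", "counteraction")],
      file.path(out_dir, "posture_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  if (!is.null(result$truth)) {
    truth_list <- split(result$truth, result$truth$participant_id) |>
      lapply(function(row) as.list(row[, -1]))
    jsonlite::write_json(truth_list, file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
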