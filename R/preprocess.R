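#' Drop flagged trials
#'
#' Removes trials whose `exclusion_reason` is anything other than `"none"`
#' (training trials, self-reported mistakes, COP-quality problems) and tallies
#' the removals. Exclusion runs before mean correction so that flagged trials
#' never contaminate the head-upright offsets.
#'
#' @param trials A trial tibble with an `exclusion_reason` column.
#' @return A list with `trials` (the retained rows, unaltered) and `report`,
#'   a list holding `n_input`, `n_excluded_by_reason` (named counts),
#'   `n_kept`, and `fraction_excluded`.
#' @export
exclude_invalid <- function(trials) {
  if (!"exclusion_reason" %in% names(trials)) {
    stop("exclude_invalid: trials need an `exclusion_reason` column", call. = FALSE)
  }
  reason <- trials$exclusion_reason
  keep <- reason == "none"
  tallies <- table(factor(reason[!keep], levels = setdiff(exclusion_levels, "none")))
  report <- list(
    n_input = nrow(trials),
    n_excluded_by_reason = as.list(tallies),
    n_kept = sum(keep),
    fraction_excluded = if (nrow(trials) == 0) 0 else sum(!keep) / nrow(trials)
  )
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Head-upright mean correction
#'
#' For every participant x task group, subtracts the mean response of that
#' group's head-upright trials (all platform and visual tilt levels pooled)
#' from all of the group's responses, in both head conditions. This removes
#' constant offsets such as display misalignment or habitual posture, and
#' makes each group's head-upright responses average exactly zero. COP values
#' are left untouched.
#'
#' @param trials A trial tibble with `participant_id`, `task`, `block`, and
#'   `response_deg` columns.
#' @return A list with `trials` (corrected) and `offsets`, a tibble of the
#'   subtracted per-group means (`participant_id`, `task`, `offset_deg`).
#' @export
mean_correct <- function(trials) {
  needed <- c("participant_id", "task", "block", "response_deg")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0) {
    stop(
      "mean_correct: missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  offsets <- trials |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::summarise(
      offset_deg = mean(.data$response_deg[.data$block == "upright"]),
      n_upright = sum(.data$block == "upright"),
      .groups = "drop"
    )
  bad <- offsets$n_upright == 0
  if (any(bad)) {
    grp <- paste(offsets$participant_id[bad], offsets$task[bad], sep = "/")
    stop(
      "mean_correct: no head-upright trials for group(s): ",
      paste(grp, collapse = ", "),
      call. = FALSE
    )
  }
  corrected <- trials |>
    dplyr::left_join(
      dplyr::select(offsets, "participant_id", "task", "offset_deg"),
      by = c("participant_id", "task")
    ) |>
    dplyr::mutate(response_deg = .data$response_deg - .data$offset_deg) |>
    dplyr::select(-"offset_deg")
  list(
    trials = corrected,
    offsets = dplyr::select(offsets, "participant_id", "task", "offset_deg")
  )
}

#' Exclusion plus mean correction in one step
#'
#' @param trials A raw trial tibble.
#' @return A list with `trials` (cleaned and corrected), `report` (from
#'   [exclude_invalid()]), and `offsets` (from [mean_correct()]).
#' @export
preprocess_trials <- function(trials) {
  excl <- exclude_invalid(trials)
  corr <- mean_correct(excl$trials)
  list(trials = corr$trials, report = excl$report, offsets = corr$offsets)
}
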