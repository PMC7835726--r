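#' Fitting options
#'
#' Controls for the per-participant multi-start bounded maximum-likelihood
#' fit. Optimisation runs in a transformed space (log for the noise SDs,
#' logit for the free weights) so every start is interior; reported estimates
#' are back-transformed. Starting points are a seeded Latin hypercube over
#' the transformed bounds, with the box midpoint always included as the first
#' start; the best start by final log-likelihood wins, ties going to the
#' earliest start.
#'
#' @param n_starts Number of optimisation starts (>= 1, default 20).
#' @param seed Integer seed for the start design.
#' @param tolerance Convergence tolerance on the objective (default 1e-9,
#'   mapped to the L-BFGS-B `factr` control).
#' @param max_iter Iteration cap per start.
#' @param fit_k_som Also fit a gain on platform tilt (adds one parameter).
#' @param fit_spv_offset Also fit an additive head-tilted offset on the SPV
#'   prediction (adds one parameter).
#' @param bounds Named list of `c(lo, hi)` bounds on the natural scale;
#'   defaults bracket the observed range of [reference_parameters()] widely.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 20,
                        seed = 1,
                        tolerance = 1e-9,
                        max_iter = 500,
                        fit_k_som = FALSE,
                        fit_spv_offset = FALSE,
                        bounds = NULL) {
  if (n_starts < 1) stop("fit_options: `n_starts` must be >= 1", call. = FALSE)
  default_bounds <- list(
    neck_tilt_deg = c(-45, 45),
    sigma_som = c(0.05, 30),
    sigma_pro = c(0.1, 60),
    sigma_com0 = c(0.1, 60),
    k_com = c(0, 2),
    omega_hisd = c(1e-3, 1 - 1e-3),
    omega_bisd = c(1e-3, 1 - 1e-3),
    k_som = c(-10, 10),
    spv_neck_offset_deg = c(-45, 45)
  )
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  for (b in default_bounds) {
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("fit_options: each bound must be finite c(lo, hi) with lo < hi",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      n_starts = as.integer(n_starts), seed = as.integer(seed),
      tolerance = tolerance, max_iter = as.integer(max_iter),
      fit_k_som = isTRUE(fit_k_som), fit_spv_offset = isTRUE(fit_spv_offset),
      bounds = default_bounds
    ),
    class = "fit_options"
  )
}

#' Free parameters of a model variant
#'
#' The direct-only (`"fixed"`) variant has no use for the neck-proprioceptive
#' noise (it never enters a prediction when both weights are 1), so its
#' parameter vector is (neck tilt, sigma_som, sigma_com0, k_com), k = 4. The
#' `"mle"` variant adds sigma_pro (k = 5); the `"free"` variant adds the two
#' constant weights (k = 7). Each enabled extension adds one parameter.
#'
#' @param variant One of `"mle"`, `"fixed"`, `"free"`.
#' @param fit_k_som,fit_spv_offset Extension flags.
#' @return Character vector of parameter names; its length is the BIC `k`.
#' @examples
#' length(variant_parameters("mle")) # 5
#' @export
variant_parameters <- function(variant = c("mle", "fixed", "free"),
                               fit_k_som = FALSE, fit_spv_offset = FALSE) {
  variant <- check_variant(variant)
  base <- switch(variant,
    fixed = c("neck_tilt_deg", "sigma_som", "sigma_com0", "k_com"),
    mle = c("neck_tilt_deg", "sigma_som", "sigma_pro", "sigma_com0", "k_com"),
    free = c(
      "neck_tilt_deg", "sigma_som", "sigma_pro", "sigma_com0", "k_com",
      "omega_hisd", "omega_bisd"
    )
  )
  c(
    base,
    if (isTRUE(fit_k_som)) "k_som",
    if (isTRUE(fit_spv_offset)) "spv_neck_offset_deg"
  )
}

#' Joint log-likelihood of a trial table under the observer model
#'
#' Sum over trials of the log Gaussian density of the observed response under
#' the model's predictive distribution for that trial's task and condition.
#'
#' @param trials A preprocessed trial tibble for a single participant.
#' @param params An [observer_params] object.
#' @param variant One of `"mle"`, `"fixed"`, `"free"`.
#' @return The log-likelihood (a single number).
#' @export
loglik_trials <- function(trials, params, variant = c("mle", "fixed", "free")) {
  variant <- check_variant(variant)
  pred <- predict_trials(trials, params, variant)
  if (any(pred$pred_sd_deg <= 0)) {
    stop("loglik_trials: non-positive predictive SD", call. = FALSE)
  }
  sum(stats::dnorm(trials$response_deg, pred$pred_mean_deg, pred$pred_sd_deg,
    log = TRUE
  ))
}

#' Bayesian Information Criterion
#'
#' `k * log(n) - 2 * loglik`; lower is better.
#'
#' @param loglik Maximised log-likelihood.
#' @param k_params Number of free parameters.
#' @param n_trials Number of trials entering the likelihood (>= 1).
#' @return The BIC score.
#' @examples
#' bic_score(-200, 5, 105)
#' @export
bic_score <- function(loglik, k_params, n_trials) {
  if (n_trials < 1) stop("bic_score: `n_trials` must be >= 1", call. = FALSE)
  k_params * log(n_trials) - 2 * loglik
}

#' Evidence label for a BIC difference
#'
#' Kass-Raftery style bands: differences in `[0, 2)` are negligible, `[2, 6)`
#' positive, `[6, 10)` strong, and `>= 10` decisive (the boundary value 10 is
#' classed as decisive).
#'
#' @param delta_bic Non-negative BIC difference(s).
#' @return Character vector of labels.
#' @examples
#' evidence_category(c(1, 4, 8, 111.371))
#' @export
evidence_category <- function(delta_bic) {
  if (any(delta_bic < 0)) {
    stop("evidence_category: `delta_bic` must be >= 0", call. = FALSE)
  }
  cut(delta_bic,
    breaks = c(0, 2, 6, 10, Inf),
    labels = c("negligible", "positive", "strong", "decisive"),
    right = FALSE, include.lowest = TRUE
  ) |> as.character()
}

#' Variance explained by the model's predicted means
#'
#' `1 - SSE/SST` with the per-trial predicted means, computed pooled over both
#' tasks and separately per task.
#'
#' @param trials A preprocessed trial tibble.
#' @param params An [observer_params] object.
#' @param variant One of `"mle"`, `"fixed"`, `"free"`.
#' @return A list with `pooled` (single number) and `by_task` (tibble with
#'   columns `task`, `r_squared`).
#' @export
r_squared_fit <- function(trials, params, variant = c("mle", "fixed", "free")) {
  variant <- check_variant(variant)
  pred <- predict_trials(trials, params, variant)
  rsq <- function(obs, mu) {
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) stop("r_squared_fit: zero total variance", call. = FALSE)
    1 - sum((obs - mu)^2) / sst
  }
  by_task <- pred |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(
      r_squared = rsq(.data$response_deg, .data$pred_mean_deg),
      .groups = "drop"
    )
  list(
    pooled = rsq(pred$response_deg, pred$pred_mean_deg),
    by_task = by_task
  )
}

# ---- internal fast likelihood machinery ------------------------------------

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

param_transform <- function(name) {
  if (name %in% c("sigma_som", "sigma_pro", "sigma_com0")) {
    return("log")
  }
  if (name %in% c("omega_hisd", "omega_bisd")) {
    return("logit")
  }
  "identity"
}

to_internal <- function(x, tr) {
  switch(tr, log = log(x), logit = logit(x), identity = x)
}
from_internal <- function(x, tr) {
  switch(tr, log = exp(x), logit = inv_logit(x), identity = x)
}

# Vectorised negative log-likelihood closure over a fixed trial table.
# `theta` lives in the transformed space; names(theta) are parameter names.
make_negloglik <- function(trials, variant, par_names) {
  is_rft <- trials$task == "RFT"
  phi_p <- trials$platform_tilt_deg
  phi_ar <- trials$ar_tilt_deg
  abs_ar <- abs(phi_ar)
  tilted <- as.numeric(trials$head_tilted)
  resp <- trials$response_deg
  trs <- vapply(par_names, param_transform, character(1))

  function(theta) {
    nat <- theta
    for (j in seq_along(par_names)) nat[j] <- from_internal(theta[j], trs[j])
    p <- list(
      neck_tilt_deg = nat[["neck_tilt_deg"]],
      sigma_som = nat[["sigma_som"]],
      sigma_pro = if ("sigma_pro" %in% par_names) nat[["sigma_pro"]] else 1,
      sigma_com0 = nat[["sigma_com0"]],
      k_com = nat[["k_com"]],
      omega_hisd = if ("omega_hisd" %in% par_names) nat[["omega_hisd"]] else NA_real_,
      omega_bisd = if ("omega_bisd" %in% par_names) nat[["omega_bisd"]] else NA_real_,
      k_som = if ("k_som" %in% par_names) nat[["k_som"]] else 1,
      spv_neck_offset_deg = if ("spv_neck_offset_deg" %in% par_names) {
        nat[["spv_neck_offset_deg"]]
      } else {
        0
      }
    )
    neck <- p$neck_tilt_deg * tilted
    sigma_com <- p$k_com * abs_ar + p$sigma_com0
    var_som <- p$sigma_som^2
    var_pro <- p$sigma_pro^2
    var_com <- sigma_com^2
    mu_hisi <- p$k_som * phi_p + neck
    mu_com <- mu_hisi + phi_ar
    var_hisi <- var_som + var_pro

    if (variant == "fixed") {
      w_his <- 1
      w_bis <- 1
    } else if (variant == "free") {
      w_his <- p$omega_hisd
      w_bis <- p$omega_bisd
    } else {
      w_his <- var_hisi / (var_com + var_hisi)
      w_bis <- (var_com + var_pro) / (var_som + var_com + var_pro)
    }

    mu_rft <- -(w_his * mu_com + (1 - w_his) * mu_hisi)
    sd_rft <- sqrt(w_his^2 * var_com + (1 - w_his)^2 * var_hisi)
    mu_spv <- -(1 - w_bis) * phi_ar + p$spv_neck_offset_deg * tilted
    mu <- ifelse(is_rft, mu_rft, mu_spv)
    sd <- ifelse(is_rft, sd_rft, p$sigma_som)

    if (any(!is.finite(mu)) || any(!is.finite(sd)) || any(sd <= 0)) {
      return(1e10)
    }
    -sum(stats::dnorm(resp, mu, sd, log = TRUE))
  }
}

# ---- fitting ----------------------------------------------------------------

#' Fit the observer model to one participant's trials
#'
#' Maximum-likelihood fit of one weighting variant to a participant's joint
#' RFT + SPV responses, using multi-start bounded quasi-Newton optimisation
#' (L-BFGS-B in a transformed space). Deterministic under
#' `options$seed`.
#'
#' @param trials A preprocessed trial tibble for a single participant, with
#'   columns `task`, `block`, `head_tilted`, `platform_tilt_deg`,
#'   `ar_tilt_deg`, `response_deg`.
#' @param variant One of `"mle"`, `"fixed"`, `"free"`.
#' @param options A [fit_options()] list.
#' @return An object of class `observer_fit` with the fitted
#'   [observer_params], the maximised log-likelihood, BIC, pooled and per-task
#'   R^2, and convergence metadata. Inspect with [tidy()] / [glance()].
#' @export
fit_observer <- function(trials, variant = c("mle", "fixed", "free"),
                         options = fit_options()) {
  variant <- check_variant(variant)
  if ("participant_id" %in% names(trials) &&
    length(unique(trials$participant_id)) > 1) {
    stop("fit_observer: trials span several participants; use fit_cohort()",
      call. = FALSE
    )
  }
  if (nrow(trials) < 2) stop("fit_observer: need at least 2 trials", call. = FALSE)
  if (length(unique(trials$task)) < 2) {
    warning("fit_observer: only one task present; joint fit is recommended")
  }

  par_names <- variant_parameters(variant, options$fit_k_som, options$fit_spv_offset)
  k <- length(par_names)
  trs <- vapply(par_names, param_transform, character(1))
  lower <- mapply(function(nm, tr) to_internal(options$bounds[[nm]][1], tr), par_names, trs)
  upper <- mapply(function(nm, tr) to_internal(options$bounds[[nm]][2], tr), par_names, trs)

  starts <- with_seed(options$seed, {
    u <- lhs::randomLHS(max(options$n_starts - 1L, 1L), k)
    mid <- matrix(0.5, nrow = 1, ncol = k)
    u <- rbind(mid, if (options$n_starts > 1L) u)
    u[seq_len(options$n_starts), , drop = FALSE]
  })
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  colnames(starts) <- par_names

  negll <- make_negloglik(trials, variant, par_names)
  factr <- max(options$tolerance / .Machine$double.eps, 1)

  best <- NULL
  best_val <- Inf
  n_conv <- 0L
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(
        par = starts[s, ], fn = negll, method = "L-BFGS-B",
        lower = lower, upper = upper,
        control = list(factr = factr, maxit = options$max_iter)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (res$value < best_val - 1e-12) {
      best_val <- res$value
      best <- res
    }
  }
  if (is.null(best)) {
    stop("fit_observer: all optimisation starts failed", call. = FALSE)
  }

  nat <- stats::setNames(
    mapply(from_internal, best$par, trs),
    par_names
  )
  # sigma_pro never enters a "fixed"-variant prediction (both direct weights
  # are exactly 1); a placeholder of 1 keeps the params object valid without
  # affecting any predicted mean or SD.
  params <- observer_params(
    neck_tilt_deg = nat[["neck_tilt_deg"]],
    sigma_som = nat[["sigma_som"]],
    sigma_pro = if ("sigma_pro" %in% par_names) nat[["sigma_pro"]] else 1,
    sigma_com0 = nat[["sigma_com0"]],
    k_com = nat[["k_com"]],
    omega_hisd = if ("omega_hisd" %in% par_names) nat[["omega_hisd"]] else NA_real_,
    omega_bisd = if ("omega_bisd" %in% par_names) nat[["omega_bisd"]] else NA_real_,
    k_som = if ("k_som" %in% par_names) nat[["k_som"]] else 1,
    spv_neck_offset_deg = if ("spv_neck_offset_deg" %in% par_names) {
      nat[["spv_neck_offset_deg"]]
    } else {
      0
    }
  )
  ll <- -best_val
  n <- nrow(trials)
  rsq <- r_squared_fit(trials, params, variant)
  structure(
    list(
      participant_id = if ("participant_id" %in% names(trials)) {
        unique(trials$participant_id)
      } else {
        NA_character_
      },
      variant = variant,
      params = params,
      estimates = nat,
      loglik = ll,
      n_trials = n,
      k_params = k,
      bic = bic_score(ll, k, n),
      r_squared = rsq$pooled,
      r_squared_by_task = rsq$by_task,
      converged = n_conv > 0L,
      n_starts_used = nrow(starts),
      trials = trials
    ),
    class = "observer_fit"
  )
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf(
    "<observer_fit> participant %s, variant \"%s\"\n",
    x$participant_id, x$variant
  ))
  cat(sprintf(
    "  loglik %.3f | BIC %.3f | R^2 %.3f | n = %d, k = %d | converged: %s\n",
    x$loglik, x$bic, x$r_squared, x$n_trials, x$k_params, x$converged
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an observer fit
#'
#' @param x An `observer_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`term`, `estimate`).
#' @method tidy observer_fit
#' @export
tidy.observer_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' One-row summary of an observer fit
#'
#' @param x An `observer_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant, loglik, BIC, pooled R^2, n, k,
#'   convergence.
#' @method glance observer_fit
#' @export
glance.observer_fit <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id,
    variant = x$variant,
    loglik = x$loglik,
    bic = x$bic,
    r_squared = x$r_squared,
    n_trials = x$n_trials,
    k_params = x$k_params,
    converged = x$converged
  )
}

#' Fit and compare the three weighting variants on one participant
#'
#' Fits `"fixed"`, `"free"` and `"mle"` on the same trials and ranks them by
#' BIC, attaching Kass-Raftery style evidence labels to the BIC differences
#' from the best variant.
#'
#' @param trials A preprocessed single-participant trial tibble.
#' @param options A [fit_options()] list.
#' @param variants Variants to include.
#' @return An object of class `observer_comparison`: a list with `table`
#'   (variant, loglik, k, bic, delta_bic, evidence) and `fits` (named list of
#'   `observer_fit`s).
#' @export
compare_variants <- function(trials, options = fit_options(),
                             variants = c("fixed", "free", "mle")) {
  variants <- vapply(variants, check_variant, character(1))
  fits <- lapply(variants, function(v) fit_observer(trials, v, options))
  names(fits) <- variants
  tab <- purrr::map_dfr(fits, glance) |>
    dplyr::arrange(.data$bic) |>
    dplyr::mutate(
      delta_bic = .data$bic - min(.data$bic),
      evidence = evidence_category(.data$delta_bic)
    )
  structure(list(table = tab, fits = fits), class = "observer_comparison")
}

#' @export
print.observer_comparison <- function(x, ...) {
  cat("<observer_comparison>\n")
  print(as.data.frame(x$table))
  invisible(x)
}

#' @param x An `observer_comparison`.
#' @param ... Unused.
#' @rdname compare_variants
#' @method tidy observer_comparison
#' @export
tidy.observer_comparison <- function(x, ...) {
  x$table
}

#' Fit every participant of a cohort
#'
#' @param trials A preprocessed trial tibble with a `participant_id` column.
#' @param variants Variants to fit for each participant.
#' @param options A [fit_options()] list.
#' @return A tibble with one row per participant x variant: glance columns
#'   plus a `fit` list-column of `observer_fit` objects.
#' @export
fit_cohort <- function(trials, variants = c("fixed", "free", "mle"),
                       options = fit_options()) {
  variants <- vapply(variants, check_variant, character(1))
  trials |>
    dplyr::group_split(.data$participant_id) |>
    purrr::map_dfr(function(sub) {
      purrr::map_dfr(variants, function(v) {
        fit <- fit_observer(sub, v, options)
        dplyr::mutate(glance(fit), fit = list(fit))
      })
    })
}

#' Cohort parameter summary
#'
#' Per-parameter median and SD across participants, plus the
#' reliability-based direct-path weights evaluated at the median parameters
#' for each visual-tilt level.
#'
#' @param fits Either a list of `observer_fit` objects, the tibble returned by
#'   [fit_cohort()], or a plain tibble of per-participant parameters with
#'   columns `neck_tilt_deg`, `sigma_som`, `sigma_pro`, `sigma_com0`, `k_com`.
#' @param ar_levels Visual-tilt levels at which to evaluate the weights.
#' @return A list with `params` (term, median, sd) and `weights`
#'   (ar_tilt_deg, omega_hisd, omega_bisd).
#' @examples
#' cohort_summary(reference_parameters())$weights
#' @export
cohort_summary <- function(fits, ar_levels = c(-36, -13, -5, 0, 5, 13, 36)) {
  par_cols <- c("neck_tilt_deg", "sigma_som", "sigma_pro", "sigma_com0", "k_com")
  if (is.data.frame(fits) && all(par_cols %in% names(fits))) {
    par_tab <- fits[, par_cols]
  } else {
    if (is.data.frame(fits) && "fit" %in% names(fits)) fits <- fits$fit
    if (inherits(fits, "observer_fit")) fits <- list(fits)
    par_tab <- purrr::map_dfr(fits, function(f) {
      p <- f$params
      tibble::tibble(
        neck_tilt_deg = p$neck_tilt_deg, sigma_som = p$sigma_som,
        sigma_pro = p$sigma_pro, sigma_com0 = p$sigma_com0, k_com = p$k_com
      )
    })
  }
  if (nrow(par_tab) == 0) stop("cohort_summary: no fits supplied", call. = FALSE)
  params <- tidyr::pivot_longer(par_tab, dplyr::everything(),
    names_to = "term", values_to = "value"
  ) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$term, par_cols))
  med <- observer_params(
    neck_tilt_deg = params$median[params$term == "neck_tilt_deg"],
    sigma_som = params$median[params$term == "sigma_som"],
    sigma_pro = params$median[params$term == "sigma_pro"],
    sigma_com0 = params$median[params$term == "sigma_com0"],
    k_com = params$median[params$term == "k_com"]
  )
  list(params = params, weights = observer_weights(med, ar_levels))
}
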