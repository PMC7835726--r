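test_that("log-likelihood matches the Gaussian density product", {
  # single standard-normal trial at its mean: -log(2*pi)/2
  tr <- tiny_trials("SPV", response = 0, ar = 0)
  p <- observer_params(0, 1, 9.276, 8.572, 0.249)
  expect_equal(loglik_trials(tr, p, "mle"), -0.9189385, tolerance = 1e-6)

  # additivity over identical independent trials
  tr2 <- tiny_trials("SPV", response = c(0, 0), ar = 0)
  expect_equal(loglik_trials(tr2, p, "mle"), 2 * loglik_trials(tr, p, "mle"))

  # brute-force oracle: log of the product of densities, trial by trial
  set.seed(42)
  d <- build_design("p1", reps_upright = 1, reps_tilted = 1)
  d <- d[sample(nrow(d), 10), ]
  d$response_deg <- stats::rnorm(10, 0, 5)
  pm <- ref_observer()
  for (v in c("fixed", "mle")) {
    pred <- predict_trials(d, pm, v)
    oracle <- log(prod(stats::dnorm(
      d$response_deg, pred$pred_mean_deg, pred$pred_sd_deg
    )))
    expect_equal(loglik_trials(d, pm, v), oracle, tolerance = 1e-10)
  }
})

test_that("BIC follows its closed form and the evidence bands", {
  expect_equal(bic_score(-200, 5, 105), 5 * log(105) + 400)
  expect_equal(bic_score(-200, 5, 105), 423.2698, tolerance = 1e-4)
  expect_equal(bic_score(-200, 4, 105), 418.6158, tolerance = 1e-4)
  expect_equal(bic_score(-200, 0, 105), 400)
  expect_error(bic_score(-200, 5, 0), ">= 1")

  expect_equal(
    evidence_category(c(0, 1, 1.999, 2, 5, 6, 9.9, 10, 111.371)),
    c(
      "negligible", "negligible", "negligible", "positive", "positive",
      "strong", "strong", "decisive", "decisive"
    )
  )
  expect_error(evidence_category(-1), ">= 0")
})

test_that("variant parameter vectors have the documented sizes", {
  expect_equal(
    variant_parameters("fixed"),
    c("neck_tilt_deg", "sigma_som", "sigma_com0", "k_com")
  )
  expect_length(variant_parameters("mle"), 5)
  expect_length(variant_parameters("free"), 7)
  expect_length(variant_parameters("mle", fit_k_som = TRUE), 6)
  expect_length(
    variant_parameters("free", fit_k_som = TRUE, fit_spv_offset = TRUE), 9
  )
  expect_true("sigma_pro" %in% variant_parameters("mle"))
  expect_false("sigma_pro" %in% variant_parameters("fixed"))
})

test_that("R^2 is 1 for perfect prediction, 0 at the grand mean, oracle otherwise", {
  # zero-noise data: the generating observer predicts every response exactly
  p <- quiet_observer()
  tr <- simulate_participant(seed = 9, params = p)
  r2 <- r_squared_fit(tr, p, "mle")
  expect_equal(r2$pooled, 1, tolerance = 1e-6)
  expect_equal(r2$by_task$r_squared, c(1, 1), tolerance = 1e-6)

  # predictions identically equal to the grand mean give 0
  tr0 <- tiny_trials("SPV", response = c(-1, 1), ar = 0) # predicted mean 0
  expect_equal(r_squared_fit(tr0, ref_observer(), "mle")$pooled, 0)

  # spreadsheet-style oracle on a 10-trial fixture
  set.seed(1)
  d <- build_design("p1", reps_upright = 1, reps_tilted = 1)[1:10, ]
  d$response_deg <- stats::rnorm(10, -d$ar_tilt_deg / 4, 3)
  pm <- ref_observer()
  pred <- predict_trials(d, pm, "mle")
  oracle <- 1 - sum((d$response_deg - pred$pred_mean_deg)^2) /
    sum((d$response_deg - mean(d$response_deg))^2)
  expect_equal(r_squared_fit(d, pm, "mle")$pooled, oracle, tolerance = 1e-12)

  expect_error(
    r_squared_fit(tiny_trials("SPV", response = c(2, 2)), pm, "mle"),
    "zero total variance"
  )
})

test_that("noiseless data identify the neck tilt almost exactly", {
  p <- quiet_observer()
  tr <- simulate_participant(seed = 21, params = p)
  fit <- fit_observer(
    tr, "mle",
    fit_options(
      n_starts = 12, seed = 1, max_iter = 2000,
      bounds = quiet_bounds
    )
  )
  expect_lt(abs(fit$params$neck_tilt_deg - 12), 0.01)
  expect_gt(fit$r_squared, 0.999)
})

test_that("fitting is deterministic and internally consistent", {
  tr <- simulate_participant(seed = 31)
  opts <- fit_options(n_starts = 4, seed = 7)
  f1 <- fit_observer(tr, "mle", opts)
  f2 <- fit_observer(tr, "mle", opts)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loglik, f2$loglik)

  # the reported loglik is the public likelihood at the fitted parameters
  expect_equal(f1$loglik, loglik_trials(tr, f1$params, "mle"), tolerance = 1e-8)
  # the BIC identity holds exactly
  expect_equal(f1$bic, f1$k_params * log(f1$n_trials) - 2 * f1$loglik)
  expect_equal(f1$k_params, 5)
  expect_equal(f1$n_trials, 210)

  td <- tidy(f1)
  expect_setequal(td$term, variant_parameters("mle"))
  gl <- glance(f1)
  expect_equal(gl$bic, f1$bic)

  expect_warning(
    fit_observer(
      tr[tr$task == "RFT", ], "mle",
      fit_options(n_starts = 2, seed = 1)
    ),
    "one task"
  )
})

test_that("richer weighting schemes fit at least as well as direct-only", {
  tr <- simulate_participant(seed = 41)
  opts <- fit_options(n_starts = 8, seed = 2)
  ll <- vapply(
    c("fixed", "mle", "free"),
    function(v) fit_observer(tr, v, opts)$loglik,
    numeric(1)
  )
  # direct-only sits on the boundary of both richer families
  expect_gte(ll[["mle"]], ll[["fixed"]] - 1e-4)
  expect_gte(ll[["free"]], ll[["fixed"]] - 1e-4)
})

test_that("model comparison recovers the generating weighting regime", {
  # generated under reliability weighting: mle must win on BIC
  tr <- simulate_participant(seed = 51)
  cmp <- compare_variants(tr, fit_options(n_starts = 8, seed = 3))
  tab <- tidy(cmp)
  expect_equal(tab$variant[1], "mle")
  expect_equal(tab$delta_bic[1], 0)
  expect_true(all(tab$delta_bic[-1] > 0))
  expect_equal(tab$evidence[1], "negligible")

  # generated direct-only: the 4-parameter fixed variant wins on BIC
  tr_fx <- simulate_participant(seed = 52, variant = "fixed")
  cmp_fx <- compare_variants(tr_fx, fit_options(n_starts = 8, seed = 3),
    variants = c("fixed", "mle")
  )
  tab_fx <- tidy(cmp_fx)
  expect_equal(tab_fx$variant[1], "fixed")
})

test_that("recovery error shrinks when the design grows tenfold", {
  truth <- ref_observer()
  rel_err <- function(fit) {
    p <- fit$params
    mean(abs(c(
      (p$neck_tilt_deg - 9.416) / 9.416,
      (p$sigma_som - 0.811) / 0.811,
      (p$sigma_pro - 9.276) / 9.276,
      (p$sigma_com0 - 8.572) / 8.572,
      (p$k_com - 0.249) / 0.249
    )))
  }
  errs <- sapply(1:3, function(i) {
    small <- simulate_participant(seed = 60 + i)
    big <- simulate_participant(
      seed = 70 + i,
      reps_upright = 30, reps_tilted = 20
    )
    opts <- fit_options(n_starts = 6, seed = i)
    c(
      small = rel_err(fit_observer(small, "mle", opts)),
      big = rel_err(fit_observer(big, "mle", opts))
    )
  })
  expect_lt(mean(errs["big", ]), mean(errs["small", ]))
})

test_that("cohort summaries reduce to medians, SDs and weights", {
  s <- cohort_summary(reference_parameters())
  med <- s$params$median[match(
    c("neck_tilt_deg", "sigma_som", "sigma_pro", "sigma_com0", "k_com"),
    s$params$term
  )]
  expect_equal(med, c(9.416, 0.811, 9.276, 8.572, 0.249), tolerance = 1e-3)
  w0 <- s$weights[s$weights$ar_tilt_deg == 0, ]
  expect_equal(round(w0$omega_hisd, 3), 0.541, tolerance = 2e-3)

  # single fit: summary equals that fit, SD 0
  tr <- simulate_participant(seed = 81)
  f <- fit_observer(tr, "mle", fit_options(n_starts = 4, seed = 1))
  s1 <- cohort_summary(list(f))
  expect_equal(s1$params$sd, rep(0, 5))
  expect_equal(
    s1$params$median[s1$params$term == "sigma_som"], f$params$sigma_som
  )
})
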