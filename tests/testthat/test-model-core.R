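test_that("visual tilt is the sum of the three stimulus tilts", {
  expect_equal(visual_tilt(3, 15, -36), -18)
  expect_equal(visual_tilt(0, 0, 0), 0)
  expect_equal(visual_tilt(-3, 0, 36), 33)
  expect_equal(visual_tilt(c(1, 2), c(0, 0), c(3, 4)), c(4, 6))
  expect_error(visual_tilt(NA, 0, 0), "finite")
  expect_error(visual_tilt(Inf, 0, 0), "finite")
})

test_that("sensory channel means and noise follow the stimulus", {
  p <- ref_observer()
  ch0 <- sensory_channels(p, 0, 0, 0)
  expect_equal(ch0$com_sd, 8.572)
  expect_equal(ch0$som_sd, 0.811)
  expect_equal(ch0$pro_sd, 9.276)

  ch36 <- sensory_channels(p, 0, 0, 36)
  expect_equal(ch36$com_sd, 8.572 + 0.249 * 36) # 17.536
  # eccentricity acts through |ar|
  expect_equal(sensory_channels(p, 0, 0, -36)$com_sd, ch36$com_sd)

  ch <- sensory_channels(p, 3, 1, 13)
  expect_equal(ch$com_mean, 3 + 9.416 + 13) # 25.416
  expect_equal(ch$pro_mean, 9.416)
  expect_equal(ch$som_mean, 3)
  # neck drops out with the head upright
  expect_equal(sensory_channels(p, 3, 0, 13)$pro_mean, 0)

  expect_error(sensory_channels(p, NaN, 0, 0), "finite")
  expect_error(observer_params(0, -1, 9, 8, 0.2), "sigma_som")
})

test_that("indirect estimates subtract/add means and add variances", {
  ch <- tibble::tibble(
    som_mean = 3, som_sd = 0.8,
    pro_mean = 15, pro_sd = 4,
    com_mean = 10, com_sd = 3
  )
  bis <- indirect_bis(ch)
  expect_equal(bis$mean, -5)
  expect_equal(bis$sd, 5) # 3-4-5

  ch$pro_sd <- 9.276
  his <- indirect_his(ch)
  expect_equal(his$mean, 18)
  expect_equal(his$sd^2, 0.64 + 9.276^2, tolerance = 1e-12) # 86.684

  # degenerate zero-noise neck returns the head channel unchanged
  ch0 <- tibble::tibble(
    som_mean = 0, som_sd = 0, pro_mean = 0, pro_sd = 0,
    com_mean = 7, com_sd = 2
  )
  expect_equal(indirect_bis(ch0), tibble::tibble(mean = 7, sd = 2))
  expect_equal(indirect_his(ch0), tibble::tibble(mean = 0, sd = 0))

  # reference-median variances behind the published weights
  chm <- sensory_channels(ref_observer(), 0, 0, 0)
  expect_equal(indirect_bis(chm)$sd^2, 8.572^2 + 9.276^2, tolerance = 1e-12)
  expect_equal(indirect_bis(chm)$sd^2, 159.5234, tolerance = 1e-3)
  expect_equal(indirect_his(chm)$sd^2, 0.811^2 + 9.276^2, tolerance = 1e-12)
  expect_equal(indirect_his(chm)$sd^2, 86.7019, tolerance = 1e-3)
})

test_that("reliability weights follow the inverse-variance rule", {
  w <- mle_weights(4, 4, 9, 9)
  expect_equal(w$omega_hisd, 0.5)
  expect_equal(w$omega_bisd, 0.5)

  ww <- observer_weights(ref_observer(), c(0, 36, -36))
  expect_equal(round(ww$omega_bisd[1], 3), 0.996)
  expect_equal(round(ww$omega_hisd[1], 3), 0.541)
  expect_equal(round(ww$omega_hisd[2], 3), 0.220)
  expect_equal(round(ww$omega_bisd[2], 3), 0.998)
  expect_equal(ww$omega_hisd[3], ww$omega_hisd[2]) # symmetric in |ar|

  expect_error(mle_weights(0, 1, 1, 1), "> 0")
  expect_error(mle_weights(-1, 1, 1, 1), "> 0")
})

test_that("convex combination of Gaussians has the stated mean and variance", {
  d <- combine_estimates(10, 2, 0, 7, 1)
  expect_equal(d, tibble::tibble(mean = 10, sd = 2)) # omega = 1 boundary
  i <- combine_estimates(10, 2, 0, 7, 0)
  expect_equal(i, tibble::tibble(mean = 0, sd = 7)) # omega = 0 boundary
  h <- combine_estimates(10, 3, 0, 3, 0.5)
  expect_equal(h$mean, 5)
  expect_equal(h$sd^2, 9 / 2) # sigma^2 / 2
  expect_error(combine_estimates(0, 1, 0, 1, 1.5), "\\[0, 1\\]")
  expect_error(combine_estimates(0, 1, 0, 1, -0.1), "\\[0, 1\\]")
})

test_that("rod-setting predictions counter the perceived head tilt", {
  p <- ref_observer()
  # direct-only: the rod mirrors the head channel exactly
  fx <- predict_rft(p, 0, 0, 36, "fixed")
  expect_equal(fx$mean, -36)
  expect_equal(fx$sd, 8.572 + 0.249 * 36)

  # reliability weighting shrinks the visual effect: slope is -omega_hisd
  ml <- predict_rft(p, 0, 0, 36, "mle")
  w36 <- observer_weights(p, 36)$omega_hisd
  expect_equal(ml$mean, -w36 * 36)
  expect_equal(ml$mean, -7.9178, tolerance = 1e-3)

  # direct and indirect means agree when only the neck is tilted,
  # so the prediction is -neck tilt for every weighting
  for (v in c("fixed", "mle")) {
    expect_equal(predict_rft(p, 0, 1, 0, v)$mean, -9.416)
  }
  pf <- observer_params(9.416, 0.811, 9.276, 8.572, 0.249,
    omega_hisd = 0.3, omega_bisd = 0.9
  )
  expect_equal(predict_rft(pf, 0, 1, 0, "free")$mean, -9.416)
  expect_error(predict_rft(p, 0, 0, 0, "free"), "omega")
})

test_that("postural-vertical predictions cancel the visual discrepancy", {
  p <- ref_observer()
  # omega_bisd = 1: the platform is set to gravity exactly
  expect_equal(predict_spv(p, 3, 0, 20, "fixed")$mean, 0)
  expect_equal(round(predict_spv(p, 0, 0, 36, "mle")$mean, 3), -0.060)
  sp <- predict_spv(p, 0, 0, 0, "mle")
  expect_equal(sp$mean, 0)
  expect_equal(sp$sd, 0.811)
  # head-tilted offset extension shifts the SPV mean only
  po <- observer_params(9.416, 0.811, 9.276, 8.572, 0.249,
    spv_neck_offset_deg = -2.402
  )
  expect_equal(
    predict_spv(po, 0, 1, 0, "mle")$mean - predict_spv(po, 0, 0, 0, "mle")$mean,
    -2.402
  )
  expect_equal(predict_rft(po, 0, 0, 13, "mle"), predict_rft(p, 0, 0, 13, "mle"))
})

test_that("weights are complementary and MLE weighting minimises variance", {
  p <- ref_observer()
  for (ar in c(0, 5, 13, 36)) {
    ch <- sensory_channels(p, 0, 0, ar)
    var_d <- ch$com_sd^2
    var_i <- ch$som_sd^2 + ch$pro_sd^2
    w <- mle_weights(var_d, var_i, ch$som_sd^2, var_d + ch$pro_sd^2)
    expect_equal(w$omega_hisd + (1 - w$omega_hisd), 1)

    # optimal combined variance and its closed form
    v_opt <- combine_estimates(0, sqrt(var_d), 0, sqrt(var_i), w$omega_hisd)$sd^2
    expect_equal(v_opt, var_d * var_i / (var_d + var_i), tolerance = 1e-12)
    expect_lte(v_opt, min(var_d, var_i))
    grid <- seq(0, 1, by = 0.01)
    v_grid <- combine_estimates(0, sqrt(var_d), 0, sqrt(var_i), grid)$sd^2
    expect_true(all(v_grid >= v_opt - 1e-12))
  }
})

test_that("rod-response gain in visual tilt equals minus the direct weight", {
  # with head and platform upright the predicted rod setting is
  # -omega_hisd(|ar|) * ar, so the through-origin slope at each
  # eccentricity is minus the weight evaluated there
  p <- ref_observer()
  for (ar in c(-36, -13, 5, 13, 36)) {
    m <- predict_rft(p, 0, 0, ar, "mle")$mean
    w <- observer_weights(p, ar)$omega_hisd
    expect_equal(m / ar, -w, tolerance = 1e-10)
  }
  # and the platform/neck terms shift the response without touching that gain
  m1 <- predict_rft(p, 3, 0, 13, "mle")$mean
  m0 <- predict_rft(p, 0, 0, 13, "mle")$mean
  expect_equal(m1 - m0, -3, tolerance = 1e-10)
})

test_that("SPV prediction ignores platform tilt and head condition", {
  p <- ref_observer()
  for (v in c("fixed", "mle")) {
    base <- predict_spv(p, 0, 0, 13, v)
    expect_equal(predict_spv(p, 3, 0, 13, v), base)
    expect_equal(predict_spv(p, -3, 1, 13, v), base)
  }
})

test_that("predictions are antisymmetric in the stimuli with no neck tilt", {
  p <- observer_params(0, 0.811, 9.276, 8.572, 0.249)
  for (v in c("fixed", "mle")) {
    expect_equal(
      predict_rft(p, 3, 0, 13, v)$mean,
      -predict_rft(p, -3, 0, -13, v)$mean
    )
    expect_equal(
      predict_spv(p, 3, 0, 13, v)$mean,
      -predict_spv(p, -3, 0, -13, v)$mean
    )
  }
})

test_that("infinite neck noise recovers the direct-only model", {
  base <- ref_observer()
  w_prev <- observer_weights(base, 13)
  for (s_pro in c(1e2, 1e4, 1e6)) {
    p <- observer_params(9.416, 0.811, s_pro, 8.572, 0.249)
    w <- observer_weights(p, 13)
    expect_gte(w$omega_hisd, w_prev$omega_hisd)
    expect_gte(w$omega_bisd, w_prev$omega_bisd)
    w_prev <- w
  }
  expect_equal(w_prev$omega_hisd, 1, tolerance = 1e-6)
  expect_equal(w_prev$omega_bisd, 1, tolerance = 1e-6)
})

test_that("predict_trials dispatches on the task column", {
  p <- ref_observer()
  tr <- dplyr::bind_rows(
    tiny_trials("RFT", response = 0, ar = 36),
    tiny_trials("SPV", response = 0, ar = 36)
  )
  out <- predict_trials(tr, p, "mle")
  expect_equal(out$pred_mean_deg[1], predict_rft(p, 0, 0, 36, "mle")$mean)
  expect_equal(out$pred_mean_deg[2], predict_spv(p, 0, 0, 36, "mle")$mean)
  expect_equal(out$pred_sd_deg[2], 0.811)
})
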