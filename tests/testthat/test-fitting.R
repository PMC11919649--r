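# ADC fits, two-compartment inversion, map fitting.

test_that("fit_adc matches the closed-form two-point solution", {
  f <- fit_adc(c(0, 1000), c(1, 0.4))
  expect_equal(f$adc, -log(0.4), tolerance = 1e-10)  # 0.916 um^2/ms
  expect_equal(f$s0, 1, tolerance = 1e-10)
  # random two-point problems: lm slope == closed form
  set.seed(4)
  for (i in 1:20) {
    b <- sort(sample(c(100, 250, 500, 750, 1000, 1400), 2))
    S <- exp(-b / 1000 * runif(1, 0.3, 2.5)) * runif(1, 0.8, 1.2)
    f2 <- fit_adc(b, S)
    expect_equal(f2$adc, -1000 * diff(log(S)) / diff(b), tolerance = 1e-9)
  }
})

test_that("fit_adc handles flat, rising and invalid signals", {
  expect_equal(fit_adc(c(0, 500, 1000), c(1, 1, 1))$adc, 0)
  rising <- fit_adc(c(0, 500, 1000), c(1, 1.1, 1.25))
  expect_equal(rising$adc, 0)
  expect_true(rising$clipped)
  bad <- fit_adc(c(0, 1000), c(1, -0.1))
  expect_true(bad$flagged)
  expect_true(is.na(bad$adc))
  expect_lte(fit_adc(c(0, 500, 1000), c(1, 0.6, 0.41))$r_squared, 1)
})

test_that("noiseless signals are recovered within tight tolerances", {
  p <- test_prot(); k <- test_kernel()
  truths <- rbind(c(15.74, 0.346, 2.119),  # reported malignant means
                  c(8, 0.6, 1.2), c(22, 0.2, 2.8), c(12, 0.45, 0.9))
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    fit <- fit_impulsed(forward_df(tr[1], tr[2], tr[3]), p, kernel = k)
    expect_lt(abs(fit$params$d_mean / tr[1] - 1), 0.02)
    expect_lt(abs(fit$params$f_in - tr[2]), 0.02)
    expect_lt(abs(fit$params$D_ex / tr[3] - 1), 0.02)
    expect_true(fit$converged)
    expect_lt(fit$residual_rms, 1e-6)  # self-consistency at the optimum
    expect_equal(fit$cellularity, fit$params$f_in / fit$params$d_mean)
  }
})

test_that("the returned optimum dominates every multi-start grid node", {
  fit <- fit_impulsed(forward_df(17, 0.3, 1.8), test_prot(),
                      kernel = test_kernel())
  expect_lte(fit$objective, min(fit$grid_objectives) + 1e-12)
})

test_that("a vanishing intracellular fraction flags the diameter", {
  fit <- fit_impulsed(forward_df(15, 0.02, 2), test_prot(),
                      kernel = test_kernel())
  expect_gt(fit$d_spread, 0.2)
  fit_ok <- fit_impulsed(forward_df(15, 0.4, 2), test_prot(),
                         kernel = test_kernel())
  expect_lte(fit_ok$d_spread, 0.2)
})

test_that("fitting requires at least two distinct diffusion times", {
  df <- forward_df(15, 0.3, 2)
  expect_error(fit_impulsed(df[df$sequence == "PGSE", ], test_prot(),
                            kernel = test_kernel()), "identifiability")
})

test_that("fit_maps: homogeneous phantom, single voxel, ROI semantics", {
  p <- test_prot(); k <- test_kernel()
  truth <- list(d_mean = 14, f_in = 0.35, D_ex = 2.1)
  ph <- generate_lesion_image(truth, p, shape = c(4, 4, 1), snr = Inf,
                              seed = 1, jitter_cv = 0, kernel = k)
  pm <- fit_maps(ph$vol, ph$mask, p, kernel = k)
  roi <- pm$roi_summary
  for (par in c("d_mean", "f_in", "D_ex", "cellularity")) {
    row <- roi[roi$parameter == par, ]
    expect_lt(row$sd, 1e-3 * abs(row$mean))  # identical voxel problems
  }
  expect_equal(roi$mean[roi$parameter == "d_mean"], 14, tolerance = 1e-3)
  # single-voxel mask equals the voxel's own fit
  mask1 <- array(0, dim(ph$mask))
  idx <- which(ph$mask == 1)[1]
  mask1[idx] <- 1
  pm1 <- fit_maps(ph$vol, mask1, p, kernel = k)
  expect_equal(pm1$roi_summary$mean[pm1$roi_summary$parameter == "f_in"],
               pm$maps$f_in[idx], tolerance = 1e-12)
  expect_true(all(pm1$roi_summary$n_voxels == 1))
})

test_that("ROI cellularity is the mean of voxel ratios, not a ratio of means", {
  # two-voxel toy: mean(f/d) != mean(f)/mean(d) by Jensen-type inequality
  f <- c(0.2, 0.5); d <- c(8, 12)
  expect_false(isTRUE(all.equal(mean(f / d), mean(f) / mean(d))))
  p <- test_prot(); k <- test_kernel()
  vol <- array(0, c(2, 1, 1, nrow(acquisition_table(p))))
  for (v in 1:2) {
    s <- forward_df(d[v], f[v], 2)
    vol[v, 1, 1, ] <- s$S
  }
  mask <- array(1, c(2, 1, 1))
  pm <- fit_maps(vol, mask, p, kernel = k)
  cell <- pm$roi_summary$mean[pm$roi_summary$parameter == "cellularity"]
  expect_equal(cell, mean(f / d), tolerance = 1e-3)
  expect_gt(abs(cell - mean(f) / mean(d)), 1e-3)
})

test_that("fit_maps validates its inputs", {
  p <- test_prot()
  n_acq <- nrow(acquisition_table(p))
  vol <- array(1, c(2, 2, 1, n_acq))
  expect_error(fit_maps(array(1, c(2, 2, n_acq)), array(1, c(2, 2, 1)), p),
               "4D")
  expect_error(fit_maps(array(1, c(2, 2, 1, 3)), array(1, c(2, 2, 1)), p),
               "acquisitions")
  expect_error(fit_maps(vol, array(1, c(3, 3, 1)), p), "mask grid")
  expect_error(fit_maps(vol, array(0, c(2, 2, 1)), p), "empty mask")
  expect_error(fit_maps(vol, array(0.5, c(2, 2, 1)), p), "0/1")
})
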