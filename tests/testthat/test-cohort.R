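# Synthetic cohort generator: enrollment, labels, truths, phantoms.

test_that("the default roster reproduces the enrollment flow exactly", {
  roster <- generate_roster(cohort_spec(), seed = 7)
  expect_equal(nrow(roster), 236)
  exc <- apply_exclusions(roster)
  expect_equal(unname(exc$report[c("small_lesion", "no_pathology",
                                   "poor_quality")]), c(10, 5, 8))
  expect_equal(unname(exc$report[["n_enrolled"]]), 213)
  expect_equal(sum(exc$cohort$group == "benign"), 83)
  expect_equal(sum(exc$cohort$group == "malignant"), 130)
  expect_equal(sum(exc$cohort$is_ibc), 117)
  # enrollment flag is the conjunction of the three criteria
  expect_equal(roster$enrolled,
               roster$lesion_diameter_mm >= 8 & roster$pathology_available &
                 roster$image_quality_ok)
})

test_that("the roster is deterministic in the seed, marginals are not", {
  r1 <- generate_roster(small_spec(), seed = 3)
  r2 <- generate_roster(small_spec(), seed = 3)
  expect_identical(r1, r2)
  r3 <- generate_roster(small_spec(), seed = 4)
  expect_false(identical(r1$patient_id, r3$patient_id))
  for (r in list(r1, r3)) {
    e <- apply_exclusions(r)
    expect_equal(sum(e$cohort$er == "pos", na.rm = TRUE), 7)
    expect_equal(sum(e$cohort$her2 == "pos", na.rm = TRUE), 4)
  }
})

test_that("exclusion edge cases behave", {
  spec0 <- cohort_spec(n_collected = 213,
                       exclusions = c(small_lesion = 0, no_pathology = 0,
                                      poor_quality = 0))
  r <- generate_roster(spec0, seed = 1)
  expect_true(all(r$enrolled))
  e <- apply_exclusions(r[0, , drop = FALSE])
  expect_equal(unname(e$report[["n_enrolled"]]), 0)
  expect_error(cohort_spec(n_collected = 10,
                           exclusions = c(small_lesion = 5, no_pathology = 5,
                                          poor_quality = 5)),
               "infeasible")
})

test_that("subtype labels maximize rule consistency under infeasible marginals", {
  rule <- impulsedr:::.subtype_rule
  expect_equal(rule("pos", "neg", "neg"), "LuminalA")
  expect_equal(rule("neg", "pos", "pos"), "LuminalB")
  expect_equal(rule("neg", "neg", "pos"), "HER2over")
  expect_equal(rule("neg", "neg", "neg"), "TN")
  roster <- generate_roster(cohort_spec(), seed = 2)
  # printed marginals are jointly infeasible: 71 + 26 HER-2+ subtypes vs 46
  # HER-2+; the attainable minimum of inconsistent records is 59
  expect_equal(attr(roster, "n_subtype_inconsistent"), 59)
})

test_that("tissue-parameter draws match their stated distributions", {
  spec <- cohort_spec()
  tp <- draw_tissue_params(spec, "malignant", 10000, seed = 5)
  expect_lt(abs(mean(tp$d_mean) - 15.74), 2 * 2.677 / sqrt(10000))
  expect_true(all(tp$d_mean > 4 & tp$d_mean < 30))
  expect_true(all(tp$f_in > 0 & tp$f_in < 1))
  expect_true(all(tp$D_ex > 0 & tp$D_ex < 3.5))
  # calibrated copula: population cellularity means follow the printed rows
  tb <- draw_tissue_params(spec, "benign", 40000, seed = 6)
  expect_equal(mean(tb$f_in / tb$d_mean), spec$params$benign$cellularity[1],
               tolerance = 0.02)
  expect_gt(cor(tb$f_in, tb$d_mean), 0.4)
  expect_error(draw_tissue_params(spec, "weird", 10), "unknown stratum")
  # degenerate SD: all draws at the mean
  s0 <- cohort_spec()
  s0$params$malignant$d[2] <- 0
  t0 <- draw_tissue_params(s0, "malignant", 50, seed = 1)
  expect_true(all(t0$d_mean == 15.74))
})

test_that("lesion phantoms honour SNR semantics", {
  p <- test_prot(); k <- test_kernel()
  truth <- list(d_mean = 15, f_in = 0.35, D_ex = 2.1)
  ph <- generate_lesion_image(truth, p, shape = c(6, 6, 3), snr = Inf,
                              seed = 2, jitter_cv = 0, kernel = k)
  s <- two_compartment_signal(c(truth, D_in = 1.58), p, kernel = k)
  vox <- which(ph$mask == 1)[1]
  ijk <- arrayInd(vox, dim(ph$mask))
  expect_equal(ph$vol[ijk[1], ijk[2], ijk[3], ], s$S_over_S0,
               tolerance = 1e-9, ignore_attr = TRUE)
  # Rician floor: background magnitude has mean sigma * sqrt(pi/2)
  phn <- generate_lesion_image(truth, p, shape = c(10, 10, 4), snr = 20,
                               seed = 3, jitter_cv = 0, kernel = k)
  bg <- phn$vol[, , , 1][phn$mask == 0]
  sigma <- 1 / 20
  expect_equal(mean(bg), sigma * sqrt(pi / 2),
               tolerance = 4 / sqrt(length(bg)))
  # determinism
  ph2 <- generate_lesion_image(truth, p, shape = c(6, 6, 3), snr = 50,
                               seed = 4, kernel = k)
  ph3 <- generate_lesion_image(truth, p, shape = c(6, 6, 3), snr = 50,
                               seed = 4, kernel = k)
  expect_identical(ph2$vol, ph3$vol)
})

test_that("run_cohort_analysis produces a complete, reproducible table", {
  p <- test_prot(); k <- test_kernel()
  res <- run_cohort_analysis(small_spec(), p, seed = 11, snr = Inf,
                             n_vox = 2, kernel = k)
  expect_equal(nrow(res$cohort), 26)
  expect_true(all(c("d_mean", "f_in", "D_ex", "cellularity", "ADC_DWI",
                    "ADC_PGSE", "ADC_17Hz", "ADC_33Hz", "d_mean_obs1",
                    "d_mean_obs2") %in% names(res$cohort)))
  expect_false(anyNA(res$cohort$d_mean))
  res2 <- run_cohort_analysis(small_spec(), p, seed = 11, snr = Inf,
                              n_vox = 2, kernel = k)
  expect_identical(res$cohort, res2$cohort)
  # noiseless fits track the jittered truth closely at the lesion level
  expect_lt(median(abs(res$cohort$d_mean - res$cohort$d_mean_truth)), 1)
})
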