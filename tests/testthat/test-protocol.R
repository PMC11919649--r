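# Gradient waveforms, b-values, diffusion times.

gamma_i <- 2.675e-4  # rad ms^-1 (mT/m)^-1 um^-1

test_that("PGSE waveforms satisfy the invariants and the closed-form b", {
  cases <- list(c(G = 30, delta = 15.9, Delta = 119.2, TE = 145),
                c(G = 33.7, delta = 18, Delta = 44, TE = 63),
                c(G = 10, delta = 5, Delta = 20, TE = 30))
  for (cs in cases) {
    w <- make_pgse(cs["G"], cs["delta"], cs["Delta"], cs["TE"],
                   dt = cs["delta"] / 200)
    expect_true(validate_waveform(w))
    # rephasing: net moment tiny relative to the pulse area
    expect_lt(abs(sum(w$g_eff)) * w$dt, 1e-9 * max(abs(w$g_eff)) * w$TE)
    b_cf <- 1000 * gamma_i^2 * cs[["G"]]^2 * cs[["delta"]]^2 *
      (cs[["Delta"]] - cs[["delta"]] / 3)
    expect_lt(abs(b_value(w) / b_cf - 1), 0.005)
  }
})

test_that("cosine OGSE matches its closed-form b and stores frequencies", {
  # pair of n-cycle cosine lobes: b = gamma^2 G^2 delta / (4 pi^2 f^2)
  for (n in c(1, 2, 3)) {
    w <- make_ogse(25, 64.2, 72.7, n, 145, f_nominal = 17 * n)
    f <- n / 64.2
    b_cf <- 1000 * gamma_i^2 * 25^2 * 64.2 / (4 * pi^2 * f^2)
    expect_lt(abs(b_value(w) / b_cf - 1), 0.005)
    expect_equal(w$f_realized, f)
    expect_true(validate_waveform(w))
  }
  w17 <- make_ogse(25, 64.2, 72.7, 1, 145, f_nominal = 17)
  expect_equal(1000 * w17$f_realized, 15.58, tolerance = 1e-3)
  expect_equal(1000 * w17$f_nominal, 17)
})

test_that("b_value scaling, zero-gradient and time-reversal properties hold", {
  w1 <- make_pgse(10, 15.9, 119.2, 145)
  w2 <- make_pgse(20, 15.9, 119.2, 145)
  expect_equal(b_value(w2) / b_value(w1), 4, tolerance = 1e-10)
  w0 <- make_pgse(0, 15.9, 119.2, 145)
  expect_equal(b_value(w0), 0)
  expect_equal(b_value(make_ogse(0, 64.2, 72.7, 2, 145)), 0)
  wr <- w1
  wr$g_eff <- rev(wr$g_eff)
  expect_equal(b_value(wr), b_value(w1), tolerance = 1e-9)
})

test_that("numerical b agrees with its FFT-domain (Parseval) evaluation", {
  for (w in list(make_pgse(22, 15.9, 119.2, 145),
                 make_ogse(30, 64.2, 72.7, 2, 145))) {
    ps <- impulsedr:::.q_power_spectrum(w, energy_tol = 1e-8)
    b_fft <- 1000 * (ps$dw / (2 * pi)) * sum(ps$wt * ps$P)
    expect_lt(abs(b_fft / b_value(w) - 1), 0.005)
  }
})

test_that("scale_to_b round-trips, enforces the limit, and handles b = 0", {
  w <- make_pgse(10, 15.9, 119.2, 145, label = "PGSE")
  ws <- scale_to_b(w, 1800)
  expect_equal(b_value(ws), 1800, tolerance = 1e-3)
  expect_lt(ws$G, 45)  # highest PGSE shell fits a single axis
  w0 <- scale_to_b(w, 0)
  expect_equal(w0$G, 0)
  expect_equal(b_value(w0), 0)
  # pure-cosine OGSE at 33 Hz / b = 300 exceeds a strict per-axis 45 mT/m
  wo <- make_ogse(10, 64.2, 72.7, 2, 145, label = "OGSE_33Hz")
  expect_error(scale_to_b(wo, 300, g_max = 45), "OGSE_33Hz")
  expect_silent(scale_to_b(wo, 300))  # combined-axis default limit
})

test_that("effective diffusion time follows the family rule", {
  expect_equal(effective_diffusion_time(make_pgse(10, 15.9, 119.2, 145)),
               119.2 - 15.9 / 3)
  # realized 33.33 Hz -> 7.5 ms; realized 16.67 Hz -> 15 ms
  expect_equal(effective_diffusion_time(make_ogse(10, 60, 70, 2, 145)), 7.5)
  expect_equal(effective_diffusion_time(make_ogse(10, 60, 70, 1, 145)), 15)
})

test_that("invalid timings and cycle counts are rejected", {
  expect_error(make_pgse(10, 18, 44, 59.5), "protocol error")
  expect_error(make_ogse(10, 64.2, 72.7, 1.5, 145), "integer")
  expect_error(make_ogse(10, 64.2, 72.7, 0, 145), "integer")
  expect_error(make_pgse(10, 15.9, 119.2, 145, dt = 1), "dt")
  expect_error(make_ogse(10, 64.2, 72.7, 2, 145, dt = 0.5), "100 samples")
})

test_that("the packaged protocol satisfies its contract", {
  p <- test_prot()
  expect_named(p$sequences, c("DWI", "PGSE", "OGSE_17Hz", "OGSE_33Hz"))
  for (s in p$sequences) {
    expect_true(s$b_values[1] == 0)
    expect_true(all(diff(s$b_values) > 0))
    expect_true(validate_waveform(s$template))
  }
  tab <- acquisition_table(p)
  expect_identical(nrow(tab), 2L + 7L + 5L + 4L)
})
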