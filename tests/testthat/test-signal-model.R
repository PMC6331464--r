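# Variable flip-angle T1 mapping and the SPGR signal model

test_that("VFA recovers T10 from noiseless dual-angle pairs across the physiological range", {
  p <- default_params
  t10 <- seq(0.3, 3, length.out = 40)
  m0 <- seq(500, 1500, length.out = 40)
  sa <- spgr_signal(m0, t10, p$alpha_a, p$tr)
  sb <- spgr_signal(m0, t10, p$alpha_b, p$tr)
  est <- compute_t10(sa, sb, p)
  expect_true(all(est$valid))
  expect_lt(max(abs(est$t10 - t10) / t10), 1e-9)
  m <- compute_m0(sb, est, p)
  expect_lt(max(abs(m$m0 - m0) / m0), 1e-9)
})

test_that("degenerate VFA inputs are flagged invalid, not errors", {
  p <- default_params
  aa <- p$alpha_a * pi / 180; ab <- p$alpha_b * pi / 180
  # signal ratio at the infinite-T10 limit: log argument exactly 1
  sr_inf <- sin(aa) * (1 - cos(ab)) / (sin(ab) * (1 - cos(aa)))
  est <- compute_t10(c(sr_inf, 0, 1), c(1, 0, NA), p)
  expect_false(any(est$valid))
  expect_true(all(is.na(est$t10)))
  # zero sb propagates into m0
  t <- compute_t10(spgr_signal(1000, 1, 2, p$tr), spgr_signal(1000, 1, 12, p$tr), p)
  m <- compute_m0(0, t, p)
  expect_false(m$valid[1])
  expect_error(compute_t10(matrix(1, 2, 2), matrix(1, 3, 3), p), "shape")
  expect_error(acq_params(alpha_a = 12, alpha_b = 12), "alpha")
})

test_that("SPGR forward reduces to the baseline at zero concentration and is monotone in Ct", {
  p <- default_params
  sh <- c(3, 3, 1)
  maps <- dcetk:::new_relaxation_maps(array(1.2, sh), m0 = array(1000, sh),
                                      valid = array(TRUE, sh))
  s0 <- array(spgr_signal(1000, 1.2, p$alpha_b, p$tr), sh)
  zero <- dynamic_series(array(0, c(sh, 21)), frame_times(p), "concentration_mM")
  sig <- spgr_forward(zero, s0, maps, p)
  expect_equal(sig$values, array(as.numeric(s0), c(sh, 21)))
  # strictly increasing in Ct at the protocol flip angle and TR
  ct_grid <- seq(0, 2, length.out = 200)
  s <- spgr_signal(1000, 1.2, p$alpha_b, p$tr, ct = ct_grid, r1 = p$r1)
  expect_true(all(diff(s) > 0))
})

test_that("Eq-style scalar evaluation matches the vectorized forward model", {
  # independent scalar transcription of the baseline-offset signal equation
  p <- default_params
  t10 <- 1.2; m0 <- 1000; ct <- 0.5
  k <- p$tr / t10; l <- p$r1 * ct * p$tr
  ab <- 12 * pi / 180
  s0 <- m0 * sin(ab) * (1 - exp(-k)) / (1 - cos(ab) * exp(-k))
  expected <- m0 * sin(ab) * (1 - exp(-(k + l))) / (1 - cos(ab) * exp(-(k + l))) +
    (s0 - m0 * sin(ab) * (1 - exp(-k)) / (1 - cos(ab) * exp(-k)))
  sh <- c(1, 1, 1)
  maps <- dcetk:::new_relaxation_maps(array(t10, sh), m0 = array(m0, sh),
                                      valid = array(TRUE, sh))
  cs <- dynamic_series(array(ct, c(sh, 2)), c(0, 73), "concentration_mM")
  got <- spgr_forward(cs, array(s0, sh), maps, p)$values[1, 1, 1, 2]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("signal-to-concentration inverts the forward model to 1e-10 over the working range", {
  p <- default_params
  ct_levels <- seq(0.01, 2, length.out = 21)
  t10s <- c(0.3, 0.6, 1.0, 1.4, 3.0)
  for (t10 in t10s) {
    sh <- c(2, 2, 1)
    maps <- dcetk:::new_relaxation_maps(array(t10, sh), m0 = array(900, sh),
                                        valid = array(TRUE, sh))
    s0 <- array(spgr_signal(900, t10, p$alpha_b, p$tr), sh)
    ct <- aperm(array(ct_levels, c(21, sh)), c(2, 3, 4, 1))
    cs <- dynamic_series(ct, frame_times(p), "concentration_mM")
    sig <- spgr_forward(cs, s0, maps, p)
    inv <- signal_to_concentration(sig, s0, maps, p)
    expect_true(all(inv$valid))
    expect_lt(max(abs(inv$conc$values - ct) / ct), 1e-10)
  }
})

test_that("inversion masks frames beyond the SPGR saturation asymptote", {
  p <- default_params
  sh <- c(1, 1, 1)
  maps <- dcetk:::new_relaxation_maps(array(1, sh), m0 = array(100, sh),
                                      valid = array(TRUE, sh))
  s0 <- array(spgr_signal(100, 1, p$alpha_b, p$tr), sh)
  sat <- 100 * sin(12 * pi / 180)   # SPGR asymptote for M0 sin(alpha)
  sig <- dynamic_series(array(c(as.numeric(s0), sat * 2), c(sh, 2)),
                        c(0, 73), "signal")
  inv <- signal_to_concentration(sig, s0, maps, p)
  expect_true(inv$valid[1, 1, 1, 1])
  expect_false(inv$valid[1, 1, 1, 2])
  expect_identical(inv$conc$values[1, 1, 1, 2], NA_real_)
  # S(t) = S(0) maps to exactly zero concentration
  expect_equal(inv$conc$values[1, 1, 1, 1], 0)
})

test_that("relaxivity and concentration enter the signal only through their product", {
  p <- default_params
  s1 <- spgr_signal(1000, 0.8, 12, p$tr, ct = 1.0, r1 = 4.2)
  s2 <- spgr_signal(1000, 0.8, 12, p$tr, ct = 0.5, r1 = 8.4)
  expect_equal(s1, s2, tolerance = 1e-15)
})
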