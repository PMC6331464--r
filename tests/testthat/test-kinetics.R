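# Tracer-kinetic forward models and input-function handling

test_that("VIF extraction averages the in-plane 3x3 neighborhood", {
  p <- default_params
  nt <- 5
  v <- array(0, c(5, 5, 3, nt))
  # identical curves everywhere -> the common curve
  curve <- c(0, 1, 2, 1.5, 1)
  v[] <- rep(curve, each = 75)
  ds <- dynamic_series(v, c(0, 73, 146, 219, 292), "signal")
  expect_equal(extract_vif(ds, c(3, 3, 2))$values, curve)
  # known constants 1..9 at one frame -> mean 5
  v2 <- array(0, c(5, 5, 1, 2))
  v2[2:4, 2:4, 1, 2] <- matrix(1:9, 3, 3)
  ds2 <- dynamic_series(v2, c(0, 73), "signal")
  expect_equal(extract_vif(ds2, c(3, 3, 1))$values, c(0, 5))
  expect_error(extract_vif(ds2, c(1, 3, 1)), "outside")
})

test_that("patch averaging reduces VIF noise standard deviation threefold", {
  # i.i.d. noise sigma on 9 voxels -> patch-mean noise sd = sigma/3
  set.seed(11)
  sigma <- 2
  reps <- 1000
  vals <- replicate(reps, {
    v <- array(rnorm(9 * 2, sd = sigma), c(3, 3, 1, 2))
    ds <- dynamic_series(v, c(0, 73), "signal")
    extract_vif(ds, c(2, 2, 1))$values[2]
  })
  expect_equal(sd(vals), sigma / 3, tolerance = 0.1)
})

test_that("whole-blood to plasma conversion divides by (1 - Hct)", {
  tm <- c(0, 73, 146)
  cb <- input_function(tm, c(0, 1.1, 0.55), "whole_blood")
  cp <- blood_to_plasma(cb, 0.45)
  expect_equal(cp$values, c(0, 2, 1))
  expect_identical(cp$kind, "plasma")
  expect_equal(blood_to_plasma(cb, 0)$values, cb$values)
  expect_equal(blood_to_plasma(input_function(tm, c(0, 0, 0), "whole_blood"),
                               0.45)$values, c(0, 0, 0))
  expect_error(blood_to_plasma(cb, 1), "hct")
  expect_error(blood_to_plasma(cp, 0.45), "whole-blood")
})

test_that("Patlak forward matches closed forms and fine-grid quadrature", {
  tm <- seq(0, 1460, by = 73)
  # Ktrans = 0 -> pure plasma-volume term
  cp <- test_cp()
  expect_equal(patlak_forward(0, 0.03, cp), 0.03 * cp$values)
  # constant plasma level: trapezoid is exact, Ct = vp c + Ktrans c t
  cpc <- input_function(tm, c(0, rep(2, 20)), "plasma")
  ct <- patlak_forward(3e-3, 0.01, cpc)
  tmin <- tm / 60
  exact <- 0.01 * cpc$values + 3e-3 * 2 * (tmin - tmin[2] / 2)
  exact[1:2] <- c(0, 0.01 * 2 + 3e-3 * 2 * tmin[2] / 2)
  expect_equal(ct, exact, tolerance = 1e-12)
  # smooth bolus curve: compare against independent quadrature on a
  # 1000x finer grid (gamma-variate shape, continuous at t = 0); the error
  # must be small on the 73 s grid and shrink as O(dt^2) under refinement
  gv <- function(t_s) { t <- t_s / 60; ifelse(t <= 0, 0, 4 * (t / 2) * exp(1 - t / 2)) }
  err_at <- function(dt) {
    tg <- seq(0, 1460, by = dt)
    fine_t <- seq(0, 1460, length.out = length(tg) * 1000 - 999)
    I_fine <- as.numeric(pracma::cumtrapz(fine_t / 60, gv(fine_t)))
    at <- 1 + 1000 * (seq_along(tg) - 1)
    ct_fine <- 0.01 * gv(tg) + 2e-3 * I_fine[at]
    ct <- patlak_forward(2e-3, 0.01, input_function(tg, gv(tg), "plasma"))
    max(abs(ct - ct_fine))
  }
  e1 <- err_at(73); e2 <- err_at(36.5); e4 <- err_at(18.25)
  expect_lt(e1, 5e-3)
  expect_gt(e2 / e1, 0.2); expect_lt(e2 / e1, 0.32)
  expect_gt(e4 / e2, 0.2); expect_lt(e4 / e2, 0.32)
})

test_that("cumulative trapezoid agrees with the pracma reference", {
  tm <- frame_times(default_params) / 60
  cp <- test_cp()$values
  mine <- as.numeric(dcetk:::trapz_weights(tm) %*% cp)
  expect_equal(mine, as.numeric(pracma::cumtrapz(tm, cp)), tolerance = 1e-14)
})

test_that("extended Tofts matches the analytic convolution of a ramp-step input", {
  tm <- seq(0, 1460, by = 73)
  c0 <- 1.5
  cpc <- input_function(tm, c(0, rep(c0, 20)), "plasma")
  kt <- 5e-3; kep <- 0.4; vp <- 0.02
  ct <- etofts_forward(kt, kep, vp, cpc)
  # the sampled curve is a linear ramp over [0, t2] then a constant; its
  # exponential-kernel convolution has a closed form
  tmin <- tm / 60; t2 <- tmin[2]
  ramp <- function(t) (c0 / t2) * exp(-kep * t) *
    ((t2 / kep - 1 / kep^2) * exp(kep * t2) + 1 / kep^2)
  I_exact <- ifelse(tmin < t2, 0,
                    ramp(tmin) + (c0 / kep) * (1 - exp(-kep * (tmin - t2))))
  exact <- vp * cpc$values + kt * I_exact
  expect_lt(max(abs(ct - exact)), 1e-3)   # trapezoid O(dt^2) on the 73 s grid
  # and the quadrature itself agrees with an independent trapezoid route
  tmins <- tm / 60
  I_ref <- vapply(seq_along(tmins), function(j) {
    if (j == 1) return(0)
    pracma::trapz(tmins[1:j], cpc$values[1:j] * exp(-kep * (tmins[j] - tmins[1:j])))
  }, 0)
  expect_equal(ct, vp * cpc$values + kt * I_ref, tolerance = 1e-14)
  expect_equal(etofts_forward(0, 0.5, 0.02, cpc), 0.02 * cpc$values)
})

test_that("the Patlak model is the kep -> 0 limit of extended Tofts, exactly", {
  set.seed(42)
  p <- default_params
  for (i in 1:100) {
    cp <- population_aif(frame_times(p), phantom_spec(), subject_seed = i)
    kt <- runif(1, 1e-4, 1e-2); vp <- runif(1, 0.001, 0.1)
    a <- etofts_forward(kt, 0, vp, cp)
    b <- patlak_forward(kt, vp, cp)
    expect_lt(max(abs(a - b)), 1e-12)
  }
})

test_that("Patlak forward is linear in its parameters (superposition)", {
  cp <- test_cp()
  a <- patlak_forward(1e-3, 0.01, cp)
  b <- patlak_forward(4e-3, 0.03, cp)
  both <- patlak_forward(5e-3, 0.04, cp)
  expect_equal(a + b, both, tolerance = 1e-14)
  expect_equal(patlak_forward(2e-3, 0.02, cp), 2 * patlak_forward(1e-3, 0.01, cp),
               tolerance = 1e-14)
})
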