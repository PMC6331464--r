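# Map agreement metrics and tissue statistics

test_that("nRMSE identities and range normalization", {
  a <- det_noise(20, 20)
  expect_equal(nrmse(a, a), 0)
  # two-voxel hand case: RMSE 0.5 over a unit reference range
  expect_equal(nrmse(c(0.5, 0.5), c(0, 1)), 0.5)
  # adding a common constant changes neither RMSE nor the range
  b <- det_noise(20, 20, f1 = 3.7, f2 = 11.1)
  expect_equal(nrmse(a + 5, b + 5), nrmse(a, b), tolerance = 1e-12)
})

test_that("SSIM identities, sign behavior, and agreement with the reference implementation", {
  a <- det_noise(32, 32)
  expect_equal(ssim(a, a), 1)
  # anti-correlated fluctuations about a common mean level -> negative SSIM
  ref <- 10 + 0.1 * (a - mean(a))
  est <- 20 - ref
  expect_lt(ssim(est, ref), 0)
  # frozen oracle values from an independent reference implementation of
  # Gaussian-weighted SSIM (11x11 window, sigma 1.5), same fixtures
  b <- det_noise(32, 32, f1 = 3.1415, f2 = 2.7182, amp = 12345.6789)
  expect_equal(ssim(0.7 * a + 0.3 * b, a), 0.8832956225875449, tolerance = 1e-6)
  i <- matrix(1:32, 32, 32); j <- t(i)
  expect_equal(ssim(a + 0.05 * sin(i * 0.3) * cos(j * 0.2), a),
               0.9982451283115886, tolerance = 1e-6)
})

test_that("Bland-Altman limits and Lin's concordance match hand evaluation", {
  x <- c(1, 2, 3, 4)
  r0 <- bland_altman(x, x)
  expect_equal(r0$mdiff, 0)
  expect_equal(r0$loa, c(0, 0))
  expect_equal(r0$ccc, 1)
  # constant offset: zero-width limits around the offset, CCC < 1
  rc <- bland_altman(x + 2, x)
  expect_equal(rc$mdiff, 2)
  expect_equal(rc$loa, c(2, 2))
  expect_lt(rc$ccc, 1)
  # hand-evaluated closed form for est (1,2,3), ref (1,2,4):
  # 2 cov / (var_e + var_r + (mean_e - mean_r)^2) = 3 / (1 + 7/3 + 1/9)
  rh <- bland_altman(c(1, 2, 3), c(1, 2, 4))
  expect_equal(rh$ccc, 3 / (1 + 7 / 3 + 1 / 9), tolerance = 1e-12)
})

test_that("1.96-sd limits of agreement cover ~95% of Gaussian differences", {
  set.seed(14)
  cover <- replicate(40, {
    e <- rnorm(500); r <- rnorm(500, sd = 0.5)
    ba <- bland_altman(e, r)
    d <- e - r
    mean(d >= ba$loa[1] & d <= ba$loa[2])
  })
  expect_gte(mean(cover), 0.93)
})

test_that("the paired Wilcoxon route agrees with exact signed-rank enumeration", {
  # enumeration oracle: distribution of W+ over all 2^n sign assignments
  exact_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    p <- if (w_obs > n * (n + 1) / 4) 2 * mean(w_all >= w_obs)
         else 2 * mean(w_all <= w_obs)
    min(1, p)
  }
  set.seed(9)
  for (rep in 1:5) {
    a <- rnorm(10); b <- a + rnorm(10, mean = 0.4)
    d <- b - a
    p_ref <- exact_p(d)
    p_got <- stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value
    expect_equal(p_got, p_ref, tolerance = 1e-12)
  }
})

test_that("tissue comparison reports per-subject medians and paired p-values", {
  set.seed(21)
  n_sub <- 10
  labs <- replicate(n_sub, make_tissue_map(c(48, 48, 1), sample(100, 1)),
                    simplify = FALSE)
  maps_a <- list(); maps_b <- list()
  for (s in seq_len(n_sub)) {
    m <- array(rnorm(48 * 48, mean = 2e-3, sd = 1e-4), c(48, 48, 1))
    maps_a[[s]] <- list(ktrans = m)
    # strictly positive per-subject shift of varying magnitude (no rank ties)
    maps_b[[s]] <- list(ktrans = m + runif(1, 3e-4, 7e-4))
  }
  out <- tissue_compare(maps_a, maps_b, labs, "ktrans",
                        alternative = "less")
  expect_true(all(out$p_value < 0.01))       # n = 10 strict shift, one-sided
  expect_equal(out$n_pairs, rep(n_sub, 4))
  # medians reported are the medians of the per-subject summaries
  nawm_a <- vapply(seq_len(n_sub),
                   function(s) median(maps_a[[s]]$ktrans[labs[[s]] == 1]), 0)
  expect_equal(out$median_a[out$tissue == "nawm"], median(nawm_a))
  # identical inputs: test centered at its null, p = 1
  same <- tissue_compare(maps_a, maps_a, labs, "ktrans")
  expect_true(all(same$p_value == 1))
})

test_that("slice-wise curve-fit error reproduces the metric identities", {
  ds <- tiny_phantom(sigma = 0, shape = c(32, 32, 3))
  cfe <- curve_fit_error(ds$conc, ds$conc, mask = ds$brain)
  expect_equal(cfe$per_slice$nrmse, rep(0, 3))
  expect_equal(cfe$per_slice$ssim, rep(1, 3))
  expect_equal(cfe$summary$sd, c(0, 0))
  # fitted maps from noisy data: error strictly positive, layout preserved
  ds2 <- tiny_phantom(sigma = 0.02, shape = c(32, 32, 2), seed = 9)
  conc <- signal_to_concentration(ds2$signal_noisy, ds2$sb, ds2$relax,
                                  ds2$spec$params)$conc
  fit <- fit_volume(conc, ds2$cp, "patlak", mask = ds2$brain)
  cfe2 <- curve_fit_error(conc, predict(fit), mask = ds2$brain)
  expect_equal(nrow(cfe2$per_slice), 2)
  expect_true(all(cfe2$per_slice$nrmse > 0))
  expect_true(all(cfe2$per_slice$ssim < 1))
})
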