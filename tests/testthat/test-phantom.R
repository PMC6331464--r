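# Digital reference object: tissue maps, parameter draws, input functions,
# and full forward simulation

test_that("tissue maps are reproducible, contiguous and cover every class", {
  for (seed in c(1, 5, 23)) {
    lab <- make_tissue_map(c(48, 48, 2), seed)
    expect_identical(lab, make_tissue_map(c(48, 48, 2), seed))
    tab <- table(factor(lab, levels = 0:5))
    expect_equal(sum(tab), 48 * 48 * 2)
    inbrain <- sum(lab > 0)
    for (code in 1:5)
      expect_gte(sum(lab == code) / inbrain, 0.01)
    # the VIF center supports an in-plane 3x3 vessel patch
    ctr <- attr(lab, "vif_center")
    patch <- lab[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1), ctr[3]]
    expect_true(all(patch == 5))
  }
  expect_false(identical(make_tissue_map(c(48, 48, 2), 1),
                         make_tissue_map(c(48, 48, 2), 2)))
})

test_that("parameter draws honor the tissue ordering and spread contract", {
  spec <- phantom_spec(shape = c(48, 48, 1))
  spec0 <- phantom_spec(shape = c(48, 48, 1), rel_spread = 0)
  lab <- make_tissue_map(spec$shape, 3)
  # zero spread: piecewise constant at the tissue means
  tru0 <- sample_parameters(lab, spec0, seed = 3)
  for (tis in c("nawm", "wmh", "dgm", "rsl")) {
    code <- dcetk:::PHANTOM_LABELS[[tis]]
    expect_equal(unique(tru0$ktrans[lab == code]), spec$ktrans[[tis]])
    expect_equal(unique(tru0$vp[lab == code]), spec$vp[[tis]])
  }
  expect_true(all(is.finite(tru0$ktrans[lab > 0])))
  # stroke-lesion permeability exceeds normal-appearing white matter in
  # every seeded realization
  for (seed in 1:100) {
    lab_s <- make_tissue_map(spec$shape, seed)
    tru <- sample_parameters(lab_s, spec, seed = seed)
    expect_gt(median(tru$ktrans[lab_s == 4]), median(tru$ktrans[lab_s == 1]))
  }
})

test_that("the population input function is a causal biexponential bolus", {
  p <- default_params
  tm <- c(-73, frame_times(p))
  spec <- phantom_spec()
  cp <- population_aif(tm, spec, subject_seed = NULL)
  expect_true(all(cp$values[tm <= 0] == 0))
  # peak on the 73 s grid falls on the first post-injection frame
  post <- which(tm > 0)
  expect_equal(which.max(cp$values[post]), 1L)
  # zero jitter: identical curves across subjects
  spec0 <- phantom_spec(aif_jitter = 0)
  c1 <- population_aif(tm, spec0, subject_seed = 1)
  c2 <- population_aif(tm, spec0, subject_seed = 2)
  expect_identical(c1$values, c2$values)
  # jittered curves differ across subjects but share the time-to-peak
  j1 <- population_aif(tm, spec, subject_seed = 101)
  j2 <- population_aif(tm, spec, subject_seed = 102)
  expect_false(identical(j1$values, j2$values))
  expect_equal(which.max(j1$values), which.max(j2$values))
})

test_that("a phantom dataset is a pure function of its spec", {
  spec <- phantom_spec(shape = c(32, 32, 1), sigma = 0.02, seed = 11)
  a <- simulate_dataset(spec, 1)
  b <- simulate_dataset(spec, 1)
  expect_identical(a$signal_noisy$values, b$signal_noisy$values)
  expect_identical(a$truth$ktrans, b$truth$ktrans)
  c2 <- simulate_dataset(spec, 2)
  expect_false(identical(a$signal_noisy$values, c2$signal_noisy$values))
})

test_that("the noiseless phantom closes the full forward-inverse loop", {
  ds <- tiny_phantom(sigma = 0)
  # stored signal inverts to stored concentration
  inv <- signal_to_concentration(ds$signal, ds$sb, ds$relax, ds$spec$params)
  b4 <- array(ds$brain, dim(ds$conc$values))
  expect_lt(max(abs(inv$conc$values - ds$conc$values)[b4]), 1e-10)
  # VFA mapping on the stored flip-angle pair recovers the true T10
  est <- compute_t10(ds$sa, ds$sb, ds$spec$params)
  expect_lt(max(abs(est$t10 - ds$relax$t10)[ds$brain], na.rm = TRUE), 1e-8)
  # voxelwise fitting of derived concentrations recovers the truth
  fit <- fit_volume(inv$conc, ds$cp, "patlak", mask = ds$brain)
  expect_lt(max(abs(fit$maps$ktrans - ds$truth$ktrans)[ds$brain]), 1e-10)
  expect_lt(max(abs(fit$maps$vp - ds$truth$vp)[ds$brain]), 1e-10)
})

test_that("an eTofts phantom closes the loop through the nonlinear fit", {
  ds <- tiny_phantom(sigma = 0, shape = c(32, 32, 1), model = "etofts")
  idx <- which(ds$brain & ds$labels == 4)[1:3]   # stroke-lesion voxels
  for (v in idx) {
    xyz <- arrayInd(v, dim(ds$brain))
    ct <- ds$conc$values[xyz[1], xyz[2], xyz[3], ]
    f <- fit_etofts(ct, ds$cp)
    th <- c(ds$truth$ktrans[v], ds$truth$kep[v], ds$truth$vp[v])
    expect_lt(max(abs(f$theta - th) / th), 0.01)
  }
})

test_that("simulated noise has the configured amplitude and scaling", {
  spec <- phantom_spec(shape = c(64, 64, 1), sigma = 0.02, seed = 2)
  ds <- simulate_dataset(spec, 1)
  noise <- ds$signal_noisy$values - ds$signal$values
  expect_equal(sd(noise), ds$sigma_abs, tolerance = 0.02)
  expect_equal(ds$sigma_abs, 0.02 * mean(ds$sb[ds$brain]), tolerance = 1e-12)
  expect_lt(abs(mean(noise)), 3 * ds$sigma_abs / sqrt(length(noise)))
})

test_that("Patlak estimator variance grows as sigma squared", {
  sigmas <- c(0.005, 0.01, 0.02, 0.04)
  vars <- vapply(sigmas, function(s) {
    ds <- simulate_dataset(phantom_spec(shape = c(32, 32, 1), sigma = s,
                                        seed = 31), 1)
    conc <- signal_to_concentration(ds$signal_noisy, ds$sb, ds$relax,
                                    ds$spec$params)$conc
    fit <- fit_volume(conc, ds$cp, "patlak", mask = ds$labels == 1)
    err <- (fit$maps$ktrans - ds$truth$ktrans)[ds$labels == 1]
    var(err, na.rm = TRUE)
  }, 0)
  slope <- coef(lm(log(vars) ~ log(sigmas)))[2]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})
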