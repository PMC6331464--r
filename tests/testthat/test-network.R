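# The dual-pathway dilated-convolution engine

test_that("the network maps 24x24xT patches to 24x24xn parameter patches", {
  for (np in 2:3) {
    spec <- network_spec(n_frames = 21, n_params = np)
    net <- init_network(spec, seed = 1)
    geoms <- dcetk:::net_geoms(spec, 2L)
    X <- matrix(det_noise(576 * 2, 21), 576 * 2, 21)
    out <- dcetk:::net_forward(net, X, geoms)$out
    expect_equal(dim(out), c(576 * 2, np))
    arr <- dcetk:::mat_to_patches(out, 24L, 2L)
    expect_equal(dim(arr), c(24, 24, np, 2))
  }
})

test_that("an all-zero network maps any input to zero", {
  spec <- tiny_net_spec()
  net <- init_network(spec, seed = 2)
  net0 <- net
  for (nm in names(net0)) net0[[nm]] <- net0[[nm]] * 0
  geoms <- dcetk:::net_geoms(spec, 1L)
  X <- matrix(det_noise(144, 5), 144, 5)
  expect_equal(max(abs(dcetk:::net_forward(net0, X, geoms)$out)), 0)
})

test_that("weight initialization is reproducible and seed-sensitive", {
  spec <- tiny_net_spec()
  expect_identical(init_network(spec, 9), init_network(spec, 9))
  expect_false(identical(init_network(spec, 9)$mix_w, init_network(spec, 10)$mix_w))
})

test_that("the double-precision layer oracle validates its own gradients", {
  # reference path: per-layer double kernels composed in the helper; its
  # analytic gradient must agree with central finite differences
  spec <- tiny_net_spec()
  net <- init_network(spec, 3)
  geoms <- dcetk:::net_geoms(spec, 2L)
  set.seed(1)
  X <- matrix(rnorm(144 * 2 * 5), 144 * 2, 5)
  Tgt <- matrix(rnorm(144 * 2 * 2), 144 * 2, 2)
  fw <- ref_net_forward(net, X, geoms)
  gr <- ref_net_backward(net, fw$cache, 2 * (fw$out - Tgt), geoms)
  lossf <- function(n) sum((ref_net_forward(n, X, geoms)$out - Tgt)^2)
  for (nm in c("dw_w", "mix_w", "loc1_w", "glo3_w", "cat_w", "fc2_w", "fc3_w")) {
    ii <- seq_len(min(4, length(net[[nm]])))
    num <- vapply(ii, function(i) {
      n2 <- net; n2[[nm]][i] <- n2[[nm]][i] + 1e-6
      n3 <- net; n3[[nm]][i] <- n3[[nm]][i] - 1e-6
      (lossf(n2) - lossf(n3)) / 2e-6
    }, 0)
    expect_lt(max(abs(num - gr[[nm]][ii]) / (abs(num) + 1e-6)), 1e-5)
  }
})

test_that("the fused single-precision engine agrees with the double oracle", {
  spec <- tiny_net_spec()
  net <- init_network(spec, 4)
  geoms <- dcetk:::net_geoms(spec, 3L)
  set.seed(2)
  X <- matrix(rnorm(144 * 3 * 5), 144 * 3, 5)
  ref <- ref_net_forward(net, X, geoms)
  got <- dcetk:::net_forward(net, X, geoms, keep_cache = TRUE)
  sc <- max(abs(ref$out))
  expect_lt(max(abs(got$out - ref$out)) / sc, 1e-5)
  dOut <- matrix(rnorm(length(ref$out)), nrow(ref$out), 2)
  gref <- ref_net_backward(net, ref$cache, dOut, geoms)
  gfus <- dcetk:::net_backward(net, got$cache, dOut, geoms)
  for (nm in names(gref)) {
    s <- max(abs(gref[[nm]]), 1e-6)
    expect_lt(max(abs(gfus[[nm]] - gref[[nm]])) / s, 1e-4)
  }
})

test_that("every layer preserves the 24x24 spatial extent", {
  # assertable end to end: output rows equal input rows for any batch size
  spec <- network_spec(n_frames = 4)
  net <- init_network(spec, 5)
  for (B in c(1L, 3L)) {
    geoms <- dcetk:::net_geoms(spec, B)
    X <- matrix(det_noise(576 * B, 4), 576 * B, 4)
    expect_equal(nrow(dcetk:::net_forward(net, X, geoms)$out), 576 * B)
  }
})

test_that("network serialization round-trips through portable JSON", {
  spec <- tiny_net_spec()
  model <- structure(list(net = init_network(spec, 6), spec = spec,
                          model = "patlak", config = training_config(),
                          history = data.frame(epoch = 1L, train = 1, val = 2),
                          best_epoch = 1L, target_scale = c(1e-3, 1e-2),
                          input_center = rep(1, 5), input_scale = rep(0.02, 5),
                          normalize_input = "baseline_mean"),
                     class = "dce_cnn")
  f <- tempfile(fileext = ".json")
  save_dce_cnn(model, f)
  back <- load_dce_cnn(f)
  expect_equal(back$net$mix_w, model$net$mix_w)
  expect_equal(back$target_scale, model$target_scale)
  expect_equal(back$input_center, model$input_center)
  expect_equal(back$input_scale, model$input_scale)
  geoms <- dcetk:::net_geoms(spec, 1L)
  X <- matrix(det_noise(144, 5), 144, 5)
  expect_equal(dcetk:::net_forward(back$net, X, geoms)$out,
               dcetk:::net_forward(model$net, X, geoms)$out)
})
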