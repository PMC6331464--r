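# Shared fixtures: everything is generated in code, nothing read from disk.

default_params <- acq_params()

# deterministic pseudo-random matrix (identical across platforms, no RNG)
det_noise <- function(n, m, f1 = 12.9898, f2 = 78.233, amp = 43758.5453) {
  i <- matrix(seq_len(n), n, m)
  j <- matrix(seq_len(m), n, m, byrow = TRUE)
  abs((sin(i * f1 + j * f2) * amp) %% 1)
}

# small plasma curve on the standard 21-frame grid
test_cp <- function(params = default_params) {
  population_aif(frame_times(params), phantom_spec(), subject_seed = NULL)
}

# tiny noiseless Patlak phantom used by several oracle tests
tiny_phantom <- function(sigma = 0, shape = c(48, 48, 2), model = "patlak",
                         seed = 7L) {
  simulate_dataset(phantom_spec(shape = shape, n_subjects = 1, model = model,
                                sigma = sigma, seed = seed), 1)
}

# -- double-precision reference network ------------------------------------
# Composes the per-layer double-precision kernels into the same
# architecture as the fused single-precision engine; serves as the
# independent numerical oracle for the engine tests.

ref_relu <- function(x) x * (x > 0)

ref_net_forward <- function(net, X, geoms) {
  spec <- attr(net, "spec")
  g1 <- geoms[["1"]]
  addb <- function(m, b) m + rep(b, each = nrow(m))
  a <- dcetk:::dwconv_fwd(X, net$dw_w, net$dw_b, g1)
  cache <- list(X = X, dw_out = a)
  cache$h0p <- addb(a %*% net$mix_w, net$mix_b)
  h0 <- ref_relu(cache$h0p)
  l <- h0
  for (i in 1:3) {
    cache[[paste0("loc", i, "_in")]] <- l
    lp <- dcetk:::conv_fwd(l, net[[paste0("loc", i, "_w")]],
                           net[[paste0("loc", i, "_b")]], g1)
    cache[[paste0("loc", i, "_p")]] <- lp
    l <- ref_relu(lp)
  }
  g <- h0
  for (i in 1:3) {
    gd <- geoms[[as.character(spec$dilations[i])]]
    cache[[paste0("glo", i, "_in")]] <- g
    gp <- dcetk:::conv_fwd(g, net[[paste0("glo", i, "_w")]],
                           net[[paste0("glo", i, "_b")]], gd)
    cache[[paste0("glo", i, "_p")]] <- gp
    g <- ref_relu(gp)
  }
  cache$cat_in <- cbind(l, g)
  cache$cat_p <- dcetk:::conv_fwd(cache$cat_in, net$cat_w, net$cat_b, g1)
  h <- ref_relu(cache$cat_p)
  cache$fc1_in <- h
  for (i in 1:3) {
    hp <- addb(h %*% net[[paste0("fc", i, "_w")]], net[[paste0("fc", i, "_b")]])
    if (i < 3) {
      cache[[paste0("fc", i, "_p")]] <- hp
      h <- ref_relu(hp)
      cache[[paste0("fc", i + 1, "_in")]] <- h
    } else h <- hp
  }
  list(out = h, cache = cache)
}

ref_net_backward <- function(net, cache, dOut, geoms) {
  spec <- attr(net, "spec")
  g1 <- geoms[["1"]]
  gr <- list()
  dh <- dOut
  for (i in 3:1) {
    gr[[paste0("fc", i, "_w")]] <- crossprod(cache[[paste0("fc", i, "_in")]], dh)
    gr[[paste0("fc", i, "_b")]] <- colSums(dh)
    dh <- dh %*% t(net[[paste0("fc", i, "_w")]])
    if (i > 1) dh <- dh * (cache[[paste0("fc", i - 1, "_p")]] > 0)
  }
  dh <- dh * (cache$cat_p > 0)
  bw <- dcetk:::conv_bwd(cache$cat_in, dh, net$cat_w, g1)
  gr$cat_w <- bw$dW; gr$cat_b <- bw$db
  f <- spec$filters
  dl <- bw$dA[, seq_len(f), drop = FALSE]
  dg <- bw$dA[, f + seq_len(f), drop = FALSE]
  for (i in 3:1) {
    dl <- dl * (cache[[paste0("loc", i, "_p")]] > 0)
    bw <- dcetk:::conv_bwd(cache[[paste0("loc", i, "_in")]], dl,
                           net[[paste0("loc", i, "_w")]], g1)
    gr[[paste0("loc", i, "_w")]] <- bw$dW
    gr[[paste0("loc", i, "_b")]] <- bw$db
    dl <- bw$dA
  }
  for (i in 3:1) {
    gd <- geoms[[as.character(spec$dilations[i])]]
    dg <- dg * (cache[[paste0("glo", i, "_p")]] > 0)
    bw <- dcetk:::conv_bwd(cache[[paste0("glo", i, "_in")]], dg,
                           net[[paste0("glo", i, "_w")]], gd)
    gr[[paste0("glo", i, "_w")]] <- bw$dW
    gr[[paste0("glo", i, "_b")]] <- bw$db
    dg <- bw$dA
  }
  dh0 <- (dl + dg) * (cache$h0p > 0)
  gr$mix_w <- crossprod(cache$dw_out, dh0)
  gr$mix_b <- colSums(dh0)
  da <- dh0 %*% t(net$mix_w)
  bw <- dcetk:::dwconv_bwd(cache$X, da, net$dw_w, g1)
  gr$dw_w <- bw$dw; gr$dw_b <- bw$db
  gr
}

# tiny network spec used by the engine tests
tiny_net_spec <- function() {
  network_spec(n_frames = 5, n_params = 2, filters = 8, cat_filters = 16,
               hidden = c(16, 8), patch = 12)
}
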