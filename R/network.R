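#' @name network
#' @title Dual-pathway dilated convolutional network
#'
#' @description A patch-to-patch regression network mapping a 24 x 24 x T
#' signal patch (frames as channels) to per-voxel kinetic parameters
#' (24 x 24 x n).  The first layer filters each input frame independently
#' with a 4 x 4 kernel, then aggregates the frames through a learned 1 x 1
#' combination into 32 feature maps.  Two parallel pathways follow: a local
#' pathway of three standard 4 x 4 convolutions and a global pathway of
#' three dilated 4 x 4 convolutions (dilation 2, 4, 8) for multi-scale
#' context.  The pathways are concatenated into a 64-filter 4 x 4
#' convolution, then three 1 x 1 layers (256, 128, n hidden nodes) act as
#' per-voxel fully-connected layers.  All layers preserve the 24 x 24
#' spatial extent via zero padding; a rectifier follows every layer except
#' the output.
#'
#' Activations are stored as `(H*W*batch) x channels` matrices; every
#' convolution is an im2col expansion followed by one BLAS GEMM.  The fused
#' forward/backward engine (src/network.cpp) runs in single precision, the
#' customary arithmetic for training convolutional networks; weights, the
#' optimizer state and the loss are kept in double precision in R.
NULL

#' Network architecture specification
#'
#' @param n_frames input channels (dynamic frames), default 21.
#' @param n_params output channels (2 Patlak, 3 eTofts).
#' @param filters feature maps per convolutional layer.
#' @param cat_filters feature maps of the post-concatenation convolution.
#' @param kernel convolution kernel edge (kernel x kernel).
#' @param dilations dilation factors of the global pathway.
#' @param local_depth number of standard convolutions in the local pathway.
#' @param hidden widths of the per-voxel fully-connected layers.
#' @param patch spatial patch edge.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_frames = 21L, n_params = 2L, filters = 32L,
                         cat_filters = 64L, kernel = 4L,
                         dilations = c(2L, 4L, 8L), local_depth = 3L,
                         hidden = c(256L, 128L), patch = 24L) {
  structure(list(n_frames = as.integer(n_frames),
                 n_params = as.integer(n_params),
                 filters = as.integer(filters),
                 cat_filters = as.integer(cat_filters),
                 kernel = as.integer(kernel),
                 dilations = as.integer(dilations),
                 local_depth = as.integer(local_depth),
                 hidden = as.integer(hidden), patch = as.integer(patch)),
            class = "network_spec")
}

validate_network_spec <- function(spec) {
  # the fused engine is compiled for the published topology: two pathways
  # of depth 3 and three per-voxel fully-connected layers
  stopifnot(spec$local_depth == 3L, length(spec$dilations) == 3L,
            length(spec$hidden) == 2L, spec$kernel >= 1L,
            spec$patch >= spec$kernel)
  invisible(spec)
}

# Geometry of a zero-padded dilated convolution on an H x W grid for batch
# size B: a source-row map D (H*W*B x k^2) giving, for each output pixel
# and kernel offset, the 1-based row of the activation matrix it reads
# (0 where the offset falls in the zero padding).  "Same" padding for the
# even kernel splits the (k-1)*d pad asymmetrically (floor on the leading
# edge), so every layer preserves the H x W extent.
conv_geom <- function(H, W, k, d, B) {
  pl <- ((k - 1L) * d) %/% 2L
  i <- rep(seq_len(H), W); j <- rep(seq_len(W), each = H)
  D <- matrix(0L, H * W * B, k * k)
  off <- rep((seq_len(B) - 1L) * H * W, each = H * W)
  o <- 0L
  for (b in 0:(k - 1L)) for (a in 0:(k - 1L)) {
    o <- o + 1L
    si <- i + a * d - pl
    sj <- j + b * d - pl
    inside <- si >= 1L & si <= H & sj >= 1L & sj <= W
    src <- ifelse(inside, si + (sj - 1L) * H, 0L)
    D[, o] <- rep(src, B) + ifelse(rep(src, B) > 0L, off, 0L)
  }
  D
}

conv_fwd <- function(A, Wm, b, geom) conv_fwd_cpp(A, Wm, b, geom)

conv_bwd <- function(A, dY, Wm, geom) conv_bwd_cpp(A, dY, Wm, geom)

# Depthwise convolution: one k x k filter per input channel (w is k2 x C).
dwconv_fwd <- function(A, w, b, geom) dwconv_fwd_cpp(A, w, b, geom)

dwconv_bwd <- function(A, dY, w, geom) dwconv_bwd_cpp(A, dY, w, geom)

relu <- function(x) x * (x > 0)

#' Initialize an untrained network
#'
#' He-style initialization: weights drawn N(0, 2/fan_in), biases zero.
#' Fully reproducible given the seed.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed.
#' @return A named list of weight matrices/vectors (class `dce_net`).
#' @export
init_network <- function(spec, seed = 1L) {
  validate_network_spec(spec)
  rng <- local_rng(seed)
  he <- function(nr, nc) matrix(rng$rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  k2 <- spec$kernel^2
  f <- spec$filters
  net <- list(
    dw_w = matrix(rng$rnorm(k2 * spec$n_frames, 0, sqrt(2 / k2)), k2, spec$n_frames),
    dw_b = numeric(spec$n_frames),
    mix_w = he(spec$n_frames, f), mix_b = numeric(f))
  for (l in seq_len(spec$local_depth)) {
    net[[paste0("loc", l, "_w")]] <- he(k2 * f, f)
    net[[paste0("loc", l, "_b")]] <- numeric(f)
  }
  for (l in seq_along(spec$dilations)) {
    net[[paste0("glo", l, "_w")]] <- he(k2 * f, f)
    net[[paste0("glo", l, "_b")]] <- numeric(f)
  }
  net$cat_w <- he(k2 * 2L * f, spec$cat_filters)
  net$cat_b <- numeric(spec$cat_filters)
  widths <- c(spec$cat_filters, spec$hidden, spec$n_params)
  for (l in seq_len(length(widths) - 1L)) {
    net[[paste0("fc", l, "_w")]] <- he(widths[l], widths[l + 1L])
    net[[paste0("fc", l, "_b")]] <- numeric(widths[l + 1L])
  }
  structure(net, spec = spec, class = "dce_net")
}

# Geometries for all dilations used by the network, for batch size B
net_geoms <- function(spec, B) {
  ds <- sort(unique(c(1L, spec$dilations)))
  g <- lapply(ds, function(d) conv_geom(spec$patch, spec$patch, spec$kernel, d, B))
  names(g) <- as.character(ds)
  g
}

# Forward pass through the fused single-precision engine.  X is
# (H*W*B) x n_frames, spatial-major within each patch.  Returns the output
# (double at the interface) and, optionally, the opaque activation cache
# consumed by net_backward.
net_forward <- function(net, X, geoms, keep_cache = FALSE) {
  spec <- attr(net, "spec")
  net_forward_cpp(unclass(net), X,
                  geoms[["1"]], geoms[[as.character(spec$dilations[1])]],
                  geoms[[as.character(spec$dilations[2])]],
                  geoms[[as.character(spec$dilations[3])]], keep_cache)
}

# Backward pass: gradient of a scalar loss with respect to every weight,
# given dOut = dLoss/dOut from the loss layer.
net_backward <- function(net, cache, dOut, geoms) {
  spec <- attr(net, "spec")
  net_backward_cpp(unclass(net), cache, dOut,
                   geoms[["1"]], geoms[[as.character(spec$dilations[1])]],
                   geoms[[as.character(spec$dilations[2])]],
                   geoms[[as.character(spec$dilations[3])]])
}

# One Adam step over the flat weight list; state carries first/second
# moments and the update counter.  Learning rate decays as
# lr_t = lr0 / (1 + decay * t).
adam_step <- function(net, grads, state, lr0, decay, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr <- lr0 / (1 + decay * state$t)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, state = state)
}

adam_init <- function(net) {
  nm <- names(net)
  list(t = 0L,
       m = lapply(net, function(x) x * 0),
       v = lapply(net, function(x) x * 0))
}

# Reshape a (patch, patch, C, B) array into the (H*W*B) x C activation
# layout and back.
patches_to_mat <- function(arr) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  m
}

mat_to_patches <- function(m, patch, B) {
  array(aperm(array(m, c(patch, patch, B, ncol(m))), c(1, 2, 4, 3)),
        c(patch, patch, ncol(m), B))
}
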