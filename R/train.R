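#' Training configuration
#'
#' Defaults follow a standard adaptive-moments protocol for this network
#' family: Adam with learning rate 1e-3 decayed per update as
#' lr_t = lr0 / (1 + 1e-4 t), up to 200 epochs of mini-batches of 1000
#' patches, an 80/20 train/validation split, and early stopping when the
#' validation loss has not improved for 15 consecutive epochs (the weights
#' of the best validation epoch are restored).  For desk-scale phantom
#' studies reduce `max_epochs` and `batch_size`.
#'
#' @param lr initial learning rate.
#' @param decay per-update learning-rate decay.
#' @param max_epochs epoch cap.
#' @param batch_size patches per mini-batch.
#' @param val_fraction fraction of patches held out for validation.
#' @param patience early-stopping patience, epochs.
#' @param lambda weight of the model-consistency loss term.
#' @param standardize_targets standardize parameter channels (by their
#'   training-set standard deviation) inside the parameter loss term.
#' @param normalize_input `"baseline_mean"` scales each subject's signal by
#'   its mean in-brain baseline intensity; `"none"` feeds raw intensities.
#' @param seed master seed for split, shuffling and weight initialization.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr = 1e-3, decay = 1e-4, max_epochs = 200L,
                            batch_size = 1000L, val_fraction = 0.2,
                            patience = 15L, lambda = 1,
                            standardize_targets = TRUE,
                            normalize_input = c("baseline_mean", "none"),
                            seed = 1L) {
  normalize_input <- match.arg(normalize_input)
  stopifnot(val_fraction > 0, val_fraction < 1, patience < max_epochs,
            lr > 0, decay >= 0, batch_size >= 1)
  structure(list(lr = lr, decay = decay, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 lambda = lambda, standardize_targets = standardize_targets,
                 normalize_input = normalize_input, seed = as.integer(seed)),
            class = "training_config")
}

# Mean in-brain baseline intensity of a signal stack (frame 1); voxels with
# zero baseline (background) are excluded.
baseline_scale <- function(signal4d) {
  b <- signal4d[, , , 1, drop = FALSE]
  b <- b[b > 0]
  if (!length(b)) 1 else mean(b)
}

#' Train the direct-inference network
#'
#' Minimizes the joint parameter + model-consistency loss ([joint_loss()])
#' over a patch set by mini-batch gradient descent with adaptive moments.
#' The consistency term uses each training subject's own plasma curve; at
#' prediction time no input function is needed.  Training is fully
#' reproducible given `config$seed`; a non-finite loss aborts with a
#' diagnostic.
#'
#' @param patches a `patch_set` (see [extract_patches()],
#'   [combine_patch_sets()]).
#' @param cp_by_subject named list of plasma `input_function`s, one per
#'   subject id appearing in `patches$subject`.
#' @param model `"patlak"` or `"etofts"`.
#' @param config a [training_config()].
#' @param spec a [network_spec()]; defaults to the standard architecture
#'   sized from the patch set.
#' @param input_scales optional named per-subject input normalization
#'   scales (as computed by the package from each subject's baseline frame);
#'   required when `config$normalize_input = "baseline_mean"`.
#' @param verbose print per-epoch losses.
#' @return An object of class `dce_cnn`: trained weights, `spec`, `model`,
#'   `config`, per-epoch `history` (train/validation loss), `best_epoch`,
#'   `target_scale`.
#' @export
train_dce_cnn <- function(patches, cp_by_subject, model = c("patlak", "etofts"),
                          config = training_config(), spec = NULL,
                          input_scales = NULL, verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(patches, "patch_set"))
  n_par <- dim(patches$targets)[3]
  if (n_par != (if (model == "patlak") 2L else 3L))
    stop("patch targets have ", n_par, " channels; wrong for ", model)
  nt <- dim(patches$inputs)[3]
  if (is.null(spec))
    spec <- network_spec(n_frames = nt, n_params = n_par,
                         patch = dim(patches$inputs)[1])
  np <- dim(patches$inputs)[4]
  pt <- spec$patch
  hw <- pt * pt

  subjects <- sort(unique(patches$subject))
  if (!all(as.character(subjects) %in% names(cp_by_subject)))
    stop("cp_by_subject must name every subject in the patch set")
  des <- lapply(cp_by_subject, consistency_design)

  # flatten the whole patch set once: (hw * np) x channels, patch-major
  Xall <- patches_to_mat(patches$inputs)
  Tall <- patches_to_mat(patches$targets)
  Call <- patches_to_mat(patches$conc)
  post <- des[[as.character(subjects[1])]]$post
  Call <- Call[, post, drop = FALSE]

  if (config$normalize_input == "baseline_mean") {
    if (is.null(input_scales))
      stop("input_scales required for baseline_mean normalization")
    for (s in subjects) {
      rows <- which(rep(patches$subject, each = hw) == s)
      Xall[rows, ] <- Xall[rows, ] / input_scales[[as.character(s)]]
    }
  }

  tscale <- if (config$standardize_targets) {
    sc <- apply(Tall, 2, stats::sd)
    ifelse(sc > 0, sc, 1)
  } else rep(1, n_par)

  # per-channel z-scoring of the input frames (training-set statistics,
  # stored with the model and re-applied at prediction): He-initialized
  # rectifier stacks expect zero-centered unit-scale inputs, while
  # baseline-scaled signals sit near 1.0 with few-percent fluctuations
  in_center <- colMeans(Xall)
  in_scale <- apply(Xall, 2, stats::sd)
  in_scale[in_scale == 0] <- 1
  Xall <- sweep(sweep(Xall, 2, in_center), 2, in_scale, "/")

  set.seed(config$seed)
  net <- init_network(spec, seed = config$seed + 1L)
  state <- adam_init(net)

  idx <- sample(np)
  n_val <- max(1L, round(config$val_fraction * np))
  val_id <- idx[seq_len(n_val)]
  train_id <- idx[-seq_len(n_val)]
  if (!length(train_id)) stop("no training patches left after the split")

  geom_cache <- new.env()
  get_geoms <- function(B) {
    key <- as.character(B)
    if (is.null(geom_cache[[key]])) geom_cache[[key]] <- net_geoms(spec, B)
    geom_cache[[key]]
  }

  batch_rows <- function(pids) {
    as.vector(outer(seq_len(hw), (pids - 1L) * hw, "+"))
  }

  # loss + gradient wrt the network output for a batch of patch ids.
  # The network regresses standardized parameter channels; predictions are
  # de-standardized (times the per-channel scale) before entering the loss,
  # an exact reparameterization that keeps the output layer O(1).
  batch_pass <- function(pids, want_grad = TRUE) {
    rows <- batch_rows(pids)
    B <- length(pids)
    geoms <- get_geoms(B)
    fw <- net_forward(net, Xall[rows, , drop = FALSE], geoms,
                      keep_cache = want_grad)
    th <- sweep(fw$out, 2, tscale, "*")
    tt <- Tall[rows, , drop = FALSE]
    cc <- Call[rows, , drop = FALSE]
    subj <- rep(patches$subject[pids], each = hw)
    loss <- 0; dOut <- if (want_grad) th * 0 else NULL
    for (s in unique(subj)) {
      sel <- which(subj == s)
      cps <- cp_by_subject[[as.character(s)]]
      l <- joint_loss(tt[sel, , drop = FALSE], th[sel, , drop = FALSE],
                      cc[sel, , drop = FALSE], cps, model = model,
                      lambda = config$lambda, scale = tscale)
      loss <- loss + as.numeric(l) * length(sel)
      if (want_grad)
        dOut[sel, ] <- joint_loss_grad(tt[sel, , drop = FALSE],
                                       th[sel, , drop = FALSE],
                                       cc[sel, , drop = FALSE], cps,
                                       model = model, lambda = config$lambda,
                                       scale = tscale) *
          (length(sel) / nrow(th))
    }
    if (want_grad) dOut <- sweep(dOut, 2, tscale, "*")  # chain rule
    loss <- loss / nrow(th)
    if (!is.finite(loss))
      stop("training diverged: non-finite loss at update ", state$t)
    if (want_grad) {
      gr <- net_backward(net, fw$cache, dOut, geoms)
      list(loss = loss, grads = gr)
    } else list(loss = loss)
  }

  eval_loss <- function(pids) {
    bs <- split(pids, ceiling(seq_along(pids) / config$batch_size))
    tot <- 0
    for (b in bs) tot <- tot + batch_pass(b, want_grad = FALSE)$loss * length(b)
    tot / length(pids)
  }

  history <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  best_val <- Inf; best_net <- net; best_epoch <- 0L; wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_id)
    bs <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (b in bs) {
      pass <- batch_pass(b, want_grad = TRUE)
      up <- adam_step(net, pass$grads, state, config$lr, config$decay)
      net <- up$net; state <- up$state
      tr_loss <- tr_loss + pass$loss * length(b)
    }
    tr_loss <- tr_loss / length(train_id)
    val_loss <- eval_loss(val_id)
    history <- rbind(history, data.frame(epoch = epoch, train = tr_loss,
                                         val = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.6g  val %.6g", epoch, tr_loss, val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss; best_net <- net; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(net = best_net, spec = spec, model = model, config = config,
                 history = history, best_epoch = best_epoch,
                 target_scale = tscale,
                 input_center = in_center, input_scale = in_scale,
                 normalize_input = config$normalize_input),
            class = "dce_cnn")
}

#' @export
print.dce_cnn <- function(x, ...) {
  cat(sprintf("Direct-inference CNN (%s targets)\n", x$model))
  cat(sprintf("  %d epochs trained, best validation at epoch %d (loss %.4g)\n",
              nrow(x$history), x$best_epoch,
              x$history$val[x$best_epoch]))
  npar <- sum(vapply(x$net, length, 0))
  cat(sprintf("  %d trainable weights; input %d frames, output %d parameters\n",
              npar, x$spec$n_frames, x$spec$n_params))
  invisible(x)
}

#' @export
summary.dce_cnn <- function(object, ...) {
  print(object)
  cat("Loss history (first/best/last epochs):\n")
  h <- object$history
  print(h[unique(c(1, object$best_epoch, nrow(h))), ])
  invisible(object$history)
}

#' Plot training and validation loss curves
#' @param x a `dce_cnn`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dce_cnn <- function(x, ...) {
  graphics::matplot(x$history$epoch, cbind(x$history$train, x$history$val),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Predict parameter maps for a whole volume
#'
#' Direct inference from the signal-time series alone: the volume is tiled
#' with stride-6 patches, each patch is pushed through the network, and
#' overlapping per-voxel predictions are averaged over the number of
#' patches containing each voxel (16 in the interior).  No input function
#' is consumed.
#'
#' @param object a trained `dce_cnn`.
#' @param signal a `dynamic_series` of signal (or a 4D array).
#' @param mask optional 3D mask; voxels outside are set `NA`.
#' @param ... unused.
#' @return A list of 3D parameter maps (`ktrans`, `vp`, plus `kep` for
#'   eTofts) with class `pk_maps`.
#' @export
predict.dce_cnn <- function(object, signal, mask = NULL, ...) {
  vol <- if (inherits(signal, "dynamic_series")) signal$values else signal
  if (dim(vol)[4] != object$spec$n_frames)
    stop("volume has ", dim(vol)[4], " frames but the network expects ",
         object$spec$n_frames)
  scale <- if (object$normalize_input == "baseline_mean") baseline_scale(vol) else 1
  spec <- object$spec
  geom_cache <- new.env()
  fun <- function(batch) {
    B <- dim(batch)[4]
    key <- as.character(B)
    if (is.null(geom_cache[[key]])) geom_cache[[key]] <- net_geoms(spec, B)
    X <- patches_to_mat(batch) / scale
    X <- sweep(sweep(X, 2, object$input_center), 2, object$input_scale, "/")
    out <- net_forward(object$net, X, geom_cache[[key]])$out
    out <- sweep(out, 2, object$target_scale, "*")  # de-standardize channels
    mat_to_patches(out, spec$patch, B)
  }
  pred <- predict_patchwise(vol, fun, spec$n_params, spec$patch, 6L)
  nms <- if (object$model == "patlak") c("ktrans", "vp") else c("ktrans", "kep", "vp")
  maps <- lapply(seq_along(nms), function(i) {
    m <- array(pred[, , , i], dim(vol)[1:3])
    if (!is.null(mask)) m[!mask] <- NA_real_
    m
  })
  names(maps) <- nms
  structure(maps, model = object$model, class = "pk_maps")
}

#' @export
print.pk_maps <- function(x, ...) {
  cat(sprintf("PK maps (%s): %s\n", attr(x, "model"),
              paste(names(x), collapse = ", ")))
  for (nm in names(x))
    cat(sprintf("  %s: median %.4g [%.4g, %.4g]\n", nm,
                stats::median(x[[nm]], na.rm = TRUE),
                stats::quantile(x[[nm]], 0.05, na.rm = TRUE),
                stats::quantile(x[[nm]], 0.95, na.rm = TRUE)))
  invisible(x)
}

#' Serialize / restore a trained network as portable JSON
#'
#' Weights, architecture and training metadata are written as plain JSON so
#' that models survive text-only transport.
#'
#' @param model a `dce_cnn`.
#' @param path output file.
#' @return `save_dce_cnn` returns the path; `load_dce_cnn` the model.
#' @export
save_dce_cnn <- function(model, path) {
  obj <- list(model = model$model,
              spec = unclass(model$spec),
              config = unclass(model$config),
              best_epoch = model$best_epoch,
              target_scale = model$target_scale,
              input_center = model$input_center,
              input_scale = model$input_scale,
              normalize_input = model$normalize_input,
              history = model$history,
              net = lapply(model$net, function(w) {
                if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
                else list(dim = length(w), data = as.numeric(w))
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dce_cnn
#' @export
load_dce_cnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, as.list(obj$spec))
  net <- lapply(obj$net, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2]) else w$data
  })
  attr(net, "spec") <- spec
  class(net) <- "dce_net"
  cfg <- do.call(training_config, as.list(obj$config))
  structure(list(net = net, spec = spec, model = obj$model, config = cfg,
                 history = as.data.frame(obj$history),
                 best_epoch = obj$best_epoch,
                 target_scale = as.numeric(obj$target_scale),
                 input_center = as.numeric(obj$input_center),
                 input_scale = as.numeric(obj$input_scale),
                 normalize_input = obj$normalize_input),
            class = "dce_cnn")
}
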