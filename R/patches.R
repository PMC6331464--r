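#' @name patches
#' @title Patch extraction and overlap-averaged reconstruction
#'
#' @description The direct-inference network operates on in-plane patches of
#' 24 x 24 voxels with the dynamic frames stacked as channels.  Training
#' patches are taken on a stride-6 lattice of origins fully inside each
#' slice; at prediction time every slice is tiled the same way (plus
#' edge-anchored origins when the slice extent is not lattice-aligned) and
#' the per-voxel predictions of all patches containing a voxel are
#' averaged — 16 predictions for interior voxels, fewer near the borders.
NULL

# Stride lattice of patch origins along one axis of extent `n`
patch_origins <- function(n, patch = 24L, stride = 6L, cover_edge = FALSE) {
  if (n < patch) stop("slice extent (", n, ") smaller than patch size (", patch, ")")
  o <- seq(1L, n - patch + 1L, by = stride)
  if (cover_edge && o[length(o)] != n - patch + 1L) o <- c(o, n - patch + 1L)
  o
}

#' Extract training patches from aligned stacks
#'
#' Divides every slice of the aligned signal / target / concentration
#' stacks into overlapping `patch` x `patch` tiles with origins on a
#' stride-`stride` lattice fully inside the slice.  The per-slice patch
#' count is `(floor((W - patch)/stride) + 1) * (floor((H - patch)/stride) + 1)`.
#' `NA` values in targets or concentration (voxels outside the brain) are
#' replaced by zero, matching the zero background signal.
#'
#' @param signal 4D array (x, y, z, t) of signal intensities.
#' @param targets 4D array (x, y, z, p) of parameter maps (p = 2 for
#'   Patlak, 3 for eTofts), or a list of 3D arrays.
#' @param conc 4D array (x, y, z, t) of observed concentrations.
#' @param subject_id identifier attached to every patch.
#' @param patch,stride patch edge and lattice stride, voxels.
#' @return An object of class `patch_set`: arrays `inputs`
#'   (patch, patch, T, N), `targets` (patch, patch, p, N), `conc`
#'   (patch, patch, T, N), integer `subject` (length N), `origin` (N x 3).
#' @export
extract_patches <- function(signal, targets, conc, subject_id = 1L,
                            patch = 24L, stride = 6L) {
  if (is.list(targets))
    targets <- array(unlist(targets), c(dim(targets[[1]]), length(targets)))
  d <- dim(signal)
  stopifnot(length(d) == 4L, identical(dim(conc), d),
            identical(dim(targets)[1:3], d[1:3]))
  ox <- patch_origins(d[1], patch, stride)
  oy <- patch_origins(d[2], patch, stride)
  np <- length(ox) * length(oy) * d[3]
  nt <- d[4]; npar <- dim(targets)[4]
  inputs <- array(0, c(patch, patch, nt, np))
  tars <- array(0, c(patch, patch, npar, np))
  concs <- array(0, c(patch, patch, nt, np))
  origin <- matrix(0L, np, 3)
  i <- 0L
  for (z in seq_len(d[3])) for (y0 in oy) for (x0 in ox) {
    i <- i + 1L
    xs <- x0:(x0 + patch - 1L); ys <- y0:(y0 + patch - 1L)
    inputs[, , , i] <- signal[xs, ys, z, ]
    tars[, , , i] <- targets[xs, ys, z, ]
    concs[, , , i] <- conc[xs, ys, z, ]
    origin[i, ] <- c(x0, y0, z)
  }
  tars[is.na(tars)] <- 0
  concs[is.na(concs)] <- 0
  inputs[is.na(inputs)] <- 0
  structure(list(inputs = inputs, targets = tars, conc = concs,
                 subject = rep(as.integer(subject_id), np), origin = origin,
                 patch = as.integer(patch), stride = as.integer(stride)),
            class = "patch_set")
}

#' Combine patch sets from several subjects
#' @param ... `patch_set` objects.
#' @return A single `patch_set`.
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "patch_set")) sets <- sets[[1]]
  bind4 <- function(field) {
    arrs <- lapply(sets, `[[`, field)
    d <- dim(arrs[[1]])
    array(do.call(c, arrs), c(d[1:3], sum(vapply(arrs, function(a) dim(a)[4], 0))))
  }
  structure(list(inputs = bind4("inputs"), targets = bind4("targets"),
                 conc = bind4("conc"),
                 subject = do.call(c, lapply(sets, `[[`, "subject")),
                 origin = do.call(rbind, lapply(sets, `[[`, "origin")),
                 patch = sets[[1]]$patch, stride = sets[[1]]$stride),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("Patch set: %d patches of %d x %d x %d from %d subject(s)\n",
              dim(x$inputs)[4], x$patch, x$patch, dim(x$inputs)[3],
              length(unique(x$subject))))
  invisible(x)
}

#' How many patches cover each voxel of a slice
#'
#' Direct enumeration of the patch-tiling coverage of a `w` x `h` slice.
#' With patch 24 and stride 6 every interior voxel (at least 24 voxels from
#' all borders on a lattice-aligned grid) is covered by exactly 16 patches.
#'
#' @param w,h slice extents.
#' @param patch,stride tiling parameters.
#' @param cover_edge also anchor patches at the far edge when the extent is
#'   not lattice-aligned (prediction-time behavior).
#' @return Integer matrix `w` x `h` of per-voxel patch counts.
#' @export
patch_coverage <- function(w, h, patch = 24L, stride = 6L, cover_edge = FALSE) {
  cnt <- matrix(0L, w, h)
  for (y0 in patch_origins(h, patch, stride, cover_edge))
    for (x0 in patch_origins(w, patch, stride, cover_edge)) {
      xs <- x0:(x0 + patch - 1L); ys <- y0:(y0 + patch - 1L)
      cnt[xs, ys] <- cnt[xs, ys] + 1L
    }
  cnt
}

#' Patchwise prediction with overlap averaging
#'
#' Applies a patch-level predictor to every stride-lattice tile of each
#' slice (with edge-anchored tiles so the whole slice is covered) and
#' averages the overlapping per-voxel predictions over the number of
#' patches actually containing each voxel.
#'
#' @param volume 4D array (x, y, z, t).
#' @param fun predictor mapping a batch array (patch, patch, t, B) to
#'   predictions (patch, patch, n_out, B).
#' @param n_out output channels per voxel.
#' @param patch,stride tiling parameters.
#' @return 4D array (x, y, z, n_out) of overlap-averaged predictions.
#' @export
predict_patchwise <- function(volume, fun, n_out, patch = 24L, stride = 6L) {
  d <- dim(volume)
  ox <- patch_origins(d[1], patch, stride, cover_edge = TRUE)
  oy <- patch_origins(d[2], patch, stride, cover_edge = TRUE)
  orig <- expand.grid(x = ox, y = oy)
  nb <- nrow(orig)
  out <- array(0, c(d[1], d[2], d[3], n_out))
  cnt <- patch_coverage(d[1], d[2], patch, stride, cover_edge = TRUE)
  for (z in seq_len(d[3])) {
    batch <- array(0, c(patch, patch, d[4], nb))
    for (i in seq_len(nb)) {
      xs <- orig$x[i]:(orig$x[i] + patch - 1L)
      ys <- orig$y[i]:(orig$y[i] + patch - 1L)
      batch[, , , i] <- volume[xs, ys, z, ]
    }
    pred <- fun(batch)
    acc <- array(0, c(d[1], d[2], n_out))
    for (i in seq_len(nb)) {
      xs <- orig$x[i]:(orig$x[i] + patch - 1L)
      ys <- orig$y[i]:(orig$y[i] + patch - 1L)
      acc[xs, ys, ] <- acc[xs, ys, ] + pred[, , , i]
    }
    out[, , z, ] <- acc / as.numeric(cnt)
  }
  out
}

#' Leave-one-subject-out folds
#'
#' @param subject_ids vector of unique subject identifiers (or a vector
#'   with repeats, which is deduplicated).
#' @return List of folds, each `list(train = ids, test = id)`; folds
#'   partition the subjects and no test subject appears in its training set.
#' @export
loso_folds <- function(subject_ids) {
  ids <- unique(subject_ids)
  if (length(ids) < 2) stop("leave-one-subject-out needs at least 2 subjects")
  lapply(ids, function(s) list(train = setdiff(ids, s), test = s))
}
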