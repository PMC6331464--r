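#' @name evaluation
#' @title Agreement metrics for parameter maps and fitted curves
#'
#' @description Map-level similarity (normalized RMSE and the structural
#' similarity index), per-voxel agreement (Bland-Altman limits of agreement
#' and Lin's concordance correlation coefficient), and tissue-wise paired
#' nonparametric comparison (Wilcoxon signed-rank on per-subject summary
#' values).  Normalization conventions are pinned and reported: nRMSE is
#' normalized by the range of the reference within the mask, and SSIM uses
#' an 11 x 11 Gaussian window (sigma 1.5) with the data range taken from
#' the reference within the mask.
NULL

#' Normalized root-mean-square error
#'
#' RMSE over masked voxels divided by the range (max - min) of the
#' reference within the mask; invariant to adding a common constant.
#'
#' @param est,ref numeric arrays of identical shape.
#' @param mask logical array (default: all finite voxels).
#' @return Non-negative scalar (0 for identical maps).
#' @export
nrmse <- function(est, ref, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(est) & is.finite(ref)
  e <- est[mask]; r <- ref[mask]
  rng <- max(r) - min(r)
  if (rng == 0) return(if (all(e == r)) 0 else Inf)
  sqrt(mean((e - r)^2)) / rng
}

# 2D separable Gaussian filtering with edge-value ("reflect") padding, the
# convention of standard SSIM reference implementations.
gauss_filter2d <- function(img, sigma = 1.5, radius = 5L) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_reflect <- function(m, r, along) {
    if (along == 1) rbind(m[r:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - r + 1), , drop = FALSE])
    else cbind(m[, r:1, drop = FALSE], m, m[, ncol(m):(ncol(m) - r + 1), drop = FALSE])
  }
  conv_axis <- function(m, along) {
    p <- pad_reflect(m, radius, along)
    out <- m * 0
    for (i in seq_along(k)) {
      if (along == 1) out <- out + k[i] * p[i:(i + nrow(m) - 1), , drop = FALSE]
      else out <- out + k[i] * p[, i:(i + ncol(m) - 1), drop = FALSE]
    }
    out
  }
  conv_axis(conv_axis(img, 1), 2)
}

#' Structural similarity index
#'
#' Standard SSIM with Gaussian weighting (11 x 11 window, sigma 1.5,
#' K1 = 0.01, K2 = 0.03).  The data range defaults to the range of the
#' reference within the mask; the window-radius border is cropped before
#' averaging, and the mean is taken over the masked voxels of the cropped
#' SSIM map.  Returns 1 iff the maps are identical within the mask.
#'
#' @param est,ref numeric matrices (2D maps) of identical shape.
#' @param mask logical matrix; default all voxels.
#' @param data_range dynamic range of the data; default `max - min` of the
#'   reference within the mask.
#' @param sigma Gaussian window sd, pixels.
#' @return Scalar in \[-1, 1\].
#' @export
ssim <- function(est, ref, mask = NULL, data_range = NULL, sigma = 1.5) {
  stopifnot(is.matrix(est), is.matrix(ref), identical(dim(est), dim(ref)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(est), ncol(est))
  if (is.null(data_range)) data_range <- diff(range(ref[mask]))
  if (data_range == 0) data_range <- 1   # constant reference: contrast term only
  radius <- 5L
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu_x <- gauss_filter2d(est, sigma, radius)
  mu_y <- gauss_filter2d(ref, sigma, radius)
  sxx <- gauss_filter2d(est * est, sigma, radius) - mu_x^2
  syy <- gauss_filter2d(ref * ref, sigma, radius) - mu_y^2
  sxy <- gauss_filter2d(est * ref, sigma, radius) - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  nr <- nrow(est); nc <- ncol(est)
  crop <- matrix(FALSE, nr, nc)
  crop[(radius + 1):(nr - radius), (radius + 1):(nc - radius)] <- TRUE
  mean(smap[crop & mask])
}

#' Bland-Altman agreement and Lin's concordance
#'
#' Mean difference, 95% limits of agreement (mean +/- 1.96 sd of the
#' differences), and Lin's concordance correlation coefficient
#' CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2).
#'
#' @param est,ref paired numeric vectors.
#' @return A list of class `agreement_report`: `mdiff`, `loa`
#'   (lower, upper), `sd_diff`, `ccc`, `n`.
#' @export
bland_altman <- function(est, ref) {
  stopifnot(length(est) == length(ref))
  ok <- is.finite(est) & is.finite(ref)
  e <- est[ok]; r <- ref[ok]
  d <- e - r
  sdd <- if (length(d) > 1) stats::sd(d) else 0
  md <- mean(d)
  ccc <- 2 * stats::cov(e, r) /
    (stats::var(e) + stats::var(r) + (mean(e) - mean(r))^2)
  structure(list(mdiff = md, loa = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 sd_diff = sdd, ccc = ccc, n = length(d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman: mdiff = %.4g, 95%% LoA [%.4g, %.4g] (n = %d)\n",
              x$mdiff, x$loa[1], x$loa[2], x$n))
  cat(sprintf("Lin's CCC = %.4f\n", x$ccc))
  invisible(x)
}

#' Tissue-wise paired comparison of two sets of parameter maps
#'
#' Summarizes one value per subject per tissue (the median of the selected
#' parameter over the tissue's voxels), then compares the two methods per
#' tissue with a paired Wilcoxon signed-rank test across subjects.
#' Pairing is at the subject level.
#'
#' @param maps_a,maps_b lists over subjects; each element a `pk_maps` (or a
#'   named list of 3D parameter arrays).
#' @param labels list over subjects of integer label arrays.
#' @param parameter which parameter map to compare (e.g. `"ktrans"`).
#' @param tissues named integer vector of label codes to include.
#' @param ... passed to [stats::wilcox.test()] (e.g. `alternative`).
#' @return Data frame with one row per tissue: per-method medians (of the
#'   per-subject summaries), the p-value, and the number of pairs; tissues
#'   with fewer than 2 pairs are flagged with `NA`.
#' @export
tissue_compare <- function(maps_a, maps_b, labels, parameter = "ktrans",
                           tissues = PHANTOM_LABELS[c("nawm", "wmh", "dgm", "rsl")],
                           ...) {
  stopifnot(length(maps_a) == length(maps_b),
            length(maps_a) == length(labels))
  n_sub <- length(maps_a)
  summarize <- function(maps, lab, code) {
    m <- maps[[parameter]]
    stats::median(m[lab == code], na.rm = TRUE)
  }
  out <- lapply(names(tissues), function(tis) {
    code <- tissues[[tis]]
    a <- vapply(seq_len(n_sub), function(s) summarize(maps_a[[s]], labels[[s]], code), 0)
    b <- vapply(seq_len(n_sub), function(s) summarize(maps_b[[s]], labels[[s]], code), 0)
    ok <- is.finite(a) & is.finite(b)
    # identical paired samples sit at the null center: p = 1 by convention
    p <- if (sum(ok) < 2) NA_real_
         else if (all(a[ok] == b[ok])) 1
         else stats::wilcox.test(a[ok], b[ok], paired = TRUE, ...)$p.value
    data.frame(tissue = tis, median_a = stats::median(a[ok]),
               median_b = stats::median(b[ok]), p_value = p, n_pairs = sum(ok))
  })
  do.call(rbind, out)
}

#' Slice-wise fitting error of a modeled concentration series
#'
#' For every axial slice, compares the fitted to the observed concentration
#' stack: nRMSE over all voxel-frames of the slice and SSIM averaged over
#' frames, then aggregates mean and sd across slices.
#'
#' @param observed,fitted `dynamic_series` (or 4D arrays) on the same grid.
#' @param mask 3D logical mask of voxels to include.
#' @return A list: `per_slice` data frame (slice, nrmse, ssim) and
#'   `summary` (mean and sd of each metric across slices).
#' @export
curve_fit_error <- function(observed, fitted, mask = NULL) {
  ov <- if (inherits(observed, "dynamic_series")) observed$values else observed
  fv <- if (inherits(fitted, "dynamic_series")) fitted$values else fitted
  stopifnot(identical(dim(ov), dim(fv)))
  d <- dim(ov)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  rows <- lapply(seq_len(d[3]), function(z) {
    m2 <- mask[, , z]
    if (!any(m2)) return(NULL)
    nr <- nrmse(fv[, , z, ], ov[, , z, ],
                mask = array(m2, c(d[1], d[2], d[4])) &
                  is.finite(fv[, , z, ]) & is.finite(ov[, , z, ]))
    ss <- mean(vapply(seq_len(d[4]), function(f) {
      o2 <- ov[, , z, f]; f2 <- fv[, , z, f]
      o2[!m2 | !is.finite(o2)] <- 0; f2[!m2 | !is.finite(f2)] <- 0
      ssim(f2, o2, mask = m2)
    }, 0))
    data.frame(slice = z, nrmse = nr, ssim = ss)
  })
  per_slice <- do.call(rbind, rows)
  list(per_slice = per_slice,
       summary = data.frame(
         metric = c("nrmse", "ssim"),
         mean = c(mean(per_slice$nrmse), mean(per_slice$ssim)),
         sd = c(stats::sd(per_slice$nrmse), stats::sd(per_slice$ssim))))
}
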