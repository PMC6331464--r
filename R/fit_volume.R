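#' Voxelwise tracer-kinetic fitting over a volume
#'
#' Applies [fit_patlak()] or [fit_etofts()] to every masked voxel of a 4D
#' concentration series.  The Patlak route solves the whole volume with one
#' shared QR factorization; the eTofts route loops voxels.  Execution is
#' deterministic: processing voxels in chunks of any size yields results
#' identical to the sequential loop.
#'
#' @param conc a `dynamic_series` with quantity `"concentration_mM"`.
#' @param cp plasma `input_function` on the same time grid.
#' @param model `"patlak"` or `"etofts"`.
#' @param mask logical 3D array selecting voxels to fit (default: all).
#' @param chunk_size voxels per processing chunk (memory/latency knob only;
#'   has no effect on the result).
#' @param ... passed on to the per-voxel fitter ([fit_patlak()] /
#'   [fit_etofts()]): `init`, `max_iter`, bounds, `clip`.
#' @return An object of class `pk_fit`: parameter maps (`ktrans`, `vp`,
#'   and `kep`/`ve` for eTofts) as 3D arrays with `NA` outside the mask or
#'   where a voxel was flagged invalid, a `valid` mask, per-voxel `sse`,
#'   the model kind, and the fitting inputs needed by its methods.
#' @seealso [predict.pk_fit()], [residuals.pk_fit()]
#' @export
fit_volume <- function(conc, cp, model = c("patlak", "etofts"), mask = NULL,
                       chunk_size = 50000L, ...) {
  model <- match.arg(model)
  stopifnot(inherits(conc, "dynamic_series"),
            conc$quantity == "concentration_mM")
  d <- dim(conc$values)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask shape must match the volume")
  nv <- prod(d[1:3])
  Y <- matrix(aperm(conc$values, c(4, 1, 2, 3)), nrow = d[4])  # frames x voxels
  idx <- which(as.logical(mask))
  shape3 <- d[1:3]
  blank <- array(NA_real_, shape3)
  maps <- list(ktrans = blank, vp = blank)
  if (model == "etofts") { maps$kep <- blank; maps$ve <- blank }
  sse <- blank
  valid <- array(FALSE, shape3)
  iter <- conv <- NULL
  if (length(idx)) {
    chunks <- split(idx, ceiling(seq_along(idx) / chunk_size))
    if (model == "patlak") {
      for (ch in chunks) {
        f <- fit_patlak_many(Y[, ch, drop = FALSE], cp, ...)
        maps$ktrans[ch] <- f$ktrans
        maps$vp[ch] <- f$vp
        sse[ch] <- f$sse
        valid[ch] <- f$valid
      }
    } else {
      for (ch in chunks) {
        for (v in ch) {
          f <- fit_etofts(Y[, v], cp, ...)
          maps$ktrans[v] <- f$theta[["ktrans"]]
          maps$kep[v] <- f$theta[["kep"]]
          maps$vp[v] <- f$theta[["vp"]]
          maps$ve[v] <- f$ve
          sse[v] <- f$sse
          valid[v] <- f$valid
        }
      }
    }
  }
  structure(list(maps = maps, model = model, valid = valid, sse = sse,
                 mask = mask, cp = cp, times = conc$times, dim = shape3),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Voxelwise %s fit: %d voxels in mask, %.1f%% valid\n",
              x$model, sum(x$mask), 100 * mean(x$valid[x$mask])))
  print(coef(x))
  invisible(x)
}

#' @export
summary.pk_fit <- function(object, ...) {
  qs <- function(m) stats::quantile(m[object$mask], c(.05, .25, .5, .75, .95),
                                    na.rm = TRUE)
  tab <- t(vapply(object$maps, qs, numeric(5)))
  cat(sprintf("Voxelwise %s fit over %d voxels (%.1f%% valid)\n",
              object$model, sum(object$mask),
              100 * mean(object$valid[object$mask])))
  cat(sprintf("Residual SSE (median): %.3g\n",
              stats::median(object$sse[object$mask], na.rm = TRUE)))
  print(signif(tab, 4))
  invisible(tab)
}

#' Median parameter values of a volume fit
#' @param object a `pk_fit`.
#' @param ... unused.
#' @export
coef.pk_fit <- function(object, ...) {
  vapply(object$maps, function(m) stats::median(m[object$mask], na.rm = TRUE),
         numeric(1))
}

#' Fitted concentration-time curves from a volume fit
#'
#' Evaluates the fitted kinetic model at every masked voxel, returning the
#' model-implied 4D concentration series on the acquisition grid.
#'
#' @param object a `pk_fit`.
#' @param ... unused.
#' @return A `dynamic_series` of fitted concentrations (`NA` outside mask).
#' @export
predict.pk_fit <- function(object, ...) {
  d <- c(object$dim, length(object$times))
  out <- array(NA_real_, d)
  g <- kinetic_grid(object$cp)
  w <- trapz_weights(g$t)
  auc <- as.numeric(w %*% g$cp)
  idx <- which(object$mask & object$valid)
  nt <- d[4]
  fitted_mat <- matrix(NA_real_, length(idx), nt)
  if (object$model == "patlak") {
    fitted_mat <- cbind(object$maps$vp[idx]) %*% rbind(g$cp) +
      cbind(object$maps$ktrans[idx]) %*% rbind(auc)
  } else {
    dmat <- pmax(outer(g$t, g$t, "-"), 0)
    for (i in seq_along(idx)) {
      v <- idx[i]
      conv <- as.numeric((w * exp(-object$maps$kep[v] * dmat)) %*% g$cp)
      fitted_mat[i, ] <- object$maps$vp[v] * g$cp +
        object$maps$ktrans[v] * conv
    }
  }
  for (f in seq_len(nt)) {
    sl <- array(NA_real_, object$dim)
    sl[idx] <- fitted_mat[, f]
    out[, , , f] <- sl
  }
  dynamic_series(out, object$times, "concentration_mM")
}

#' Residual concentration curves of a volume fit
#'
#' @param object a `pk_fit`.
#' @param conc the observed concentration `dynamic_series` the fit was run on.
#' @param ... unused.
#' @return 4D array of residuals (observed - fitted).
#' @export
residuals.pk_fit <- function(object, conc, ...) {
  stopifnot(inherits(conc, "dynamic_series"))
  conc$values - predict(object)$values
}
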