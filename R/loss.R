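#' @name joint_loss
#' @title Joint parameter + kinetic-model-consistency loss
#'
#' @description The training objective combines two terms per voxel: the
#' squared error between true and predicted kinetic parameters, and the
#' squared discrepancy between the observed concentration-time curve and
#' the curve implied by the predicted parameters through the (differentiable,
#' trapezoid-quadrature) kinetic forward model:
#'
#'   L = || theta - theta_hat ||^2 + lambda || Ct - f_tk(theta_hat) ||^2
#'
#' The consistency term is evaluated on the post-injection frames (the
#' baseline frame has zero model concentration by construction).  With
#' `reduction = "sum"` and `lambda = 1` the raw two-term objective is
#' reproduced literally; the training default normalizes both terms by
#' their element counts (`reduction = "mean"`) and optionally standardizes
#' the parameter channels (`scale`), since Ktrans (~1e-3 min^-1) and vp
#' (~1e-2) live on different scales.
NULL

# Design/operator bundle for evaluating f_tk and its Jacobian on a fixed
# plasma curve.  For Patlak f is linear: f = theta %*% t(A).
consistency_design <- function(cp, times = NULL) {
  g <- kinetic_grid(cp, times)
  w <- trapz_weights(g$t)
  list(t = g$t, cp = g$cp, w = w,
       auc = as.numeric(w %*% g$cp),
       d = pmax(outer(g$t, g$t, "-"), 0),
       post = g$t > 0)
}

# f_tk and per-parameter derivatives for a matrix of parameter rows.
# theta columns: (ktrans, vp) for Patlak, (ktrans, kep, vp) for eTofts.
# Returns fitted curves (rows x frames, post frames only) and derivative
# matrices of the same shape.
tk_forward_jac <- function(theta, des, model, need_jac = TRUE) {
  post <- des$post
  if (model == "patlak") {
    A <- cbind(des$auc[post], des$cp[post])            # d/dktrans, d/dvp
    f <- theta %*% t(A)
    jac <- if (need_jac) list(A = A) else NULL
    list(f = f, jac = jac)
  } else {
    n <- nrow(theta); tp <- which(post)
    f <- matrix(0, n, length(tp))
    dI <- I <- matrix(0, n, length(tp))
    kep <- theta[, 2]
    for (jj in seq_along(tp)) {
      j <- tp[jj]; k <- seq_len(j)
      wk <- des$w[j, k] * des$cp[k]
      ek <- exp(-outer(kep, des$t[j] - des$t[k]))      # exponents <= 0
      I[, jj] <- as.numeric(ek %*% wk)
      if (need_jac)
        dI[, jj] <- as.numeric(-(ek * rep(des$t[j] - des$t[k], each = n)) %*% wk)
    }
    f <- theta[, 3] * matrix(des$cp[post], n, length(tp), byrow = TRUE) +
      theta[, 1] * I
    list(f = f, jac = if (need_jac) list(I = I, dI = dI) else NULL)
  }
}

#' Evaluate the joint loss
#'
#' @param theta_true matrix (voxels x p) of target parameters.
#' @param theta_pred matrix (voxels x p) of predicted parameters; columns
#'   (ktrans, vp) for Patlak, (ktrans, kep, vp) for eTofts.
#' @param ct_obs matrix (voxels x frames) of observed concentrations on the
#'   full acquisition grid.
#' @param cp plasma `input_function` (or vector with `times`).
#' @param times seconds; only when `cp` is a plain vector.
#' @param model `"patlak"` or `"etofts"`.
#' @param lambda weight of the consistency term.
#' @param scale optional per-channel standardization of the parameter term
#'   (vector of length p); default none.
#' @param reduction `"mean"` (per-element, the training default) or
#'   `"sum"` (the raw two-term objective).
#' @return Scalar loss; attributes `param` and `consistency` carry the two
#'   terms separately.
#' @export
joint_loss <- function(theta_true, theta_pred, ct_obs, cp, times = NULL,
                       model = c("patlak", "etofts"), lambda = 1,
                       scale = NULL, reduction = c("mean", "sum")) {
  model <- match.arg(model)
  reduction <- match.arg(reduction)
  theta_true <- rbind(theta_true); theta_pred <- rbind(theta_pred)
  ct_obs <- rbind(ct_obs)
  np <- if (model == "patlak") 2L else 3L
  if (ncol(theta_pred) != np)
    stop("theta has ", ncol(theta_pred), " columns but the ", model,
         " model has ", np, " parameters")
  des <- consistency_design(cp, times)
  if (ncol(ct_obs) == length(des$t)) ct_obs <- ct_obs[, des$post, drop = FALSE]
  s <- if (is.null(scale)) rep(1, np) else scale
  rp <- sweep(theta_true - theta_pred, 2, s, "/")
  f <- tk_forward_jac(theta_pred, des, model, need_jac = FALSE)$f
  rc <- ct_obs - f
  if (reduction == "mean") {
    lp <- mean(rp^2); lc <- mean(rc^2)
  } else {
    lp <- sum(rp^2); lc <- sum(rc^2)
  }
  structure(lp + lambda * lc, param = lp, consistency = lc)
}

#' Gradient of the joint loss with respect to the predicted parameters
#'
#' @inheritParams joint_loss
#' @return Matrix (voxels x p), d loss / d theta_pred.
#' @export
joint_loss_grad <- function(theta_true, theta_pred, ct_obs, cp, times = NULL,
                            model = c("patlak", "etofts"), lambda = 1,
                            scale = NULL, reduction = c("mean", "sum")) {
  model <- match.arg(model)
  reduction <- match.arg(reduction)
  theta_true <- rbind(theta_true); theta_pred <- rbind(theta_pred)
  ct_obs <- rbind(ct_obs)
  np <- ncol(theta_pred)
  des <- consistency_design(cp, times)
  if (ncol(ct_obs) == length(des$t)) ct_obs <- ct_obs[, des$post, drop = FALSE]
  s <- if (is.null(scale)) rep(1, np) else scale
  fz <- tk_forward_jac(theta_pred, des, model, need_jac = TRUE)
  rc <- fz$f - ct_obs
  npar_el <- length(theta_pred); nc_el <- length(rc)
  wp <- if (reduction == "mean") 1 / npar_el else 1
  wc <- if (reduction == "mean") 1 / nc_el else 1
  gp <- -2 * wp * sweep(theta_true - theta_pred, 2, s^2, "/")
  if (model == "patlak") {
    gc <- 2 * wc * (rc %*% fz$jac$A)
  } else {
    gc <- cbind(rowSums(rc * fz$jac$I),
                theta_pred[, 1] * rowSums(rc * fz$jac$dI),
                as.numeric(rc %*% des$cp[des$post])) * (2 * wc)
  }
  gp + lambda * gc
}
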