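#' @name kinetics
#' @title Tracer-kinetic models
#'
#' @description Patlak and extended Tofts models of contrast-agent exchange
#' between blood plasma and the extravascular extracellular space (EES):
#'
#'   Patlak:  Ct(t) = vp Cp(t) + Ktrans int_0^t Cp(tau) dtau
#'   eTofts:  Ct(t) = vp Cp(t) + Ktrans int_0^t Cp(tau) e^(-kep (t - tau)) dtau
#'
#' Time axes at the interface are seconds (the acquisition grid); rates are
#' converted internally to minutes so Ktrans and kep come out in min^-1.
#' Both integrals use cumulative trapezoid quadrature on the native frame
#' grid, with the same weight matrix for both models so that the nesting
#' identity eTofts(kep = 0) == Patlak holds exactly.  Plasma concentration
#' is taken as 0 at t <= 0 (the baseline frame is the quadrature anchor).
NULL

# Cumulative trapezoid weight matrix on grid t (rows: upper limit t_j).
# (W %*% y)[j] equals the trapezoid integral of y over [t_1, t_j]; the
# lower-triangular form is shared by the Patlak integral and the
# exponential-kernel convolution of the eTofts model.
trapz_weights <- function(t) {
  n <- length(t)
  w <- matrix(0, n, n)
  if (n < 2) return(w)
  dt <- diff(t)
  for (j in 2:n) {
    w[j, 1:(j - 1)] <- w[j, 1:(j - 1)] + dt[1:(j - 1)] / 2
    w[j, 2:j] <- w[j, 2:j] + dt[1:(j - 1)] / 2
  }
  w
}

kinetic_grid <- function(cp, times = NULL) {
  if (inherits(cp, "input_function")) {
    if (cp$kind != "plasma")
      stop("kinetic models require a plasma input function")
    times <- cp$times
    cpv <- cp$values
  } else {
    if (is.null(times)) stop("times required when cp is a plain vector")
    cpv <- as.numeric(cp)
  }
  tm <- times / 60                       # minutes, so rates are min^-1
  cpv[times <= 0] <- 0                   # no tracer before injection
  list(t = tm, cp = cpv)
}

#' Patlak forward model
#'
#' @param ktrans volume transfer constant, min^-1.
#' @param vp fractional plasma volume.
#' @param cp plasma input function (an `input_function` of kind
#'   `"plasma"`, or a plain concentration vector with `times`).
#' @param times seconds; required only when `cp` is a plain vector.
#' @return Tissue concentration curve (mM) on the acquisition grid.
#' @export
patlak_forward <- function(ktrans, vp, cp, times = NULL) {
  g <- kinetic_grid(cp, times)
  vp * g$cp + ktrans * as.numeric(trapz_weights(g$t) %*% g$cp)
}

#' Extended Tofts forward model
#'
#' @param kep EES-to-plasma backflux rate constant, min^-1 (>= 0).
#' @inheritParams patlak_forward
#' @return Tissue concentration curve (mM) on the acquisition grid.
#' @export
etofts_forward <- function(ktrans, kep, vp, cp, times = NULL) {
  stopifnot(kep >= 0)
  g <- kinetic_grid(cp, times)
  vp * g$cp + ktrans * etofts_integral(g$t, g$cp, kep)
}

# int_0^{t_j} Cp(tau) exp(-kep (t_j - tau)) dtau, trapezoid on the grid.
etofts_integral <- function(t, cp, kep) {
  w <- trapz_weights(t)
  d <- pmax(outer(t, t, "-"), 0)         # t_j - t_k, clamped where W = 0
  as.numeric((w * exp(-kep * d)) %*% cp)
}

# derivative of etofts_integral with respect to kep
etofts_integral_dkep <- function(t, cp, kep) {
  w <- trapz_weights(t)
  d <- pmax(outer(t, t, "-"), 0)
  as.numeric(-(w * d * exp(-kep * d)) %*% cp)
}

#' Voxelwise Patlak fit (linear least squares)
#'
#' Ordinary least squares on the design \[Cp(t), int_0^t Cp\], solved by QR.
#' The pre-contrast baseline frame (t <= 0) anchors the quadrature but is
#' excluded from the residuals.  Estimates are returned raw (possibly
#' negative) unless `clip` is set.
#'
#' @param ct tissue concentration curve, mM, on the full acquisition grid.
#' @param clip clip negative parameter estimates to zero (default off).
#' @inheritParams patlak_forward
#' @return A list: `theta = c(ktrans, vp)`, `sse`, `valid`.
#' @export
fit_patlak <- function(ct, cp, times = NULL, clip = FALSE) {
  g <- kinetic_grid(cp, times)
  if (length(ct) != length(g$t)) stop("ct and cp grids differ in length")
  if (length(g$t) < 3) stop("Patlak fit needs at least 3 frames")
  post <- g$t > 0
  x <- cbind(cp = g$cp, auc = as.numeric(trapz_weights(g$t) %*% g$cp))[post, , drop = FALSE]
  y <- ct[post]
  if (!all(is.finite(x)) || !all(is.finite(y)) || qr(x)$rank < 2)
    return(list(theta = c(ktrans = NA_real_, vp = NA_real_),
                sse = NA_real_, valid = FALSE))
  fit <- lm.fit(x, y)
  th <- c(ktrans = unname(fit$coefficients["auc"]),
          vp = unname(fit$coefficients["cp"]))
  if (clip) th <- pmax(th, 0)
  list(theta = th, sse = sum(fit$residuals^2), valid = TRUE)
}

# Patlak OLS over many voxels at once: Y is frames x voxels.  The design is
# shared, so one QR factorization serves the whole volume.
fit_patlak_many <- function(Y, cp, times = NULL, clip = FALSE) {
  g <- kinetic_grid(cp, times)
  post <- g$t > 0
  x <- cbind(g$cp, as.numeric(trapz_weights(g$t) %*% g$cp))[post, , drop = FALSE]
  Yp <- Y[post, , drop = FALSE]
  bad <- !is.finite(colSums(Yp))
  Yp[, bad] <- 0
  if (qr(x)$rank < 2) {
    nv <- ncol(Y)
    return(list(ktrans = rep(NA_real_, nv), vp = rep(NA_real_, nv),
                sse = rep(NA_real_, nv), valid = rep(FALSE, nv)))
  }
  fit <- lm.fit(x, Yp)
  ktrans <- fit$coefficients[2, ]
  vp <- fit$coefficients[1, ]
  if (clip) { ktrans <- pmax(ktrans, 0); vp <- pmax(vp, 0) }
  sse <- colSums(as.matrix(fit$residuals)^2)
  ktrans[bad] <- NA_real_; vp[bad] <- NA_real_; sse[bad] <- NA_real_
  list(ktrans = unname(ktrans), vp = unname(vp), sse = unname(sse),
       valid = !bad)
}

#' Voxelwise extended Tofts fit (bounded quasi-Newton NLS)
#'
#' Minimizes the sum of squared residuals over (Ktrans, kep, vp) with a
#' limited-memory BFGS quasi-Newton method under box bounds, analytic
#' gradients, and a hard iteration cap.  By default the start is warm:
#' Ktrans and vp are seeded from the closed-form Patlak fit (the kep -> 0
#' nested model) and kep from the middle of its bound range, which keeps
#' the 30-iteration budget sufficient across the low-permeability regime.
#' Non-convergence is not an error: the best iterate is returned with
#' `converged = FALSE`.
#'
#' @param init starting point `c(ktrans, kep, vp)`; `NULL` (default) uses
#'   the Patlak-informed warm start.
#' @param max_iter iteration cap (default 30).
#' @param lower,upper box bounds on `c(ktrans, kep, vp)`.
#' @inheritParams fit_patlak
#' @return A list: `theta = c(ktrans, kep, vp)`, `ve` (= ktrans/kep where
#'   kep > 0), `sse`, `iterations`, `converged`, `valid`.
#' @export
fit_etofts <- function(ct, cp, times = NULL, init = NULL,
                       max_iter = 30, lower = c(0, 0, 0),
                       upper = c(0.1, 10, 1)) {
  g <- kinetic_grid(cp, times)
  if (length(ct) != length(g$t)) stop("ct and cp grids differ in length")
  if (length(g$t) < 4) stop("eTofts fit needs at least 4 frames")
  bad_theta <- c(ktrans = NA_real_, kep = NA_real_, vp = NA_real_)
  if (!all(is.finite(ct)) || !all(is.finite(g$cp)) || all(g$cp == 0))
    return(list(theta = bad_theta, ve = NA_real_, sse = NA_real_,
                iterations = 0L, converged = FALSE, valid = FALSE))
  post <- g$t > 0
  w <- trapz_weights(g$t)
  d <- pmax(outer(g$t, g$t, "-"), 0)
  y <- ct[post]
  fn <- function(th) {
    pred <- th[3] * g$cp + th[1] * as.numeric((w * exp(-th[2] * d)) %*% g$cp)
    sum((pred[post] - y)^2)
  }
  gr <- function(th) {
    e <- exp(-th[2] * d)
    conv <- as.numeric((w * e) %*% g$cp)
    dconv <- as.numeric(-(w * d * e) %*% g$cp)
    r <- (th[3] * g$cp + th[1] * conv)[post] - y
    2 * c(sum(r * conv[post]),
          th[1] * sum(r * dconv[post]),
          sum(r * g$cp[post]))
  }
  if (is.null(init)) {
    fp <- fit_patlak(ct, cp, times)
    init <- c(min(max(fp$theta[["ktrans"]], lower[1] + 1e-4), upper[1]),
              min(max(0.5, lower[2]), upper[2]),
              min(max(fp$theta[["vp"]], lower[3] + 1e-3), upper[3]))
    if (any(!is.finite(init))) init <- c(1e-3, 0.5, 0.02)
  }
  res <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter, factr = 1e3))
  th <- c(ktrans = res$par[1], kep = res$par[2], vp = res$par[3])
  list(theta = th,
       ve = if (th["kep"] > 0) unname(th["ktrans"] / th["kep"]) else NA_real_,
       sse = res$value,
       iterations = unname(res$counts[1]),
       converged = res$convergence == 0,
       valid = TRUE)
}
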