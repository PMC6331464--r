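#' @name spgr
#' @title Spoiled gradient-echo signal model
#'
#' @description The steady-state spoiled gradient-echo (SPGR) magnitude at
#' flip angle alpha is
#'
#'   S = M0 sin(alpha) (1 - e^-(K+L)) / (1 - cos(alpha) e^-(K+L))
#'
#' with K = TR / T10 and L = r1 Ct TR.  All internal units are SI: TR and
#' T10 in seconds, Ct in mM, r1 in s^-1 mM^-1, so L is dimensionless.
#' The dynamic forward model used throughout the package is the
#' baseline-offset form: the pure SPGR term above plus the constant offset
#' (S(0) - SPGR(Ct = 0)), which anchors the curve to the measured baseline
#' frame; its inversion below is the exact algebraic inverse.
NULL

#' Steady-state SPGR signal
#'
#' Vectorized over any mix of `m0`, `t10`, `ct` (recycled as in base R).
#'
#' @param m0 equilibrium magnetization (arbitrary units).
#' @param t10 pre-contrast longitudinal relaxation time, seconds.
#' @param alpha flip angle, degrees.
#' @param tr repetition time, seconds.
#' @param ct contrast-agent concentration, mM (default 0 = pre-contrast).
#' @param r1 relaxivity, s^-1 mM^-1.
#' @return Signal magnitude, same shape as the recycled inputs.
#' @export
spgr_signal <- function(m0, t10, alpha, tr, ct = 0, r1 = 4.2) {
  a <- deg2rad(alpha)
  e <- exp(-(tr / t10 + r1 * ct * tr))
  m0 * sin(a) * (1 - e) / (1 - cos(a) * e)
}

new_relaxation_maps <- function(t10, m0 = NULL, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(t10) & t10 > 0
  structure(list(t10 = t10, m0 = m0, valid = valid), class = "relaxation_maps")
}

#' @export
print.relaxation_maps <- function(x, ...) {
  n <- length(x$t10)
  cat(sprintf("Relaxation maps: %d voxels, %.1f%% valid%s\n", n,
              100 * mean(x$valid), if (is.null(x$m0)) " (T10 only)" else ""))
  if (any(x$valid))
    cat(sprintf("  T10 range (valid): [%.3g, %.3g] s\n",
                min(x$t10[x$valid]), max(x$t10[x$valid])))
  invisible(x)
}

#' Variable flip-angle T10 estimation
#'
#' Two-point closed-form estimate of the pre-contrast longitudinal
#' relaxation time from a pair of SPGR acquisitions at flip angles
#' `alpha_a` < `alpha_b`:
#'
#'   1/T10 = (1/TR) ln\[(SR sin(ab) cos(aa) - sin(aa) cos(ab)) /
#'                     (SR sin(ab) - sin(aa))\],  SR = Sa / Sb.
#'
#' Voxels where the log argument is non-positive, non-finite, or where the
#' resulting T10 is non-positive are flagged invalid and carry `NA`;
#' degenerate background voxels (zero signal) never raise an error.
#'
#' @param sa,sb pre-contrast images at `alpha_a` and `alpha_b`; numeric
#'   arrays of identical shape.
#' @param params an [acq_params()] object.
#' @return A `relaxation_maps` object with fields `t10` (seconds, `NA`
#'   where invalid), `m0` (`NULL` until [compute_m0()]), `valid`.
#' @seealso [compute_m0()], [spgr_signal()]
#' @export
compute_t10 <- function(sa, sb, params) {
  if (!identical(dim(sa) %||% length(sa), dim(sb) %||% length(sb)))
    stop("sa and sb must have identical shape")
  if (params$alpha_a == params$alpha_b)
    stop("degenerate VFA pair: alpha_a == alpha_b")
  aa <- deg2rad(params$alpha_a); ab <- deg2rad(params$alpha_b)
  sr <- sa / sb
  arg <- (sr * sin(ab) * cos(aa) - sin(aa) * cos(ab)) / (sr * sin(ab) - sin(aa))
  ok <- is.finite(arg) & arg > 0
  t10 <- sa * NA_real_
  lg <- log(arg[ok])
  t10[ok] <- params$tr / lg
  ok[ok] <- lg > 0            # T10 must be positive and finite
  t10[!ok] <- NA_real_
  new_relaxation_maps(t10, valid = ok & is.finite(t10))
}

#' Equilibrium magnetization from the higher-flip-angle image
#'
#' Algebraic inverse of the steady-state SPGR magnitude at `alpha_b`:
#' M0 = Sb (1 - cos(ab) e^-K) / (sin(ab) (1 - e^-K)), K = TR/T10.
#' Invalid T10 voxels propagate; non-positive Sb yields an invalid voxel.
#'
#' @param sb pre-contrast image at `alpha_b`.
#' @param maps a `relaxation_maps` object from [compute_t10()].
#' @inheritParams compute_t10
#' @return The input `maps` with `m0` filled in and `valid` updated.
#' @export
compute_m0 <- function(sb, maps, params) {
  ab <- deg2rad(params$alpha_b)
  e <- exp(-params$tr / maps$t10)
  m0 <- sb * (1 - cos(ab) * e) / (sin(ab) * (1 - e))
  ok <- maps$valid & is.finite(m0) & m0 > 0
  m0[!ok] <- NA_real_
  new_relaxation_maps(maps$t10, m0 = m0, valid = ok)
}

#' Dynamic series container
#'
#' A 4D grid (x, y, z, t) of signal intensity or contrast-agent
#' concentration together with its time axis.
#'
#' @param values 4D numeric array (x, y, z, t).
#' @param times seconds since injection; strictly increasing, first frame
#'   pre-contrast at t <= 0.
#' @param quantity `"signal"` or `"concentration_mM"`.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(values, times,
                           quantity = c("signal", "concentration_mM")) {
  quantity <- match.arg(quantity)
  if (length(dim(values)) != 4L)
    stop("values must be a 4D array (x, y, z, t); got ",
         length(dim(values)), " dimensions")
  if (dim(values)[4L] != length(times))
    stop("length(times) must equal the 4th extent of values")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1L] > 0) stop("first frame must be pre-contrast (t <= 0)")
  structure(list(values = values, times = as.numeric(times),
                 quantity = quantity), class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Dynamic series (%s): %d x %d x %d voxels, %d frames over %.0f s\n",
              x$quantity, d[1], d[2], d[3], d[4], diff(range(x$times))))
  invisible(x)
}

#' SPGR dynamic forward model: concentration to signal
#'
#' Applies the baseline-offset SPGR model voxelwise and framewise:
#' S(t) = SPGR(Ct(t)) + (S(0) - SPGR(0)), with per-voxel (M0, T10) from
#' `maps` and the measured baseline image `s0`.  At Ct = 0 the two bracketed
#' terms cancel and S(t) = S(0) exactly.
#'
#' @param ct a `dynamic_series` with quantity `"concentration_mM"`.
#' @param s0 baseline (pre-contrast) image at `alpha_b`, 3D array.
#' @param maps valid `relaxation_maps` (t10 + m0).
#' @param params an [acq_params()] object.
#' @param tol negative concentrations beyond `-tol` raise an error; small
#'   negative noise excursions are tolerated.
#' @return A `dynamic_series` with quantity `"signal"`; invalid map voxels
#'   yield `NA` frames.
#' @export
spgr_forward <- function(ct, s0, maps, params, tol = 1e-6) {
  stopifnot(inherits(ct, "dynamic_series"), ct$quantity == "concentration_mM")
  if (min(ct$values, na.rm = TRUE) < -tol)
    stop("negative concentrations beyond tolerance in input")
  d <- dim(ct$values)
  nt <- d[4L]
  ab <- deg2rad(params$alpha_b)
  k <- params$tr / maps$t10
  base <- spgr_signal(maps$m0, maps$t10, params$alpha_b, params$tr)
  off <- as.numeric(s0) - base              # baseline offset, per voxel
  sig <- array(NA_real_, d)
  msa <- maps$m0 * sin(ab)
  for (f in seq_len(nt)) {
    ctf <- array(ct$values[, , , f], d[1:3])
    e <- exp(-(k + params$r1 * params$tr * ctf))
    sig[, , , f] <- msa * (1 - e) / (1 - cos(ab) * e) + off
  }
  sig[array(!maps$valid, d)] <- NA_real_
  dynamic_series(sig, ct$times, "signal")
}

#' SPGR inversion: signal to concentration
#'
#' Closed-form inversion of the baseline-offset SPGR model.  With
#' B = S(t) - (S(0) - SPGR(0)) and E = (M0 sin(a) - B)/(M0 sin(a) - B cos(a)),
#' the concentration is Ct = (-ln(E) - K) / (r1 TR).  Frames where E falls
#' outside (0, 1] — e.g. signal beyond the SPGR saturation asymptote — are
#' masked invalid (`NA`) rather than raising; noise excursions of the signal
#' below baseline stay inside (0, 1] and yield retained, unclipped negative
#' concentrations.
#'
#' @param s a `dynamic_series` with quantity `"signal"`.
#' @param clip_negative clip negative concentrations to zero (default off,
#'   so that fitting sees unbiased noise).
#' @inheritParams spgr_forward
#' @return A list: `conc` (a `dynamic_series`, quantity
#'   `"concentration_mM"`) and `valid` (4D logical mask of usable frames).
#' @export
signal_to_concentration <- function(s, s0, maps, params, clip_negative = FALSE) {
  stopifnot(inherits(s, "dynamic_series"), s$quantity == "signal")
  d <- dim(s$values)
  nt <- d[4L]
  ab <- deg2rad(params$alpha_b)
  k <- params$tr / maps$t10
  base <- spgr_signal(maps$m0, maps$t10, params$alpha_b, params$tr)
  off <- as.numeric(s0) - base
  msa <- maps$m0 * sin(ab)
  conc <- array(NA_real_, d)
  valid <- array(FALSE, d)
  for (f in seq_len(nt)) {
    b <- array(s$values[, , , f], d[1:3]) - off
    e <- (msa - b) / (msa - b * cos(ab))
    ok <- maps$valid & is.finite(e) & e > 0 & e <= 1
    e[!ok] <- 1                       # placeholder; masked below
    ctf <- (-log(e) - k) / (params$r1 * params$tr)
    ctf[!ok] <- NA_real_
    if (clip_negative) ctf <- pmax(ctf, 0)
    conc[, , , f] <- ctf
    valid[, , , f] <- ok & is.finite(ctf)
  }
  list(conc = dynamic_series(conc, s$times, "concentration_mM"), valid = valid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
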