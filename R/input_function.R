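#' Vascular / arterial input function container
#'
#' A 1D contrast-agent concentration-time curve on the acquisition grid,
#' either whole-blood (as measured in a vessel such as the superior sagittal
#' sinus) or plasma (after hematocrit correction).
#'
#' @param times seconds since injection.
#' @param values concentration, mM; non-negative.
#' @param kind `"whole_blood"` or `"plasma"`.
#' @return An object of class `input_function`.
#' @export
input_function <- function(times, values, kind = c("whole_blood", "plasma")) {
  kind <- match.arg(kind)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind), class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Input function (%s): %d samples, peak %.3g mM at t = %.0f s\n",
              x$kind, length(x$times), max(x$values),
              x$times[which.max(x$values)]))
  invisible(x)
}

#' Extract a vascular input function from a vessel neighborhood
#'
#' Averages the time courses of the in-plane 3x3 voxel neighborhood centred
#' on `center` (one slice), the standard way to smooth a single-voxel VIF
#' measured in the superior sagittal sinus.  The series may hold signal or
#' concentration; conversion is the caller's responsibility.
#'
#' @param series a `dynamic_series`.
#' @param center integer vector `c(x, y, z)`, 1-based voxel index.
#' @return A list with `times` and `values` (the per-frame patch mean),
#'   plus `quantity` inherited from the series.
#' @export
extract_vif <- function(series, center) {
  stopifnot(inherits(series, "dynamic_series"), length(center) == 3L)
  d <- dim(series$values)
  if (center[1] < 2 || center[1] > d[1] - 1 ||
      center[2] < 2 || center[2] > d[2] - 1 ||
      center[3] < 1 || center[3] > d[3])
    stop("3x3 neighborhood of center voxel lies outside the volume")
  xs <- (center[1] - 1):(center[1] + 1)
  ys <- (center[2] - 1):(center[2] + 1)
  patch <- series$values[xs, ys, center[3], , drop = FALSE]
  list(times = series$times,
       values = apply(patch, 4, mean),
       quantity = series$quantity)
}

#' Whole-blood to plasma concentration
#'
#' Cp(t) = Cb(t) / (1 - Hct).
#'
#' @param cb an `input_function` of kind `"whole_blood"`.
#' @param hct hematocrit fraction in [0, 1).
#' @return An `input_function` of kind `"plasma"`.
#' @export
blood_to_plasma <- function(cb, hct) {
  stopifnot(inherits(cb, "input_function"))
  if (cb$kind != "whole_blood")
    stop("blood_to_plasma expects a whole-blood input function")
  if (!is.numeric(hct) || hct < 0 || hct >= 1)
    stop("hct must lie in [0, 1)")
  input_function(cb$times, cb$values / (1 - hct), "plasma")
}

#' Read / write input-function curves as 2-column delimited text
#'
#' Plain-text interchange format: `time_s` and `conc_mM` columns.
#'
#' @param path file path.
#' @param x an `input_function`.
#' @param kind curve kind recorded on read.
#' @return `read_aif` returns an `input_function`; `write_aif` its path.
#' @export
read_aif <- function(path, kind = "plasma") {
  d <- utils::read.table(path, header = TRUE)
  input_function(d[[1]], d[[2]], kind)
}

#' @rdname read_aif
#' @export
write_aif <- function(x, path) {
  stopifnot(inherits(x, "input_function"))
  utils::write.table(data.frame(time_s = x$times, conc_mM = x$values),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
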