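#' @name phantom
#' @title Seeded digital reference object for brain DCE-MRI
#'
#' @description Generates synthetic multi-subject brain DCE datasets with
#' known ground truth: a tissue label map (normal-appearing white matter,
#' white-matter hyperintensities, deep gray matter, recent stroke lesion,
#' plus a small venous vessel region used for VIF extraction), per-voxel
#' pharmacokinetic parameter maps drawn from tissue-conditional
#' distributions in the low-permeability (subtle blood-brain-barrier leak)
#' regime, a biexponential population plasma input function with
#' per-subject jitter, and the noiseless and noisy signal series obtained
#' by pushing the ground truth through the kinetic and SPGR forward models.
#' Every dataset is a pure function of its spec (including the seed).
NULL

#' Phantom specification
#'
#' Tissue means default to a subtle-BBB-leak brain regime: Ktrans (min^-1)
#' of 1e-3 (NAWM), 2e-3 (WMH), 1.5e-3 (DGM), 5e-3 (RSL); vp of 0.01, 0.015,
#' 0.03, 0.02, with a blood vessel at vp = 0.6 and Ktrans = 0; kep =
#' Ktrans / 0.2 for eTofts phantoms (ve = 0.2).  T10 defaults are 1.5 T
#' values: 0.6 s white matter, 1.0 s gray matter, 1.4 s blood.
#'
#' @param shape 3D grid `c(nx, ny, nz)`.
#' @param n_subjects number of synthetic subjects.
#' @param model kinetic model generating the tissue curves.
#' @param ktrans,vp named per-tissue means (min^-1 / fraction).
#' @param t10 named per-tissue T10, seconds.
#' @param ve EES volume fraction used to derive kep for eTofts phantoms.
#' @param rel_spread relative standard deviation of the per-voxel parameter
#'   draws around the tissue mean (same for Ktrans and vp).
#' @param aif biexponential plasma input-function parameters, mM and
#'   min^-1: Cp(t) = dose (a1 e^(-m1 t) + a2 e^(-m2 t)) for t > 0.
#' @param aif_jitter per-subject lognormal sd of the multiplicative jitter
#'   applied independently to the peak (a1) and tail (a2) amplitudes.
#' @param sigma additive Gaussian signal noise, as a fraction of the mean
#'   in-brain baseline signal.
#' @param m0 equilibrium magnetization assigned to in-brain voxels.
#' @param params an [acq_params()] object.
#' @param seed integer seed; the dataset is fully determined by it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 4), n_subjects = 6,
                         model = c("patlak", "etofts"),
                         ktrans = c(nawm = 1e-3, wmh = 2e-3, dgm = 1.5e-3,
                                    rsl = 5e-3, vessel = 0),
                         vp = c(nawm = 0.01, wmh = 0.015, dgm = 0.03,
                                rsl = 0.02, vessel = 0.6),
                         t10 = c(nawm = 0.6, wmh = 0.6, dgm = 1.0,
                                 rsl = 1.0, vessel = 1.4),
                         ve = 0.2, rel_spread = 0.1,
                         aif = c(dose = 1, a1 = 4.5, m1 = 0.6,
                                 a2 = 1.2, m2 = 0.05),
                         aif_jitter = 0.15, sigma = 0.02, m0 = 1000,
                         params = acq_params(), seed = 1L) {
  model <- match.arg(model)
  tissues <- c("nawm", "wmh", "dgm", "rsl", "vessel")
  stopifnot(length(shape) == 3L, all(shape[1:2] >= 32), n_subjects >= 1,
            all(tissues %in% names(ktrans)), all(tissues %in% names(vp)),
            all(tissues %in% names(t10)),
            rel_spread >= 0, aif_jitter >= 0, sigma >= 0, ve > 0)
  structure(list(shape = as.integer(shape), n_subjects = as.integer(n_subjects),
                 model = model, ktrans = ktrans, vp = vp, t10 = t10, ve = ve,
                 rel_spread = rel_spread, aif = aif, aif_jitter = aif_jitter,
                 sigma = sigma, m0 = m0, params = params,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Tissue label codes
PHANTOM_LABELS <- c(background = 0L, nawm = 1L, wmh = 2L, dgm = 3L,
                    rsl = 4L, vessel = 5L)

#' Synthetic tissue label map
#'
#' Deterministic given the seed.  Each slice holds an elliptical "brain"
#' filled with NAWM, a central deep-gray blob, a periventricular WMH ring
#' segment, one recent-stroke-lesion blob at a seeded location, and a small
#' rectangular vessel (sagittal-sinus-like) region at the posterior midline
#' that spans all slices so a 3x3 in-plane VIF patch always fits.  Every
#' tissue class occupies at least 1% of in-brain voxels by construction.
#'
#' @param shape 3D grid `c(nx, ny, nz)`.
#' @param seed integer seed.
#' @return Integer 3D array of labels (0 = background, 1 = NAWM, 2 = WMH,
#'   3 = DGM, 4 = RSL, 5 = vessel) with attribute `vif_center`.
#' @export
make_tissue_map <- function(shape, seed = 1L) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  rng <- local_rng(seed)
  cx <- nx / 2 + rng$runif(1, -1, 1)
  cy <- ny / 2 + rng$runif(1, -1, 1)
  rx <- 0.42 * nx; ry <- 0.45 * ny
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  brain <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
  lab2 <- matrix(PHANTOM_LABELS[["background"]], nx, ny)
  lab2[brain] <- PHANTOM_LABELS[["nawm"]]
  # deep gray matter: central ellipse
  dgm <- ((xg - cx) / (0.16 * nx))^2 + ((yg - cy) / (0.14 * ny))^2 <= 1
  lab2[dgm & brain] <- PHANTOM_LABELS[["dgm"]]
  # WMH: ring segment around the DGM (periventricular caps)
  r2 <- ((xg - cx) / (0.26 * nx))^2 + ((yg - cy) / (0.24 * ny))^2
  wmh <- r2 > 1 & r2 <= 1.8 & abs(yg - cy) > 0.12 * ny
  lab2[wmh & brain & lab2 == PHANTOM_LABELS[["nawm"]]] <- PHANTOM_LABELS[["wmh"]]
  # recent stroke lesion: one blob at a seeded angular position
  ang <- rng$runif(1, 0, 2 * pi)
  lx <- cx + 0.28 * nx * cos(ang)
  ly <- cy + 0.28 * ny * sin(ang)
  rsl <- ((xg - lx) / (0.09 * nx))^2 + ((yg - ly) / (0.09 * ny))^2 <= 1
  lab2[rsl & brain] <- PHANTOM_LABELS[["rsl"]]
  # vessel: posterior-midline rectangle (>= 3 voxels wide so a 3x3 VIF
  # patch fits), sized with the grid so it stays >= 1% of in-brain area
  hx <- max(1L, round(0.035 * nx)); hy <- max(2L, round(0.045 * ny))
  vx <- round(cx) + (-hx:hx)
  vy <- round(cy + 0.36 * ny) + (-hy:(hy - 1))
  vy <- vy[vy <= ny]
  lab2[vx, vy] <- PHANTOM_LABELS[["vessel"]]
  labels <- array(rep(lab2, nz), dim = c(nx, ny, nz))
  attr(labels, "vif_center") <- c(round(cx), round(cy + 0.36 * ny),
                                  ceiling(nz / 2))
  labels
}

# Self-contained RNG stream: leaves the global .Random.seed untouched.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = function(...) draw(stats::runif, ...),
       rnorm = function(...) draw(stats::rnorm, ...),
       rlnorm = function(...) draw(stats::rlnorm, ...),
       sample = function(...) draw(base::sample, ...))
}

#' Ground-truth parameter maps from a label map
#'
#' Per-voxel draws from tissue-conditional normal distributions (mean from
#' the spec, sd = `rel_spread` times the mean), truncated at zero.  The
#' default means encode the tissue ordering seen in small-vessel-disease
#' brains: RSL and WMH Ktrans above NAWM, vessel vp highest.
#'
#' @param labels integer label array from [make_tissue_map()].
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return A list of 3D arrays: `ktrans`, `vp` (plus `kep` for eTofts),
#'   `NA` outside the brain, and logical `valid`.
#' @export
sample_parameters <- function(labels, spec, seed = spec$seed) {
  rng <- local_rng(seed + 1000L)
  draw_map <- function(means) {
    out <- array(NA_real_, dim(labels))
    for (tis in names(PHANTOM_LABELS)[-1]) {
      idx <- which(labels == PHANTOM_LABELS[[tis]])
      if (!length(idx)) next
      mu <- means[[tis]]
      out[idx] <- pmax(rng$rnorm(length(idx), mu, spec$rel_spread * mu), 0)
    }
    out
  }
  maps <- list(ktrans = draw_map(spec$ktrans), vp = draw_map(spec$vp))
  if (spec$model == "etofts") maps$kep <- maps$ktrans / spec$ve
  maps$valid <- labels > 0
  maps
}

#' Population plasma input function
#'
#' Biexponential bolus shape Cp(t) = dose (a1 e^(-m1 t) + a2 e^(-m2 t)) for
#' t > 0 (zero at t <= 0; rates in min^-1), with per-subject multiplicative
#' lognormal jitter on the peak and tail amplitudes.  On a 73 s grid the
#' default parameters place the peak at the first post-injection frame.
#'
#' @param times seconds since injection.
#' @param spec a [phantom_spec()] (fields `aif`, `aif_jitter`).
#' @param subject_seed seed of the per-subject jitter draw; use `NULL` for
#'   the unjittered population curve.
#' @return An `input_function` of kind `"plasma"`.
#' @export
population_aif <- function(times, spec, subject_seed = NULL) {
  a <- spec$aif
  j1 <- j2 <- 1
  if (!is.null(subject_seed) && spec$aif_jitter > 0) {
    rng <- local_rng(subject_seed)
    j1 <- rng$rlnorm(1, 0, spec$aif_jitter)
    j2 <- rng$rlnorm(1, 0, spec$aif_jitter)
  }
  tm <- times / 60
  v <- a[["dose"]] * (j1 * a[["a1"]] * exp(-a[["m1"]] * tm) +
                      j2 * a[["a2"]] * exp(-a[["m2"]] * tm))
  v[times <= 0] <- 0
  input_function(times, v, "plasma")
}

#' Simulate a complete phantom dataset
#'
#' Composes the generator end to end for one synthetic subject:
#' tissue map -> ground-truth parameter draws -> kinetic forward model ->
#' SPGR forward model -> additive Gaussian noise (sd = sigma times the mean
#' in-brain baseline signal, independent per voxel and frame).  All
#' intermediates are stored so each stage can be tested against its oracle.
#'
#' @param spec a [phantom_spec()].
#' @param subject subject index in `1:n_subjects`; together with
#'   `spec$seed` it determines every random draw.
#' @return An object of class `phantom_dataset`: `labels`, `truth`
#'   (parameter maps), `cp` (plasma input function), `conc` and `signal`
#'   (noiseless `dynamic_series`), `signal_noisy`, `sa`/`sb` pre-contrast
#'   flip-angle images (noiseless and noisy), `relax` (true T10/M0 maps),
#'   `vif_center`, `brain` mask, `sigma_abs` (absolute noise sd), `spec`,
#'   `subject`.
#' @export
simulate_dataset <- function(spec, subject = 1L) {
  stopifnot(inherits(spec, "phantom_spec"),
            subject >= 1, subject <= spec$n_subjects)
  base_seed <- spec$seed * 1000L + as.integer(subject)
  labels <- make_tissue_map(spec$shape, base_seed)
  truth <- sample_parameters(labels, spec, base_seed)
  params <- spec$params
  times <- frame_times(params)
  cp <- population_aif(times, spec,
                       subject_seed = if (spec$aif_jitter > 0) base_seed + 2000L else NULL)
  brain <- labels > 0
  nt <- length(times)
  d4 <- c(spec$shape, nt)

  # per-voxel tissue curves
  g <- kinetic_grid(cp)
  w <- trapz_weights(g$t)
  conc <- array(0, d4)
  idx <- which(brain)
  if (spec$model == "patlak") {
    auc <- as.numeric(w %*% g$cp)
    cmat <- cbind(truth$vp[idx]) %*% rbind(g$cp) +
      cbind(truth$ktrans[idx]) %*% rbind(auc)
  } else {
    cmat <- etofts_forward_rows(truth$ktrans[idx], truth$kep[idx],
                                truth$vp[idx], g$cp, g$t)
  }
  for (f in seq_len(nt)) {
    sl <- array(0, spec$shape)
    sl[idx] <- cmat[, f]
    conc[, , , f] <- sl
  }
  conc <- dynamic_series(conc, times, "concentration_mM")

  # relaxation maps and pre-contrast images
  t10 <- array(NA_real_, spec$shape)
  for (tis in names(PHANTOM_LABELS)[-1])
    t10[labels == PHANTOM_LABELS[[tis]]] <- spec$t10[[tis]]
  m0 <- array(NA_real_, spec$shape)
  m0[brain] <- spec$m0
  relax <- new_relaxation_maps(t10, m0 = m0, valid = brain)
  sb <- array(0, spec$shape)
  sb[brain] <- spgr_signal(m0[brain], t10[brain], params$alpha_b, params$tr)
  sa <- array(0, spec$shape)
  sa[brain] <- spgr_signal(m0[brain], t10[brain], params$alpha_a, params$tr)

  signal <- spgr_forward(conc, sb, relax, params)
  signal$values[array(!brain, d4)] <- 0

  sigma_abs <- spec$sigma * mean(sb[brain])
  rng <- local_rng(base_seed + 3000L)
  noisy <- signal
  sa_noisy <- sa; sb_noisy <- sb
  if (spec$sigma > 0) {
    noisy$values <- signal$values +
      array(rng$rnorm(prod(d4), 0, sigma_abs), d4)
    sa_noisy <- sa + array(rng$rnorm(prod(spec$shape), 0, sigma_abs), spec$shape)
    sb_noisy <- sb + array(rng$rnorm(prod(spec$shape), 0, sigma_abs), spec$shape)
  }
  structure(list(labels = labels, truth = truth, cp = cp, conc = conc,
                 signal = signal, signal_noisy = noisy,
                 sa = sa, sb = sb, sa_noisy = sa_noisy, sb_noisy = sb_noisy,
                 relax = relax, vif_center = attr(labels, "vif_center"),
                 brain = brain, sigma_abs = sigma_abs, spec = spec,
                 subject = as.integer(subject)),
            class = "phantom_dataset")
}

# eTofts forward for many voxels at once; theta vectors indexed by row.
# Looping over frames keeps every exponent non-positive (no overflow for
# large kep) while staying vectorized over voxels.
etofts_forward_rows <- function(ktrans, kep, vp, cp, t) {
  w <- trapz_weights(t)
  n <- length(ktrans); nt <- length(t)
  out <- matrix(0, n, nt)
  for (j in seq_len(nt)) {
    k <- seq_len(j)
    ek <- exp(-outer(kep, t[j] - t[k]))          # n x j, exponents <= 0
    out[, j] <- vp * cp[j] + ktrans * as.numeric(ek %*% (w[j, k] * cp[k]))
  }
  out
}

#' @export
print.phantom_dataset <- function(x, ...) {
  d <- x$spec$shape
  cat(sprintf("Phantom dataset (subject %d, %s model, seed %d)\n",
              x$subject, x$spec$model, x$spec$seed))
  cat(sprintf("  grid %d x %d x %d, %d frames, noise sigma = %.3g (abs %.3g)\n",
              d[1], d[2], d[3], length(x$conc$times), x$spec$sigma, x$sigma_abs))
  tab <- table(factor(x$labels, levels = PHANTOM_LABELS,
                      labels = names(PHANTOM_LABELS)))
  print(tab)
  invisible(x)
}

#' Simulate a multi-subject phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @return List of `phantom_dataset`, one per subject.
#' @export
simulate_cohort <- function(spec) {
  lapply(seq_len(spec$n_subjects), function(s) simulate_dataset(spec, s))
}
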