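#' @name io
#' @title Volume I/O, configuration and run manifests
#'
#' @description NIfTI is the on-disk format for all 3D/4D images (via the
#' RNifti reader, preserving the affine); input functions travel as
#' 2-column delimited text; run configuration is YAML; every pipeline stage
#' writes a JSON manifest recording the configuration hash, seed and input
#' checksums so each artifact is reproducible from its manifest.
#' Voxel indices are 1-based at the R interface; the time axis is the 4th
#' dimension.
NULL

#' Read a 4D NIfTI volume as a dynamic series
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param times optional time axis (seconds); default built from `params`.
#' @param params an [acq_params()] used to construct frame times when
#'   `times` is missing.
#' @param quantity stored quantity.
#' @return A `dynamic_series`; the NIfTI affine is kept in attribute
#'   `affine`.
#' @export
read_nifti_4d <- function(path, times = NULL, params = acq_params(),
                          quantity = "signal") {
  img <- RNifti::readNifti(path)
  a <- RNifti::xform(img)
  v <- array(as.numeric(img), dim(img))
  if (length(dim(v)) != 4L)
    stop("expected a 4D volume, got ", length(dim(v)), "D: ", path)
  if (is.null(times)) {
    if (dim(v)[4] != params$n_frames)
      stop("volume has ", dim(v)[4], " frames; acquisition expects ",
           params$n_frames)
    times <- frame_times(params)
  }
  out <- dynamic_series(v, times, quantity)
  attr(out, "affine") <- a
  out
}

#' Read a 3D NIfTI map
#' @param path NIfTI file.
#' @return 3D numeric array with attribute `affine`.
#' @export
read_nifti_3d <- function(path) {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim(img))
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)  # single-slice volume
  if (length(dim(v)) != 3L)
    stop("expected a 3D volume, got ", length(dim(v)), "D: ", path)
  attr(v, "affine") <- RNifti::xform(img)
  v
}

#' Write an array or dynamic series as NIfTI
#' @param x 3D/4D array or `dynamic_series`.
#' @param path output file.
#' @param affine optional 4x4 affine (defaults to the `affine` attribute or
#'   identity).
#' @return The path, invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL) {
  if (inherits(x, "dynamic_series")) {
    affine <- affine %||% attr(x, "affine")
    x <- x$values
  }
  affine <- affine %||% attr(x, "affine") %||% diag(4)
  img <- RNifti::asNifti(unclass(x))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' YAML configuration with a fixed schema: top-level blocks `acquisition`,
#' `model`, `fitting`, `network`, `training`, `phantom`, `paths`, `seed`.
#' Unknown keys are rejected; missing mandatory keys raise an error naming
#' the key.
#'
#' @param path YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("acquisition", "model", "fitting", "network", "training",
               "phantom", "paths", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("missing mandatory configuration key: seed")
  acq_allowed <- c("tr", "alpha_a", "alpha_b", "r1", "frame_interval",
                   "n_frames", "hct")
  if (!is.null(cfg$acquisition)) {
    bad <- setdiff(names(cfg$acquisition), acq_allowed)
    if (length(bad))
      stop("unknown acquisition key(s): ", paste(bad, collapse = ", "))
    cfg$params <- do.call(acq_params, cfg$acquisition)
  } else cfg$params <- acq_params()
  class(cfg) <- "run_config"
  cfg
}

# md5 of an object via its serialized representation
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Write a JSON run manifest
#'
#' Records the subcommand, configuration (and its hash), seed, package
#' version, input file checksums and output files of a pipeline stage.
#'
#' @param path manifest output path.
#' @param command stage name.
#' @param config configuration list.
#' @param seed integer seed used.
#' @param inputs character vector of input file paths (checksummed).
#' @param outputs character vector of files written.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, inputs = character(),
                           outputs = character()) {
  man <- list(command = command,
              package_version = as.character(utils::packageVersion("dcetk")),
              seed = seed,
              config = config,
              config_hash = hash_obj(config),
              inputs = as.list(tools::md5sum(inputs)),
              outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(man)
}
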