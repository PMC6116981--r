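#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return Object of class `mri_volume`: list with `data` (array),
#'   `affine` (4x4, voxel index to world mm) and `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read '%s' as NIfTI: %s",
                                 path, conditionMessage(e))))
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(img))
  structure(list(data = dat, affine = aff,
                 voxel_size = sqrt(colSums(aff[1:3, 1:3]^2))),
            class = "mri_volume")
}

#' Write an array as a NIfTI-1 volume
#'
#' Lossless round trip of data and affine: the affine is stored in the
#' sform (code 2) and the data as float64.
#'
#' @param data 3-D or 4-D numeric array, or an `mri_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 affine; ignored when `data` is an `mri_volume`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, affine = diag(4)) {
  if (inherits(data, "mri_volume")) {
    affine <- data$affine
    data <- data$data
  }
  stopifnot(length(dim(data)) %in% c(3L, 4L), all(dim(affine) == c(4, 4)))
  img <- RNifti::asNifti(data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# defaults shared by the YAML config and the in-memory pipeline entry
.default_config_list <- function() {
  pr <- default_protocols()
  list(
    protocols = list(
      low  = list(tr = pr$low$tr, flip_nominal = pr$low$flip_nominal,
                  te = pr$low$te),
      high = list(tr = pr$high$tr, flip_nominal = pr$high$flip_nominal,
                  te = pr$high$te),
      afi  = list(tr1 = pr$afi$tr1, tr2 = pr$afi$tr2,
                  flip_nominal = pr$afi$flip_nominal)),
    fit = unclass(fit_config())[
      c("n_echoes", "t1_max", "t2star_max", "t1_tol", "q_threshold",
        "min_echoes", "b1_median_filter", "bias_poly_order", "bias_k")],
    normalization = list(csf_prob_min = 0.99, t1_min = 2900,
                         t2star_min = 500, ellipsoid = NULL),
    paths = list(low = NULL, high = NULL, afi_s1 = NULL, afi_s2 = NULL,
                 b1plus = NULL, b1minus = NULL, csf_prob = NULL,
                 output_dir = NULL),
    seed = 1L)
}

#' Pipeline configuration
#'
#' Nested list of every tunable of the processing chain, initialised to
#' the method defaults (N = 3 echoes, clips 6000 ms / 1500 ms,
#' normalisation thresholds 0.99 / 2900 ms / 500 ms, dephasing cutoff
#' 0.5 cycles) and overridable field by field.
#'
#' @param ... Named overrides merged recursively into the defaults, e.g.
#'   `fit = list(t1_max = 5000)`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config_list()
  overrides <- list(...)
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      else base[nm] <- upd[nm]
    }
    base
  }
  cfg <- merge_in(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round trips losslessly: unknown keys are preserved, missing keys take
#' their defaults on reading.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Export a phantom as NIfTI truth maps plus a sidecar config
#'
#' Writes one volume per truth map (`h2o`, `t1`, `t2star`, `b1plus`,
#' `b1minus`, optionally `delta_f`, and integer `labels`) and a YAML
#' sidecar with voxel size, noise level and seed.
#'
#' @param phantom An `mri_phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "mri_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- phantom_affine(phantom)
  maps <- c("h2o", "t1", "t2star", "b1plus", "b1minus")
  if (!is.null(phantom$delta_f)) maps <- c(maps, "delta_f")
  for (m in maps)
    write_volume(phantom[[m]], file.path(dir, paste0(m, ".nii.gz")), aff)
  if (!is.null(phantom$labels))
    write_volume(array(as.numeric(phantom$labels), phantom$dim),
                 file.path(dir, "labels.nii.gz"), aff)
  yaml::write_yaml(list(voxel_size = phantom$voxel_size,
                        noise_sigma = phantom$noise_sigma,
                        seed = phantom$seed,
                        has_delta_f = !is.null(phantom$delta_f)),
                   file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  side <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  rd <- function(m) read_volume(file.path(dir, paste0(m, ".nii.gz")))$data
  delta_f <- if (isTRUE(side$has_delta_f)) rd("delta_f") else NULL
  labels_path <- file.path(dir, "labels.nii.gz")
  labels <- if (file.exists(labels_path))
    array(as.integer(round(read_volume(labels_path)$data)),
          dim(rd("h2o"))) else NULL
  phantom_spec(rd("h2o"), rd("t1"), rd("t2star"), rd("b1plus"),
               rd("b1minus"), delta_f = delta_f,
               voxel_size = as.numeric(side$voxel_size),
               noise_sigma = side$noise_sigma %||% 0,
               seed = side$seed, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
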