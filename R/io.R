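#' Write a voxel time-series set as a 4D NIfTI volume
#'
#' Voxels are placed back on the source grid by their 3D coordinates
#' (column-major order); background voxels are 0.  The TR is stored in the
#' header (`pixdim[4]`).
#'
#' @param ts a [voxel_ts()] with a `voxel_index`.
#' @param path output `.nii` / `.nii.gz` path.
#' @param shape 3D grid dimensions.
#' @return the path, invisibly.
#' @export
write_epi <- function(ts, path, shape) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (is.null(ts$voxel_index))
    stop("'ts' carries no voxel coordinates")
  n_vol <- ncol(ts$data)
  arr <- array(0, dim = c(shape, n_vol))
  lin <- as.vector((ts$voxel_index[, 1L]) +
                   (ts$voxel_index[, 2L] - 1L) * shape[1L] +
                   (ts$voxel_index[, 3L] - 1L) * shape[1L] * shape[2L])
  nvox_grid <- prod(shape)
  for (v in seq_len(n_vol))
    arr[lin + (v - 1L) * nvox_grid] <- ts$data[, v]
  attr(arr, "pixdim") <- c(1, 1, 1, ts$tr)
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Read a 4D EPI NIfTI volume into a voxel time-series set
#'
#' Extracts the masked voxels in column-major (R array) order — the order
#' round-trips exactly through [write_epi()] / [map_to_volume()].  The TR is
#' taken from the header `pixdim[4]` unless overridden.
#'
#' @param path a 4D NIfTI file.
#' @param mask optional logical 3D array / vector selecting voxels; default
#'   all voxels.
#' @param tr TR override in seconds; required if the header holds none.
#' @return a [voxel_ts()]; the grid dimensions are attached as attribute
#'   `"shape"`.
#' @export
read_epi <- function(path, mask = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI volume, got ", length(dim(arr)), "D: ", path)
  shape <- dim(arr)[1:3]
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 4L || !is.finite(pd[4L]) || pd[4L] <= 0)
      stop("no usable TR in the NIfTI header (pixdim[4] = ",
           if (length(pd) >= 4L) pd[4L] else "absent",
           "); supply 'tr' explicitly")
    tr <- pd[4L]
  }
  nvox <- prod(shape)
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  mask <- as.logical(mask)
  if (length(mask) != nvox)
    stop("mask has ", length(mask), " voxels but the volume grid has ", nvox)
  sel <- which(mask)
  dat <- matrix(arr, nrow = nvox)[sel, , drop = FALSE]
  out <- voxel_ts(dat, tr = tr, voxel_index = arrayInd(sel, shape))
  attr(out, "shape") <- shape
  out
}

#' Place per-voxel values back on the volume grid
#'
#' @param values one value per voxel.
#' @param voxel_index voxels x 3 coordinate matrix.
#' @param shape 3D grid dimensions.
#' @param background fill value outside the voxel set (default 0).
#' @return a 3D array.
#' @export
map_to_volume <- function(values, voxel_index, shape, background = 0) {
  arr <- array(background, dim = shape)
  lin <- voxel_index[, 1L] + (voxel_index[, 2L] - 1L) * shape[1L] +
    (voxel_index[, 3L] - 1L) * shape[1L] * shape[2L]
  arr[lin] <- values
  arr
}

write_map_nifti <- function(values, voxel_index, shape, path) {
  img <- RNifti::asNifti(map_to_volume(values, voxel_index, shape),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write parameter-estimate, p-value and residual maps as 3D NIfTI images
#'
#' One file per quantity (`alpha`, `beta_r`, `beta_c`, `p_alpha`,
#' `p_beta_r`, `p_beta_c`, `residual_rms`), background 0, plus a binary
#' `mask` image marking the voxels that were fit.
#'
#' @param pe_maps a [fit_spatial_glm()] result.
#' @param voxel_index voxels x 3 coordinate matrix.
#' @param shape 3D grid dimensions.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return named vector of file paths, invisibly.
#' @export
write_pe_maps <- function(pe_maps, voxel_index, shape, dir, prefix = "") {
  stopifnot(inherits(pe_maps, "pe_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fields <- c("alpha", "beta_r", "beta_c",
              "p_alpha", "p_beta_r", "p_beta_c", "residual_rms")
  paths <- character(0)
  for (f in fields) {
    p <- file.path(dir, paste0(prefix, f, ".nii.gz"))
    write_map_nifti(pe_maps[[f]], voxel_index, shape, p)
    paths[f] <- p
  }
  p <- file.path(dir, paste0(prefix, "mask.nii.gz"))
  write_map_nifti(rep(1, nrow(voxel_index)), voxel_index, shape, p)
  paths["mask"] <- p
  invisible(paths)
}

#' Read a physiological trace from plain text
#'
#' Accepts a single-column file of samples or a two-column (time, value)
#' file.  The sampling rate comes from, in order of precedence: the
#' `sampling_rate_hz` argument, a JSON sidecar `<path>.json` with a
#' `sampling_rate_hz` field, or (two-column input) the median time step.
#'
#' @param path text file.
#' @param sampling_rate_hz optional explicit sampling rate.
#' @param modality `"cardiac"` or `"respiratory"`.
#' @return a [physio_trace()].
#' @export
read_physio_trace <- function(path, sampling_rate_hz = NULL,
                              modality = c("cardiac", "respiratory")) {
  modality <- match.arg(modality)
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) > 2L) stop("expected 1 or 2 columns in ", path)
  if (is.null(sampling_rate_hz)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      sampling_rate_hz <- meta$sampling_rate_hz
    } else if (ncol(tab) == 2L) {
      sampling_rate_hz <- 1 / stats::median(diff(tab[[1L]]))
    }
    if (is.null(sampling_rate_hz))
      stop("no sampling rate: supply 'sampling_rate_hz', a '", sidecar,
           "' sidecar, or a two-column (time, value) file")
  }
  physio_trace(tab[[ncol(tab)]], sampling_rate_hz, modality)
}

#' Write a physiological trace with its JSON sidecar
#'
#' @param trace a [physio_trace()].
#' @param path output text file (one sample per line); the sampling rate
#'   and modality go to `<path>.json`.
#' @return the path, invisibly.
#' @export
write_physio_trace <- function(trace, path) {
  stopifnot(inherits(trace, "physio_trace"))
  utils::write.table(data.frame(trace$samples), path,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = trace$sampling_rate_hz,
                            modality = trace$modality),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write refined regressor spectra as two-column tabular text
#'
#' One file per regressor (`cardiac.tsv`, `respiratory.tsv`), columns
#' `frequency_hz` and `amplitude`.
#'
#' @param regressors a [spectral_regressors()].
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_spectra <- function(regressors, dir) {
  stopifnot(inherits(regressors, "spectral_regressors"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c(cardiac = file.path(dir, "cardiac.tsv"),
           respiratory = file.path(dir, "respiratory.tsv"))
  utils::write.table(
    data.frame(frequency_hz = regressors$frequencies_hz,
               amplitude = regressors$xc),
    out["cardiac"], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(frequency_hz = regressors$frequencies_hz,
               amplitude = regressors$xr),
    out["respiratory"], sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Tissue mask from a PVE NIfTI image
#'
#' @param path 3D NIfTI of partial-volume estimates in `[0, 1]`.
#' @param threshold minimum PVE (strict `>`; default 0.7).
#' @param label tissue label.
#' @return a [tissue_mask()] over the full grid (column-major voxel order);
#'   grid dimensions attached as attribute `"shape"`.
#' @export
build_mask_from_pve <- function(path, threshold = 0.7,
                                label = c("grey", "white", "other")) {
  label <- match.arg(label)
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  if (length(d) > 3L) stop("expected a 3D PVE volume: ", path)
  d <- c(d, rep(1L, 3L - length(d)))  # trailing singleton dims may be dropped
  out <- tissue_mask(as.vector(arr), threshold = threshold, label = label)
  attr(out, "shape") <- d
  out
}

#' Validated run configuration for the end-to-end pipeline
#'
#' Collects every fixed analysis constant: band edge `fmin_hz` (0.2 Hz),
#' data-driven split (0.6 Hz), convergence tolerance (0.01), iteration cap
#' (50), per-voxel significance threshold (p < 0.01), PVE threshold (0.7)
#' and pulsatility window (0.04 Hz).
#'
#' @param epi path to the 4D EPI NIfTI.
#' @param pve path to the tissue PVE NIfTI.
#' @param out output directory.
#' @param cardiac,respiratory optional trace file paths (informed mode).
#' @param mode `"informed"` or `"data_driven"`.
#' @param tr optional TR override in seconds.
#' @param fmin_hz,split_hz,tolerance,max_iter,p_threshold,pve_threshold,window_hz
#'   analysis constants (defaults above).
#' @param trace_rate_hz optional sampling-rate override for the trace files.
#' @param seed RNG seed recorded in the provenance log.
#' @return class `"run_config"`.
#' @export
run_config <- function(epi, pve, out,
                       cardiac = NULL, respiratory = NULL,
                       mode = c("data_driven", "informed"), tr = NULL,
                       fmin_hz = 0.2, split_hz = 0.6, tolerance = 0.01,
                       max_iter = 50L, p_threshold = 0.01,
                       pve_threshold = 0.7, window_hz = 0.04,
                       trace_rate_hz = NULL, seed = 1L) {
  mode <- match.arg(mode)
  for (nm in c("fmin_hz", "split_hz", "tolerance", "p_threshold",
               "pve_threshold", "window_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) stop("'", nm, "' must be positive")
  }
  if (mode == "data_driven" && fmin_hz >= split_hz)
    stop("need fmin_hz < split_hz for data-driven mode")
  if (mode == "informed" && (is.null(cardiac) || is.null(respiratory)))
    stop("informed mode requires 'cardiac' and 'respiratory' trace files")
  for (p in c(epi, pve, cardiac, respiratory))
    if (!file.exists(p)) stop("input not found: ", p)
  structure(list(epi = epi, pve = pve, out = out, cardiac = cardiac,
                 respiratory = respiratory, mode = mode, tr = tr,
                 fmin_hz = fmin_hz, split_hz = split_hz,
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 p_threshold = p_threshold, pve_threshold = pve_threshold,
                 window_hz = window_hz, trace_rate_hz = trace_rate_hz,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full spectral dual-regression pipeline
#'
#' Reads the EPI volume and PVE map, builds the tissue mask, computes
#' normalized band spectra, validates the configuration against the data's
#' Nyquist frequency, runs the dual regression in the configured mode, and
#' writes PE/p/residual maps (NIfTI), refined spectra and iteration trace
#' (tabular text), the metrics report and a provenance log (JSON) into the
#' output directory.  Deterministic given the configuration.
#'
#' @param config a [run_config()].
#' @return the [metrics_report()], invisibly, with the fit attached as
#'   attribute `"fit"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  mask <- stage("mask", build_mask_from_pve(config$pve,
                                            threshold = config$pve_threshold))
  shape <- attr(mask, "shape")
  ts <- stage("load_epi", read_epi(config$epi, mask = mask$members,
                                   tr = config$tr))
  nyq <- 1 / (2 * ts$tr)
  if (config$fmin_hz >= nyq)
    stop("pipeline stage 'config': fmin_hz (", config$fmin_hz,
         ") is not below the Nyquist frequency (",
         format(nyq, digits = 4), " Hz)")
  spectra <- stage("spectra",
                   band_normalize(amplitude_spectrum(ts),
                                  fmin = config$fmin_hz))
  external <- NULL
  if (config$mode == "informed") {
    cardiac <- stage("traces", read_physio_trace(
      config$cardiac, sampling_rate_hz = config$trace_rate_hz, "cardiac"))
    respiratory <- stage("traces", read_physio_trace(
      config$respiratory, sampling_rate_hz = config$trace_rate_hz,
      "respiratory"))
    external <- stage("informed_init",
                      informed_init(cardiac, respiratory, tr = ts$tr,
                                    n_volumes = ncol(ts$data),
                                    fmin = config$fmin_hz))
    fit <- stage("dualreg", dualreg(spectra, init = external,
                                    tolerance = config$tolerance,
                                    max_iter = config$max_iter))
    fit$init_mode <- "informed"
  } else {
    fit <- stage("dualreg", dualreg(spectra, mode = "data_driven",
                                    split_hz = config$split_hz,
                                    tolerance = config$tolerance,
                                    max_iter = config$max_iter))
  }
  mask_fit <- tissue_mask(mask$pve[mask$members],
                          threshold = config$pve_threshold,
                          label = mask$label)
  report <- stage("metrics",
                  metrics_report(fit, mask_fit, external = external,
                                 p_threshold = config$p_threshold,
                                 window_hz = config$window_hz))

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  stage("write", {
    write_pe_maps(fit$pe_maps, ts$voxel_index, shape,
                  file.path(config$out, "maps"))
    write_spectra(fit$regressors, file.path(config$out, "spectra"))
    utils::write.table(
      data.frame(iteration = seq_len(fit$n_iterations), fit$change_trace),
      file.path(config$out, "iteration_trace.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      c(unclass(report),
        list(mode = config$mode, tolerance = config$tolerance,
             max_iter = config$max_iter, fmin_hz = config$fmin_hz,
             split_hz = config$split_hz, seed = config$seed,
             tr = ts$tr, n_volumes = ncol(ts$data),
             nyquist_hz = nyq)),
      file.path(config$out, "report.json"), auto_unbox = TRUE, digits = NA)
  })
  attr(report, "fit") <- fit
  invisible(report)
}
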