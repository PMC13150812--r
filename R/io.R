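# drop S3 classes recursively so configuration trees serialize as plain JSON
.unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(unclass(x), .unclass_deep)
  else if (is.data.frame(x)) x
  else unclass(x)
}

#' Run manifest
#'
#' Provenance record embedded in every output container: configuration
#' content, seed, package version, timestamp and the invoking command.
#' Reruns from an identical manifest reproduce stochastic outputs
#' bit-for-bit because all randomness flows from the recorded seed.
#'
#' @param cfg,sim Configurations to record (optional).
#' @param seed Seed in force.
#' @param command Free-form command-line string.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(cfg = NULL, sim = NULL, seed = NULL, command = "") {
  structure(list(
    package = "swim2dms",
    version = as.character(utils::packageVersion("swim2dms")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, command = command,
    config = if (!is.null(cfg)) unclass(cfg),
    sim = if (!is.null(sim)) unclass(sim)),
    class = "run_manifest")
}

#' Write/read a data cube container
#'
#' The cube container is a raw little-endian float64 matrix (row-major,
#' index-fastest) beside a JSON sidecar `<path>.json` holding the axes,
#' dimensions, configurations and manifest, so the roundtrip is lossless.
#'
#' @param cube A `data_cube`.
#' @param path Path of the binary matrix file (sidecar written alongside).
#' @param manifest Optional [run_manifest()].
#' @return `write_cube` returns `path` invisibly; `read_cube` a `data_cube`.
#' @export
write_cube <- function(cube, path, manifest = NULL) {
  stopifnot(inherits(cube, "data_cube"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(cube$intensities)), con, size = 8, endian = "little")
  side <- list(format = "swim2dms-cube-v1",
               n_indices = nrow(cube$intensities),
               n_bins = ncol(cube$intensities),
               product_axis = cube$product_axis,
               index_axis = cube$index_axis,
               meta = .unclass_deep(cube$meta[setdiff(names(cube$meta),
                                                      "peaks")]),
               manifest = if (!is.null(manifest)) .unclass_deep(manifest))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing cube sidecar file: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("n_indices", "n_bins", "product_axis"))
    if (is.null(side[[f]])) stop("cube sidecar is missing field: ", f)
  n <- side$n_indices * side$n_bins
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(vals) != n) stop("cube payload truncated: expected ", n, " values")
  structure(list(intensities = matrix(vals, nrow = side$n_indices,
                                      byrow = TRUE),
                 product_axis = side$product_axis,
                 index_axis = if (!is.null(side$index_axis)) side$index_axis
                              else seq_len(side$n_indices) - 1L,
                 meta = side$meta),
            class = "data_cube")
}

#' CSV import/export for small cubes
#'
#' Plain-text cube: first column the SWIM index, remaining columns one per
#' product bin with the bin m/z in the header (`mz_<value>`).
#'
#' @inheritParams write_cube
#' @return `write_cube_csv` returns `path` invisibly; `read_cube_csv` a
#'   `data_cube`.
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "data_cube"))
  df <- data.frame(index = cube$index_axis, cube$intensities)
  names(df)[-1] <- paste0("mz_", format(cube$product_axis, trim = TRUE,
                                        digits = 12))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"index" %in% names(df) || ncol(df) < 2 ||
      !all(startsWith(names(df)[-1], "mz_")))
    stop("not a cube CSV: need an 'index' column and 'mz_*' bin columns")
  structure(list(intensities = as.matrix(df[, -1, drop = FALSE]),
                 product_axis = as.numeric(sub("^mz_", "", names(df)[-1])),
                 index_axis = df$index,
                 meta = list()),
            class = "data_cube")
}

#' Export a cube as mzML
#'
#' Writes one centroid-free spectrum per SWIM index (the index recorded as
#' the scan's acquisition number and retention time, in seconds at the index
#' rate) via the `mzR` Bioconductor backend.
#'
#' @param cube A `data_cube`.
#' @param path Output `.mzML` path.
#' @return `path` invisibly.
#' @export
export_mzml <- function(cube, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML export needs the mzR package")
  stopifnot(inherits(cube, "data_cube"))
  n <- nrow(cube$intensities)
  nb <- ncol(cube$intensities)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = nb,
    totIonCurrent = rowSums(cube$intensities),
    retentionTime = as.numeric(cube$index_axis),
    basePeakMZ = cube$product_axis[max.col(cube$intensities, "first")],
    basePeakIntensity = apply(cube$intensities, 1, max),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(cube$product_axis), highMZ = max(cube$product_axis),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("index=%d", seq_len(n) - 1L),
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  spectra <- lapply(seq_len(n), function(i)
    cbind(mz = cube$product_axis, intensity = cube$intensities[i, ]))
  mzR::writeMSData(spectra, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Import an mzML file written by [export_mzml()]
#'
#' @param path `.mzML` path.
#' @return A `data_cube` (intensities at float precision).
#' @export
read_mzml_cube <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML import needs the mzR package")
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  structure(list(intensities = do.call(rbind, lapply(pk, function(p) p[, 2])),
                 product_axis = pk[[1]][, 1],
                 index_axis = hdr$retentionTime,
                 meta = list(source = path)),
            class = "data_cube")
}

#' Write a 2D peak list as CSV
#'
#' @param peaks A `peaks2d` data frame.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}
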