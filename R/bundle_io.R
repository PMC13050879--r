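#' Write an epoch set to a canonical on-disk bundle
#'
#' The bundle is a directory holding one little-endian binary array per
#' field (`data.f64`, float64; `labels.i32`, int32) plus a JSON sidecar
#' (`sidecar.json`) recording dtype, shape, sampling metadata and a
#' `format_version` key. Arrays are written in R's column-major order of the
#' `[trial, channel, time]` array, so a round trip is bit-exact.
#'
#' @param epochs an `eeg_epochs` object; sets containing non-finite values
#'   are rejected before anything is written.
#' @param path directory to create (must not exist as a non-bundle file).
#' @return `path`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(epochs, path) {
  validate_epochs(epochs)  # refuses NaN/Inf before any I/O
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create bundle directory: ", path, call. = FALSE)
  }
  sidecar <- list(
    format_version = 1L,
    fields = list(
      data   = list(file = "data.f64", dtype = "float64",
                    shape = as.integer(dim(epochs$data))),
      labels = list(file = "labels.i32", dtype = "int32",
                    shape = length(epochs$labels))),
    fs = epochs$fs, t_start = epochs$t_start,
    channel_names = as.list(epochs$channel_names),
    normalized = epochs$normalized, meta = epochs$meta)
  con <- file(file.path(path, "data.f64"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  close(con)
  con <- file(file.path(path, "labels.i32"), "wb")
  writeBin(as.integer(epochs$labels), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(sidecar, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an epoch-set bundle written by [write_epochs()]
#'
#' Shapes declared in the sidecar are checked against the binary file sizes
#' before anything is materialised, so a truncated or inconsistent bundle
#' fails cleanly with no partial object. Loaded objects are re-validated
#' against the `eeg_epochs` invariants.
#'
#' @param path bundle directory.
#' @return an `eeg_epochs` object.
#' @export
read_epochs <- function(path) {
  sc_path <- file.path(path, "sidecar.json")
  if (!file.exists(sc_path))
    stop("not a bundle: missing sidecar.json in ", path, call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$format_version))
    stop("sidecar lacks a format_version field", call. = FALSE)
  shape <- as.integer(sc$fields$data$shape)
  if (length(shape) != 3L)
    stop("sidecar field `data`: shape must have 3 dimensions", call. = FALSE)
  n_lab <- as.integer(sc$fields$labels$shape)

  dfile <- file.path(path, sc$fields$data$file)
  lfile <- file.path(path, sc$fields$labels$file)
  for (f in c(dfile, lfile))
    if (!file.exists(f)) stop("bundle missing array file: ", f, call. = FALSE)
  if (file.size(dfile) != prod(shape) * 8)
    stop(sprintf(
      "field `data`: file holds %d bytes but sidecar shape [%s] needs %d",
      file.size(dfile), paste(shape, collapse = ", "), prod(shape) * 8),
      call. = FALSE)
  if (file.size(lfile) != n_lab * 4)
    stop(sprintf("field `labels`: file holds %d bytes, expected %d",
                 file.size(lfile), n_lab * 4), call. = FALSE)
  if (n_lab != shape[1L])
    stop(sprintf("field `labels`: %d labels for %d trials", n_lab, shape[1L]),
         call. = FALSE)

  con <- file(dfile, "rb")
  dat <- readBin(con, "double", n = prod(shape), size = 8L, endian = "little")
  close(con)
  con <- file(lfile, "rb")
  lab <- readBin(con, "integer", n = n_lab, size = 4L, endian = "little")
  close(con)
  meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
  eeg_epochs(array(dat, shape), lab, sc$fs,
             unlist(sc$channel_names, use.names = FALSE),
             t_start = sc$t_start %||% 0, meta = meta,
             normalized = isTRUE(sc$normalized))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import epoched trials from an EDF/GDF recording (optional)
#'
#' Thin optional shim around the Python `mne` reader: it extracts cue-locked
#' epochs from an EDF or GDF file and converts them to the canonical bundle.
#' It requires a `python` with `mne` on the PATH and is never needed by the
#' rest of the package — all analysis runs on bundles or in-memory
#' `eeg_epochs` (typically from [simulate_mi_eeg()]).
#'
#' @param path EDF/GDF file.
#' @param tmin,tmax epoch window in seconds relative to each event.
#' @param python python executable to use.
#' @return an `eeg_epochs` object.
#' @export
import_edf <- function(path, tmin = 0, tmax = 4, python = "python") {
  if (Sys.which(python) == "")
    stop("EDF/GDF import needs a `python` with mne installed", call. = FALSE)
  out <- tempfile("edf_bundle_")
  script <- sprintf(paste0(
    "import json, sys, numpy as np, mne, os\n",
    "raw = mne.io.read_raw(%s, preload=True, verbose='error')\n",
    "ev, ev_id = mne.events_from_annotations(raw, verbose='error')\n",
    "ep = mne.Epochs(raw, ev, tmin=%f, tmax=%f, baseline=None,\n",
    "                preload=True, verbose='error')\n",
    "X = ep.get_data() * 1e6\n",
    "y = ep.events[:, 2] - ep.events[:, 2].min()\n",
    "os.makedirs(%s, exist_ok=True)\n",
    "X.astype('<f8').tofile(os.path.join(%s, 'data.f64'))\n",
    "y.astype('<i4').tofile(os.path.join(%s, 'labels.i32'))\n",
    "sc = {'format_version': 1,\n",
    "      'fields': {'data': {'file': 'data.f64', 'dtype': 'float64',\n",
    "                          'shape': list(X.shape)},\n",
    "                 'labels': {'file': 'labels.i32', 'dtype': 'int32',\n",
    "                            'shape': int(len(y))}},\n",
    "      'fs': float(ep.info['sfreq']), 't_start': %f,\n",
    "      'channel_names': list(ep.ch_names), 'normalized': False,\n",
    "      'meta': {'source': %s}}\n",
    "json.dump(sc, open(os.path.join(%s, 'sidecar.json'), 'w'))\n"),
    deparse(path), tmin, tmax, deparse(out), deparse(out), deparse(out),
    tmin, deparse(basename(path)), deparse(out))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2(python, sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("mne import failed for ", path, call. = FALSE)
  x <- read_epochs(out)
  # arrays arrive C-ordered (time fastest within trial-major layout): reorder
  d <- dim(x$data)
  x$data <- aperm(array(as.vector(x$data), d[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
  validate_epochs(x)
  x
}
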