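# File-format glue: 32-bit float TIFF maps with JSON sidecars, 3-D TIFF
# histogram stacks, binary float32 waveforms, YAML run configs.

sidecarPath <- function(path) paste0(path, ".json")

# Power-of-two scale keeps integer-valued maps (counts, quantized dwells)
# exactly representable after the float32 round trip.
tiffScale <- function(mx) {
  if (mx <= 0) 1 else 2^ceiling(log2(mx))
}

#' Write / read a numeric map as 32-bit TIFF with a JSON sidecar
#'
#' Values are stored as \code{value / scale} in 32-bit TIFF samples with the
#' scale (a power of two just above the maximum) and units recorded in a
#' \code{<path>.json} sidecar, together with the package's pixel convention
#' (0-based, row-major, row = y). Integer-valued maps (counts, quantized
#' dwells) are flagged in the sidecar and round-trip exactly; arbitrary
#' doubles round-trip to 32-bit sample precision (~2e-10 relative).
#'
#' @param map numeric matrix.
#' @param path output TIFF path.
#' @param units free-text units string recorded in the sidecar.
#' @param meta optional named list merged into the sidecar.
#' @return \code{writeMapTiff}: the path, invisibly. \code{readMapTiff}: the
#'   matrix, with the sidecar attached as attribute \code{"meta"}.
#' @export
writeMapTiff <- function(map, path, units = "", meta = list()) {
  stopIfNot(is.matrix(map) && all(is.finite(map)), "map must be finite")
  stopIfNot(all(map >= 0), "maps are stored unsigned; values must be >= 0")
  sc <- tiffScale(max(map))
  tiff::writeTIFF(map / sc, path, bits.per.sample = 32, reduce = FALSE)
  side <- utils::modifyList(
    list(scale = sc, units = units, nrow = nrow(map), ncol = ncol(map),
         integral = all(map == round(map)),
         pixel_convention = "0-based, row-major, (row m, col n)"),
    meta)
  jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeMapTiff
#' @export
readMapTiff <- function(path) {
  side <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  raw <- tiff::readTIFF(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  out <- raw * side$scale
  if (isTRUE(side$integral)) out <- round(out)
  attr(out, "meta") <- side
  out
}

#' Export decay histograms as a 3-D TIFF stack
#'
#' Writes the per-pixel decay histograms of an acquisition as a multi-plane
#' 32-bit TIFF, one plane per time bin, with binning metadata in the
#' sidecar. Intended for small crops; pass \code{rows}/\code{cols} to crop.
#'
#' @param acq an [AcquisitionResult-class] with recorded histograms.
#' @param path output TIFF path.
#' @param rows,cols optional index vectors cropping the field.
#' @return the path, invisibly.
#' @export
exportHistogramStack <- function(acq, path, rows = NULL, cols = NULL) {
  stopIfNot(length(acq@hist) > 0, "acquisition has no recorded histograms")
  hs <- acq@hist
  if (!is.null(rows)) hs <- hs[rows, , , drop = FALSE]
  if (!is.null(cols)) hs <- hs[, cols, , drop = FALSE]
  sc <- tiffScale(max(hs))
  planes <- lapply(seq_len(dim(hs)[3]), function(b) hs[, , b] / sc)
  tiff::writeTIFF(planes, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(scale = sc, bin_width_ps = acq@binWidthPs, bins = dim(hs)[3],
         nrow = dim(hs)[1], ncol = dim(hs)[2]),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname exportHistogramStack
#' @export
readHistogramStack <- function(path) {
  side <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(side$nrow, side$ncol, side$bins))
  for (b in seq_along(planes)) arr[, , b] <- round(planes[[b]] * side$scale)
  attr(arr, "bin_width_ps") <- side$bin_width_ps
  arr
}

#' Write / read a scan waveform as binary float32 + JSON header
#'
#' \code{vx} and \code{vy} are interleaved little-endian float32; the JSON
#' header carries the sampling rate, voltage step, settling coefficient,
#' clock indices and pixel spans, so the waveform re-imports to an equal
#' in-memory object (voltages to float32 precision).
#'
#' @param w a [ScanWaveform-class].
#' @param path output binary path (header goes to \code{<path>.json}).
#' @return \code{writeWaveformBin}: the path, invisibly.
#'   \code{readWaveformBin}: the [ScanWaveform-class].
#' @export
writeWaveformBin <- function(w, path) {
  stopIfNot(is(w, "ScanWaveform"), "w must be a ScanWaveform")
  n <- length(w@vx)
  inter <- numeric(2 * n)
  if (n > 0) {
    inter[seq(1, 2 * n, 2)] <- w@vx
    inter[seq(2, 2 * n, 2)] <- w@vy
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(inter, con, size = 4, endian = "little")
  jsonlite::write_json(
    list(n = n, f = w@f, vs = w@vs, beta = w@beta,
         dwell_clock = which(w@dwellClock), line_clock = which(w@lineClock),
         pixel_spans = w@pixelSpans,
         layout = "interleaved float32 little-endian (vx, vy)"),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeWaveformBin
#' @export
readWaveformBin <- function(path) {
  side <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  n <- side$n
  con <- file(path, "rb"); on.exit(close(con))
  inter <- readBin(con, "numeric", n = 2 * n, size = 4, endian = "little")
  dc <- logical(n); dc[side$dwell_clock] <- TRUE
  lc <- logical(n); lc[side$line_clock] <- TRUE
  ps <- as.data.frame(side$pixel_spans)
  if (nrow(ps) == 0)
    ps <- data.frame(row = integer(0), col = integer(0), start = integer(0),
                     n = integer(0), settle = integer(0))
  new("ScanWaveform",
      vx = if (n > 0) inter[seq(1, 2 * n, 2)] else numeric(0),
      vy = if (n > 0) inter[seq(2, 2 * n, 2)] else numeric(0),
      f = side$f, dwellClock = dc, lineClock = lc, pixelSpans = ps,
      beta = side$beta, vs = side$vs)
}

#' Read a structured run configuration
#'
#' Loads a YAML config with blocks \code{phantom}, \code{acquisition},
#' \code{planner}, \code{scan}, \code{experiment} and top-level \code{seed}
#' and \code{outdir}, filling package defaults for anything omitted.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return a nested list with all defaults resolved.
#' @export
readRunConfig <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    seed = 1L,
    outdir = ".",
    phantom = list(generator = "two_species", shape = c(64L, 64L),
                   bright_rate = 8.71, dim_rate = 1.17,
                   tau_bright = 0.8, tau_dim = 2.5, dcr = 100),
    acquisition = list(rep_rate = 20e6, bin_width_ps = 100,
                       irf_sigma_ps = 40, t0_ns = 0.55),
    planner = list(i_target = 250, t_min = 50, t_max = 600, step = 1,
                   block = 32L, t_prescan = 100, roi_mode = "auto"),
    scan = list(vs_volts = 0.01, f_hz = 1e7, beta_factor = 0.02,
                smooth_window = 5L),
    experiment = list(mode = "enhance", estimator = "ls"))
  cfg <- utils::modifyList(defaults, user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

configAcqParams <- function(cfg) {
  a <- lapply(cfg$acquisition, as.numeric)   # YAML 1.1 may yield strings
  acqParams(repRate = a$rep_rate, binWidthPs = a$bin_width_ps,
            irfSigmaPs = a$irf_sigma_ps, t0Ns = a$t0_ns)
}
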