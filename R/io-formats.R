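# Reading time-lapse frame series (TIFF/PNG + filename metadata) and
# writing result tables, label masks and run manifests.

#' Default filename pattern for frame series
#'
#' Frames are named `<chamber>_<channel>_t<hours>_p<pair>.tif`, e.g.
#' `ch01_brightfield_t12_p0.tif`. The pattern is a regular expression with
#' exactly four capture groups, in order: chamber, channel, time (hours),
#' pair index.
#'
#' @export
defaultFramePattern <- function() {
  "^(.+)_(brightfield|fluorescence)_t([0-9.]+)_p([01])\\.(?:tif|tiff|png)$"
}

readImageFile <- function(path, normalization = c("bitdepth", "minmax")) {
  normalization <- match.arg(normalization)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", path))
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # first channel of RGB
  # readTIFF/readPNG already scale integer data by bit depth to [0,1]
  if (normalization == "minmax") {
    rg <- range(px)
    px <- if (diff(rg) > 0) (px - rg[1L]) / diff(rg) else px * 0
  }
  px
}

#' Load a time-lapse frame series
#'
#' Reads every image in `root` whose filename matches `pattern` (four
#' capture groups: chamber, channel, time in hours, pair index), normalizes
#' intensities, and returns the frames sorted by (chamber, time, pair,
#' channel).
#'
#' @param root directory holding the frames.
#' @param pattern regular expression with capture groups; see
#'   [defaultFramePattern()].
#' @param normalization `"bitdepth"` (integer images are scaled by their
#'   bit depth, so the maximal representable value maps to 1) or
#'   `"minmax"`.
#' @return list of [WormFrame-class], possibly empty (with a warning).
#' @export
loadSeries <- function(root, pattern = defaultFramePattern(),
                       normalization = c("bitdepth", "minmax")) {
  normalization <- match.arg(normalization)
  if (!dir.exists(root)) stop("input directory does not exist: ", root)
  files <- list.files(root, full.names = FALSE)
  files <- files[grepl(pattern, files, perl = TRUE)]
  if (!length(files)) {
    warning("no frames matching pattern in ", root)
    return(list())
  }
  m <- regmatches(files, regexec(pattern, files, perl = TRUE))
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    g <- m[[i]]
    if (length(g) < 5L)
      stop("filename does not parse against pattern: ", files[i])
    px <- readImageFile(file.path(root, files[i]), normalization)
    frames[[i]] <- new("WormFrame",
      pixels = pmin(pmax(px, 0), 1), channel = g[3L], chamberId = g[2L],
      timeH = as.numeric(g[4L]), pairIndex = as.integer(g[5L]),
      path = file.path(root, files[i]))
  }
  ord <- order(
    vapply(frames, chamberId, ""),
    vapply(frames, frameTime, 0),
    vapply(frames, pairIndex, 0L),
    vapply(frames, frameChannel, ""))
  frames <- frames[ord]
  key <- vapply(frames, function(f)
    paste(chamberId(f), frameChannel(f), frameTime(f), pairIndex(f)), "")
  if (anyDuplicated(key))
    stop("duplicate (chamber, channel, time, pair) keys in series")
  for (ch in unique(vapply(frames, chamberId, ""))) {
    dims <- unique(t(vapply(frames[vapply(frames, chamberId, "") == ch],
                            function(f) dim(framePixels(f)), c(0L, 0L))))
    if (nrow(dims) > 1L)
      stop("mixed image sizes within chamber ", ch)
  }
  frames
}

#' Write a frame to TIFF
#'
#' @param frame a [WormFrame-class].
#' @param dir output directory.
#' @return the file path written (named
#'   `<chamber>_<channel>_t<hours>_p<pair>.tif`, 16-bit grayscale).
#' @export
writeFrame <- function(frame, dir) {
  path <- file.path(dir, sprintf("%s_%s_t%g_p%d.tif",
    chamberId(frame), frameChannel(frame), frameTime(frame),
    pairIndex(frame)))
  tiff::writeTIFF(framePixels(frame), path, bits.per.sample = 16L)
  path
}

#' Write an integer label mask as 16-bit TIFF
#'
#' Worm counts are far below 65535, so labels are stored losslessly as
#' `label / 65535` in a 16-bit grayscale TIFF.
#'
#' @param labels integer matrix (0 = background).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLabelMask <- function(labels, path) {
  if (max(labels) > 65535L) stop("label values exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label mask written by [writeLabelMask()]
#'
#' @param path TIFF file.
#' @return integer matrix.
#' @export
readLabelMask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write all pipeline results
#'
#' Writes measurement and survival tables as CSV, label masks as 16-bit
#' TIFF, and a JSON run manifest (inputs, config hash, seed, file list).
#' Tables round-trip exactly through [readMeasurementTable()].
#'
#' @param outDir output directory (created if needed).
#' @param measurements per-worm measurement table (may be empty).
#' @param survivalTable survival-curve table (`t`, `S`, `SE`, `n_at_risk`),
#'   or `NULL`.
#' @param masks named list of integer label matrices, written as
#'   `mask_<name>.tif`.
#' @param manifest list of run metadata to store alongside (config, seed,
#'   hash); serialized to `manifest.json`.
#' @return character vector of files written (the manifest lists them too).
#' @export
writeResults <- function(outDir, measurements = NULL, survivalTable = NULL,
                         masks = list(), manifest = list()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  written <- character()
  if (!is.null(measurements)) {
    p <- file.path(outDir, "measurements.csv")
    write.csv(measurements, p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(survivalTable)) {
    p <- file.path(outDir, "survival.csv")
    write.csv(survivalTable, p, row.names = FALSE)
    written <- c(written, p)
  }
  for (nm in names(masks)) {
    p <- file.path(outDir, paste0("mask_", nm, ".tif"))
    writeLabelMask(masks[[nm]], p)
    written <- c(written, p)
  }
  manifest$files <- basename(written)
  manifest$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(written, mp)
}

#' Read back a measurement table written by [writeResults()]
#'
#' @param path CSV file.
#' @return data.frame with the original column types.
#' @export
readMeasurementTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

configHash <- function(config) {
  sanitize <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, sanitize)
      return(x[!vapply(x, is.null, NA)])
    }
    x
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(sanitize(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
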