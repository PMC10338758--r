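#' Raw frame layout description
#'
#' The cine `.raw` layout of EPID frame files varies between detector
#' generations, so the byte layout is configurable: header size, bytes per
#' pixel, endianness and scan order. The default is headerless 16-bit unsigned
#' little-endian, row-major. `invert = TRUE` applies the portal-image grayscale
#' convention in which 0 is white (open beam, high detector signal) and 1 is
#' black (blocked/attenuated), so implanted markers and the region outside the
#' aperture map toward 1.
#'
#' @param bytes_per_pixel 1 or 2.
#' @param header_bytes Bytes to skip before pixel data.
#' @param endian `"little"` or `"big"`.
#' @param invert Map low detector signal toward 1 (black) after min-max
#'   normalization.
#' @return An object of class `raw_dialect`.
#' @export
raw_dialect <- function(bytes_per_pixel = 2L, header_bytes = 0L,
                        endian = c("little", "big"), invert = TRUE) {
  endian <- match.arg(endian)
  stopifnot(bytes_per_pixel %in% c(1L, 2L), header_bytes >= 0)
  structure(
    list(bytes_per_pixel = as.integer(bytes_per_pixel),
         header_bytes = as.integer(header_bytes),
         endian = endian, invert = isTRUE(invert)),
    class = "raw_dialect"
  )
}

#' Construct a normalized EPID frame
#'
#' @param pixels Square numeric matrix with values in `[0, 1]`, 0 = white
#'   (open beam) and 1 = black (blocked), rows along the tilt axis and columns
#'   along the pan axis.
#' @param index 1-based position within the acquisition series.
#' @param frame_rate_hz Acquisition rate used to stamp `time_s`.
#' @return An object of class `epid_image` with fields `pixels`, `index` and
#'   `time_s = (index - 1) / frame_rate_hz`.
#' @export
epid_image <- function(pixels, index = 1L, frame_rate_hz = 2.0) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  if (!all(is.finite(pixels))) stop("epid_image: non-finite pixel values")
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("epid_image: pixel values must lie in [0, 1]")
  index <- as.integer(index)
  if (index < 1L) stop("epid_image: index must be >= 1")
  structure(
    list(pixels = pixels, index = index,
         time_s = (index - 1L) / frame_rate_hz),
    class = "epid_image"
  )
}

#' @export
print.epid_image <- function(x, ...) {
  cat(sprintf("EPID frame #%d (t = %.2f s), %d x %d px, range [%.3f, %.3f]\n",
              x$index, x$time_s, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

.as_pixels <- function(image) {
  if (inherits(image, "epid_image")) image$pixels else image
}

# Min-max normalization of raw detector counts into the [0,1] grayscale
# convention. Affine-invariant: positive rescaling of the counts leaves the
# result unchanged.
.normalize_counts <- function(counts, invert = TRUE) {
  rng <- range(counts)
  if (rng[2] <= rng[1])
    stop("degenerate image: frame has no contrast (all pixel values equal)")
  g <- (counts - rng[1]) / (rng[2] - rng[1])
  if (invert) 1 - g else g
}

#' Read one raw binary EPID frame
#'
#' Reads a raw detector frame, min-max normalizes the counts and maps them into
#' the 0 (white) to 1 (black) grayscale convention (see [raw_dialect()]).
#'
#' @param path Path to the raw file.
#' @param dialect A [raw_dialect()].
#' @param geometry A [geometry_config()]; fixes the expected matrix size.
#' @param index Frame index within its series.
#' @return An [epid_image()].
#' @export
read_raw_frame <- function(path, dialect = raw_dialect(),
                           geometry = geometry_config(), index = 1L) {
  n_px <- geometry$matrix_size^2
  expected <- dialect$header_bytes + n_px * dialect$bytes_per_pixel
  actual <- file.size(path)
  if (is.na(actual)) stop(sprintf("cannot read raw frame '%s'", path))
  if (actual != expected)
    stop(sprintf(
      "raw frame '%s': expected %d bytes (%d header + %d^2 x %d), got %d",
      path, expected, dialect$header_bytes, geometry$matrix_size,
      dialect$bytes_per_pixel, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  if (dialect$header_bytes > 0) readBin(con, "raw", n = dialect$header_bytes)
  counts <- readBin(con, "integer", n = n_px, size = dialect$bytes_per_pixel,
                    signed = FALSE, endian = dialect$endian)
  m <- matrix(as.numeric(counts), nrow = geometry$matrix_size, byrow = TRUE)
  epid_image(.normalize_counts(m, dialect$invert), index = index,
             frame_rate_hz = geometry$frame_rate_hz)
}

#' Write one frame as a raw binary file
#'
#' Inverse of [read_raw_frame()]: quantizes a normalized grayscale frame to the
#' dialect's bit depth and writes it row-major. Round-trips exactly (within one
#' quantization step) for frames whose grayscale spans the full `[0, 1]` range,
#' which renderer output does by construction.
#'
#' @param image An [epid_image()] or a numeric matrix in `[0, 1]` (grayscale
#'   convention, 1 = black).
#' @param path Output path.
#' @param dialect A [raw_dialect()].
#' @return `path`, invisibly.
#' @export
write_raw_frame <- function(image, path, dialect = raw_dialect()) {
  g <- .as_pixels(image)
  vmax <- 2^(8L * dialect$bytes_per_pixel) - 1
  counts <- if (dialect$invert) (1 - g) * vmax else g * vmax
  counts <- round(counts)
  con <- file(path, "wb")
  on.exit(close(con))
  if (dialect$header_bytes > 0)
    writeBin(raw(dialect$header_bytes), con)
  # row-major scan order: transpose before writing column-wise
  writeBin(as.integer(t(counts)), con, size = dialect$bytes_per_pixel,
           endian = dialect$endian)
  invisible(path)
}

.read_one_frame <- function(path, dialect, geometry, index) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "raw")
    return(read_raw_frame(path, dialect, geometry, index))
  counts <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop(sprintf("unsupported frame format '%s' (%s)", ext, path))
  }
  if (length(dim(counts)) == 3L) counts <- counts[, , 1L]
  epid_image(.normalize_counts(counts, dialect$invert), index = index,
             frame_rate_hz = geometry$frame_rate_hz)
}

#' Read an ordered EPID image series
#'
#' Frames are taken either from a manifest (plain text, one path per line, or
#' a YAML list under the key `frames`) in manifest order, or from a directory
#' sorted by filename. Indices are assigned 1..N in acquisition order and
#' `time_s` follows from the frame rate.
#'
#' @param path Directory containing frames, or a manifest file.
#' @param metadata A [series_metadata()].
#' @param dialect A [raw_dialect()] used for `.raw` frames and for the
#'   grayscale polarity of TIFF/PNG frames.
#' @return An object of class `epid_series`: a list with `images` (list of
#'   [epid_image()]) and `metadata`.
#' @export
read_image_series <- function(path, metadata, dialect = raw_dialect()) {
  stopifnot(inherits(metadata, "series_metadata"))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(raw|tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    entries <- if (ext %in% c("yml", "yaml")) {
      y <- yaml::read_yaml(path)
      if (is.list(y) && !is.null(y$frames)) unlist(y$frames) else unlist(y)
    } else {
      readLines(path, warn = FALSE)
    }
    entries <- entries[nzchar(trimws(entries))]
    base <- dirname(path)
    files <- ifelse(grepl("^(/|[A-Za-z]:)", entries), entries,
                    file.path(base, entries))
  } else {
    stop(sprintf("series path '%s' does not exist", path))
  }
  if (length(files) == 0L) stop("no frames found in series")
  geom <- metadata$geometry
  images <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- .read_one_frame(files[i], dialect, geom, index = i)
    if (nrow(img$pixels) != nrow(images[[1]]$pixels %||% img$pixels))
      stop(sprintf("inconsistent frame dimensions at '%s'", files[i]))
    images[[i]] <- img
  }
  structure(list(images = images, metadata = metadata), class = "epid_series")
}

#' Write a rendered series to disk as raw frames
#'
#' @param images List of [epid_image()] (or an `epid_series`).
#' @param dir Output directory (created if needed).
#' @param dialect A [raw_dialect()].
#' @return Character vector of the files written, invisibly.
#' @export
write_image_series <- function(images, dir, dialect = raw_dialect()) {
  if (inherits(images, "epid_series")) images <- images$images
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%04d.raw", seq_along(images)))
  for (i in seq_along(images)) write_raw_frame(images[[i]], paths[i], dialect)
  invisible(paths)
}

.offsets_csv_header <- c("index", "time_s", "n_markers", "pan_mm", "tilt_mm",
                         "et_pan_mm", "et_tilt_mm", "et_2d_mm", "included",
                         "reason")

#' Write per-frame offsets and tracking errors as CSV
#'
#' One row per collected frame: acquisition index and time, detected marker
#' count, pan/tilt offsets of the marker COM relative to the aperture center
#' (mm at isocenter), the baseline-referenced tracking errors, an inclusion
#' flag and, for excluded frames, the exclusion reason (E_T cells left empty).
#'
#' @param series A `tracking_series` from [tracking_error_series()] or
#'   [analyze_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_offsets_csv <- function(series, path) {
  stopifnot(inherits(series, "tracking_series"))
  df <- series$offsets[, .offsets_csv_header]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back an offsets CSV written by [write_offsets_csv()]
#'
#' @param path CSV path.
#' @return A data frame with the fixed offsets-CSV columns.
#' @export
read_offsets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .offsets_csv_header))
    stop("not an offsets CSV: unexpected header")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
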