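# MLC aperture detection: half-maximum segmentation of the in-field region,
# Moore-neighbor boundary tracing emitting Freeman 8-direction chain codes,
# and the area-centroid aperture center.

# Half-maximum edge convention: threshold midway between the modal in-field
# and modal blocked grayscale values (64-bin histogram, modes taken on either
# side of the mid-range).
.halfmax_threshold <- function(x) {
  rng <- range(x)
  mid <- mean(rng)
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = 65L),
                      plot = FALSE)
  low <- h$mids <= mid
  m_lo <- h$mids[low][which.max(h$counts[low])]
  m_hi <- h$mids[!low][which.max(h$counts[!low])]
  (m_lo + m_hi) / 2
}

#' Segment the MLC-defined radiation field
#'
#' In the 0 (white) to 1 (black) grayscale convention the open field is bright
#' on the detector and therefore *low*-valued, so in-field pixels are those
#' below the edge threshold. The mask is the largest connected region below
#' the threshold, with interior holes (marker shadows) filled. The default
#' threshold follows the standard 50% field-edge convention: halfway between
#' the modal in-field and modal blocked grayscale values.
#'
#' A modal-contrast guard rejects frames whose "two modes" are closer than
#' `min_contrast`: per-frame min-max normalization stretches even a fully
#' blocked, noise-only frame across `[0, 1]`, but its half-split modal
#' separation stays well below that of a frame with a genuine aperture.
#'
#' @param image An [epid_image()] or numeric matrix in the grayscale
#'   convention.
#' @param edge_threshold Grayscale threshold; `NULL` (default) uses the
#'   half-maximum rule.
#' @param min_field_area_px2 Minimum plausible aperture area; smaller largest
#'   regions raise a no-field error.
#' @param min_contrast Minimum mean grayscale separation between the blocked
#'   and in-field regions.
#' @param connectivity 4 or 8 (default) for region connectivity.
#' @return Logical matrix of in-field pixels with attribute `threshold`.
#' @export
segment_field <- function(image, edge_threshold = NULL,
                          min_field_area_px2 = 400, min_contrast = 0.35,
                          connectivity = 8L) {
  px <- .as_pixels(image)
  rng <- range(px)
  if (rng[2] <= rng[1])
    stop("no radiation field detected: frame has no contrast")
  thr <- edge_threshold %||% .halfmax_threshold(px)
  mask <- px < thr
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L)
    stop("no radiation field detected: no pixels below the edge threshold")
  sizes <- tabulate(lab)
  best <- which.max(sizes)
  if (sizes[best] < min_field_area_px2)
    stop(sprintf(
      "no radiation field detected: largest candidate region is %d px^2 (< %g)",
      sizes[best], min_field_area_px2))
  m <- fill_holes(lab == best)
  if (mean(px[!m]) - mean(px[m]) < min_contrast)
    stop("no radiation field detected: in-field/blocked contrast too low")
  attr(m, "threshold") <- thr
  m
}

# Freeman 8-direction codes as (row, col) steps. Code 0 = +col (east, pan+),
# then counter-row ("up"), proceeding so that 90-degree image rotation maps
# code k to (k + 2) mod 8.
.freeman_offsets <- rbind(
  c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
  c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

# Clockwise cycle of codes on screen (row axis pointing down).
.freeman_cw <- c(0L, 7L, 6L, 5L, 4L, 3L, 2L, 1L)

.code_of_offset <- local({
  m <- matrix(NA_integer_, 3L, 3L)
  for (i in 0:7) m[.freeman_offsets[i + 1L, 1L] + 2L,
                   .freeman_offsets[i + 1L, 2L] + 2L] <- i
  function(d) m[d[1L] + 2L, d[2L] + 2L]
})

#' Trace the field boundary with a Freeman chain code
#'
#' Moore-neighbor boundary tracing of a single filled region, starting from
#' its top-most then left-most pixel and proceeding clockwise on screen, with
#' Jacob's stopping criterion (terminate on re-entering the start pixel with
#' the initial backtrack direction). Interior holes are filled before tracing,
#' so marker shadows inside the aperture do not perturb the contour.
#'
#' The enclosed area in pixels is recovered from the chain itself: the
#' shoelace area of the polygon through boundary-pixel centers plus the
#' lattice-point correction `L/2 + 1` (`L` = chain length), which reproduces
#' the interior pixel count exactly for rectilinear regions (e.g. a `w x h`
#' rectangle gives `(w-1)(h-1) + (w-1) + (h-1) + 1 = wh`).
#'
#' @param mask Logical/binary matrix containing exactly one connected region
#'   of at least 2 pixels.
#' @return An object of class `aperture_contour` with fields `chain_code`
#'   (integer codes 0-7), `start_px`, `boundary_px` (closed, first row equals
#'   last row; 0-based (row, col)), `center_px` (area centroid, 0-based),
#'   `area_px2`, `n_interior_px` and the filled `mask`.
#' @export
trace_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- fill_holes(mask != 0)
  npx <- sum(mask)
  if (npx == 0L) stop("cannot trace boundary: empty mask")
  if (npx == 1L) stop("degenerate contour: region is a single pixel")
  lab <- label_components(mask, 8L)
  if (max(lab) > 1L)
    stop("cannot trace boundary: mask has more than one connected region")
  nr <- nrow(mask); nc <- ncol(mask)
  rc <- which(mask, arr.ind = TRUE)
  r0 <- min(rc[, 1L])
  c0 <- min(rc[rc[, 1L] == r0, 2L])
  cw_pos <- match(0:7, .freeman_cw)
  p <- c(r0, c0)
  b_code <- 4L   # backtrack west of the start pixel: background by construction
  maxit <- 8L * npx + 8L
  chain <- integer(maxit)
  n_chain <- 0L
  boundary <- matrix(NA_integer_, maxit + 1L, 2L)
  boundary[1L, ] <- p
  nb_pts <- 1L
  repeat {
    start_pos <- cw_pos[b_code + 1L]
    found <- FALSE
    prev_code <- b_code
    for (k in 0:7) {
      code <- .freeman_cw[((start_pos - 1L + k) %% 8L) + 1L]
      q <- p + .freeman_offsets[code + 1L, ]
      if (q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L && q[2L] <= nc &&
          mask[q[1L], q[2L]]) {
        found <- TRUE
        break
      }
      prev_code <- code
    }
    if (!found) stop("degenerate contour: isolated pixel during tracing")
    # Jacob's stopping criterion: the contour is closed once the walk is back
    # at the start pixel and about to repeat its first move
    if (n_chain > 0L && p[1L] == r0 && p[2L] == c0 && code == chain[1L]) break
    n_chain <- n_chain + 1L
    chain[n_chain] <- code
    nb_pts <- nb_pts + 1L
    boundary[nb_pts, ] <- q
    prev_abs <- p + .freeman_offsets[prev_code + 1L, ]
    b_code <- .code_of_offset(prev_abs - q)
    p <- q
    if (n_chain >= maxit) stop("boundary tracing failed to close")
  }
  chain <- chain[seq_len(n_chain)]
  boundary <- boundary[seq_len(nb_pts), , drop = FALSE]
  verts0 <- boundary - 1L  # 0-based pixel coordinates
  # shoelace over the closed polygon through boundary-pixel centers
  y <- verts0[-nb_pts, 1L]; x <- verts0[-nb_pts, 2L]
  shoelace <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  area <- shoelace + length(chain) / 2 + 1
  structure(
    list(chain_code = chain,
         start_px = c(r0, c0) - 1L,
         boundary_px = verts0,
         center_px = c(mean(rc[, 1L]), mean(rc[, 2L])) - 1,
         area_px2 = area,
         n_interior_px = npx,
         mask = mask),
    class = "aperture_contour"
  )
}

#' @export
print.aperture_contour <- function(x, ...) {
  cat(sprintf(
    "Aperture contour: %d chain codes, area %.1f px^2, center (%.2f, %.2f) px\n",
    length(x$chain_code), x$area_px2, x$center_px[1], x$center_px[2]))
  invisible(x)
}

#' Geometric center of the aperture
#'
#' The aperture center is the area centroid of the enclosed (hole-filled)
#' region — the mean 0-based (row, col) coordinate over interior pixels — not
#' the mean of the boundary points, which would be biased by MLC-step
#' pixelation of the contour.
#'
#' @param contour An [trace_boundary()] result.
#' @return Numeric `(row, col)`, 0-based, sub-pixel.
#' @export
aperture_center <- function(contour) {
  stopifnot(inherits(contour, "aperture_contour"))
  contour$center_px
}
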