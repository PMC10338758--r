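# Implanted-marker detection: connected-neighbor labeling of the thresholded
# LoG response, blob shape/size/position filtering, and the combined
# center-of-mass of the surviving markers.

#' Label candidate marker blobs
#'
#' Connected-component labeling of the detection mask at the configured
#' neighbor connectivity (8 by default, i.e. diagonal-touching pixels join).
#' Each component becomes a blob whose sub-pixel centroid and second moments
#' are weighted by the magnitude of the underlying filter response; a 1/12
#' px^2 single-pixel inertia term regularizes the moments so one-pixel blobs
#' have elongation 1.
#'
#' @param mask Logical matrix, e.g. from [response_threshold()].
#' @param response Numeric matrix of filter responses on the same grid.
#' @param connectivity 4 or 8.
#' @return List of `marker_blob` objects with fields `pixels` (0-based
#'   (row, col) members), `centroid_px` (0-based, sub-pixel), `area_px2`,
#'   `elongation` (major/minor axis ratio) and `mean_response`.
#' @export
label_candidates <- function(mask, response, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.matrix(response),
            all(dim(mask) == dim(response)))
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  nr <- nrow(mask)
  idx <- which(lab > 0L)
  groups <- split(idx, lab[idx])
  lapply(groups[order(as.integer(names(groups)))], function(ids) {
    r <- (ids - 1L) %% nr          # 0-based rows
    cc <- (ids - 1L) %/% nr        # 0-based cols
    w <- abs(response[ids])
    if (sum(w) == 0) w <- rep(1, length(ids))
    W <- sum(w)
    cr <- sum(w * r) / W
    ccol <- sum(w * cc) / W
    mu20 <- sum(w * (r - cr)^2) / W + 1 / 12
    mu02 <- sum(w * (cc - ccol)^2) / W + 1 / 12
    mu11 <- sum(w * (r - cr) * (cc - ccol)) / W
    half <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    lam1 <- (mu20 + mu02) / 2 + half
    lam2 <- (mu20 + mu02) / 2 - half
    structure(
      list(pixels = cbind(row = r, col = cc),
           centroid_px = c(cr, ccol),
           area_px2 = length(ids),
           elongation = sqrt(lam1 / max(lam2, 1e-12)),
           mean_response = mean(response[ids])),
      class = "marker_blob")
  })
}

#' Marker acceptance rules
#'
#' Filtering rules applied to candidate blobs. The edge margin defaults to
#' 1.24 mm at isocenter: markers closer than this to the MLC field edge are
#' unreliable because leaf penumbra and partial occlusion distort or hide
#' their shadows. The area window 4-120 px^2 brackets the detected footprint
#' of a 3 mm x 1 mm seed: the projected ellipse itself is ~73 px^2 at
#' 0.18 mm/px, and the thresholded LoG response extends one blur ring beyond
#' it. The elongation cap rejects the extended ridge responses produced by
#' the field edge itself.
#'
#' @param edge_margin_mm Minimum centroid distance from the traced field edge.
#' @param min_area_px2,max_area_px2 Blob area window in pixels.
#' @param max_elongation Maximum major/minor axis ratio.
#' @param require_complete If `TRUE` (default) a frame only enters the
#'   tracking-error statistics when all expected markers are found; if `FALSE`
#'   one detected marker suffices.
#' @return An object of class `marker_filter_rules`.
#' @export
marker_filter_rules <- function(edge_margin_mm = 1.24, min_area_px2 = 4,
                                max_area_px2 = 120, max_elongation = 6,
                                require_complete = TRUE) {
  stopifnot(edge_margin_mm >= 0, min_area_px2 >= 1,
            max_area_px2 >= min_area_px2, max_elongation >= 1)
  structure(
    list(edge_margin_mm = edge_margin_mm, min_area_px2 = min_area_px2,
         max_area_px2 = max_area_px2, max_elongation = max_elongation,
         require_complete = isTRUE(require_complete)),
    class = "marker_filter_rules"
  )
}

#' Filter candidate blobs into a marker set
#'
#' Keeps blobs whose centroid lies inside the aperture and farther than the
#' edge margin from the traced boundary, whose area falls in the configured
#' window and whose elongation is below the cap. If more blobs survive than
#' markers are expected, the strongest `expected_markers` by absolute mean
#' response are kept (ties: larger area, then smaller row, then smaller
#' column — a deterministic total order). Every rejected blob is recorded with
#' its first failing rule so exclusions are auditable.
#'
#' @param blobs List of blobs from [label_candidates()].
#' @param contour An `aperture_contour` from [trace_boundary()].
#' @param rules A [marker_filter_rules()].
#' @param expected_markers Number of implanted fiducials.
#' @param geometry A [geometry_config()] (converts the edge margin to pixels).
#' @return An object of class `marker_set` with fields `blobs`, `com_px`
#'   (unweighted mean of blob centroids; `NA` when nothing detected),
#'   `n_detected`, `complete` and a data frame `excluded` of rejection
#'   reasons.
#' @export
filter_markers <- function(blobs, contour, rules = marker_filter_rules(),
                           expected_markers = 3L,
                           geometry = geometry_config()) {
  stopifnot(inherits(contour, "aperture_contour"))
  bd <- contour$boundary_px
  nr <- nrow(contour$mask); nc <- ncol(contour$mask)
  keep <- logical(length(blobs))
  reason <- character(length(blobs))
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    ri <- round(b$centroid_px[1L]) + 1L
    ci <- round(b$centroid_px[2L]) + 1L
    inside <- ri >= 1L && ri <= nr && ci >= 1L && ci <= nc &&
      contour$mask[ri, ci]
    d_mm <- min(sqrt((bd[, 1L] - b$centroid_px[1L])^2 +
                       (bd[, 2L] - b$centroid_px[2L])^2)) *
      geometry$pixel_mm_at_iso
    if (!inside) {
      reason[i] <- "outside aperture"
    } else if (d_mm <= rules$edge_margin_mm) {
      reason[i] <- sprintf("within %.2f mm of field edge", rules$edge_margin_mm)
    } else if (b$area_px2 < rules$min_area_px2) {
      reason[i] <- "below minimum area"
    } else if (b$area_px2 > rules$max_area_px2) {
      reason[i] <- "above maximum area"
    } else if (b$elongation > rules$max_elongation) {
      reason[i] <- "too elongated"
    } else {
      keep[i] <- TRUE
    }
  }
  kept <- blobs[keep]
  if (length(kept) > expected_markers) {
    o <- order(-vapply(kept, function(b) abs(b$mean_response), 0),
               -vapply(kept, function(b) b$area_px2, 0),
               vapply(kept, function(b) b$centroid_px[1L], 0),
               vapply(kept, function(b) b$centroid_px[2L], 0))
    dropped <- kept[o[-seq_len(expected_markers)]]
    kept <- kept[o[seq_len(expected_markers)]]
    for (b in dropped) {
      keep_i <- which(vapply(blobs, identical, TRUE, y = b))[1L]
      keep[keep_i] <- FALSE
      reason[keep_i] <- "weaker than expected_markers stronger candidates"
    }
  }
  n <- length(kept)
  com <- if (n >= 1L) {
    colMeans(do.call(rbind, lapply(kept, function(b) b$centroid_px)))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(blobs = kept,
         com_px = unname(com),
         n_detected = n,
         complete = n == expected_markers,
         excluded = data.frame(
           blob = which(!keep & nzchar(reason)),
           reason = reason[!keep & nzchar(reason)],
           stringsAsFactors = FALSE)),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Marker set: %d detected (%scomplete)", x$n_detected,
              if (x$complete) "" else "in"))
  if (x$n_detected >= 1L)
    cat(sprintf(", COM (%.2f, %.2f) px", x$com_px[1], x$com_px[2]))
  cat("\n")
  invisible(x)
}

#' Combined center-of-mass of detected markers
#'
#' The unweighted arithmetic mean of the per-marker centroids: each marker
#' votes equally, so per-marker contrast differences from overlying anatomy do
#' not shift the surrogate position.
#'
#' @param ms A `marker_set`.
#' @return Numeric `(row, col)`, 0-based, sub-pixel.
#' @export
markers_com <- function(ms) {
  stopifnot(inherits(ms, "marker_set"))
  if (ms$n_detected == 0L)
    stop("undefined COM: no markers detected in this frame")
  ms$com_px
}

#' Detect markers in one frame
#'
#' Full per-frame marker pipeline: LoG filter (negated so dark marker shadows
#' give positive peaks), robust thresholding, restriction to the aperture
#' interior, connected-neighbor labeling and rule-based filtering.
#'
#' @param image An [epid_image()] or numeric matrix.
#' @param contour An `aperture_contour` for the same frame.
#' @param params A [log_params()].
#' @param k_sigma Threshold for [response_threshold()].
#' @param rules A [marker_filter_rules()].
#' @param expected_markers Number of implanted fiducials.
#' @param geometry A [geometry_config()].
#' @param connectivity 4 or 8 for blob labeling.
#' @return A `marker_set` (see [filter_markers()]).
#' @export
detect_markers <- function(image, contour, params = log_params(), k_sigma = 5,
                           rules = marker_filter_rules(), expected_markers = 3L,
                           geometry = geometry_config(), connectivity = 8L) {
  resp <- -log_filter(image, params)
  th <- response_threshold(resp, k_sigma)
  blobs <- label_candidates(th$mask & contour$mask, resp, connectivity)
  ms <- filter_markers(blobs, contour, rules, expected_markers, geometry)
  ms$threshold <- th$threshold
  ms
}
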