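#' Laplacian-of-Gaussian filter parameters
#'
#' `sigma_px` sets the blob scale: a LoG filter responds maximally to blobs of
#' radius about `sigma_px * sqrt(2)`. The default 2.0 px targets the projected
#' shadow of a 1 mm diameter gold seed at 0.18 mm/px (diameter ~5.6 px, radius
#' ~2.8 px). The kernel is truncated at `kernel_halfwidth_px`, at least
#' `ceiling(3 * sigma_px)`.
#'
#' @param sigma_px Gaussian scale in pixels (> 0).
#' @param kernel_halfwidth_px Truncation radius in pixels; default
#'   `ceiling(3 * sigma_px)`.
#' @return An object of class `log_params`.
#' @export
log_params <- function(sigma_px = 2.0, kernel_halfwidth_px = NULL) {
  stopifnot(is.numeric(sigma_px), sigma_px > 0)
  hw <- as.integer(kernel_halfwidth_px %||% ceiling(3 * sigma_px))
  if (hw < ceiling(3 * sigma_px))
    stop("kernel_halfwidth_px must be >= ceiling(3 * sigma_px)")
  structure(list(sigma_px = sigma_px, kernel_halfwidth_px = hw),
            class = "log_params")
}

#' Laplacian-of-Gaussian kernel
#'
#' Evaluates
#' \deqn{L(x, y) = -\frac{1}{\pi\sigma^4}\Big(1 - \frac{x^2+y^2}{2\sigma^2}\Big)
#'   e^{-(x^2+y^2)/(2\sigma^2)}}
#' on the truncated grid and subtracts the mean so the discrete kernel sums to
#' zero exactly (a constant image then filters to exactly zero).
#'
#' @param params A [log_params()].
#' @return A square numeric matrix of side `2 * kernel_halfwidth_px + 1`.
#' @export
log_kernel <- function(params = log_params()) {
  s <- params$sigma_px
  h <- params$kernel_halfwidth_px
  x <- -h:h
  r2 <- outer(x^2, x^2, "+")
  k <- -(1 / (pi * s^4)) * (1 - r2 / (2 * s^2)) * exp(-r2 / (2 * s^2))
  k - mean(k)
}

# Symmetric (reflective) padding by (hr, hc) pixels on each side.
.pad_reflect <- function(m, hr, hc) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(hr < nr, hc < nc)
  ri <- c(if (hr > 0) hr:1, 1:nr, if (hr > 0) nr:(nr - hr + 1))
  ci <- c(if (hc > 0) hc:1, 1:nc, if (hc > 0) nc:(nc - hc + 1))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with reflective border handling, via zero-padded FFT.
.conv2_reflect <- function(img, kernel) {
  hr <- (nrow(kernel) - 1L) %/% 2L
  hc <- (ncol(kernel) - 1L) %/% 2L
  pad <- .pad_reflect(img, hr, hc)
  fr <- stats::nextn(nrow(pad) + 2L * hr, c(2L, 3L, 5L))
  fc <- stats::nextn(ncol(pad) + 2L * hc, c(2L, 3L, 5L))
  A <- matrix(0, fr, fc); A[seq_len(nrow(pad)), seq_len(ncol(pad))] <- pad
  K <- matrix(0, fr, fc); K[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (fr * fc)
  full[seq_len(nrow(img)) + 2L * hr, seq_len(ncol(img)) + 2L * hc, drop = FALSE]
}

# Normalized Gaussian blur kernel (sums to 1).
.gaussian_kernel <- function(sigma_px, halfwidth = ceiling(3 * sigma_px)) {
  x <- -halfwidth:halfwidth
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma_px^2))
  g / sum(g)
}

#' Filter a frame with the Laplacian of Gaussian
#'
#' Convolves the frame with [log_kernel()] using reflective border padding and
#' returns the signed response on the same grid. In the 0 (white) to 1 (black)
#' grayscale convention, dark marker shadows produce strongly negative
#' responses at their centers; [detect_markers()] therefore thresholds the
#' negated response.
#'
#' @param image An [epid_image()] or numeric matrix.
#' @param params A [log_params()].
#' @return Numeric matrix of signed filter responses, same size as the input.
#' @export
log_filter <- function(image, params = log_params()) {
  px <- .as_pixels(image)
  side <- 2L * params$kernel_halfwidth_px + 1L
  if (side > nrow(px) || side > ncol(px))
    stop(sprintf("LoG kernel (%d px) exceeds the image (%d x %d px)",
                 side, nrow(px), ncol(px)))
  .conv2_reflect(px, log_kernel(params))
}

#' Threshold a filter response with a robust noise scale
#'
#' The detection mask keeps pixels whose response exceeds
#' `median + k_sigma * scale`, with the scale the MAD (consistent for a normal
#' background); if the MAD degenerates to zero the SD is used. The threshold
#' actually applied is returned for logging. Background-dominated EPID frames
#' make the median/MAD essentially insensitive to the blobs themselves.
#'
#' @param filtered Numeric response matrix, e.g. from [log_filter()].
#' @param k_sigma Threshold in robust-scale units; default 5.
#' @return List with `mask` (logical matrix), `threshold` and `scale`.
#' @export
response_threshold <- function(filtered, k_sigma = 5) {
  stopifnot(is.matrix(filtered), all(is.finite(filtered)))
  med <- stats::median(filtered)
  sc <- stats::mad(filtered)
  if (sc == 0) sc <- stats::sd(filtered)
  if (!is.finite(sc) || sc == 0) {
    warning("response_threshold: zero-variance response, returning empty mask")
    return(list(mask = matrix(FALSE, nrow(filtered), ncol(filtered)),
                threshold = Inf, scale = 0))
  }
  thr <- med + k_sigma * sc
  list(mask = filtered > thr, threshold = thr, scale = sc)
}
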