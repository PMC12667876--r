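#' Parameters of the wavelet-product mask chain
#'
#' The membrane-marker mask is built by blurring the frame with Gaussians
#' at multiples of the Airy-disc size, subtracting each blurred image from
#' the next-smaller-scale one to obtain band-pass wavelet planes,
#' multiplying the planes together, thresholding the product at a multiple
#' of the original frame's standard deviation, and dilating the result.
#'
#' @param scale_multipliers strictly increasing multipliers of the base
#'   Airy scale, length >= 2; default `c(1, 2, 3, 4)`.
#' @param sd_threshold_factor threshold = this factor times the SD of the
#'   original frame; default 3.
#' @param dilation_cycles 0, 1 or 2 binary dilations with a 3x3 element;
#'   default 1.
#' @param background_mode_factor multiplier of the modal intensity used as
#'   the background level in intensity measurements; default 1.5 (used by
#'   the ratio stage, carried here so one object configures the recipe).
#' @param airy_interpretation how "Airy disc size" maps to the base
#'   Gaussian sigma; see [airy_sigma_px()].
#' @param sd_on_roi if `TRUE`, the SD defining the threshold is computed
#'   over the cell ROI only instead of the whole frame (whole frame is the
#'   default reading).
#' @return an object of class `wavelet_params`.
#' @export
wavelet_params <- function(scale_multipliers = c(1, 2, 3, 4),
                           sd_threshold_factor = 3,
                           dilation_cycles = 1,
                           background_mode_factor = 1.5,
                           airy_interpretation = "radius-as-sigma",
                           sd_on_roi = FALSE) {
  stopifnot(is.numeric(scale_multipliers), length(scale_multipliers) >= 2L,
            all(is.finite(scale_multipliers)), all(scale_multipliers > 0),
            all(diff(scale_multipliers) > 0),
            is.numeric(sd_threshold_factor), length(sd_threshold_factor) == 1L,
            is.finite(sd_threshold_factor), sd_threshold_factor > 0,
            dilation_cycles %in% 0:2,
            is.numeric(background_mode_factor), background_mode_factor >= 1)
  structure(list(scale_multipliers = as.numeric(scale_multipliers),
                 sd_threshold_factor = sd_threshold_factor,
                 dilation_cycles = as.integer(dilation_cycles),
                 background_mode_factor = background_mode_factor,
                 airy_interpretation = airy_interpretation,
                 sd_on_roi = isTRUE(sd_on_roi)),
            class = "wavelet_params")
}

# Reflected index into 1..n (scipy-style 'reflect': edge repeated,
# (dcba|abcd|dcba)); valid for any offset.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep_len(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

#' Discrete Gaussian kernel
#'
#' Normalised 1-D Gaussian kernel truncated at 4 sigma; `sigma = 0` gives
#' the identity kernel.
#'
#' @param sigma standard deviation in pixels (>= 0).
#' @return numeric vector of odd length summing to 1.
#' @export
gaussian_kernel <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            sigma >= 0)
  if (sigma == 0) return(1)
  r <- ceiling(4 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with reflect padding
#'
#' Separable convolution of a 2-D image with an isotropic Gaussian.
#' Borders are handled by reflect padding (edge pixel repeated), which
#' avoids the dark-edge artifacts of zero padding that would depress the
#' frame SD used for thresholding.
#'
#' @param frame numeric matrix, all values finite.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(frame, sigma) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (length(frame) == 0L) stop("empty frame")
  if (!all(is.finite(frame))) stop("frame must be finite-valued")
  k <- gaussian_kernel(sigma)
  if (length(k) == 1L) return(frame + 0)
  r <- (length(k) - 1L) %/% 2L
  conv_rows <- function(m) {
    # convolve along each row (x direction): pad columns by reflection
    n <- ncol(m)
    pad <- m[, reflect_index(seq.int(1L - r, n + r), n), drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(k))
      out <- out + k[j] * pad[, j:(j + n - 1L), drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(frame))))
}

#' Multiscale Gaussian blur stack
#'
#' Blurs a frame at each scale multiplier times the base Airy scale,
#' smallest scale first.
#'
#' @param frame numeric matrix.
#' @param airy_px base scale in pixels (the Airy-disc size as sigma).
#' @param multipliers increasing scale multipliers.
#' @return list of blurred matrices, one per multiplier, smallest first.
#' @export
scale_stack <- function(frame, airy_px, multipliers = c(1, 2, 3, 4)) {
  stopifnot(is.numeric(airy_px), airy_px > 0, all(diff(multipliers) > 0))
  lapply(sort(multipliers), function(m) gaussian_blur(frame, m * airy_px))
}

#' Wavelet (difference-of-Gaussian) planes
#'
#' Each blurred image is subtracted from the one at the next smaller
#' scale, producing band-pass planes that are positive at spot-like
#' structures.
#'
#' @param blurred list of blurred images ordered smallest scale first.
#' @return list of `length(blurred) - 1` difference images.
#' @export
wavelet_planes <- function(blurred) {
  stopifnot(is.list(blurred))
  if (length(blurred) < 2L) stop("need at least two scales to form wavelets")
  lapply(seq_len(length(blurred) - 1L),
         function(i) blurred[[i]] - blurred[[i + 1L]])
}

#' Pixel-wise product of wavelet planes
#'
#' Negative plane values are clamped to zero before multiplying so that an
#' odd number of negative responses cannot create spurious positive
#' product pixels.
#'
#' @param planes list of equally sized difference images.
#' @return numeric matrix, the multiscale product.
#' @export
wavelet_product <- function(planes) {
  stopifnot(is.list(planes), length(planes) >= 1L)
  d <- dim(planes[[1L]])
  for (p in planes)
    if (!identical(dim(p), d)) stop("wavelet planes differ in shape")
  Reduce(`*`, lapply(planes, function(p) pmax(p, 0)))
}

# 3x3 full-connectivity binary dilation by shift-OR; repeated `cycles`
# times.  Pixels beyond the border are treated as background.
binary_dilate <- function(mask, cycles = 1L) {
  stopifnot(is.matrix(mask))
  m <- mask
  storage.mode(m) <- "logical"
  ny <- nrow(m); nx <- ncol(m)
  for (i in seq_len(cycles)) {
    out <- m
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ys <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
      xs <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
      # clamp duplicates an edge row/col; mask it out so nothing leaks in
      valid_y <- seq_len(ny) + dy >= 1L & seq_len(ny) + dy <= ny
      valid_x <- seq_len(nx) + dx >= 1L & seq_len(nx) + dx <= nx
      shifted <- m[ys, xs, drop = FALSE]
      shifted[!valid_y, ] <- FALSE
      shifted[, !valid_x] <- FALSE
      out <- out | shifted
    }
    m <- out
  }
  m
}

#' Threshold the wavelet product and dilate into the final mask
#'
#' The threshold is `sd_threshold_factor` times the standard deviation of
#' the ORIGINAL frame (not the product image); pixels with product
#' strictly above it form the mask, which is then dilated
#' `dilation_cycles` times with a 3x3 element.
#'
#' @param product wavelet-product image.
#' @param original_frame the unfiltered frame the product derives from.
#' @param params a [wavelet_params()].
#' @param roi optional logical matrix; if given and `params$sd_on_roi` is
#'   `TRUE` the SD is computed over the ROI pixels only.
#' @return an object of class `segmentation_result` with elements `mask`
#'   (logical matrix), `threshold_value`, `pre_dilation_mask`, and
#'   `degenerate` (TRUE when the original frame had zero variance).
#' @export
threshold_and_dilate <- function(product, original_frame, params = wavelet_params(),
                                 roi = NULL) {
  stopifnot(identical(dim(product), dim(original_frame)),
            inherits(params, "wavelet_params"))
  vals <- if (params$sd_on_roi && !is.null(roi)) original_frame[roi]
          else as.vector(original_frame)
  s <- stats::sd(vals)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) s <- 0
  thr <- params$sd_threshold_factor * s
  pre <- product > thr
  mask <- if (params$dilation_cycles > 0L)
    binary_dilate(pre, params$dilation_cycles) else pre
  structure(list(mask = mask, pre_dilation_mask = pre,
                 threshold_value = thr, degenerate = degenerate),
            class = "segmentation_result")
}

#' Segment one marker frame with the full wavelet chain
#'
#' Runs blur stack, wavelet planes, product, threshold and dilation on a
#' single 2-D frame.
#'
#' @param frame numeric matrix (the membrane-marker frame).
#' @param airy_px base Airy scale in pixels (sigma of the 1x blur).
#' @param params a [wavelet_params()].
#' @param roi optional cell ROI (see [threshold_and_dilate()]).
#' @param keep_intermediates if `TRUE` the blurred stack, planes and
#'   product are attached for diagnostics.
#' @return a `segmentation_result` with `airy_px` recorded.
#' @export
segment_frame <- function(frame, airy_px, params = wavelet_params(),
                          roi = NULL, keep_intermediates = FALSE) {
  blurred <- scale_stack(frame, airy_px, params$scale_multipliers)
  planes <- wavelet_planes(blurred)
  prod <- wavelet_product(planes)
  res <- threshold_and_dilate(prod, frame, params, roi = roi)
  res$airy_px <- airy_px
  if (keep_intermediates) {
    res$blurred <- blurred
    res$planes <- planes
    res$wavelet_product <- prod
  }
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation: %d mask px (%.2f%% of frame), threshold %.4g%s\n",
              sum(x$mask), 100 * mean(x$mask), x$threshold_value,
              if (isTRUE(x$degenerate)) " [degenerate: zero-variance frame]"
              else ""))
  invisible(x)
}

#' Segment every frame of a movie's marker channel
#'
#' Applies the full wavelet-product chain independently per frame of the
#' marker channel.  Z-stacks are reduced to 2-D by a central-slice mean
#' projection first.
#'
#' @param stack an [image_stack()].
#' @param marker_channel channel name to segment.
#' @param optics an [optics_spec()]; the base scale is
#'   [airy_sigma_px()] of the marker channel.
#' @param params a [wavelet_params()].
#' @param roi optional cell ROI mask.
#' @param n_central slices used by the mean projection when the movie has
#'   more than one z-slice; default 11.
#' @return list of `segmentation_result`, one per frame.
#' @export
segment_movie <- function(stack, marker_channel, optics,
                          params = wavelet_params(), roi = NULL,
                          n_central = 11L) {
  stopifnot(inherits(stack, "image_stack"), inherits(optics, "optics_spec"))
  if (!marker_channel %in% stack$channels)
    stop("marker channel '", marker_channel, "' not present in the movie (",
         paste(stack$channels, collapse = ", "), ")")
  airy <- airy_sigma_px(optics, marker_channel, params$airy_interpretation)
  lapply(seq_len(stack$sizes[["T"]]), function(t) {
    fr <- get_frame(stack, t, marker_channel, n_central = n_central)
    segment_frame(fr, airy, params, roi = roi)
  })
}
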