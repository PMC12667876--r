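#' Multi-channel time-lapse image container
#'
#' A thin wrapper around a 5-D numeric array in TZCYX order (time, z-slice,
#' channel, y, x) with timing and channel metadata.  Single-plane movies
#' simply have a Z extent of 1.
#'
#' @param data numeric array with `dim` of length 5 (T, Z, C, Y, X), or a
#'   2-D matrix which is promoted to 1 x 1 x 1 x Y x X with a warning.
#' @param channels character vector of channel names, length C.
#' @param channel_roles named character vector mapping channel name to
#'   role (`"marker"`, `"biosensor"` or `"recruited-enzyme"`); optional.
#' @param frame_interval_s seconds between frames; default 30.
#' @param treatment_time_min stimulation time in minutes from movie start;
#'   default 2.
#' @param z_step_um z spacing in microns (for z-stacks); default NA.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, channels = NULL, channel_roles = NULL,
                        frame_interval_s = 30, treatment_time_min = 2,
                        z_step_um = NA_real_) {
  if (is.matrix(data)) {
    warning("2-D image promoted to a 1-frame, 1-slice, 1-channel stack")
    data <- array(data, dim = c(1L, 1L, 1L, nrow(data), ncol(data)))
  }
  stopifnot(is.array(data), length(dim(data)) == 5L, is.numeric(data))
  d <- dim(data)
  names(d) <- c("T", "Z", "C", "Y", "X")
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[["C"]]))
  stopifnot(length(channels) == d[["C"]], !anyDuplicated(channels))
  if (!is.null(channel_roles)) {
    stopifnot(all(names(channel_roles) %in% channels),
              all(channel_roles %in% c("marker", "biosensor",
                                       "recruited-enzyme")))
  }
  stopifnot(frame_interval_s > 0, treatment_time_min >= 0)
  structure(list(data = data, sizes = d, channels = channels,
                 channel_roles = channel_roles,
                 frame_interval_s = frame_interval_s,
                 treatment_time_min = treatment_time_min,
                 z_step_um = z_step_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- x$sizes
  cat(sprintf("Image stack: %d frame(s) x %d slice(s) x %d channel(s) x %d x %d px\n",
              d[["T"]], d[["Z"]], d[["C"]], d[["Y"]], d[["X"]]))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  frame interval %g s, treatment at %g min\n",
              x$frame_interval_s, x$treatment_time_min))
  invisible(x)
}

#' Frame times in minutes
#'
#' @param stack an [image_stack()].
#' @return numeric vector, `(0:(T-1)) * frame_interval_s / 60`.
#' @export
frame_times_min <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  (seq_len(stack$sizes[["T"]]) - 1L) * stack$frame_interval_s / 60
}

#' Extract one 2-D frame of one channel
#'
#' Z-stacks are reduced by the central-slice mean projection
#' ([mean_projection()]); single-plane movies return the plane as-is.
#'
#' @param stack an [image_stack()].
#' @param t frame index (1-based).
#' @param channel channel name.
#' @param n_central slices for the mean projection; capped at Z.
#' @return numeric Y x X matrix.
#' @export
get_frame <- function(stack, t, channel, n_central = 11L) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- match(channel, stack$channels)
  if (is.na(ci)) stop("unknown channel '", channel, "'")
  if (t < 1L || t > stack$sizes[["T"]]) stop("frame index out of range")
  z <- stack$sizes[["Z"]]
  sl <- stack$data[t, , ci, , , drop = FALSE]
  dim(sl) <- c(z, stack$sizes[["Y"]], stack$sizes[["X"]])
  if (z == 1L) {
    m <- sl[1L, , ]
    dim(m) <- c(stack$sizes[["Y"]], stack$sizes[["X"]])
    m
  } else {
    mean_projection(sl, min(n_central, z))
  }
}
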