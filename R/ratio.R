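#' Central-slice mean projection of a z-stack
#'
#' Averages the `n_central` slices centred on the middle slice.  With an
#' even slice count (or an even `n_central`) the centre is tied toward the
#' lower index, i.e. slices `m - floor((n-1)/2) .. m + ceiling((n-1)/2)`
#' around the 0-based middle index `m = floor((Z-1)/2)`.
#'
#' @param zstack numeric array Z x Y x X.
#' @param n_central number of slices to average (1..Z).
#' @return numeric Y x X matrix.
#' @export
mean_projection <- function(zstack, n_central) {
  stopifnot(is.array(zstack), length(dim(zstack)) == 3L)
  z <- dim(zstack)[1L]
  if (!is.numeric(n_central) || length(n_central) != 1L || n_central <= 0)
    stop("n_central must be a positive integer")
  n_central <- as.integer(n_central)
  if (n_central > z) stop("n_central (", n_central, ") exceeds slice count (",
                          z, ")")
  m0 <- (z - 1L) %/% 2L                       # 0-based middle, tie to lower
  lo <- m0 - (n_central - 1L) %/% 2L
  lo <- min(max(lo, 0L), z - n_central)       # keep window inside the stack
  idx <- (lo + 1L):(lo + n_central)
  out <- matrix(0, dim(zstack)[2L], dim(zstack)[3L])
  for (i in idx) out <- out + zstack[i, , ]
  out / n_central
}

#' Modal background level of a frame
#'
#' Returns `factor` times the mode of the intensity histogram.  The mode
#' is taken over integer bins (bin width 1 by default, matching raw
#' camera/PMT counts); ties are broken toward the lowest modal bin and
#' flagged via the `"tied"` attribute.  Pixels at or below the returned
#' level are treated as background in intensity measurements.
#'
#' @param frame numeric matrix or vector.
#' @param factor multiplier of the mode; default 1.5.
#' @param bin_width histogram bin width; default 1 (exact for
#'   integer-valued images).
#' @return background level (numeric scalar) with attribute `mode` (the
#'   modal bin value) and `tied` (logical).
#' @export
modal_background <- function(frame, factor = 1.5, bin_width = 1) {
  v <- as.vector(frame)
  if (length(v) == 0L) stop("empty frame")
  stopifnot(is.finite(factor), factor >= 1, bin_width > 0)
  bins <- floor(v / bin_width)
  tab <- table(bins)
  top <- max(tab)
  modal_bins <- as.numeric(names(tab)[tab == top])
  tied <- length(modal_bins) > 1L
  mode_val <- min(modal_bins) * bin_width
  structure(factor * mode_val, mode = mode_val, tied = tied)
}

#' Biosensor ratio of one frame
#'
#' The headline metric: mean background-subtracted biosensor intensity
#' over the mask-inside-cell region divided by the mean over the whole
#' cell ROI.  Background subtraction clamps at zero
#' (`max(pixel - background_level, 0)`).  The numerator region is
#' `mask & roi` so a neighbouring cell's vesicles cannot contaminate the
#' trace.  An empty numerator region (or a zero denominator) yields `NA` —
#' a missing frame, never a zero.
#'
#' @param frame biosensor frame (numeric matrix).
#' @param mask logical matrix (membrane mask).
#' @param roi logical matrix (whole-cell ROI).
#' @param background_level scalar background level (e.g. from
#'   [modal_background()]); 0 disables subtraction.
#' @param statistic `"mean"` (default) or `"integrated"` (sum); the ratio
#'   of means is the conventional reading, a ratio of sums scales with
#'   mask area.
#' @return list with `ratio` and `mask_area_px` (pixels in `mask & roi`).
#' @export
frame_ratio <- function(frame, mask, roi, background_level = 0,
                        statistic = c("mean", "integrated")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(frame), identical(dim(frame), dim(mask)),
            identical(dim(frame), dim(roi)))
  roi <- roi != 0; mask <- mask != 0
  if (!any(roi)) stop("cell ROI is empty")
  num_region <- mask & roi
  area <- sum(num_region)
  if (area == 0L)
    return(list(ratio = NA_real_, mask_area_px = 0L))
  bs <- pmax(frame - background_level, 0)
  f <- if (statistic == "mean") mean else sum
  den <- f(bs[roi])
  ratio <- if (den == 0) NA_real_ else f(bs[num_region]) / den
  list(ratio = ratio, mask_area_px = area)
}

#' Extract a cell's ratio trace from a movie
#'
#' Applies the central-slice projection (for z-stacks), per-frame modal
#' background subtraction on the biosensor channel and [frame_ratio()]
#' across all frames.  Times are `frame index * frame interval`, in
#' minutes.  Missing frames (empty mask within the ROI) propagate as `NA`
#' and are never interpolated.
#'
#' @param stack an [image_stack()].
#' @param masks list of per-frame masks (logical matrices or
#'   `segmentation_result`s), length T.
#' @param roi logical whole-cell ROI matrix.
#' @param channel biosensor channel name.
#' @param cell_id,experiment_id identifiers recorded in the trace.
#' @param background_mode_factor multiplier of the modal intensity used as
#'   background level per frame; `NULL` disables background subtraction.
#' @param statistic see [frame_ratio()].
#' @param n_central slices for the mean projection.
#' @return a `ratio_trace` data frame with columns `experiment_id`,
#'   `cell_id`, `channel`, `time_min`, `ratio`, `mask_area_px`,
#'   `qc_excluded`, `qc_reason`, and attribute `treatment_time_min`.
#' @export
extract_trace <- function(stack, masks, roi, channel,
                          cell_id = "cell1", experiment_id = "exp1",
                          background_mode_factor = 1.5,
                          statistic = "mean", n_central = 11L) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- stack$sizes[["T"]]
  if (length(masks) != nt)
    stop("need one mask per frame (", nt, "), got ", length(masks))
  times <- frame_times_min(stack)
  ratio <- numeric(nt); area <- integer(nt)
  for (t in seq_len(nt)) {
    fr <- get_frame(stack, t, channel, n_central = n_central)
    m <- masks[[t]]
    if (inherits(m, "segmentation_result")) m <- m$mask
    bg <- if (is.null(background_mode_factor)) 0
          else as.numeric(modal_background(fr, background_mode_factor))
    r <- frame_ratio(fr, m, roi, background_level = bg,
                     statistic = statistic)
    ratio[t] <- r$ratio; area[t] <- r$mask_area_px
  }
  if (all(is.na(ratio)))
    stop("all frames missing: mask never intersects the cell ROI")
  out <- data.frame(experiment_id = experiment_id, cell_id = cell_id,
                    channel = channel, time_min = times, ratio = ratio,
                    mask_area_px = area, qc_excluded = FALSE,
                    qc_reason = "", stringsAsFactors = FALSE)
  attr(out, "treatment_time_min") <- stack$treatment_time_min
  class(out) <- c("ratio_trace", "data.frame")
  out
}

#' Flag a trace as excluded from analysis
#'
#' Mirrors the manual QC step of time-lapse experiments (cells that move
#' too much or die are excluded); the judgement itself is the analyst's.
#'
#' @param trace a `ratio_trace`.
#' @param reason short free-text reason.
#' @return the trace with `qc_excluded = TRUE`.
#' @export
qc_exclude <- function(trace, reason = "manual exclusion") {
  trace$qc_excluded <- TRUE
  trace$qc_reason <- reason
  trace
}

#' Grand mean and SEM across experiments
#'
#' Implements the two-level aggregation convention of live-cell imaging
#' papers: at each time point every experiment's cells are averaged first,
#' then the grand mean is the mean of the per-experiment means and the SEM
#' is the SD of the per-experiment means divided by the square root of the
#' number of experiments.  QC-excluded traces are skipped; an experiment
#' left with no cells is dropped with a warning.  With a single experiment
#' the SEM is 0 by convention and flagged.
#'
#' @param traces one `ratio_trace` or an rbind of several (tidy layout).
#' @return an `aggregate_trace` data frame with columns `channel`,
#'   `time_min`, `grand_mean`, `sem`, `n_experiments`, `n_cells`.
#' @export
grand_mean <- function(traces) {
  df <- as.data.frame(traces)
  stopifnot(all(c("experiment_id", "cell_id", "channel", "time_min",
                  "ratio") %in% names(df)))
  if (!"qc_excluded" %in% names(df)) df$qc_excluded <- FALSE
  kept <- df[!df$qc_excluded & !is.na(df$ratio), , drop = FALSE]
  dropped <- setdiff(unique(df$experiment_id), unique(kept$experiment_id))
  if (length(dropped))
    warning("experiment(s) with no usable cells dropped: ",
            paste(dropped, collapse = ", "))
  if (nrow(kept) == 0L) stop("no usable traces to aggregate")
  out <- do.call(rbind, lapply(split(kept, kept$channel), function(ch) {
    res <- do.call(rbind, lapply(split(ch, ch$time_min), function(tt) {
      exp_means <- tapply(tt$ratio, tt$experiment_id, mean)
      n_exp <- length(exp_means)
      gm <- mean(exp_means)
      sem <- if (n_exp > 1L) stats::sd(exp_means) / sqrt(n_exp) else 0
      data.frame(channel = ch$channel[1L], time_min = tt$time_min[1L],
                 grand_mean = gm, sem = sem, n_experiments = n_exp,
                 n_cells = length(unique(paste(tt$experiment_id,
                                               tt$cell_id))),
                 stringsAsFactors = FALSE)
    }))
    res[order(res$time_min), , drop = FALSE]
  }))
  rownames(out) <- NULL
  if (any(out$n_experiments == 1L))
    attr(out, "single_experiment") <- TRUE
  class(out) <- c("aggregate_trace", "data.frame")
  out
}

#' Automatic whole-cell ROI for synthetic movies
#'
#' Manual ROI drawing has no place in a simulation pipeline, so this
#' fallback thresholds the temporal mean of a channel at
#' `level_factor` times its modal background and keeps the largest
#' connected component (8-connectivity).
#'
#' @param stack an [image_stack()].
#' @param channel channel to threshold (usually the biosensor).
#' @param level_factor multiplier of the modal intensity; default 1.05.
#' @param n_central slices for the projection.
#' @return logical Y x X matrix.
#' @export
auto_cell_roi <- function(stack, channel, level_factor = 1.05,
                          n_central = 11L) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- stack$sizes[["T"]]
  acc <- 0
  for (t in seq_len(nt)) acc <- acc + get_frame(stack, t, channel, n_central)
  avg <- acc / nt
  lev <- as.numeric(modal_background(avg, level_factor))
  fg <- avg > lev
  if (!any(fg)) stop("no foreground above ", level_factor, "x modal level")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# 8-connected component labelling by vectorised label propagation: seed
# each foreground pixel with a unique id and take the neighbourhood
# minimum until a fixed point; labels are then compacted to 1..k.
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(Inf, ny, nx)
  lab[mask] <- which(mask)
  repeat {
    new <- lab
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
      oky <- ys >= 1L & ys <= ny; okx <- xs >= 1L & xs <= nx
      shifted <- matrix(Inf, ny, nx)
      shifted[oky, okx] <- lab[ys[oky], xs[okx]]
      new <- pmin(new, shifted)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, ny, nx)
  ids <- sort(unique(lab[is.finite(lab)]))
  out[mask] <- match(lab[mask], ids)
  out
}
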