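#' Read a multi-page TIFF movie
#'
#' Movies are stored as multi-page 16-bit TIFF with pages in TZCYX order
#' (channel fastest, then slice, then frame) plus a JSON sidecar
#' `<path>.json` describing axes, sizes, channels and timing, written by
#' [write_movie()].  If no sidecar is present the layout must be supplied
#' explicitly; a single 2-D page is promoted to a 1x1x1xYxX stack with a
#' warning.
#'
#' @param path TIFF file path.
#' @param sizes optional named integer vector `c(T=,Z=,C=)` overriding the
#'   sidecar.
#' @param channels,frame_interval_s,treatment_time_min overrides for the
#'   sidecar metadata.
#' @return an [image_stack()].
#' @export
read_movie <- function(path, sizes = NULL, channels = NULL,
                       frame_interval_s = NULL, treatment_time_min = NULL) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot read TIFF '", path, "': ",
                           conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  n <- length(pages)
  if (is.null(sizes)) {
    if (!is.null(meta$sizes)) {
      sizes <- unlist(meta$sizes)[c("T", "Z", "C")]
    } else if (n == 1L) {
      warning("single-page TIFF without sidecar promoted to 1x1x1 stack")
      sizes <- c(T = 1L, Z = 1L, C = 1L)
    } else {
      stop("no sidecar metadata for '", path,
           "'; pass sizes = c(T=, Z=, C=) explicitly")
    }
  }
  sizes <- as.integer(sizes); names(sizes) <- c("T", "Z", "C")
  if (prod(sizes) != n)
    stop("page count ", n, " does not match T*Z*C = ", prod(sizes))
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, dim = c(sizes[["T"]], sizes[["Z"]], sizes[["C"]], ny, nx))
  p <- 1L
  for (t in seq_len(sizes[["T"]]))
    for (z in seq_len(sizes[["Z"]]))
      for (ci in seq_len(sizes[["C"]])) {
        arr[t, z, ci, , ] <- pages[[p]]
        p <- p + 1L
      }
  if (is.null(channels))
    channels <- meta$channels %||% paste0("ch", seq_len(sizes[["C"]]))
  roles <- NULL
  if (length(meta$channel_roles))
    roles <- structure(unlist(meta$channel_roles),
                       names = names(meta$channel_roles))
  image_stack(arr, channels = channels, channel_roles = roles,
              frame_interval_s = frame_interval_s %||%
                (meta$frame_interval_s %||% 30),
              treatment_time_min = treatment_time_min %||%
                (meta$treatment_time_min %||% 2),
              z_step_um = meta$z_step_um %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a movie as multi-page 16-bit TIFF plus JSON sidecar
#'
#' Pixel values are rounded and clamped to 0..65535.  Page order is TZCYX
#' (channel fastest).  The sidecar `<path>.json` records the layout so
#' [read_movie()] can restore the stack without guessing.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack$sizes
  pages <- vector("list", prod(d[c("T", "Z", "C")]))
  p <- 1L
  for (t in seq_len(d[["T"]]))
    for (z in seq_len(d[["Z"]]))
      for (ci in seq_len(d[["C"]])) {
        m <- stack$data[t, z, ci, , ]
        dim(m) <- c(d[["Y"]], d[["X"]])
        pages[[p]] <- pmin(pmax(round(m), 0), 65535) / 65535
        p <- p + 1L
      }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(axes = "TZCYX",
               sizes = as.list(d),
               channels = stack$channels,
               channel_roles = as.list(stack$channel_roles),
               frame_interval_s = stack$frame_interval_s,
               treatment_time_min = stack$treatment_time_min,
               z_step_um = stack$z_step_um)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-frame binary masks as an 8-bit TIFF
#'
#' Masks are written 0/255, one page per frame.
#'
#' @param masks list of logical matrices, or of `segmentation_result`s.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(masks, path) {
  pages <- lapply(masks, function(m) {
    if (inherits(m, "segmentation_result")) m <- m$mask
    stopifnot(is.matrix(m))
    (m != 0) * 1
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a binary mask TIFF
#'
#' @param path TIFF path written by [write_mask()] (or any TIFF whose
#'   nonzero pixels mean foreground).
#' @return list of logical matrices, one per page.
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(m) m > 0)
}

# full-precision numeric formatting so CSV round-trips are bit-exact
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write ratio traces to a tidy CSV
#'
#' Columns: experiment_id, cell_id, channel, time_min, ratio,
#' mask_area_px, qc_excluded, qc_reason.  Numerics are written with 17
#' significant digits so a read-back reproduces the trace bit-exactly.
#' Leading `#` comment lines may carry provenance (e.g. the config hash).
#'
#' @param traces a `ratio_trace` data frame or an rbind of several.
#' @param path output CSV path.
#' @param comments character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, comments = character()) {
  df <- as.data.frame(traces)
  need <- c("experiment_id", "cell_id", "channel", "time_min", "ratio",
            "mask_area_px", "qc_excluded", "qc_reason")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  lines <- if (length(comments)) paste0("# ", comments) else character()
  body <- c(paste(need, collapse = ","),
            do.call(paste, c(list(sep = ","),
                             list(df$experiment_id, df$cell_id, df$channel,
                                  fmt_num(df$time_min), fmt_num(df$ratio),
                                  as.integer(df$mask_area_px),
                                  tolower(as.character(df$qc_excluded)),
                                  ifelse(is.na(df$qc_reason) |
                                           df$qc_reason == "", "",
                                         df$qc_reason)))))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a trace CSV written by [write_traces()]
#'
#' @param path CSV path.
#' @return a `ratio_trace` data frame.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(experiment_id = "character",
                                       cell_id = "character",
                                       channel = "character",
                                       time_min = "numeric",
                                       ratio = "numeric",
                                       mask_area_px = "integer",
                                       qc_excluded = "logical",
                                       qc_reason = "character"))
  class(df) <- c("ratio_trace", "data.frame")
  df
}

#' Write an aggregate (grand-mean) trace to CSV
#'
#' @param agg an `aggregate_trace` data frame from [grand_mean()].
#' @param path output CSV path.
#' @param comments leading `# ` comment lines.
#' @return `path`, invisibly.
#' @export
write_aggregate <- function(agg, path, comments = character()) {
  stopifnot(all(c("channel", "time_min", "grand_mean", "sem") %in% names(agg)))
  lines <- if (length(comments)) paste0("# ", comments) else character()
  body <- c("channel,time_min,grand_mean,sem,n_experiments,n_cells",
            paste(agg$channel, fmt_num(agg$time_min), fmt_num(agg$grand_mean),
                  fmt_num(agg$sem), agg$n_experiments, agg$n_cells,
                  sep = ","))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a cell ROI from a mask TIFF or a polygon vertex file
#'
#' Polygon files are plain text: one `y x` pair per line (0-based pixel
#' coordinates, origin top-left, y before x); `#` starts a comment.  The
#' polygon is rasterised by an even-odd point-in-polygon test on pixel
#' centres.
#'
#' @param path `.tif`/`.tiff` mask or polygon text file.
#' @param dim_yx image dimensions `c(Y, X)`; required for polygon files.
#' @return logical Y x X matrix.
#' @export
read_roi <- function(path, dim_yx = NULL) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    return(read_mask(path)[[1L]])
  if (is.null(dim_yx))
    stop("dim_yx = c(Y, X) is required to rasterise a polygon ROI")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  verts <- do.call(rbind, lapply(strsplit(lines, "[,[:space:]]+"),
                                 function(v) as.numeric(v[1:2])))
  if (nrow(verts) < 3L) stop("polygon ROI needs at least 3 vertices")
  polygon_mask(verts[, 1L], verts[, 2L], dim_yx)
}

# even-odd rasterisation of a polygon given 0-based (y, x) vertices
polygon_mask <- function(py, px, dim_yx) {
  ny <- dim_yx[1L]; nx <- dim_yx[2L]
  yy <- matrix(rep(seq_len(ny) - 1L, nx), ny, nx)
  xx <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  inside <- matrix(FALSE, ny, nx)
  n <- length(py)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > yy) != (py[j] > yy)) &
      (xx < (px[j] - px[i]) * (yy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
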