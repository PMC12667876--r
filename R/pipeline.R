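#' Assemble and validate a pipeline configuration
#'
#' The configuration mirrors the analysis stages: file paths, optics,
#' channel roles, timing, wavelet mask parameters, ratio parameters and
#' fit parameters.  It can be given as a YAML file or a nested list;
#' missing groups fall back to the documented defaults (30 s frames,
#' 2 min baseline, the standard wavelet recipe).
#'
#' @param x path to a YAML file, or a nested list.
#' @param overrides named list merged over the file values (e.g. from CLI
#'   flags), using dot-paths such as `wavelet.sd_threshold_factor`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list(), overrides = list()) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    yaml::read_yaml(x)
  } else x
  stopifnot(is.list(cfg))
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    cfg <- assign_path(cfg, parts, overrides[[key]])
  }
  defaults <- list(
    paths = list(movie = NULL, roi = NULL, out_dir = "."),
    optics = list(numerical_aperture = 1.45, pixel_size_nm = 70,
                  emission_nm = list(marker = 600, biosensor = 520)),
    channels = list(marker = "marker", biosensor = "biosensor"),
    timing = list(frame_interval_s = 30, baseline_min = 2),
    wavelet = list(scale_multipliers = c(1, 2, 3, 4),
                   sd_threshold_factor = 3, dilation_cycles = 1,
                   background_mode_factor = 1.5,
                   airy_interpretation = "radius-as-sigma"),
    ratio = list(background_mode_factor = 1.5, statistic = "mean",
                 n_central = 11, roi_level_factor = 1.05),
    fit = list(model = "auto", ci = "asymptotic",
               include_baseline = FALSE),
    seed = 1L)
  known <- names(defaults)
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  user_channels <- cfg$channels                  # a channel map replaces,
  cfg <- modifyList(defaults, cfg)               # never merges with, the
  if (!is.null(user_channels)) cfg$channels <- user_channels  # default map
  roles <- unlist(cfg$channels)
  if (sum(roles == "marker") != 1L)
    stop("exactly one channel must have the role 'marker'")
  if (anyDuplicated(names(cfg$channels)))
    stop("channel names must be unique")
  structure(cfg, class = c("pipeline_config", "list"))
}

assign_path <- function(lst, parts, value) {
  if (length(parts) == 1L) {
    lst[[parts]] <- value
  } else {
    if (is.null(lst[[parts[1L]]])) lst[[parts[1L]]] <- list()
    lst[[parts[1L]]] <- assign_path(lst[[parts[1L]]], parts[-1L], value)
  }
  lst
}

canonicalise <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, canonicalise)
  } else x
}

#' MD5 hash of a configuration
#'
#' The configuration is canonicalised (keys sorted recursively) and
#' serialised to YAML before hashing, so logically equal configs hash
#' equally regardless of key order.  The output directory is excluded:
#' where results are written does not change what they are.
#'
#' @param config a [pipeline_config()] or plain list.
#' @return 32-character MD5 string.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$paths)) cfg$paths$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(canonicalise(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

log_msg <- function(level, ...) {
  message("[", level, "] ", ...)
}

#' Generate the synthetic fixture suite (pipeline stage)
#'
#' Wraps [write_fixture_suite()] with seed logging and collision
#' handling.
#'
#' @param out_dir output directory (created if missing).
#' @param seed base seed; the per-scene seeds are `seed + 0:3`.
#' @param force overwrite an existing non-empty directory.
#' @param n_frames,width,height forwarded to the generator.
#' @return the manifest, invisibly.
#' @export
cmd_simulate <- function(out_dir, seed = 1L, force = FALSE,
                         n_frames = 64L, width = 256L, height = 256L) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory '", out_dir,
         "' is not empty; use force = TRUE to overwrite")
  seeds <- c(decay = seed, recruitment = seed + 1L, control = seed + 2L,
             background = seed + 3L)
  log_msg("INFO", "simulating fixture suite with seeds ",
          paste(seeds, collapse = ", "))
  man <- write_fixture_suite(out_dir, seeds = seeds, n_frames = n_frames,
                             width = width, height = height)
  log_msg("INFO", "wrote ", length(man), " scene(s) to ", out_dir)
  invisible(man)
}

#' Run the full analysis pipeline on one or more movies
#'
#' segment -> quantify -> aggregate -> fit, end to end.  Each movie is
#' one experiment (its basename is the experiment id); cells come from
#' the configured ROI files or, when none are given, from the automatic
#' whole-cell ROI.  Per-cell failures are logged and skipped.  Outputs
#' (tidy trace CSV, aggregate CSV, fit JSON, run manifest JSON) carry the
#' config hash; they contain no timestamps, so identical inputs yield
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()], YAML path or list.
#' @return list with `traces`, `aggregate`, `fits` and the output paths,
#'   invisibly.
#' @export
cmd_run <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  movies <- cfg$paths$movie
  if (is.null(movies) || !length(movies))
    stop("config paths.movie is required")
  out_dir <- cfg$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(cfg)
  optics <- optics_spec(cfg$optics$numerical_aperture,
                        cfg$optics$pixel_size_nm,
                        unlist(cfg$optics$emission_nm))
  wp <- wavelet_params(
    scale_multipliers = cfg$wavelet$scale_multipliers,
    sd_threshold_factor = cfg$wavelet$sd_threshold_factor,
    dilation_cycles = cfg$wavelet$dilation_cycles,
    background_mode_factor = cfg$wavelet$background_mode_factor,
    airy_interpretation = cfg$wavelet$airy_interpretation)
  roles <- unlist(cfg$channels)
  marker <- names(roles)[roles == "marker"]
  sensors <- names(roles)[roles == "biosensor"]

  all_traces <- list()
  for (mv in movies) {
    exp_id <- sub("\\.tiff?$", "", basename(mv), ignore.case = TRUE)
    log_msg("INFO", "processing ", mv)
    stack <- read_movie(mv)
    missing_ch <- setdiff(c(marker, sensors), stack$channels)
    if (length(missing_ch))
      stop("movie '", mv, "' lacks configured channel(s): ",
           paste(missing_ch, collapse = ", "))
    masks <- segment_movie(stack, marker, optics, wp,
                           n_central = cfg$ratio$n_central)
    rois <- if (!is.null(cfg$paths$roi)) {
      lapply(cfg$paths$roi, read_roi,
             dim_yx = c(stack$sizes[["Y"]], stack$sizes[["X"]]))
    } else {
      log_msg("INFO", "no ROI configured; using automatic whole-cell ROI")
      list(auto_cell_roi(stack, sensors[1L],
                         level_factor = cfg$ratio$roi_level_factor,
                         n_central = cfg$ratio$n_central))
    }
    for (i in seq_along(rois)) {
      cell_id <- paste0("cell", i)
      for (ch in sensors) {
        tr <- tryCatch(
          extract_trace(stack, masks, rois[[i]], ch, cell_id = cell_id,
                        experiment_id = exp_id,
                        background_mode_factor =
                          cfg$ratio$background_mode_factor,
                        statistic = cfg$ratio$statistic,
                        n_central = cfg$ratio$n_central),
          error = function(e) {
            log_msg("WARN", "skipping ", exp_id, "/", cell_id, "/", ch,
                    ": ", conditionMessage(e))
            NULL
          })
        if (!is.null(tr)) all_traces[[length(all_traces) + 1L]] <- tr
      }
    }
  }
  if (!length(all_traces)) stop("empty result set: no cell produced a trace")
  traces <- do.call(rbind, all_traces)
  class(traces) <- c("ratio_trace", "data.frame")
  agg <- grand_mean(traces)

  t0 <- cfg$timing$baseline_min
  fits <- lapply(split(agg, agg$channel), function(a) {
    model <- cfg$fit$model
    if (model == "auto") {
      post <- a$grand_mean[a$time_min >= t0]
      model <- if (post[length(post)] < post[1L]) "decay" else "association"
    }
    f <- tryCatch(fit_one_phase(a$time_min, a$grand_mean, model = model,
                                t0 = t0, ci = cfg$fit$ci,
                                include_baseline =
                                  isTRUE(cfg$fit$include_baseline)),
                  error = function(e) {
                    log_msg("WARN", "fit failed for channel ",
                            a$channel[1L], ": ", conditionMessage(e))
                    NULL
                  })
    f
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]

  trace_path <- file.path(out_dir, "traces.csv")
  write_traces(traces, trace_path, comments = paste0("config_hash: ", hash))
  agg_path <- file.path(out_dir, "aggregate.csv")
  write_aggregate(agg, agg_path, comments = paste0("config_hash: ", hash))
  fit_path <- file.path(out_dir, "fits.json")
  fit_json <- lapply(fits, function(f) list(
    model = f$model, y0 = f$coefficients[["y0"]],
    plateau = f$coefficients[["plateau"]], K = f$coefficients[["K"]],
    tau_min = f$tau, ci95_tau = f$ci95_tau, r_squared = f$r_squared,
    df = f$df, n_points = f$n_points, converged = f$converged,
    identifiable = f$identifiable))
  jsonlite::write_json(list(config_hash = hash, fits = fit_json),
                       fit_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  man_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(list(config_hash = hash,
                            movies = as.list(movies),
                            outputs = list(traces = trace_path,
                                           aggregate = agg_path,
                                           fits = fit_path),
                            n_traces = length(all_traces)),
                       man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_msg("INFO", "wrote ", trace_path, ", ", agg_path, ", ", fit_path)
  invisible(list(traces = traces, aggregate = agg, fits = fits,
                 paths = list(traces = trace_path, aggregate = agg_path,
                              fits = fit_path, manifest = man_path)))
}
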