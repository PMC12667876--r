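# run expr with a local, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

superellipse_mask <- function(ny, nx, cy, cx, ry, rx, exponent = 2.5) {
  yy <- matrix(rep(seq_len(ny) - 1L, nx), ny, nx)
  xx <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  (abs((yy - cy) / ry))^exponent + (abs((xx - cx) / rx))^exponent <= 1
}

# truncated unit-peak Gaussian spot added in place; returns total added
add_spot <- function(img, y, x, sigma, peak) {
  r <- ceiling(3 * sigma)
  ys <- (round(y) - r):(round(y) + r)
  xs <- (round(x) - r):(round(x) + r)
  if (min(ys) < 0L || min(xs) < 0L || max(ys) > nrow(img) - 1L ||
      max(xs) > ncol(img) - 1L)
    stop("vesicle at (", y, ", ", x, ") overlaps the image border")
  g <- outer(exp(-((ys - y)^2) / (2 * sigma^2)),
             exp(-((xs - x)^2) / (2 * sigma^2)))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + peak * g
  img
}

disk_mask <- function(ny, nx, y, x, radius) {
  yy <- matrix(rep(seq_len(ny) - 1L, nx), ny, nx)
  xx <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  (yy - y)^2 + (xx - x)^2 <= radius^2
}

#' Define a synthetic time-lapse biosensor experiment
#'
#' Builds the ground truth for a simulated movie: a superellipse cell
#' footprint filled with cytosolic signal, diffraction-limited vesicles
#' (isotropic Gaussian spots, sigma = radius/2) labelled in a membrane
#' marker channel, and one or more biosensor channels whose vesicular
#' enrichment follows a [kinetics_spec()] around the treatment time.
#' Rendering ([render_movie()]) applies the Gaussian PSF and, optionally,
#' Poisson photon noise plus Gaussian read noise on top of a camera
#' offset.  The cell does not move; vesicle geometry is static.
#'
#' The per-frame biosensor spot amplitude is calibrated against the
#' PSF-blurred components so that, with the true vesicle mask and the
#' footprint as ROI, the mask-to-whole-cell ratio of the noise-free movie
#' equals the analytic enrichment curve exactly.
#'
#' @param width,height image size in pixels; default 256.
#' @param n_frames number of frames; default 64.
#' @param frame_interval_s seconds per frame; default 30.
#' @param kinetics named list of [kinetics_spec()], one per biosensor
#'   channel (names become channel names).
#' @param optics an [optics_spec()] with wavelengths for `"marker"` and
#'   every biosensor channel.
#' @param n_vesicles number of vesicles (20-60 is typical); default 40.
#' @param radius_range vesicle radius range in pixels; default `c(5, 8)`
#'   (0.7-1.1 um late-endosome/lysosome diameters at 70 nm/px).
#' @param peak_marker mean peak marker intensity of a vesicle in expected
#'   photon counts; per-vesicle peaks vary uniformly within +/-30%.
#' @param cyto named cytosol levels (expected counts) per channel.
#' @param noise list `(poisson=, read_sd=, offset=)` or `NULL` for a
#'   noise-free scene.
#' @param n_slices,z_step_um optional z-stack mode: slices rendered with a
#'   Gaussian axial intensity profile, spacing in microns.
#' @param seed RNG seed (mandatory); governs vesicle placement and noise.
#' @return an object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(width = 256L, height = 256L, n_frames = 64L,
                            frame_interval_s = 30,
                            kinetics = list(biosensor = kinetics_spec(
                              "one_phase_decay", y0 = 2, plateau = 1.1,
                              K = 1 / 9.5, treatment_time_min = 2)),
                            optics = NULL,
                            n_vesicles = 40L,
                            radius_range = c(5, 8),
                            peak_marker = 1200,
                            cyto = NULL,
                            noise = list(poisson = TRUE, read_sd = 2,
                                         offset = 100),
                            n_slices = 1L, z_step_um = 0.175,
                            seed) {
  if (missing(seed)) stop("seed is mandatory for scene generation")
  stopifnot(is.list(kinetics), length(kinetics) >= 1L,
            !is.null(names(kinetics)),
            all(vapply(kinetics, inherits, TRUE, "kinetics_spec")),
            n_frames >= 1L, width >= 32L, height >= 32L)
  bios <- names(kinetics)
  channels <- c("marker", bios)
  if (is.null(optics)) {
    wl <- c(600, rep(520, length(bios)))
    names(wl) <- channels
    optics <- optics_spec(1.45, 70, wl)
  }
  if (!all(channels %in% names(optics$emission_nm)))
    stop("optics must provide wavelengths for channels: ",
         paste(channels, collapse = ", "))
  if (is.null(cyto)) {
    # organelle markers are predominantly membrane-bound (low cytosolic
    # pool); biosensors keep a substantial cytosolic fraction
    cyto <- c(25, rep(150, length(bios)))
    names(cyto) <- channels
  }
  stopifnot(all(channels %in% names(cyto)))
  tt <- vapply(kinetics, `[[`, 0, "treatment_time_min")
  if (length(unique(tt)) > 1L)
    stop("all channels must share one treatment time")

  cy <- (height - 1) / 2; cx <- (width - 1) / 2
  ry <- 0.42 * height; rx <- 0.42 * width
  footprint <- superellipse_mask(height, width, cy, cx, ry, rx)

  ves <- with_seed(seed, {
    if (n_vesicles > 0L) {
      radius <- stats::runif(n_vesicles, radius_range[1L], radius_range[2L])
      peak <- peak_marker * stats::runif(n_vesicles, 0.7, 1.3)
      y <- numeric(n_vesicles); x <- numeric(n_vesicles)
      for (i in seq_len(n_vesicles)) {
        repeat {
          yy <- cy + 0.88 * ry * (2 * stats::runif(1) - 1)
          xx <- cx + 0.88 * rx * (2 * stats::runif(1) - 1)
          margin <- ceiling(3 * radius[i]) + 1
          inside <- footprint[round(yy) + 1L, round(xx) + 1L]
          if (inside && yy >= margin && xx >= margin &&
              yy <= height - 1 - margin && xx <= width - 1 - margin) {
            y[i] <- yy; x[i] <- xx; break
          }
        }
      }
      data.frame(id = seq_len(n_vesicles), y = y, x = x,
                 radius_px = radius, peak = peak)
    } else {
      data.frame(id = integer(), y = numeric(), x = numeric(),
                 radius_px = numeric(), peak = numeric())
    }
  })

  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 kinetics = kinetics, optics = optics,
                 channels = channels, cyto = cyto, vesicles = ves,
                 footprint = footprint, noise = noise,
                 n_slices = as.integer(n_slices), z_step_um = z_step_um,
                 treatment_time_min = unname(tt[1L]), seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %dx%d px, %d frame(s) @ %g s, %d vesicle(s), seed %d\n",
              x$width, x$height, x$n_frames, x$frame_interval_s,
              nrow(x$vesicles), x$seed))
  for (ch in names(x$kinetics))
    cat("  ", ch, ": ", x$kinetics[[ch]]$model, "\n", sep = "")
  invisible(x)
}

#' Ground-truth vesicle mask of a scene
#'
#' Pixels within each vesicle's radius of its centre (the geometry the
#' segmentation chain is judged against).
#'
#' @param scene a [synthetic_scene()].
#' @return logical height x width matrix.
#' @export
true_mask <- function(scene) {
  m <- matrix(FALSE, scene$height, scene$width)
  for (i in seq_len(nrow(scene$vesicles)))
    m <- m | disk_mask(scene$height, scene$width, scene$vesicles$y[i],
                       scene$vesicles$x[i], scene$vesicles$radius_px[i])
  m
}

#' Render a scene into a movie plus ground truth
#'
#' Each frame is the cell-footprint cytosolic baseline plus the vesicle
#' spots, the biosensor-channel spot amplitude following the scene's
#' kinetics; the PSF is applied as a Gaussian blur and Poisson-Gaussian
#' noise is applied last.  With the same scene (hence seed) the movie is
#' bit-identical across calls.
#'
#' @param scene a [synthetic_scene()].
#' @param noise override the scene's noise model (`TRUE` = use it,
#'   `FALSE` = render noise-free).
#' @param psf apply the PSF blur; default `TRUE`.
#' @return list with `stack` (an [image_stack()]) and `truth`: per-frame
#'   ground-truth masks, the analytic ratio table (`time_min`, `channel`,
#'   `true_ratio`), the vesicle table (with each vesicle's integrated
#'   marker intensity), the footprint and the kinetics.
#' @export
render_movie <- function(scene, noise = TRUE, psf = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  use_noise <- isTRUE(noise) && !is.null(scene$noise)
  nz <- scene$n_slices
  ny <- scene$height; nx <- scene$width
  chans <- scene$channels
  nc <- length(chans)
  times <- (seq_len(scene$n_frames) - 1L) * scene$frame_interval_s / 60

  # static spot field (unit global amplitude, per-vesicle peaks as weights)
  spots <- matrix(0, ny, nx)
  total_per_ves <- numeric(nrow(scene$vesicles))
  for (i in seq_len(nrow(scene$vesicles))) {
    before <- sum(spots)
    spots <- add_spot(spots, scene$vesicles$y[i], scene$vesicles$x[i],
                      scene$vesicles$radius_px[i] / 2,
                      scene$vesicles$peak[i])
    total_per_ves[i] <- sum(spots) - before
  }
  mask <- true_mask(scene)
  fp <- scene$footprint

  # per-channel blurred components; biosensor amplitude A(t) is solved on
  # these so the noise-free mask/cell ratio equals the analytic curve
  comp <- lapply(chans, function(ch) {
    sig <- if (psf) scene$optics$psf_sigma_px[[ch]] else 0
    cy <- scene$cyto[[ch]] * fp
    if (sig > 0) list(cyto = gaussian_blur(cy, sig),
                      spots = gaussian_blur(spots, sig))
    else list(cyto = cy, spots = spots)
  })
  names(comp) <- chans

  amp_for_ratio <- function(ch, R) {
    b <- comp[[ch]]
    mnum <- mask & fp
    mc_n <- mean(b$cyto[mnum]); mc_d <- mean(b$cyto[fp])
    ms_n <- mean(b$spots[mnum]); ms_d <- mean(b$spots[fp])
    den <- ms_n - R * ms_d
    if (den <= 0) stop("target ratio ", R, " unreachable for channel ", ch)
    a <- (R * mc_d - mc_n) / den
    if (a < 0) stop("target ratio ", R, " below the cytosol-only ratio")
    a
  }

  truth_ratio <- do.call(rbind, lapply(chans[-1L], function(ch) {
    data.frame(time_min = times, channel = ch,
               true_ratio = enrichment_at(scene$kinetics[[ch]], times),
               stringsAsFactors = FALSE)
  }))

  zw <- if (nz > 1L) {
    zc <- (nz - 1) / 2
    exp(-(((seq_len(nz) - 1) - zc) * scene$z_step_um)^2 / (2 * 1.0^2))
  } else 1

  arr <- array(0, dim = c(scene$n_frames, nz, nc, ny, nx))
  with_seed(scene$seed, {
    for (t in seq_len(scene$n_frames)) {
      for (ci in seq_along(chans)) {
        ch <- chans[ci]
        expected <- if (ch == "marker") {
          comp[[ch]]$cyto + comp[[ch]]$spots
        } else {
          R <- enrichment_at(scene$kinetics[[ch]], times[t])
          A <- if (nrow(scene$vesicles)) amp_for_ratio(ch, R) else 0
          comp[[ch]]$cyto + A * comp[[ch]]$spots
        }
        for (z in seq_len(nz)) {
          img <- expected * zw[z]
          if (use_noise) {
            nm <- scene$noise
            if (isTRUE(nm$poisson))
              img <- matrix(stats::rpois(length(img), pmax(img, 0)), ny, nx)
            img <- img + (nm$offset %||% 0) +
              stats::rnorm(length(img), 0, nm$read_sd %||% 0)
          }
          arr[t, z, ci, , ] <- img
        }
      }
    }
  })

  roles <- c(marker = "marker",
             stats::setNames(rep("biosensor", nc - 1L), chans[-1L]))
  stack <- image_stack(arr, channels = chans, channel_roles = roles,
                       frame_interval_s = scene$frame_interval_s,
                       treatment_time_min = scene$treatment_time_min,
                       z_step_um = if (nz > 1L) scene$z_step_um else NA_real_)
  ves <- scene$vesicles
  ves$total_marker <- total_per_ves
  list(stack = stack,
       truth = list(masks = rep(list(mask), scene$n_frames),
                    ratio = truth_ratio,
                    vesicles = ves,
                    footprint = fp,
                    kinetics = scene$kinetics))
}

#' Preset scenes for the fixture suite
#'
#' Three study designs: an inhibitor-style decay of the biosensor ratio
#' (baseline ratio 2.0 falling to 1.1 with tau = 9.5 min), a
#' dimerisation-style recruitment (1.1 rising to 2.0 with tau = 2 min),
#' and a kinase-dead negative control (constant 1.5).  All use 2 min of
#' baseline at 30 s per frame.  The baseline ratios sit above the
#' cytosol-only floor (~1.005 after PSF edge rolloff) that any rendered
#' scene must respect.
#'
#' @param name `"decay"`, `"recruitment"`, `"control"` or `"background"`
#'   (a no-vesicle noise scene for false-positive checks).
#' @param seed RNG seed.
#' @param n_frames,width,height scene geometry; defaults 64 frames at
#'   256 x 256.  The vesicle count scales with the cell area (40 at the
#'   default geometry) so smaller scenes keep the same vesicle density
#'   and the biosensor enrichment stays physically reachable.
#' @return a [synthetic_scene()].
#' @export
preset_scene <- function(name = c("decay", "recruitment", "control",
                                  "background"),
                         seed, n_frames = 64L, width = 256L,
                         height = 256L) {
  name <- match.arg(name)
  kin <- switch(name,
    decay = kinetics_spec("one_phase_decay", y0 = 2, plateau = 1.1,
                          K = 1 / 9.5, treatment_time_min = 2),
    recruitment = kinetics_spec("one_phase_association", y0 = 1.1,
                                plateau = 2, K = 1 / 2,
                                treatment_time_min = 2),
    control = kinetics_spec("constant", y0 = 1.5, treatment_time_min = 2),
    background = kinetics_spec("constant", y0 = 1, treatment_time_min = 2))
  n_ves <- max(4L, as.integer(round(40 * (width / 256) * (height / 256))))
  synthetic_scene(width = width, height = height, n_frames = n_frames,
                  kinetics = list(biosensor = kin),
                  n_vesicles = if (name == "background") 0L else n_ves,
                  # the background scene is pure detector output: no cell,
                  # no vesicles, just offset + noise
                  cyto = if (name == "background")
                    c(marker = 0, biosensor = 0) else NULL,
                  seed = seed)
}

#' Write the synthetic fixture suite
#'
#' Renders the preset scenes and writes, per scene: the movie (16-bit
#' multi-page TIFF + JSON sidecar), the ground-truth masks (8-bit TIFF),
#' the analytic ratio table and vesicle table (CSV), and the true kinetic
#' parameters (CSV, including tau = 1/K).  A JSON manifest indexes the
#' files with their MD5 checksums.
#'
#' @param out_dir output directory (created if missing).
#' @param seeds named or unnamed integer seeds, one per scene; default
#'   `c(decay = 101, recruitment = 102, control = 103, background = 104)`.
#' @param n_frames,width,height geometry forwarded to [preset_scene()].
#' @return the manifest, invisibly (list with one entry per scene).
#' @export
write_fixture_suite <- function(out_dir,
                                seeds = c(decay = 101L, recruitment = 102L,
                                          control = 103L,
                                          background = 104L),
                                n_frames = 64L, width = 256L,
                                height = 256L) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (is.null(names(seeds)))
    names(seeds) <- c("decay", "recruitment", "control",
                      "background")[seq_along(seeds)]
  manifest <- list()
  for (nm in names(seeds)) {
    scene <- preset_scene(nm, seed = seeds[[nm]], n_frames = n_frames,
                          width = width, height = height)
    rend <- render_movie(scene)
    movie <- file.path(out_dir, paste0(nm, ".tif"))
    write_movie(rend$stack, movie)
    maskf <- file.path(out_dir, paste0(nm, "_true_masks.tif"))
    write_mask(rend$truth$masks, maskf)
    ratf <- file.path(out_dir, paste0(nm, "_true_ratio.csv"))
    utils::write.csv(rend$truth$ratio, ratf, row.names = FALSE)
    vesf <- file.path(out_dir, paste0(nm, "_vesicles.csv"))
    utils::write.csv(rend$truth$vesicles, vesf, row.names = FALSE)
    kin <- scene$kinetics[[1L]]
    parf <- file.path(out_dir, paste0(nm, "_true_params.csv"))
    utils::write.csv(data.frame(channel = names(scene$kinetics)[1L],
                                model = kin$model, y0 = kin$y0,
                                plateau = kin$plateau, K = kin$K,
                                tau_min = 1 / kin$K,
                                treatment_time_min = kin$treatment_time_min),
                     parf, row.names = FALSE)
    files <- c(movie = movie, sidecar = paste0(movie, ".json"),
               masks = maskf, ratio = ratf, vesicles = vesf, params = parf)
    manifest[[nm]] <- list(scene = nm, seed = seeds[[nm]],
                           files = as.list(files),
                           md5 = as.list(tools::md5sum(unname(files))))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
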