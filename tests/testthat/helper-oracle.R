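# Brute-force reference implementations of the segmentation chain,
# written as direct per-pixel loops so they are structurally independent
# of the production code (separable convolution, shift-OR dilation).

oracle_reflect <- function(i, n) {
  # build the reflected index by walking, not by modular arithmetic
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_blur <- function(frame, sigma) {
  if (sigma == 0) return(frame)
  r <- ceiling(4 * sigma)
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)              # full 2-D kernel, not separable passes
  ny <- nrow(frame); nx <- ncol(frame)
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x2 in seq_len(nx)) {
    rows <- vapply(y + (-r:r), oracle_reflect, 1L, n = ny)
    cols <- vapply(x2 + (-r:r), oracle_reflect, 1L, n = nx)
    out[y, x2] <- sum(k2 * frame[rows, cols])
  }
  out
}

oracle_dilate <- function(mask, cycles) {
  ny <- nrow(mask); nx <- ncol(mask)
  for (cyc in seq_len(cycles)) {
    out <- matrix(FALSE, ny, nx)
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      hit <- FALSE
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1L && yy <= ny && xx >= 1L && xx <= nx && mask[yy, xx])
          hit <- TRUE
      }
      out[y, x] <- hit
    }
    mask <- out
  }
  mask
}

# the whole chain, per-pixel: blur stack, planes, clamped product,
# threshold on the original frame's SD, dilation
oracle_segment <- function(frame, airy_px, multipliers = c(1, 2, 3, 4),
                           sd_factor = 3, dilation = 1L) {
  blurred <- lapply(multipliers, function(m) oracle_blur(frame, m * airy_px))
  ny <- nrow(frame); nx <- ncol(frame)
  prod <- matrix(1, ny, nx)
  for (i in seq_len(length(blurred) - 1L)) {
    plane <- blurred[[i]] - blurred[[i + 1L]]
    for (y in seq_len(ny)) for (x in seq_len(nx))
      prod[y, x] <- prod[y, x] * max(plane[y, x], 0)
  }
  thr <- sd_factor * stats::sd(as.vector(frame))
  mask <- prod > thr
  if (dilation > 0L) mask <- oracle_dilate(mask, dilation)
  list(blurred = blurred, product = prod, threshold = thr, mask = mask)
}

# small seeded scene used by several files: fast to render, one biosensor
tiny_decay_scene <- function(seed = 7L, n_frames = 6L, noise = TRUE) {
  synthetic_scene(width = 96L, height = 96L, n_frames = n_frames,
                  kinetics = list(biosensor = kinetics_spec(
                    "one_phase_decay", y0 = 2, plateau = 1.1, K = 1 / 9.5,
                    treatment_time_min = 2)),
                  n_vesicles = 6L,
                  noise = if (noise) list(poisson = TRUE, read_sd = 2,
                                          offset = 100) else NULL,
                  seed = seed)
}
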