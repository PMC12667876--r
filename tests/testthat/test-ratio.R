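test_that("central-slice projection picks the documented window", {
  # 57 slices, value of slice i is i: the 11 central slices are 24..34
  # (1-based), so the projection is mean(24:34) = 29
  z <- array(0, dim = c(57L, 2L, 2L))
  for (i in 1:57) z[i, , ] <- i
  expect_equal(mean_projection(z, 11L), matrix(29, 2L, 2L))
  # even slice count ties toward the lower index: 4 slices, n=2 -> 2:3
  z4 <- array(0, dim = c(4L, 1L, 1L)); for (i in 1:4) z4[i, , ] <- i
  expect_equal(mean_projection(z4, 2L)[1L, 1L], 2.5)
  # all slices identical: projection equals any slice
  zc <- array(7, dim = c(5L, 3L, 3L))
  expect_equal(mean_projection(zc, 3L), matrix(7, 3L, 3L))
  # n_central = total is the ordinary mean projection
  expect_equal(mean_projection(z4, 4L)[1L, 1L], 2.5)
  expect_error(mean_projection(z4, 0L), "positive")
  expect_error(mean_projection(z4, 9L), "exceeds")
})

test_that("modal background is factor times the histogram mode", {
  expect_equal(as.numeric(modal_background(matrix(100L, 4L, 4L))), 150)
  expect_equal(as.numeric(modal_background(matrix(100L, 4L, 4L),
                                           factor = 2)), 200)
  # background-dominated frame with sparse bright spots: mode = offset
  set.seed(61)
  fr <- matrix(80, 50L, 50L) + matrix(sample(0:1, 2500, TRUE), 50L)
  fr[1:3, 1:3] <- 4000
  lev <- modal_background(fr)
  expect_lte(abs(attr(lev, "mode") - 80), 1)     # within one histogram bin
  # ties are flagged and resolved toward the lowest bin
  tie <- modal_background(c(1, 1, 5, 5))
  expect_true(attr(tie, "tied"))
  expect_equal(as.numeric(tie), 1.5)
})

test_that("frame ratio is a mean-over-mask to mean-over-cell quotient", {
  # hand-computed 6x6 fixture: biosensor only inside a 2x2 mask block
  fr <- matrix(0, 6L, 6L)
  fr[3:4, 3:4] <- 5
  roi <- matrix(TRUE, 6L, 6L)
  mask <- matrix(FALSE, 6L, 6L); mask[3:4, 3:4] <- TRUE
  r <- frame_ratio(fr, mask, roi)
  # mean over mask = 5; mean over cell = 4*5/36; ratio = 36/4 = 9
  expect_equal(r$ratio, 9)
  expect_identical(r$mask_area_px, 4L)
  # uniform biosensor over the cell: ratio exactly 1
  expect_identical(frame_ratio(matrix(3.3, 6L, 6L), mask, roi)$ratio, 1)
  # scale invariance with zero background
  expect_equal(frame_ratio(2 * fr, mask, roi)$ratio, r$ratio)
  # empty numerator region is missing, not zero
  disjoint <- frame_ratio(fr, mask, !mask)
  expect_true(is.na(disjoint$ratio))
  expect_identical(disjoint$mask_area_px, 0L)
  expect_error(frame_ratio(fr, mask, matrix(FALSE, 6L, 6L)), "empty")
})

test_that("background subtraction clamps at zero and shifts the ratio", {
  fr <- matrix(10, 4L, 4L); fr[2L, 2L] <- 110
  mask <- matrix(FALSE, 4L, 4L); mask[2L, 2L] <- TRUE
  roi <- matrix(TRUE, 4L, 4L)
  # level 10 wipes the cytosol, keeping only the spot
  r <- frame_ratio(fr, mask, roi, background_level = 10)
  expect_equal(r$ratio, 100 / (100 / 16))
  # integrated (sum) statistic scales with area as documented
  ri <- frame_ratio(fr, mask, roi, background_level = 10,
                    statistic = "integrated")
  expect_equal(ri$ratio, 1)
})

test_that("trace times follow the 30-second frame interval in minutes", {
  sc <- tiny_decay_scene(seed = 19L, n_frames = 5L, noise = FALSE)
  rd <- render_movie(sc, noise = FALSE)
  tr <- extract_trace(rd$stack, rd$truth$masks, rd$truth$footprint,
                      "biosensor", background_mode_factor = NULL)
  expect_equal(tr$time_min, c(0, 0.5, 1, 1.5, 2))
  expect_equal(attr(tr, "treatment_time_min"), 2)
  expect_error(extract_trace(rd$stack, rd$truth$masks[1:2],
                             rd$truth$footprint, "biosensor"),
               "one mask per frame")
})

test_that("grand mean averages experiments, then cells, with SEM across experiments", {
  mk <- function(exp, cell, val)
    data.frame(experiment_id = exp, cell_id = cell, channel = "b",
               time_min = 0, ratio = val, mask_area_px = 1L,
               qc_excluded = FALSE, qc_reason = "")
  # three experiments with per-experiment means 1, 2, 3
  tr <- rbind(mk("e1", "c1", 1), mk("e2", "c1", 2), mk("e3", "c1", 3))
  agg <- grand_mean(tr)
  expect_equal(agg$grand_mean, 2)
  expect_equal(agg$sem, 1 / sqrt(3))             # sd({1,2,3}) = 1
  expect_equal(agg$sem, 0.5773503, tolerance = 1e-7)
  expect_identical(agg$n_experiments, 3L)
  expect_identical(agg$n_cells, 3L)
  # cells average within experiment first
  tr2 <- rbind(mk("e1", "c1", 0.5), mk("e1", "c2", 1.5),
               mk("e2", "c1", 2), mk("e3", "c1", 3))
  expect_equal(grand_mean(tr2)$grand_mean, 2)
  # identical values give SEM 0
  tr3 <- rbind(mk("e1", "c1", 2), mk("e2", "c1", 2), mk("e3", "c1", 2))
  expect_equal(grand_mean(tr3)$sem, 0)
  # single experiment: SEM 0 by convention, flagged
  agg1 <- grand_mean(mk("e1", "c1", 1.7))
  expect_equal(agg1$sem, 0)
  expect_true(isTRUE(attr(agg1, "single_experiment")))
})

test_that("flat hierarchies reduce to the ordinary mean and SEM", {
  set.seed(71)
  vals <- rnorm(8, 2, 0.3)
  tr <- do.call(rbind, lapply(seq_along(vals), function(i)
    data.frame(experiment_id = paste0("e", i), cell_id = "c1",
               channel = "b", time_min = 0, ratio = vals[i],
               mask_area_px = 1L, qc_excluded = FALSE, qc_reason = "")))
  agg <- grand_mean(tr)
  expect_equal(agg$grand_mean, mean(vals))
  expect_equal(agg$sem, sd(vals) / sqrt(length(vals)))
})

test_that("QC-excluded traces are skipped and empty experiments dropped", {
  mk <- function(exp, val, excl = FALSE)
    data.frame(experiment_id = exp, cell_id = "c1", channel = "b",
               time_min = 0, ratio = val, mask_area_px = 1L,
               qc_excluded = excl, qc_reason = "")
  tr <- rbind(mk("e1", 1), mk("e2", 2), mk("e3", 99, excl = TRUE))
  expect_warning(agg <- grand_mean(tr), "e3")
  expect_equal(agg$grand_mean, 1.5)
  expect_identical(agg$n_experiments, 2L)
})

test_that("automatic cell ROI recovers the footprint on synthetic data", {
  sc <- tiny_decay_scene(seed = 27L, n_frames = 3L)
  rd <- render_movie(sc)
  roi <- auto_cell_roi(rd$stack, "biosensor")
  fp <- rd$truth$footprint
  jac <- sum(roi & fp) / sum(roi | fp)
  expect_gte(jac, 0.9)
})
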