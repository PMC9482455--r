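render_spots <- function(xy, amp = 3000, pixel_size = 5, noise_sd = 0, seed = NULL) {
  cells <- data.frame(class = "input", x = xy[, 1], y = xy[, 2],
                      gfp = 0, dsred = amp)
  render_tracing_section(cells, section_geometry(pixel_size = pixel_size),
                         noise_sd = noise_sd, seed = seed)
}

test_that("a blank noise-free image yields no detections, with a warning", {
  img <- matrix(100, 50, 50)
  expect_warning(det <- detect_blobs(img), "blank")
  expect_equal(nrow(det), 0)
})

test_that("planted non-overlapping spots are detected at their centers", {
  xy <- cbind(c(-1500, -1000, -500, 500, 1200), c(500, 1500, 2500, 800, 2000))
  sec <- render_spots(xy)
  det <- detect_blobs(sec$image[, , 3], min_area = 2, pixel_size = 5,
                      origin = sec$geometry$frame[1:2])
  expect_equal(nrow(det), 5)
  d <- vapply(seq_len(5), function(i) {
    min(sqrt((det$x - xy[i, 1])^2 + (det$y - xy[i, 2])^2))
  }, numeric(1))
  expect_true(all(d <= 5))  # within 1 px (5 um)
})

test_that("two merged spots give one detection (documented limitation)", {
  xy <- cbind(c(-1000, -995), c(500, 502))   # 5-6 um apart, psf 10 um
  sec <- render_spots(xy)
  det <- detect_blobs(sec$image[, , 3], min_area = 2, pixel_size = 5,
                      origin = sec$geometry$frame[1:2])
  expect_equal(nrow(det), 1)
})

test_that("detection is invariant to positive channel rescaling", {
  xy <- cbind(c(-1200, -400, 800), c(400, 1400, 2400))
  sec <- render_spots(xy, noise_sd = 20, seed = 12)
  ch <- sec$image[, , 3]
  d1 <- detect_blobs(ch, min_area = 2, pixel_size = 5)
  d2 <- detect_blobs(ch * 7.3, min_area = 2, pixel_size = 5)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1$x, d2$x, tolerance = 1e-12)
  expect_equal(d2$mean_intensity, d1$mean_intensity * 7.3, tolerance = 1e-12)
})

test_that("mask overlap separates starters, inputs and helper-only cells", {
  geom <- section_geometry(pixel_size = 5)
  cells <- data.frame(
    class = c("starter", "input", "helper"),
    x = c(-1200, -400, 900), y = c(400, 1600, 2500),
    gfp = c(3000, 0, 3000), dsred = c(3000, 3000, 0))
  sec <- render_tracing_section(cells, geom, noise_sd = 0)
  org <- geom$frame[1:2]
  g <- detect_blobs(sec$image[, , 2], 2, pixel_size = 5, origin = org)
  r <- detect_blobs(sec$image[, , 3], 2, pixel_size = 5, origin = org)
  cl <- classify_cells(g, r)
  expect_equal(sort(cl$class), c("helper_only", "input", "starter"))
  # identical masks -> starter; zero overlap -> input (already covered above);
  # bookkeeping: no cell lost or double-counted
  expect_equal(nrow(cl), 3)
})

test_that("a rendered cohort section classifies to the planted per-class counts", {
  cfg <- image_mode_config()
  sim <- simulate_animal(cfg, "WT_young", "M", "cq1", seed = 33, level = "cells")
  q <- image_mode_counts(sim$cells)
  expect_equal(q$S, sim$animal$S)
  truth <- stats::setNames(sim$counts$count, sim$counts$key)
  expect_equal(q$counts[names(truth)], truth)
  expect_equal(q$n_helper, sum(sim$cells$class == "helper"))
  # S + N_tot + helper_only equals total planted cells (none lost)
  expect_equal(q$S + sum(q$counts) + q$n_helper + q$n_flagged, nrow(sim$cells))
})

test_that("starters outside ipsilateral CA1 are flagged and excluded", {
  cells <- data.frame(class = c("starter", "starter", "input"),
                      key = c("CA1_Py_ipsi", "SUB_ipsi", "CA3_Py_ipsi"))
  out <- restrict_starters(cells)
  expect_equal(out$class, c("starter", "starter_flagged", "input"))
  all_bad <- data.frame(class = "starter", key = "SUB_ipsi")
  expect_error(restrict_starters(all_bad), "CSI undefined")
})
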