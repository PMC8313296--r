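# Grid detector: preprocessing, NCC detection, NMS, evaluation.

test_that("letterbox preprocessing produces a 448 canvas with an exact inverse", {
  cfg <- detector_config()
  # identity on a canvas-sized input
  img <- matrix(runif(448 * 448, 0, 255), 448, 448)
  pp <- detect_preprocess(img, cfg)
  expect_equal(dim(pp$canvas), c(448, 448))
  expect_equal(pp$transform$scale, 1)
  expect_equal(pp$canvas, img)
  # 2x downscale: canvas point maps back to source at double coordinates
  big <- matrix(runif(896 * 896, 0, 255), 896, 896)
  pp2 <- detect_preprocess(big, cfg)
  expect_equal(pp2$transform$scale, 0.5)
  src <- (c(100, 100) - c(pp2$transform$offset_x, pp2$transform$offset_y)) /
    pp2$transform$scale
  expect_equal(src, c(200, 200))
  # wide input letterboxes vertically by 112 canvas px
  wide <- matrix(runif(448 * 896, 0, 255), 448, 896)
  pp3 <- detect_preprocess(wide, cfg)
  expect_equal(pp3$transform$scale, 0.5)
  expect_equal(pp3$transform$offset_y, 112)
  expect_equal(pp3$transform$offset_x, 0)
  # letterbox rows hold the background level
  expect_true(all(pp3$canvas[1:112, ] == cfg$background_level))
})

test_that("a blank image yields an empty detection list", {
  dets <- detect_cells(matrix(200, 300, 300))
  expect_equal(nrow(dets), 0)
  expect_named(dets, c("X", "Y", "W", "H", "p", "class"))
})

test_that("detections carry five numeric predictions with valid ranges", {
  spec <- small_spec(n_cells = 8, seed = 13)
  ph <- generate_phantom(spec, small_geom(nx = 2, ny = 2))
  dets <- detect_cells(ph$panorama)
  expect_true(all(dets$p >= 0 & dets$p <= 1))
  expect_true(all(dets$W > 0 & dets$H > 0))
  expect_true(all(is.na(dets$class)))
})

test_that("a single rendered soma is localized within 3 px of its centre", {
  spec <- small_spec(noise_sd = 0)
  for (orient in c(0, 0.7, 1.3)) {
    patch <- render_cell(spec, "pyknotic", 0, orientation = orient)
    canvas <- matrix(200, 300, 300)
    ctr <- attr(patch, "center")
    cx <- 151; cy <- 142
    rows <- cy - ctr[2] + seq_len(nrow(patch))
    cols <- cx - ctr[1] + seq_len(ncol(patch))
    keep <- !is.na(patch)
    sub <- canvas[rows, cols]; sub[keep] <- patch[keep]
    canvas[rows, cols] <- sub
    dets <- detect_cells(canvas)
    expect_equal(nrow(dets), 1)
    expect_lte(abs(dets$X - cx), 3)
    expect_lte(abs(dets$Y - cy), 3)
  }
})

test_that("recall on a well-separated 20-cell phantom is at least 0.9", {
  spec <- small_spec(n_cells = 20, seed = 11)
  ph <- generate_phantom(spec, small_geom(nx = 4, ny = 4))
  dets <- detect_cells(stitch(ph$manifest))
  ev <- evaluate_detections(dets, ph$truth)
  expect_gte(ev$recall, 0.9)
})

test_that("detection is translation-covariant on noise-free phantoms", {
  spec <- small_spec(n_cells = 3, noise_sd = 0, seed = 21)
  ph <- generate_phantom(spec, small_geom(nx = 3, ny = 3))
  px <- ph$panorama$pixels
  dx <- 5L; dy <- 7L
  shifted <- matrix(200, nrow(px), ncol(px))
  shifted[(dy + 1):nrow(px), (dx + 1):ncol(px)] <-
    px[1:(nrow(px) - dy), 1:(ncol(px) - dx)]
  d0 <- detect_cells(px)
  d1 <- detect_cells(shifted)
  expect_equal(nrow(d0), nrow(d1))
  d0 <- d0[order(d0$X, d0$Y), ]; d1 <- d1[order(d1$X, d1$Y), ]
  expect_true(all(abs(d1$X - d0$X - dx) <= 1))
  expect_true(all(abs(d1$Y - d0$Y - dy) <= 1))
})

test_that("mean best-match confidence never rises with added noise", {
  mean_p_at <- function(noise_sd) {
    spec <- small_spec(n_cells = 8, noise_sd = noise_sd, seed = 33)
    ph <- generate_phantom(spec, small_geom(nx = 2, ny = 2))
    dets <- detect_cells(ph$panorama)
    # per truth cell, the best confidence of any detection within 10 px
    vapply(seq_len(nrow(ph$truth)), function(i) {
      near <- abs(dets$X - ph$truth$cx[i]) <= 10 &
        abs(dets$Y - ph$truth$cy[i]) <= 10
      if (any(near)) max(dets$p[near]) else 0
    }, numeric(1)) |> mean()
  }
  ps <- vapply(c(2, 8, 20), mean_p_at, numeric(1))
  expect_true(all(diff(ps) <= 1e-9))
})

test_that("NMS resolves hand-built cases per the greedy rule", {
  two <- data.frame(X = c(50, 50), Y = c(50, 50), W = 20, H = 20,
                    p = c(0.9, 0.6), class = NA_character_)
  expect_equal(nms(two)$p, 0.9)
  # a lone box below the 0.5 floor disappears
  low <- data.frame(X = 10, Y = 10, W = 8, H = 8, p = 0.4,
                    class = NA_character_)
  expect_equal(nrow(nms(low)), 0)
  # disjoint boxes both survive
  far <- data.frame(X = c(10, 90), Y = c(10, 90), W = 10, H = 10,
                    p = c(0.8, 0.7), class = NA_character_)
  expect_equal(sort(nms(far)$p), c(0.7, 0.8))
  # suppression happens before flooring: a 0.45 box may suppress a 0.44
  # overlapping box, then both drop
  pair <- data.frame(X = c(30, 31), Y = c(30, 30), W = 20, H = 20,
                     p = c(0.45, 0.44), class = NA_character_)
  expect_equal(nrow(nms(pair)), 0)
})

test_that("NMS equals a brute-force max-pick oracle on random box sets", {
  set.seed(202)
  for (k in seq_len(200)) {
    dets <- random_boxes(sample(1:12, 1))
    got <- nms(dets)
    want <- nms_oracle(dets)
    got <- got[order(got$X, got$Y, got$p), c("X", "Y", "W", "H", "p")]
    want <- want[order(want$X, want$Y, want$p), c("X", "Y", "W", "H", "p")]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("evaluation matches greedily by IoU with ghosts excluded", {
  truth <- data.frame(X = c(50, 150, 250), Y = 50, W = 30, H = 30,
                      status = c("viable", "pyknotic", "ghost"))
  # perfect detections with true classes: accuracy 1 on the 2 non-ghosts
  dets <- data.frame(X = c(50, 150), Y = 50, W = 30, H = 30, p = 0.9,
                     class = c("viable", "pyknotic"))
  ev <- evaluate_detections(dets, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$n_truth, 2)
  # empty detections: recall 0
  ev0 <- evaluate_detections(dets[0, ], truth)
  expect_equal(ev0$recall, 0)
  # a ghost-matching detection hurts precision unless ghost-tolerant
  dg <- rbind(dets, data.frame(X = 250, Y = 50, W = 30, H = 30, p = 0.8,
                               class = "viable"))
  expect_lt(evaluate_detections(dg, truth)$precision, 1)
  expect_equal(evaluate_detections(dg, truth, ghost_tolerant = TRUE)$precision, 1)
  # wrong class counts against accuracy but not recall
  dw <- dets; dw$class <- c("viable", "viable")
  evw <- evaluate_detections(dw, truth)
  expect_equal(evw$recall, 1)
  expect_equal(evw$accuracy, 0.5)
})

test_that("detector config enforces threshold ordering", {
  expect_error(detector_config(confidence_floor = 0.8, display_floor = 0.7))
  expect_error(detector_config(grid_S = 0))
})
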