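# Acquisition accounting, stitching and downscaling.

test_that("tile count accounting is exact across all three map generations", {
  expect_identical(expected_tile_count(897, 61), 54717)
  expect_identical(expected_tile_count(1649, 61), 100589)
  expect_identical(expected_tile_count(120262, 61), 7335982)
  expect_identical(expected_tile_count(0, 61), 0)
  expect_error(expected_tile_count(-1, 61), "non-negative")
})

test_that("storage estimate uses 1e6 px/Mpx and 1e12 bytes/TB", {
  expect_equal(storage_estimate(75276e6, 1), 0.075276)
  expect_equal(round(storage_estimate(75276e6, 1), 2), 0.08)
  expect_equal(storage_estimate(0, 1), 0)
  expect_equal(storage_estimate(1e12, 1), 1.0)
})

test_that("geometry validation rejects degenerate inputs", {
  expect_error(acquisition_geometry(overlap_px = 256, tile_width_px = 256))
  expect_error(acquisition_geometry(beams_per_mfov = 0))
  expect_error(acquisition_geometry(beams_per_mfov = 6, beam_grid = c(2, 2),
                                    mfov_layout = "rectangular"))
})

test_that("hexagonal beam layout follows ring order (1 + 6 + 12 + 18 + 24)", {
  geom <- acquisition_geometry(beams_per_mfov = 61, mfov_layout = "hexagonal",
                               n_mfov = 3)
  tiles <- tile_origins(geom)
  expect_equal(nrow(tiles), 183)
  one <- tiles[tiles$mfov == 1, ]
  # ring membership by centre distance from the mFOV's central beam
  ctr <- one[1, c("x_px", "y_px")]
  d <- sqrt((one$x_px - ctr$x_px)^2 + (one$y_px - ctr$y_px)^2)
  s <- geom$tile_width_px - geom$overlap_px
  expect_equal(sum(d < s * 0.6), 1)              # centre beam
  expect_equal(sum(d < s * 1.2) - 1, 6)          # first ring
})

test_that("stitching copies tiles at recorded coordinates", {
  # single tile: panorama identical to the tile
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  tiles <- data.frame(tile_id = "m00001_b01", mfov = 1, beam = 1,
                      x_px = 0L, y_px = 0L, width = 64L, height = 64L)
  m <- tile_manifest(tiles, list(m00001_b01 = img))
  expect_equal(stitch(m)$pixels, img)

  # two 512-px tiles at x = 0 and x = 480: union width 992
  t2 <- data.frame(tile_id = c("a", "b"), mfov = 1, beam = 1:2,
                   x_px = c(0L, 480L), y_px = 0L, width = 512L, height = 64L)
  imgs <- list(a = matrix(1, 64, 512), b = matrix(2, 64, 512))
  m2 <- tile_manifest(t2, imgs, overlap_px = 32L)
  pano <- stitch(m2)
  expect_equal(dim(pano$pixels), c(64, 992))
  # last-indexed tile wins in the 32-px overlap strip
  expect_true(all(pano$pixels[, 481:512] == 2))
})

test_that("coordinate collisions beyond the declared overlap warn, not error", {
  t2 <- data.frame(tile_id = c("a", "b"), mfov = 1, beam = 1:2,
                   x_px = c(0L, 4L), y_px = 0L, width = 64L, height = 64L)
  imgs <- list(a = matrix(1, 64, 64), b = matrix(2, 64, 64))
  m <- tile_manifest(t2, imgs, overlap_px = 0L)
  expect_warning(pano <- stitch(m), "beyond the declared overlap")
  expect_equal(dim(pano$pixels), c(64, 68))
})

test_that("partition then stitch is pixel-identical, and positions follow the stride", {
  geom <- small_geom(nx = 2, ny = 2, tile = 512, overlap = 32)
  P <- matrix(sample(0:255, 992 * 992, replace = TRUE), 992, 992)
  m <- tile_partition(P, geom)
  expect_setequal(unique(m$tiles$x_px), c(0L, 480L))  # stride = tile - overlap
  expect_identical(stitch(m)$pixels * 1, P * 1)
  # a panorama exactly one tile in size: manifest of 1 tile at (0, 0)
  one <- tile_partition(matrix(0, 512, 512),
                        small_geom(nx = 1, ny = 1, tile = 512))
  expect_equal(nrow(one$tiles), 1)
  expect_equal(c(one$tiles$x_px, one$tiles$y_px), c(0L, 0L))
})

test_that("stitch is idempotent on its own output", {
  geom <- small_geom(nx = 2, ny = 2, tile = 64, overlap = 16)
  P <- matrix(sample(0:255, 112 * 112, replace = TRUE), 112, 112)
  pano <- stitch(tile_partition(P, geom))
  again <- stitch(tile_partition(pano$pixels,
                                 small_geom(nx = 1, ny = 1, tile = 112)))
  expect_identical(again$pixels * 1, P * 1)
})

test_that("downscale_for_detection scales, clamps, and preserves coordinates", {
  P <- panorama(matrix(runif(400 * 400, 0, 255), 400, 400), pixel_size_nm = 12)
  ds <- downscale_for_detection(P, native_cell_px = 400, target_cell_px = 200)
  expect_equal(ds$scale, 0.5)
  expect_equal(dim(ds$panorama$pixels), c(200, 200))
  expect_equal(ds$panorama$pixel_size_nm, 24)
  # identity and never-upsample clamps
  expect_equal(downscale_for_detection(P, 200)$scale, 1)
  expect_identical(downscale_for_detection(P, 100)$panorama$pixels, P$pixels)
  expect_error(downscale_for_detection(P, -5))
})

test_that("a ground-truth centre maps through downscale within 1 px", {
  spec <- small_spec(n_cells = 6, seed = 3)
  ph <- generate_phantom(spec, small_geom(nx = 3, ny = 3))
  ds <- downscale_for_detection(ph$panorama, native_cell_px = 400)
  expect_equal(ds$scale, 0.5)
  # the brightest-to-darkest structure: re-detect soma centres at half scale
  for (i in seq_len(nrow(ph$truth))) {
    x2 <- ph$truth$cx[i] * ds$scale; y2 <- ph$truth$cy[i] * ds$scale
    # darkest pixel within a small window of the mapped centre is the soma
    win <- ds$panorama$pixels[round(y2) + (-3:3) + 1, round(x2) + (-3:3) + 1]
    expect_lt(min(win), 140)
  }
})

test_that("area-averaging resize is exact on block means", {
  img <- matrix(1:16, 4, 4)
  half <- resize_area(img, 2, 2)
  expect_equal(half, matrix(c(mean(img[1:2, 1:2]), mean(img[3:4, 1:2]),
                              mean(img[1:2, 3:4]), mean(img[3:4, 3:4])), 2, 2))
  # fractional scale conserves total mass
  img2 <- matrix(runif(90 * 70), 90, 70)
  out <- resize_area(img2, 33, 41)
  expect_equal(mean(out), mean(img2), tolerance = 1e-10)
})
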