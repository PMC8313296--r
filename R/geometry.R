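# Acquisition geometry: accounting for multibeam SEM mosaics and the tile
# layout used by the phantom generator and the stitcher.

#' Multibeam acquisition geometry
#'
#' Describes one mSEM acquisition: how many beams image simultaneously within
#' a multibeam field of view (mFOV), the per-beam tile dimensions, the
#' physical pixel size, the overlap between neighbouring tiles, and how beams
#' and mFOVs are laid out. The 61-beam default mirrors the hexagonal beam
#' array of the instrument class this package emulates (one central beam plus
#' rings of 6, 12, 18 and 24).
#'
#' @param beams_per_mfov beams (tiles) acquired per mFOV; default 61.
#' @param tile_width_px,tile_height_px per-beam tile dimensions in pixels.
#' @param pixel_size_nm physical pixel size in nanometres; default 12.
#' @param overlap_px overlap between neighbouring tiles in pixels; must be
#'   smaller than both tile dimensions.
#' @param mfov_layout `"rectangular"` or `"hexagonal"` beam/mFOV packing.
#' @param n_mfov number of mFOVs in the acquisition.
#' @param beam_grid for the rectangular layout, `c(rows, cols)` with
#'   `rows * cols == beams_per_mfov`; a near-square factorisation is chosen
#'   when omitted.
#' @param mfov_grid for the rectangular layout, `c(rows, cols)` of mFOVs.
#' @return an object of class `osteo_geometry`.
#' @export
acquisition_geometry <- function(beams_per_mfov = 61L,
                                 tile_width_px = 256L,
                                 tile_height_px = 256L,
                                 pixel_size_nm = 12,
                                 overlap_px = 32L,
                                 mfov_layout = c("rectangular", "hexagonal"),
                                 n_mfov = 1L,
                                 beam_grid = NULL,
                                 mfov_grid = NULL) {
  mfov_layout <- match.arg(mfov_layout)
  stopifnot(beams_per_mfov >= 1, pixel_size_nm > 0, n_mfov >= 1,
            tile_width_px >= 1, tile_height_px >= 1,
            overlap_px >= 0, overlap_px < min(tile_width_px, tile_height_px))
  if (mfov_layout == "rectangular") {
    if (is.null(beam_grid)) beam_grid <- near_square_grid(beams_per_mfov)
    if (prod(beam_grid) != beams_per_mfov)
      stop("beam_grid rows * cols must equal beams_per_mfov")
    if (is.null(mfov_grid)) mfov_grid <- near_square_grid(n_mfov)
    if (prod(mfov_grid) != n_mfov)
      stop("mfov_grid rows * cols must equal n_mfov")
  }
  structure(list(beams_per_mfov = as.integer(beams_per_mfov),
                 tile_width_px = as.integer(tile_width_px),
                 tile_height_px = as.integer(tile_height_px),
                 pixel_size_nm = pixel_size_nm,
                 overlap_px = as.integer(overlap_px),
                 mfov_layout = mfov_layout,
                 n_mfov = as.integer(n_mfov),
                 beam_grid = beam_grid,
                 mfov_grid = mfov_grid),
            class = "osteo_geometry")
}

# Smallest-perimeter integer grid holding exactly n items (rows x cols = n).
near_square_grid <- function(n) {
  r <- floor(sqrt(n))
  while (r >= 1 && n %% r != 0) r <- r - 1
  c(as.integer(r), as.integer(n / r))
}

#' Expected number of per-beam images in an acquisition
#'
#' Each mFOV is imaged simultaneously by all beams, so the total image count
#' is the product of the mFOV count and the beams per mFOV. Reproduces the
#' "total images in area" accounting of a multibeam acquisition exactly.
#'
#' @param n_mfov number of multibeam fields of view (>= 0).
#' @param beams_per_mfov beams per mFOV (>= 0).
#' @return integer-valued count.
#' @examples
#' expected_tile_count(897, 61)  # 54717
#' @export
expected_tile_count <- function(n_mfov, beams_per_mfov = 61L) {
  if (any(n_mfov < 0) || any(beams_per_mfov < 0))
    stop("tile counts require non-negative inputs")
  n_mfov * beams_per_mfov
}

#' Storage estimate for a greyscale acquisition
#'
#' @param n_pixels total pixel count (1 megapixel = 1e6 pixels).
#' @param bytes_per_pixel bytes per pixel; 1 for 8-bit greyscale.
#' @return size in terabytes (1 TB = 1e12 bytes).
#' @examples
#' storage_estimate(75276e6)  # 0.0753 TB, i.e. 0.08 at 2-digit rounding
#' @export
storage_estimate <- function(n_pixels, bytes_per_pixel = 1) {
  stopifnot(all(n_pixels >= 0), all(bytes_per_pixel >= 0))
  n_pixels * bytes_per_pixel / 1e12
}

# Axial hex-lattice offsets in ring order: centre, then rings of 6k tiles.
# spacing_x is the centre-to-centre distance of horizontal neighbours.
hex_ring_offsets <- function(n, spacing_x, spacing_y = spacing_x * sqrt(3) / 2) {
  if (n < 1) return(matrix(numeric(0), 0, 2))
  ax <- matrix(c(0, 0), 1, 2)  # axial (q, r)
  dirs <- matrix(c(1, 0, 1, -1, 0, -1, -1, 0, -1, 1, 0, 1), ncol = 2, byrow = TRUE)
  k <- 1L
  while (nrow(ax) < n) {
    q <- -k; r <- k  # start at the "south-west" corner of ring k
    for (d in seq_len(6L)) {
      for (s in seq_len(k)) {
        ax <- rbind(ax, c(q, r))
        q <- q + dirs[d, 1L]; r <- r + dirs[d, 2L]
        if (nrow(ax) >= n) break
      }
      if (nrow(ax) >= n) break
    }
    k <- k + 1L
  }
  cbind(x = spacing_x * (ax[, 1L] + ax[, 2L] / 2), y = spacing_y * ax[, 2L])
}

#' Tile origins for an acquisition geometry
#'
#' Lays out every per-beam tile of the acquisition and returns its recorded
#' stage coordinates (top-left corner, 0-based pixels). Rectangular layouts
#' tile the plane exactly with stride `tile - overlap`; hexagonal layouts
#' place beams on a hex lattice in ring order and mFOV centres on a coarser
#' hex lattice.
#'
#' @param geom an [acquisition_geometry()].
#' @return data frame with columns `tile_id, mfov, beam, x_px, y_px, width,
#'   height`.
#' @export
tile_origins <- function(geom) {
  stopifnot(inherits(geom, "osteo_geometry"))
  tw <- geom$tile_width_px; th <- geom$tile_height_px
  sx <- tw - geom$overlap_px; sy <- th - geom$overlap_px
  if (geom$mfov_layout == "rectangular") {
    bg <- geom$beam_grid; mg <- geom$mfov_grid
    beam_off <- expand.grid(bx = seq_len(bg[2L]) - 1L, by = seq_len(bg[1L]) - 1L)
    mfov_off <- expand.grid(mx = seq_len(mg[2L]) - 1L, my = seq_len(mg[1L]) - 1L)
    rows <- do.call(rbind, lapply(seq_len(nrow(mfov_off)), function(m) {
      data.frame(mfov = m,
                 beam = seq_len(nrow(beam_off)),
                 x_px = mfov_off$mx[m] * bg[2L] * sx + beam_off$bx * sx,
                 y_px = mfov_off$my[m] * bg[1L] * sy + beam_off$by * sy)
    }))
  } else {
    n_rings <- 0L
    while (1 + 3 * n_rings * (n_rings + 1) < geom$beams_per_mfov)
      n_rings <- n_rings + 1L
    beam_off <- hex_ring_offsets(geom$beams_per_mfov, sx)
    mfov_off <- hex_ring_offsets(geom$n_mfov, (2 * n_rings + 1) * sx)
    rows <- do.call(rbind, lapply(seq_len(geom$n_mfov), function(m) {
      data.frame(mfov = m,
                 beam = seq_len(geom$beams_per_mfov),
                 x_px = round(mfov_off[m, 1L] + beam_off[, 1L]),
                 y_px = round(mfov_off[m, 2L] + beam_off[, 2L]))
    }))
  }
  rows$x_px <- as.integer(rows$x_px - min(rows$x_px))
  rows$y_px <- as.integer(rows$y_px - min(rows$y_px))
  data.frame(tile_id = sprintf("m%05d_b%02d", rows$mfov, rows$beam),
             mfov = rows$mfov, beam = rows$beam,
             x_px = rows$x_px, y_px = rows$y_px,
             width = tw, height = th,
             stringsAsFactors = FALSE)
}

#' Pixel extent of an acquisition (bounding box of all tile footprints)
#' @param geom an [acquisition_geometry()].
#' @return `c(width, height)` in pixels.
#' @export
panorama_extent <- function(geom) {
  tiles <- tile_origins(geom)
  c(width = max(tiles$x_px + tiles$width), height = max(tiles$y_px + tiles$height))
}
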