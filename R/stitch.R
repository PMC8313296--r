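# Tile manifests, coordinate-based stitching and detection-scale downscaling.

#' Construct a tile manifest
#'
#' A manifest pairs per-beam tile records (recorded stage coordinates in
#' pixels) with the tile rasters themselves, either in memory or as file
#' paths. It is the interchange object between the phantom generator, the
#' stitcher and on-disk tile sets.
#'
#' @param tiles data frame with columns `tile_id, mfov, beam, x_px, y_px,
#'   width, height` and optionally `path`.
#' @param images named list of greyscale matrices keyed by `tile_id`, or
#'   `NULL` when tiles live on disk (then `tiles$path` must be set).
#' @param pixel_size_nm physical pixel size carried through to panoramas.
#' @param overlap_px declared overlap between neighbouring tiles; used only
#'   to warn about coordinate collisions beyond it.
#' @return object of class `osteo_manifest`.
#' @export
tile_manifest <- function(tiles, images = NULL, pixel_size_nm = 12,
                          overlap_px = 0L) {
  need <- c("tile_id", "mfov", "beam", "x_px", "y_px", "width", "height")
  if (!all(need %in% names(tiles)))
    stop("manifest tiles need columns: ", paste(need, collapse = ", "))
  if (!is.null(images)) {
    stopifnot(all(tiles$tile_id %in% names(images)))
  } else if (is.null(tiles$path)) {
    stop("either in-memory images or a path column is required")
  }
  structure(list(tiles = tiles, images = images,
                 pixel_size_nm = pixel_size_nm,
                 overlap_px = as.integer(overlap_px)),
            class = "osteo_manifest")
}

#' @export
print.osteo_manifest <- function(x, ...) {
  cat(sprintf("<osteo_manifest> %d tiles, %d mFOV(s), %g nm/px, overlap %d px\n",
              nrow(x$tiles), length(unique(x$tiles$mfov)),
              x$pixel_size_nm, x$overlap_px))
  invisible(x)
}

manifest_tile_image <- function(manifest, i) {
  id <- manifest$tiles$tile_id[i]
  if (!is.null(manifest$images)) return(manifest$images[[id]])
  path <- manifest$tiles$path[i]
  if (is.na(path) || !file.exists(path))
    stop("missing tile file for tile ", id, ": ", path)
  read_grey_tiff(path)
}

#' Stitch a tile manifest into a panorama
#'
#' Tiles are copied verbatim at their recorded stage coordinates — no
#' resampling, no correlation refinement. Where footprints overlap the
#' later-indexed tile wins by default (`blend = "last"`), which makes
#' stitching an exact inverse of [tile_partition()]; `blend = "mean"`
#' averages overlapping pixels instead. Pixels covered by no tile are filled
#' with `background`. Tiles overlapping a previously placed tile by more
#' than the manifest's declared overlap trigger a warning (coordinates are
#' trusted regardless).
#'
#' @param manifest an [tile_manifest()].
#' @param blend `"last"` (last-writer-wins copy) or `"mean"`.
#' @param background grey level for uncovered pixels.
#' @return object of class `osteo_panorama`: list with `pixels`,
#'   `origin_offset`, `pixel_size_nm`, `provenance`.
#' @export
stitch <- function(manifest, blend = c("last", "mean"), background = 200) {
  stopifnot(inherits(manifest, "osteo_manifest"))
  blend <- match.arg(blend)
  t <- manifest$tiles
  if (nrow(t) == 0L) stop("cannot stitch an empty manifest")
  x0 <- min(t$x_px); y0 <- min(t$y_px)
  W <- max(t$x_px + t$width) - x0
  H <- max(t$y_px + t$height) - y0
  pano <- matrix(background, H, W)
  counts <- if (blend == "mean") matrix(0L, H, W) else NULL
  if (blend == "mean") pano[] <- 0
  covered <- matrix(FALSE, H, W)
  collision <- FALSE
  for (i in seq_len(nrow(t))) {
    img <- manifest_tile_image(manifest, i)
    rows <- (t$y_px[i] - y0) + seq_len(t$height[i])
    cols <- (t$x_px[i] - x0) + seq_len(t$width[i])
    ov <- sum(covered[rows, cols])
    # generous allowance (2x the nominal overlap strips): hexagonal layouts
    # overlap more along lattice diagonals than the per-axis figure
    allowed <- 2L * manifest$overlap_px *
      (t$width[i] + t$height[i] + 2L * manifest$overlap_px)
    if (ov > max(allowed, 0L)) collision <- TRUE
    if (blend == "last") {
      pano[rows, cols] <- img
    } else {
      pano[rows, cols] <- pano[rows, cols] + img
      counts[rows, cols] <- counts[rows, cols] + 1L
    }
    covered[rows, cols] <- TRUE
  }
  if (blend == "mean") {
    pano[counts > 0L] <- pano[counts > 0L] / counts[counts > 0L]
    pano[counts == 0L] <- background
  }
  if (collision)
    warning("tile footprints overlap beyond the declared overlap; ",
            "recorded coordinates used as-is")
  panorama(pano, origin_offset = c(x0, y0),
           pixel_size_nm = manifest$pixel_size_nm,
           provenance = "stitched from manifest")
}

#' Construct a panorama object
#' @param pixels greyscale matrix.
#' @param origin_offset `(x, y)` pixel offset of the panorama origin.
#' @param pixel_size_nm composite pixel size in nanometres.
#' @param provenance free-text note on where the raster came from.
#' @export
panorama <- function(pixels, origin_offset = c(0, 0), pixel_size_nm = 12,
                     provenance = "") {
  structure(list(pixels = pixels, origin_offset = origin_offset,
                 pixel_size_nm = pixel_size_nm, provenance = provenance),
            class = "osteo_panorama")
}

#' @export
print.osteo_panorama <- function(x, ...) {
  cat(sprintf("<osteo_panorama> %d x %d px @ %.3g nm/px (%s)\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size_nm, x$provenance))
  invisible(x)
}

#' Partition a panorama into an overlapping tile manifest
#'
#' The inverse of [stitch()]: crops the panorama into tiles of the
#' geometry's dimensions on a rectangular covering grid with stride
#' `tile - overlap`. When the panorama extent is not an exact multiple of
#' the stride the final row/column of tiles is shifted inward so the union
#' of footprints always equals the panorama. Overlap regions are copies of
#' the same pixels, so `stitch(tile_partition(P))` is pixel-identical to P.
#'
#' @param pano an [panorama()] (or bare matrix).
#' @param geom an [acquisition_geometry()] supplying tile dimensions and
#'   overlap.
#' @return an [tile_manifest()] with in-memory tiles.
#' @export
tile_partition <- function(pano, geom) {
  px <- if (inherits(pano, "osteo_panorama")) pano$pixels else pano
  psz <- if (inherits(pano, "osteo_panorama")) pano$pixel_size_nm else geom$pixel_size_nm
  tw <- geom$tile_width_px; th <- geom$tile_height_px
  H <- nrow(px); W <- ncol(px)
  if (H < th || W < tw)
    stop("panorama (", W, "x", H, ") is smaller than one tile (", tw, "x", th, ")")
  xs <- cover_positions(W, tw, tw - geom$overlap_px)
  ys <- cover_positions(H, th, th - geom$overlap_px)
  grid <- expand.grid(x = xs, y = ys)
  nb <- geom$beams_per_mfov
  idx <- seq_len(nrow(grid)) - 1L
  tiles <- data.frame(
    tile_id = sprintf("m%05d_b%02d", idx %/% nb + 1L, idx %% nb + 1L),
    mfov = idx %/% nb + 1L, beam = idx %% nb + 1L,
    x_px = grid$x, y_px = grid$y, width = tw, height = th,
    stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(tiles)), function(i)
    px[tiles$y_px[i] + seq_len(th), tiles$x_px[i] + seq_len(tw), drop = FALSE])
  names(images) <- tiles$tile_id
  tile_manifest(tiles, images, pixel_size_nm = psz,
                overlap_px = geom$overlap_px)
}

# 0-based tile start positions covering [0, extent) with the given stride;
# the last tile is clamped so its footprint ends exactly at the extent.
cover_positions <- function(extent, tile, stride) {
  xs <- seq(0L, max(extent - tile, 0L), by = stride)
  if (max(xs) + tile < extent) xs <- c(xs, extent - tile)
  as.integer(xs)
}

#' Downscale a panorama so cells reach a target display size
#'
#' Computes `scale = min(1, target_cell_px / native_cell_px)` — images are
#' never upsampled — and applies exact area-averaging resampling. The
#' returned panorama records the composite pixel size
#' `pixel_size_nm / scale`.
#'
#' @param pano an [panorama()].
#' @param native_cell_px typical cell extent in native pixels (> 0).
#' @param target_cell_px desired cell extent after downscaling; default 200.
#' @return list with elements `panorama` and `scale`.
#' @export
downscale_for_detection <- function(pano, native_cell_px, target_cell_px = 200) {
  stopifnot(inherits(pano, "osteo_panorama"),
            native_cell_px > 0, target_cell_px > 0)
  scale <- min(1, target_cell_px / native_cell_px)
  if (scale == 1) return(list(panorama = pano, scale = 1))
  H <- nrow(pano$pixels); W <- ncol(pano$pixels)
  out <- resize_area(pano$pixels, max(1L, round(W * scale)), max(1L, round(H * scale)))
  list(panorama = panorama(out, origin_offset = pano$origin_offset * scale,
                           pixel_size_nm = pano$pixel_size_nm / scale,
                           provenance = sprintf("%s; downscaled x%.4g",
                                                pano$provenance, scale)),
       scale = scale)
}
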