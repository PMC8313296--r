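# Static slippy-map export: tile pyramid in the XYZ scheme (y increasing
# downward, flat specimen plane — no map projection) plus pin overlays for
# classified cells, green for viable and red for pyknotic.

#' Build a slippy-map tile pyramid from a panorama
#'
#' The native resolution becomes zoom level `max_zoom =
#' ceil(log2(max_dim / tile_size))`; each coarser level is an exact 2x2
#' area-averaged reduction, until level 0 fits in a single tile. Edge tiles
#' are padded with the background level.
#'
#' @param pano an [panorama()] or greyscale matrix.
#' @param tile_size square tile side in pixels; default 256.
#' @param background pad level for edge tiles.
#' @return object of class `osteo_pyramid`: list with `tile_size`,
#'   `max_zoom`, native `width`/`height`, and `levels` — one entry per zoom
#'   with `zoom, width, height, nx, ny, tiles` (tiles indexed
#'   `[[x + 1]][[y + 1]]`, 0-based x/y tile coordinates).
#' @export
build_tile_pyramid <- function(pano, tile_size = 256L, background = 200) {
  px <- if (inherits(pano, "osteo_panorama")) pano$pixels else pano
  stopifnot(nrow(px) >= 1, ncol(px) >= 1, tile_size >= 1)
  max_zoom <- max(0L, ceiling(log2(max(dim(px)) / tile_size)))
  levels <- vector("list", max_zoom + 1L)
  img <- px
  for (z in seq(max_zoom, 0L)) {
    H <- nrow(img); W <- ncol(img)
    nx <- as.integer(ceiling(W / tile_size)); ny <- as.integer(ceiling(H / tile_size))
    tiles <- lapply(seq_len(nx) - 1L, function(tx) {
      lapply(seq_len(ny) - 1L, function(ty) {
        tile <- matrix(background, tile_size, tile_size)
        rows <- (ty * tile_size + 1L):min((ty + 1L) * tile_size, H)
        cols <- (tx * tile_size + 1L):min((tx + 1L) * tile_size, W)
        tile[seq_along(rows), seq_along(cols)] <- img[rows, cols]
        tile
      })
    })
    levels[[z + 1L]] <- list(zoom = z, width = W, height = H,
                             nx = nx, ny = ny, tiles = tiles)
    if (z > 0L) img <- halve_image(img, background)
  }
  structure(list(tile_size = as.integer(tile_size),
                 max_zoom = max_zoom,
                 width = ncol(px), height = nrow(px),
                 levels = levels),
            class = "osteo_pyramid")
}

#' @export
print.osteo_pyramid <- function(x, ...) {
  cat(sprintf("<osteo_pyramid> %d x %d px, %d zoom levels (max %d), %d px tiles\n",
              x$width, x$height, length(x$levels), x$max_zoom, x$tile_size))
  invisible(x)
}

#' Write a tile pyramid as tiles/{z}/{x}/{y}.png
#'
#' @param pyr an [build_tile_pyramid()] result.
#' @param dir output directory; tiles land under `dir/tiles/`.
#' @param viewer also emit a minimal static viewer page (untested
#'   convenience output).
#' @return `dir`, invisibly.
#' @export
write_tile_pyramid <- function(pyr, dir, viewer = FALSE) {
  for (lev in pyr$levels) {
    for (tx in seq_len(lev$nx) - 1L) {
      d <- file.path(dir, "tiles", lev$zoom, tx)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (ty in seq_len(lev$ny) - 1L) {
        png::writePNG(round(clamp255(lev$tiles[[tx + 1L]][[ty + 1L]])) / 255,
                      file.path(d, paste0(ty, ".png")))
      }
    }
  }
  if (viewer) write_viewer_page(pyr, dir)
  invisible(dir)
}

write_viewer_page <- function(pyr, dir) {
  html <- c("<!doctype html><title>osteocyte atlas</title>",
            sprintf("<p>XYZ tile pyramid: tiles/{z}/{x}/{y}.png, max zoom %d, %d px tiles.</p>",
                    pyr$max_zoom, pyr$tile_size),
            sprintf("<img src='tiles/0/0/0.png' alt='overview'>"))
  writeLines(html, file.path(dir, "index.html"))
  invisible(NULL)
}

#' Filter classified cells for display
#'
#' Keeps cells whose detection confidence is strictly greater than `floor`
#' (default 0.7 — "greater than 70% confidence" read as strict) and turns
#' them into a pin set coloured by status. Cells with no status (failed
#' segmentation) are not pinned.
#'
#' @param cells cell listing from [classify_cells()] / [emit_records()].
#' @param floor confidence display floor; default 0.7.
#' @return data frame of class `osteo_pinset`: `cell_id, x_px, y_px,
#'   status, p, n_processes, color`.
#' @export
display_filter <- function(cells, floor = 0.7) {
  keep <- cells$p > floor & !is.na(cells$status)
  out <- data.frame(
    cell_id = if (!is.null(cells$cell_id)) cells$cell_id[keep] else
      sprintf("cell%04d", which(keep)),
    x_px = cells$X[keep], y_px = cells$Y[keep],
    status = cells$status[keep], p = cells$p[keep],
    n_processes = cells$n_processes[keep],
    color = ifelse(cells$status[keep] == "viable", "green", "red"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("osteo_pinset", "data.frame")
  out
}

#' Export pins as GeoJSON and CSV overlays
#'
#' Pin positions are written in normalized map coordinates `u = x / width`,
#' `v = y / height` of the native-resolution level, so they scale with any
#' zoom; the transform is exactly invertible (`x = u * width`) to well
#' under half a pixel. Out-of-bounds pins abort with the offending cell id.
#'
#' @param pins an [display_filter()] pin set.
#' @param pyramid an [build_tile_pyramid()] (supplies the native extent).
#' @param dir output directory for `pins.geojson` and `pins.csv`.
#' @return list with `geojson` (the feature collection) and the normalized
#'   pin table; files are written when `dir` is given.
#' @export
export_pins <- function(pins, pyramid, dir = NULL) {
  W <- pyramid$width; H <- pyramid$height
  bad <- pins$x_px < 0 | pins$x_px > W | pins$y_px < 0 | pins$y_px > H
  if (any(bad))
    stop("pin outside panorama bounds: ",
         paste(pins$cell_id[bad], collapse = ", "))
  u <- pins$x_px / W; v <- pins$y_px / H
  features <- lapply(seq_len(nrow(pins)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(u[i], v[i])),
         properties = list(cell_id = pins$cell_id[i],
                           status = pins$status[i],
                           p = pins$p[i],
                           n_processes = pins$n_processes[i],
                           color = pins$color[i]))
  })
  geojson <- list(type = "FeatureCollection", features = features)
  table <- data.frame(cell_id = pins$cell_id, u = u, v = v,
                      x_px = pins$x_px, y_px = pins$y_px,
                      status = pins$status, p = pins$p,
                      n_processes = pins$n_processes,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(geojson, file.path(dir, "pins.geojson"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(table, file.path(dir, "pins.csv"), row.names = FALSE)
  }
  list(geojson = geojson, pins = table)
}
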