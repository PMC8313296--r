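# Plain-text and TIFF interchange: tile manifests (CSV + JSON mirror),
# ground truth, detection and cell listings, transfer curves.

#' Write a tile manifest (tiles + CSV/JSON manifest files) to a directory
#'
#' Tiles are written as single-channel 8-bit TIFFs named
#' `m{mfov:05d}_b{beam:02d}.tif`; the manifest CSV has the header
#' `tile_id,mfov,beam,x_px,y_px,width,height,path` and a JSON mirror sits
#' alongside it.
#'
#' @param manifest an [tile_manifest()] with in-memory images.
#' @param dir output directory (created if needed).
#' @return the manifest CSV path, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  stopifnot(inherits(manifest, "osteo_manifest"), !is.null(manifest$images))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- manifest$tiles
  t$path <- file.path(dir, paste0(t$tile_id, ".tif"))
  for (i in seq_len(nrow(t)))
    write_grey_tiff(manifest$images[[t$tile_id[i]]], t$path[i])
  csv <- file.path(dir, "manifest.csv")
  utils::write.csv(t, csv, row.names = FALSE)
  jsonlite::write_json(list(pixel_size_nm = manifest$pixel_size_nm,
                            overlap_px = manifest$overlap_px,
                            tiles = t),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a tile manifest from a manifest.csv or manifest.json
#'
#' Tile images stay on disk and are read lazily by [stitch()].
#'
#' @param path path to `manifest.csv` or `manifest.json`.
#' @param pixel_size_nm pixel size when reading a bare CSV (the JSON mirror
#'   carries it).
#' @param overlap_px declared overlap when reading a bare CSV.
#' @return an [tile_manifest()].
#' @export
read_manifest <- function(path, pixel_size_nm = 12, overlap_px = 0L) {
  if (grepl("\\.json$", path)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    tiles <- as.data.frame(m$tiles)
    pixel_size_nm <- m$pixel_size_nm
    overlap_px <- m$overlap_px
  } else {
    tiles <- utils::read.csv(path, stringsAsFactors = FALSE)
    # the JSON mirror carries acquisition metadata the CSV lacks
    sibling <- file.path(dirname(path), "manifest.json")
    if (file.exists(sibling)) {
      m <- jsonlite::read_json(sibling, simplifyVector = TRUE)
      pixel_size_nm <- m$pixel_size_nm
      overlap_px <- m$overlap_px
    }
  }
  # resolve tile paths relative to the manifest location
  missing <- !file.exists(tiles$path)
  tiles$path[missing] <- file.path(dirname(path), basename(tiles$path[missing]))
  tile_manifest(tiles, images = NULL, pixel_size_nm = pixel_size_nm,
                overlap_px = overlap_px)
}

#' Write phantom ground truth as CSV
#' @param truth ground-truth data frame from [generate_phantom()].
#' @param path output CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Read phantom ground truth from CSV
#' @param path CSV path.
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a detection or cell listing as CSV
#' @param x data frame from [detect_cells()] or [classify_cells()].
#' @param path output CSV path.
#' @export
write_listing <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a detection or cell listing CSV
#' @param path CSV path.
#' @export
read_listing <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cell graph as node/edge CSVs and GraphML
#' @param g an [build_cell_graph()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cell_graph <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(g$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(g$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  igraph::write_graph(as_igraph(g, weighted = TRUE),
                      file.path(dir, "graph.graphml"), format = "graphml")
  invisible(dir)
}

#' Write a transfer curve as CSV
#'
#' Columns `fraction_removed, mean_transfer, std_transfer`.
#' @param curve an [node_removal_curve()] result.
#' @param path output CSV path.
#' @export
write_transfer_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
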