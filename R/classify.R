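# Morphological viability classification: segment each detected cell,
# count its visible dendritic processes, and apply the process-count rule
# (three or more visible processes = viable, fewer = pyknotic).

#' Classifier configuration
#'
#' @param fg_threshold grey level below which a pixel is foreground
#'   (cellular material is dark on a light resin background).
#' @param close_radius radius (px) of the morphological closing applied to
#'   the raw mask.
#' @param soma_open_px diameter (px) of the opening that strips thin
#'   process rays to isolate the soma body.
#' @param annulus_factor the counting annulus sits at this multiple of the
#'   soma-equivalent radius (the maximum centroid-to-boundary distance of
#'   the soma component); default 1.2.
#' @param merge_deg annulus crossings closer than this angular distance
#'   merge into one process; default 15.
#' @param ghost_center_floor mean grey level of the central disc above
#'   which a cell is flagged `ghost_suspect` (ghost lacunae have a bright
#'   featureless resin fill where a soma would be dark).
#' @param patch_factor crop factor around the detection box; default 1.5.
#' @return object of class `osteo_classifier_config`.
#' @export
classifier_config <- function(fg_threshold = 130,
                              close_radius = 1L,
                              soma_open_px = 7L,
                              annulus_factor = 1.2,
                              merge_deg = 15,
                              ghost_center_floor = 140,
                              patch_factor = 1.5) {
  stopifnot(annulus_factor > 1, merge_deg >= 0, patch_factor >= 1)
  structure(list(fg_threshold = fg_threshold,
                 close_radius = as.integer(close_radius),
                 soma_open_px = as.integer(soma_open_px),
                 annulus_factor = annulus_factor,
                 merge_deg = merge_deg,
                 ghost_center_floor = ghost_center_floor,
                 patch_factor = patch_factor),
            class = "osteo_classifier_config")
}

#' Segment a cell patch into a binary mask
#'
#' Thresholds dark foreground, applies a small morphological closing, and
#' keeps the connected component containing the patch centre (falling back
#' to the largest component when the centre pixel is background). An empty
#' foreground signals an unsegmentable cell and returns `NULL`.
#'
#' @param patch greyscale matrix cropped around one detection.
#' @param cfg an [classifier_config()].
#' @return logical matrix mask, or `NULL` when unsegmentable.
#' @export
segment_cell <- function(patch, cfg = classifier_config()) {
  mask <- patch < cfg$fg_threshold
  if (!any(mask)) return(NULL)
  brush <- EBImage::makeBrush(2L * cfg$close_radius + 1L, shape = "disc")
  mask <- EBImage::closing(mask * 1, brush) > 0.5
  lab <- EBImage::bwlabel(mask * 1)
  ctr <- lab[(nrow(lab) + 1L) %/% 2L, (ncol(lab) + 1L) %/% 2L]
  if (ctr == 0) {
    sizes <- tabulate(lab[lab > 0])
    if (length(sizes) == 0L) return(NULL)
    ctr <- which.max(sizes)
  }
  lab == ctr
}

# Soma-only mask: opening removes thin process rays.
soma_mask <- function(mask, cfg) {
  brush <- EBImage::makeBrush(cfg$soma_open_px, shape = "disc")
  soma <- EBImage::opening(mask * 1, brush) > 0.5
  if (!any(soma)) mask else soma
}

#' Count visible processes on a segmented cell mask
#'
#' Counts the distinct crossings of the mask through an annulus placed just
#' outside the soma: the soma body is isolated by a morphological opening,
#' the annulus radius is `annulus_factor` times the maximum
#' centroid-to-boundary distance of the soma, and the ring is sampled at 1
#' degree resolution (at three radii across the annulus width to avoid
#' aliasing gaps). Crossing arcs whose centres lie within `merge_deg` of
#' each other merge into a single process. For the thin rays this package
#' renders, mask crossings coincide with skeleton crossings.
#'
#' @param mask logical matrix from [segment_cell()].
#' @param cfg an [classifier_config()].
#' @return integer process count.
#' @export
count_processes <- function(mask, cfg = classifier_config()) {
  stopifnot(any(mask))
  soma <- soma_mask(mask, cfg)
  idx <- which(soma, arr.ind = TRUE)
  cy <- mean(idx[, 1L]) - 1; cx <- mean(idx[, 2L]) - 1
  r_eq <- sqrt(max((idx[, 1L] - 1 - cy)^2 + (idx[, 2L] - 1 - cx)^2))
  # +1 px guard band: the opening slightly shaves high-curvature soma tips,
  # which would otherwise let the annulus graze the soma itself
  r_ann <- cfg$annulus_factor * r_eq + 1
  theta <- (0:359) * pi / 180
  hit <- rep(FALSE, length(theta))
  for (r in r_ann + c(0, 1, 2)) {
    px <- round(cx + r * cos(theta)) + 1L
    py <- round(cy + r * sin(theta)) + 1L
    ok <- px >= 1L & px <= ncol(mask) & py >= 1L & py <= nrow(mask)
    hit[ok] <- hit[ok] | mask[cbind(py[ok], px[ok])]
  }
  count_circular_runs(hit, cfg$merge_deg)
}

# Count runs of TRUE on a circular boolean sequence (1 sample per degree),
# merging runs whose angular centres are closer than merge_deg.
count_circular_runs <- function(hit, merge_deg) {
  n <- length(hit)
  if (!any(hit)) return(0L)
  if (all(hit)) return(1L)
  # rotate so position 1 is FALSE, making runs non-wrapping
  start <- which(!hit)[1L]
  h <- hit[c(start:n, seq_len(start - 1L))]
  r <- rle(h)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  centers <- ((begins + ends) / 2)[r$values]  # angular centres (degrees-ish)
  if (length(centers) <= 1L) return(length(centers))
  centers <- sort(centers %% n)
  gaps <- diff(c(centers, centers[1L] + n))
  cnt <- sum(gaps >= merge_deg)
  if (cnt == 0L) 1L else cnt
}

#' Viability status from a process count
#'
#' Three or more visible processes classifies a cell as viable; fewer than
#' three as pyknotic. A pure threshold, vectorized.
#'
#' @param n_processes non-negative integer vector.
#' @return character vector of `"viable"` / `"pyknotic"`.
#' @export
classify_status <- function(n_processes) {
  stopifnot(all(n_processes >= 0))
  ifelse(n_processes >= 3, "viable", "pyknotic")
}

#' Assemble the cell listing from detections and process counts
#'
#' One row per detection: the five box predictions, the process count, the
#' viability status derived by [classify_status()], the ghost-suspect flag,
#' and the physical centre in micrometres (`pixel * pixel_size_nm / 1000`).
#'
#' @param dets detection data frame (`X, Y, W, H, p`).
#' @param n_processes integer vector aligned with `dets` (NA =
#'   unsegmentable).
#' @param ghost_suspect logical vector aligned with `dets`.
#' @param pixel_size_nm panorama pixel size in nanometres.
#' @return data frame `X, Y, W, H, p, n_processes, status, ghost_suspect,
#'   cx_um, cy_um`.
#' @export
emit_records <- function(dets, n_processes, ghost_suspect = NULL,
                         pixel_size_nm = 12) {
  if (is.null(ghost_suspect)) ghost_suspect <- rep(FALSE, nrow(dets))
  if (length(n_processes) != nrow(dets) ||
      length(ghost_suspect) != nrow(dets))
    stop("detections, process counts and flags must be aligned")
  status <- rep(NA_character_, nrow(dets))
  ok <- !is.na(n_processes)
  status[ok] <- classify_status(n_processes[ok])
  data.frame(X = dets$X, Y = dets$Y, W = dets$W, H = dets$H, p = dets$p,
             n_processes = n_processes, status = status,
             ghost_suspect = ghost_suspect,
             cx_um = dets$X * pixel_size_nm / 1000,
             cy_um = dets$Y * pixel_size_nm / 1000,
             stringsAsFactors = FALSE)
}

#' Classify every detection on a panorama
#'
#' Crops a `patch_factor` x box patch around each detection, segments it,
#' flags ghost suspects (bright featureless centre), counts processes and
#' emits the full cell listing. Unsegmentable detections get `NA` counts
#' and status and are excluded from downstream accuracy denominators.
#'
#' @param pano an [panorama()] (source frame of the detections).
#' @param dets detection data frame from [detect_cells()].
#' @param cfg an [classifier_config()].
#' @return cell listing data frame from [emit_records()].
#' @export
classify_cells <- function(pano, dets, cfg = classifier_config()) {
  px <- pano$pixels
  n <- nrow(dets)
  n_proc <- rep(NA_integer_, n)
  ghost <- rep(FALSE, n)
  for (i in seq_len(n)) {
    half_w <- cfg$patch_factor * dets$W[i] / 2
    half_h <- cfg$patch_factor * dets$H[i] / 2
    half <- max(half_w, half_h)
    x0 <- max(0L, floor(dets$X[i] - half)); x1 <- min(ncol(px) - 1L, ceiling(dets$X[i] + half))
    y0 <- max(0L, floor(dets$Y[i] - half)); y1 <- min(nrow(px) - 1L, ceiling(dets$Y[i] + half))
    patch <- px[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
    mask <- segment_cell(patch, cfg)
    # ghost check: mean grey of the central disc (radius = 1/4 patch)
    ctr_y <- (nrow(patch) + 1) / 2; ctr_x <- (ncol(patch) + 1) / 2
    rr <- row(patch) - ctr_y; cc <- col(patch) - ctr_x
    disc <- rr^2 + cc^2 <= (min(dim(patch)) / 8)^2
    ghost[i] <- mean(patch[disc]) > cfg$ghost_center_floor
    if (is.null(mask)) next
    n_proc[i] <- count_processes(mask, cfg)
  }
  recs <- emit_records(dets, n_proc, ghost, pano$pixel_size_nm)
  recs
}
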