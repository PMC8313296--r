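# Synthetic mSEM phantom: seeded tile sets of osteocyte-like fields with
# known ground truth, so every downstream stage is testable without any
# external data.
#
# Grey-level convention (8-bit): light background (~200) as produced by
# backscatter imaging of carbon-coated resin blocks, dark somata (~60),
# ghost lacunae as a smooth ring outline with a featureless resin fill.

#' Phantom specification
#'
#' Parameters of the synthetic osteocyte field. The default class balance
#' (600 viable : 50 pyknotic, i.e. a viable fraction of 12/13) mirrors the
#' composition of the manual annotation set this workflow was designed
#' around; ghost lacunae (resin-filled empty lacunae with no cellular
#' material) are added at a small rate because they are a known confounder
#' of process-count classification.
#'
#' @param n_cells number of objects (cells + ghosts) to place.
#' @param viable_fraction probability that a non-ghost cell is viable;
#'   viable cells draw 3-8 processes, pyknotic cells 0-2.
#' @param ghost_fraction probability that an object is a ghost lacuna.
#' @param soma_axes_px full major and minor axis of the elliptical soma in
#'   native pixels.
#' @param process_length_px length of each dendritic process ray.
#' @param process_width_px stroke width of a process ray.
#' @param noise_sd standard deviation of additive Gaussian grey noise.
#' @param background_level,soma_level 8-bit grey levels of resin background
#'   and soma interior.
#' @param ghost_ring_level,ghost_fill_level grey levels of the ghost lacuna
#'   outline and its smooth interior.
#' @param min_process_sep_deg minimum angular separation between process
#'   rays of one cell (degrees).
#' @param bbox_margin_px margin added around the soma extent to form the
#'   ground-truth bounding box.
#' @param process_count_sampler function `(status, rng_ready)` returning a
#'   process count; the default draws uniformly from 3-8 for viable and 0-2
#'   for pyknotic cells, so the status/process-count rule holds by
#'   construction.
#' @param seed integer seed; fixed (spec, geometry, seed) gives
#'   byte-identical tiles.
#' @return object of class `osteo_phantom_spec`.
#' @export
phantom_spec <- function(n_cells = 200L,
                         viable_fraction = 600 / 650,
                         ghost_fraction = 0.05,
                         soma_axes_px = c(20, 12),
                         process_length_px = 40,
                         process_width_px = 2,
                         noise_sd = 8,
                         background_level = 200,
                         soma_level = 60,
                         ghost_ring_level = 90,
                         ghost_fill_level = 180,
                         min_process_sep_deg = 22,
                         bbox_margin_px = 6,
                         process_count_sampler = NULL,
                         seed = 1L) {
  stopifnot(n_cells >= 0, viable_fraction >= 0, viable_fraction <= 1,
            ghost_fraction >= 0, ghost_fraction <= 1,
            length(soma_axes_px) == 2L, all(soma_axes_px > 0),
            process_length_px > 0, noise_sd >= 0,
            min_process_sep_deg >= 20)
  if (is.null(process_count_sampler))
    process_count_sampler <- function(status) {
      switch(status,
             viable = sample(3:8, 1L),
             pyknotic = sample(0:2, 1L),
             ghost = 0L)
    }
  structure(list(n_cells = as.integer(n_cells),
                 viable_fraction = viable_fraction,
                 ghost_fraction = ghost_fraction,
                 soma_axes_px = soma_axes_px,
                 process_length_px = process_length_px,
                 process_width_px = process_width_px,
                 noise_sd = noise_sd,
                 background_level = background_level,
                 soma_level = soma_level,
                 ghost_ring_level = ghost_ring_level,
                 ghost_fill_level = ghost_fill_level,
                 min_process_sep_deg = min_process_sep_deg,
                 bbox_margin_px = bbox_margin_px,
                 process_count_sampler = process_count_sampler,
                 seed = as.integer(seed)),
            class = "osteo_phantom_spec")
}

#' Default desk-scale acquisition geometry for phantoms
#'
#' A 2 x 2 grid of rectangular mFOVs, 16 beams (4 x 4 tiles of 256 px) each,
#' 32 px overlap, 12 nm pixels: an 1824 x 1824 px panorama that holds the
#' default 200-cell phantom comfortably while keeping every stage fast on a
#' single CPU.
#' @export
default_phantom_geometry <- function() {
  acquisition_geometry(beams_per_mfov = 16L, tile_width_px = 256L,
                       tile_height_px = 256L, pixel_size_nm = 12,
                       overlap_px = 32L, mfov_layout = "rectangular",
                       n_mfov = 4L, beam_grid = c(4L, 4L),
                       mfov_grid = c(2L, 2L))
}

# Ellipse boundary radius along polar angle phi in the ellipse frame.
ellipse_radius <- function(a, b, phi) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

# Axis-aligned half-extents of an ellipse with semi-axes a >= b rotated by
# theta.
ellipse_extent <- function(a, b, theta) {
  c(x = sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    y = sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

# Sample n ray angles in [0, 2*pi) with circular minimum separation.
sample_process_angles <- function(n, min_sep_deg) {
  if (n == 0L) return(numeric(0))
  min_sep <- min_sep_deg * pi / 180
  for (try in seq_len(200L)) {
    ang <- sort(stats::runif(n, 0, 2 * pi))
    gaps <- diff(c(ang, ang[1L] + 2 * pi))
    if (n == 1L || all(gaps >= min_sep)) return(ang)
  }
  # fall back to an evenly spaced fan (always valid for n <= 8 at <= 45 deg)
  seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)] + stats::runif(1L, 0, 2 * pi / n)
}

#' Render one osteocyte-like cell as an image patch
#'
#' Draws a dark elliptical soma with `n_processes` thin radial rays on a
#' transparent patch (NA = untouched background). Ghosts render as a smooth
#' lacuna outline with a featureless resin fill and no rays. Rendering is
#' noise-free; noise is added panorama-wide by [generate_phantom()].
#'
#' @param spec an [phantom_spec()].
#' @param status `"viable"`, `"pyknotic"` or `"ghost"`.
#' @param n_processes ray count, 0-8; must be consistent with `status`
#'   (viable >= 3, pyknotic <= 2, ghost 0).
#' @param orientation soma major-axis angle in radians.
#' @param process_angles optional ray angles (radians, relative to the
#'   soma frame); sampled with the spec's minimum separation when omitted.
#' @return numeric matrix patch with attributes `center` (0-based x, y of
#'   the soma centre within the patch) and `process_angles`.
#' @export
render_cell <- function(spec, status = c("viable", "pyknotic", "ghost"),
                        n_processes = 0L, orientation = 0,
                        process_angles = NULL) {
  status <- match.arg(status)
  if (n_processes > 8L) stop("at most 8 processes are supported")
  if (status == "viable" && n_processes < 3L)
    stop("viable cells carry >= 3 processes")
  if (status == "pyknotic" && n_processes > 2L)
    stop("pyknotic cells carry <= 2 processes")
  if (status == "ghost" && n_processes != 0L)
    stop("ghost lacunae carry no processes")
  a <- spec$soma_axes_px[1L] / 2; b <- spec$soma_axes_px[2L] / 2
  R <- ceiling(a + spec$process_length_px + 2)
  side <- 2L * R + 1L
  patch <- matrix(NA_real_, side, side)
  cx <- R; cy <- R  # 0-based centre
  xs <- matrix(rep(0:(side - 1L), each = side), side) - cx
  ys <- matrix(rep(0:(side - 1L), side), side) - cy
  # coordinates in the soma frame
  xr <- xs * cos(orientation) + ys * sin(orientation)
  yr <- -xs * sin(orientation) + ys * cos(orientation)
  q <- (xr / a)^2 + (yr / b)^2
  if (status == "ghost") {
    patch[q <= 1 & q >= 0.64] <- spec$ghost_ring_level
    patch[q < 0.64] <- spec$ghost_fill_level
  } else {
    patch[q <= 1] <- spec$soma_level
    if (is.null(process_angles))
      process_angles <- sample_process_angles(n_processes,
                                              spec$min_process_sep_deg)
    hw <- spec$process_width_px / 2
    for (ang in process_angles) {
      r0 <- ellipse_radius(a, b, ang) - 1
      r1 <- r0 + spec$process_length_px
      ux <- cos(ang); uy <- sin(ang)          # soma frame
      t <- xr * ux + yr * uy                  # along-ray coordinate
      d <- abs(-xr * uy + yr * ux)            # distance to ray line
      patch[t >= r0 & t <= r1 & d <= hw] <- spec$soma_level
    }
  }
  attr(patch, "center") <- c(cx, cy)
  attr(patch, "process_angles") <- if (status == "ghost") numeric(0) else process_angles
  patch
}

#' Generate a seeded synthetic phantom tile set with ground truth
#'
#' Places `n_cells` objects uniformly over the panorama by rejection
#' sampling (minimum centre spacing of twice the major soma axis, and a
#' margin keeping every rendered ray inside the panorama), renders them onto
#' a noisy background, and partitions the result into the geometry's
#' overlapping tile manifest. Deterministic for fixed (spec, geometry).
#'
#' @param spec an [phantom_spec()].
#' @param geom an [acquisition_geometry()]; hexagonal layouts place cells
#'   only inside covered tile footprints.
#' @return list with `manifest` (an [tile_manifest()]), `truth` (data frame
#'   `cell_id, cx, cy, X, Y, W, H, n_processes, status`) and `panorama`.
#' @export
generate_phantom <- function(spec, geom = default_phantom_geometry()) {
  stopifnot(inherits(spec, "osteo_phantom_spec"),
            inherits(geom, "osteo_geometry"))
  ext <- panorama_extent(geom)
  W <- ext[["width"]]; H <- ext[["height"]]
  tiles <- tile_origins(geom)
  with_seed(spec$seed, {
    a <- spec$soma_axes_px[1L] / 2
    margin <- ceiling(a + spec$process_length_px + spec$bbox_margin_px + 2)
    if (W <= 2 * margin || H <= 2 * margin)
      stop("panorama too small for the requested cell size")
    min_d2 <- (2 * spec$soma_axes_px[1L])^2
    n <- spec$n_cells
    # statuses and process counts first, in a fixed draw order
    is_ghost <- if (n > 0L) stats::runif(n) < spec$ghost_fraction else logical(0)
    is_viable <- if (n > 0L) stats::runif(n) < spec$viable_fraction else logical(0)
    status <- ifelse(is_ghost, "ghost", ifelse(is_viable, "viable", "pyknotic"))
    n_proc <- vapply(status, function(s)
      as.integer(spec$process_count_sampler(s)), integer(1L))
    orientation <- stats::runif(n, 0, pi)
    # rejection-sampled placement
    cx <- numeric(n); cy <- numeric(n)
    placed <- 0L; tries <- 0L; max_tries <- max(2000L, 400L * n)
    hex <- geom$mfov_layout == "hexagonal"
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("placement capacity exceeded: could not place ", n,
             " cells with minimum spacing ", sqrt(min_d2), " px")
      x <- stats::runif(1L, margin, W - 1 - margin)
      y <- stats::runif(1L, margin, H - 1 - margin)
      if (hex && !point_covered(x, y, tiles, margin)) next
      if (placed > 0L) {
        d2 <- (cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2
        if (min(d2) < min_d2) next
      }
      placed <- placed + 1L
      cx[placed] <- round(x); cy[placed] <- round(y)
    }
    # render
    pano <- matrix(spec$background_level, H, W)
    for (i in seq_len(n)) {
      patch <- render_cell(spec, status[i], n_proc[i], orientation[i])
      ctr <- attr(patch, "center")
      rows <- cy[i] - ctr[2L] + seq_len(nrow(patch))
      cols <- cx[i] - ctr[1L] + seq_len(ncol(patch))
      sub <- pano[rows, cols]
      keep <- !is.na(patch)
      sub[keep] <- pmin(sub[keep], patch[keep])
      pano[rows, cols] <- sub
    }
    if (spec$noise_sd > 0)
      pano <- pano + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    pano <- round(clamp255(pano))
    # ground-truth boxes: soma extent plus margin
    m <- spec$bbox_margin_px
    b <- spec$soma_axes_px[2L] / 2
    exts <- t(vapply(orientation, function(th) ellipse_extent(a, b, th),
                     numeric(2L)))
    truth <- data.frame(
      cell_id = if (n > 0L) sprintf("c%04d", seq_len(n)) else character(0),
      cx = cx, cy = cy, X = cx, Y = cy,
      W = if (n > 0L) 2 * exts[, 1L] + 2 * m else numeric(0),
      H = if (n > 0L) 2 * exts[, 2L] + 2 * m else numeric(0),
      n_processes = n_proc, status = status,
      stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    pan <- panorama(pano, pixel_size_nm = geom$pixel_size_nm,
                    provenance = sprintf("phantom seed %d", spec$seed))
    manifest <- if (geom$mfov_layout == "rectangular") {
      tile_partition(pan, geom)
    } else {
      crop_manifest(pan, tiles, geom)
    }
    list(manifest = manifest, truth = truth, panorama = pan)
  })
}

# Crop a panorama at pre-computed tile origins (hexagonal layouts, where the
# tile union is not a full rectangle; stitch() refills uncovered corners
# with the background level).
crop_manifest <- function(pano, tiles, geom) {
  px <- pano$pixels
  images <- lapply(seq_len(nrow(tiles)), function(i)
    px[tiles$y_px[i] + seq_len(tiles$height[i]),
       tiles$x_px[i] + seq_len(tiles$width[i]), drop = FALSE])
  names(images) <- tiles$tile_id
  tile_manifest(tiles, images, pixel_size_nm = pano$pixel_size_nm,
                overlap_px = geom$overlap_px)
}

# Is point (x, y) inside at least one tile footprint, with a safety margin?
point_covered <- function(x, y, tiles, margin) {
  any(x >= tiles$x_px + margin & x < tiles$x_px + tiles$width - margin &
        y >= tiles$y_px + margin & y < tiles$y_px + tiles$height - margin)
}
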