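# Small fixtures shared across tests. Everything is generated in code.

# One-mFOV rectangular geometry: nx x ny tiles of `tile` px, `overlap` px.
small_geom <- function(nx = 2L, ny = 2L, tile = 256L, overlap = 32L) {
  acquisition_geometry(beams_per_mfov = nx * ny,
                       tile_width_px = tile, tile_height_px = tile,
                       overlap_px = overlap, mfov_layout = "rectangular",
                       n_mfov = 1L, beam_grid = c(ny, nx),
                       mfov_grid = c(1L, 1L))
}

# Phantom spec defaulted for quick tests (no ghosts, moderate noise).
small_spec <- function(n_cells = 10L, noise_sd = 8, ghost_fraction = 0,
                       seed = 1L, ...) {
  phantom_spec(n_cells = n_cells, noise_sd = noise_sd,
               ghost_fraction = ghost_fraction, seed = seed, ...)
}

# Independent greedy-NMS oracle: repeatedly take the highest-confidence
# remaining box (ties by X then Y), keep it, discard every remaining box
# overlapping it beyond `iou`; finally drop kept boxes with p <= floor.
# Deliberately written as a max-pick loop, not a sort, to stay independent
# of the package implementation.
nms_oracle <- function(dets, iou = 0.5, floor = 0.5) {
  remaining <- dets
  kept <- dets[0, , drop = FALSE]
  while (nrow(remaining) > 0L) {
    best <- which(remaining$p == max(remaining$p))
    if (length(best) > 1L) {
      sub <- remaining[best, , drop = FALSE]
      best <- best[order(sub$X, sub$Y)[1L]]
    }
    b <- remaining[best, , drop = FALSE]
    kept <- rbind(kept, b)
    ious <- box_iou(remaining, b)
    remaining <- remaining[ious <= iou, , drop = FALSE]
  }
  kept <- kept[kept$p > floor, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# Brute-force global efficiency via Floyd-Warshall on an adjacency matrix.
efficiency_oracle <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# Random box set for NMS property tests.
random_boxes <- function(n) {
  data.frame(X = round(runif(n, 0, 60)), Y = round(runif(n, 0, 60)),
             W = round(runif(n, 8, 30)), H = round(runif(n, 8, 30)),
             p = runif(n), class = NA_character_,
             stringsAsFactors = FALSE)
}

# Random cell graph: n nodes scattered in a square, built with the package
# linking rule (used where the graph itself is not under test).
random_cellgraph <- function(n, side_um = 150, radius = 60) {
  cells <- data.frame(cx_um = runif(n, 0, side_um),
                      cy_um = runif(n, 0, side_um),
                      status = sample(c("viable", "pyknotic"), n,
                                      replace = TRUE, prob = c(0.8, 0.2)))
  build_cell_graph(cells, link_radius_um = radius)
}
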