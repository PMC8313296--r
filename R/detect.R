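# Single-pass grid detector for osteocyte-like somata.
#
# The output contract follows the grid-based single-shot detector family:
# the image is divided into an S x S grid, each grid cell contributes at
# most one candidate bounding box with five predictions (X, Y, W, H, p),
# overlapping boxes are resolved by non-max suppression, and only boxes
# with confidence above 0.5 survive. The backend here is deterministic:
# normalized cross-correlation against a bank of elliptical soma templates.

#' Detector configuration
#'
#' @param input_side_px side of the square detector canvas; default 448.
#' @param grid_S grid subdivision per canvas side; default 7.
#' @param confidence_floor boxes with p <= this are dropped after NMS;
#'   default 0.5.
#' @param display_floor confidence required for a pin to be displayed in
#'   atlas export; default 0.7. Must be >= `confidence_floor`.
#' @param nms_iou IoU above which the lower-confidence box is suppressed.
#' @param soma_axes_px full axes of the elliptical soma template.
#' @param n_orientations number of template orientations spanning 180
#'   degrees.
#' @param template_scales multiplicative scale factors for the template
#'   bank.
#' @param box_margin_px margin added around the template ellipse extent to
#'   form the reported box (matches the ground-truth convention).
#' @param background_level,soma_level grey levels used to render templates
#'   and to letterbox the canvas.
#' @param ncc_low,ncc_high NCC scores mapped linearly (and clipped) onto
#'   confidence 0 and 1.
#' @param min_ncc candidates below this raw NCC are discarded before NMS.
#' @return object of class `osteo_detector_config`.
#' @export
detector_config <- function(input_side_px = 448L,
                            grid_S = 7L,
                            confidence_floor = 0.5,
                            display_floor = 0.7,
                            nms_iou = 0.5,
                            soma_axes_px = c(20, 12),
                            n_orientations = 6L,
                            template_scales = 1,
                            box_margin_px = 6,
                            background_level = 200,
                            soma_level = 60,
                            ncc_low = 0.2,
                            ncc_high = 0.9,
                            min_ncc = 0.15) {
  stopifnot(grid_S >= 1, input_side_px >= 1,
            confidence_floor >= 0, confidence_floor <= display_floor,
            display_floor <= 1, nms_iou >= 0, nms_iou <= 1,
            n_orientations >= 1, all(template_scales > 0),
            ncc_high > ncc_low)
  structure(list(input_side_px = as.integer(input_side_px),
                 grid_S = as.integer(grid_S),
                 confidence_floor = confidence_floor,
                 display_floor = display_floor,
                 nms_iou = nms_iou,
                 soma_axes_px = soma_axes_px,
                 n_orientations = as.integer(n_orientations),
                 template_scales = template_scales,
                 box_margin_px = box_margin_px,
                 background_level = background_level,
                 soma_level = soma_level,
                 ncc_low = ncc_low, ncc_high = ncc_high,
                 min_ncc = min_ncc),
            class = "osteo_detector_config")
}

# Zero-mean, unit-norm elliptical soma templates over scales x orientations.
# Each entry carries the box extents reported for a match.
build_template_bank <- function(cfg) {
  bank <- list()
  for (s in cfg$template_scales) {
    a <- cfg$soma_axes_px[1L] * s / 2
    b <- cfg$soma_axes_px[2L] * s / 2
    R <- ceiling(a) + 2L
    side <- 2L * R + 1L
    xs <- matrix(rep(0:(side - 1L), each = side), side) - R
    ys <- matrix(rep(0:(side - 1L), side), side) - R
    for (k in seq_len(cfg$n_orientations)) {
      th <- (k - 1L) * pi / cfg$n_orientations
      xr <- xs * cos(th) + ys * sin(th)
      yr <- -xs * sin(th) + ys * cos(th)
      tpl <- matrix(cfg$background_level, side, side)
      tpl[(xr / a)^2 + (yr / b)^2 <= 1] <- cfg$soma_level
      t0 <- tpl - mean(tpl)
      t0 <- t0 / sqrt(sum(t0^2))
      ext <- ellipse_extent(a, b, th)
      bank[[length(bank) + 1L]] <-
        list(t0 = t0, side = side,
             box_w = 2 * ext[["x"]] + 2 * cfg$box_margin_px,
             box_h = 2 * ext[["y"]] + 2 * cfg$box_margin_px)
    }
  }
  bank
}

#' Letterbox an image onto the square detector canvas
#'
#' Aspect-preserving placement onto an `input_side_px` square canvas padded
#' with the background level. Images larger than the canvas are downscaled
#' by area averaging; smaller images are centred without upsampling. The
#' returned affine transform maps canvas coordinates back to source pixels.
#'
#' @param image greyscale matrix.
#' @param cfg an [detector_config()].
#' @return list with `canvas` (square matrix) and `transform`
#'   (`list(scale, offset_x, offset_y)` such that
#'   `src = (canvas_coord - offset) / scale`).
#' @export
detect_preprocess <- function(image, cfg = detector_config()) {
  H <- nrow(image); W <- ncol(image)
  stopifnot(H >= 1, W >= 1)
  side <- cfg$input_side_px
  scale <- min(1, side / max(H, W))
  newW <- max(1L, round(W * scale)); newH <- max(1L, round(H * scale))
  resized <- if (scale < 1) resize_area(image, newW, newH) else image
  ox <- (side - newW) %/% 2L; oy <- (side - newH) %/% 2L
  canvas <- matrix(cfg$background_level, side, side)
  canvas[oy + seq_len(newH), ox + seq_len(newW)] <- resized
  list(canvas = canvas,
       transform = list(scale = scale, offset_x = ox, offset_y = oy))
}

# Pooled NCC response over the template bank: per-pixel max score and the
# index of the winning template. Margins where no full template fits are
# -Inf.
ncc_response <- function(image, bank) {
  H <- nrow(image); W <- ncol(image)
  resp <- matrix(-Inf, H, W)
  tidx <- matrix(0L, H, W)
  S1all <- NULL
  for (t in seq_along(bank)) {
    tpl <- bank[[t]]
    k <- tpl$side
    if (k > H || k > W) next
    cc <- xcorr_valid(image, tpl$t0)
    S1 <- window_sums(image, k, k)
    S2 <- window_sums(image^2, k, k)
    denom <- sqrt(pmax(S2 - S1^2 / (k * k), 1e-9))
    ncc <- cc / denom
    c0 <- (k - 1L) %/% 2L
    rows <- c0 + seq_len(nrow(ncc)); cols <- c0 + seq_len(ncol(ncc))
    cur <- resp[rows, cols]
    upd <- ncc > cur
    cur[upd] <- ncc[upd]
    resp[rows, cols] <- cur
    ti <- tidx[rows, cols]
    ti[upd] <- t
    tidx[rows, cols] <- ti
  }
  list(resp = resp, tidx = tidx)
}

# Best candidate per grid block for one grid phase. Returns a data frame of
# raw candidates (0-based x/y of the response peak, template index, ncc).
grid_candidates <- function(resp, tidx, block, offset_x, offset_y, min_ncc) {
  H <- nrow(resp); W <- ncol(resp)
  out <- list()
  y0s <- seq(-offset_y, H - 1L, by = block)
  x0s <- seq(-offset_x, W - 1L, by = block)
  for (y0 in y0s) {
    rows <- (max(y0, 0L) + 1L):min(y0 + block, H)
    if (rows[1L] > rows[length(rows)]) next
    for (x0 in x0s) {
      cols <- (max(x0, 0L) + 1L):min(x0 + block, W)
      if (cols[1L] > cols[length(cols)]) next
      sub <- resp[rows, cols, drop = FALSE]
      m <- which.max(sub)
      v <- sub[m]
      if (!is.finite(v) || v < min_ncc) next
      ri <- (m - 1L) %% nrow(sub) + 1L
      ci <- (m - 1L) %/% nrow(sub) + 1L
      out[[length(out) + 1L]] <-
        c(x = cols[ci] - 1L, y = rows[ri] - 1L,
          t = tidx[rows[ri], cols[ci]], ncc = v)
    }
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), t = integer(0),
                      ncc = numeric(0)))
  as.data.frame(do.call(rbind, out))
}

#' Detect osteocyte-like cells in an image
#'
#' Runs the template-bank detector once over the image. Images no larger
#' than the canvas side are letterboxed via [detect_preprocess()] and
#' scanned with a single S x S grid; larger images (stitched panoramas) are
#' scanned at native resolution with the same grid-cell size and two grid
#' phases per axis, so cells falling on a grid boundary in one phase are
#' recovered in another. Candidates are resolved by [nms()] and the 0.5
#' confidence floor, then mapped back to source-frame pixels.
#'
#' @param image greyscale matrix or [panorama()].
#' @param cfg an [detector_config()].
#' @return data frame of detections `X, Y, W, H, p, class` (class `NA`
#'   before classification), in source-frame pixels, ordered by descending
#'   confidence.
#' @export
detect_cells <- function(image, cfg = detector_config()) {
  if (inherits(image, "osteo_panorama")) image <- image$pixels
  bank <- build_template_bank(cfg)
  block <- max(1L, round(cfg$input_side_px / cfg$grid_S))
  big <- max(dim(image)) > cfg$input_side_px
  if (big) {
    work <- image
    tr <- list(scale = 1, offset_x = 0L, offset_y = 0L)
    phases <- expand.grid(ox = c(0L, block %/% 2L), oy = c(0L, block %/% 2L))
  } else {
    pp <- detect_preprocess(image, cfg)
    work <- pp$canvas
    tr <- pp$transform
    phases <- data.frame(ox = 0L, oy = 0L)
  }
  rsp <- ncc_response(work, bank)
  cands <- do.call(rbind, lapply(seq_len(nrow(phases)), function(i)
    grid_candidates(rsp$resp, rsp$tidx, block,
                    phases$ox[i], phases$oy[i], cfg$min_ncc)))
  if (is.null(cands) || nrow(cands) == 0L)
    return(empty_detections())
  dets <- data.frame(
    X = cands$x, Y = cands$y,
    W = vapply(cands$t, function(t) bank[[t]]$box_w, numeric(1L)),
    H = vapply(cands$t, function(t) bank[[t]]$box_h, numeric(1L)),
    p = pmin(pmax((cands$ncc - cfg$ncc_low) / (cfg$ncc_high - cfg$ncc_low),
                  0), 1),
    class = NA_character_, stringsAsFactors = FALSE)
  dets <- nms(dets, iou = cfg$nms_iou, confidence_floor = cfg$confidence_floor)
  dets$X <- (dets$X - tr$offset_x) / tr$scale
  dets$Y <- (dets$Y - tr$offset_y) / tr$scale
  dets$W <- dets$W / tr$scale
  dets$H <- dets$H / tr$scale
  rownames(dets) <- NULL
  dets
}

empty_detections <- function() {
  data.frame(X = numeric(0), Y = numeric(0), W = numeric(0), H = numeric(0),
             p = numeric(0), class = character(0), stringsAsFactors = FALSE)
}

#' Intersection-over-union of center-format boxes
#'
#' @param a,b data frames (or one-row lists) with columns `X, Y, W, H`
#'   (box centres and extents). `a` may have many rows and `b` one, or
#'   vice versa (standard recycling on coordinates).
#' @return numeric vector of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ax0 <- a$X - a$W / 2; ax1 <- a$X + a$W / 2
  ay0 <- a$Y - a$H / 2; ay1 <- a$Y + a$H / 2
  bx0 <- b$X - b$W / 2; bx1 <- b$X + b$W / 2
  by0 <- b$Y - b$H / 2; by1 <- b$Y + b$H / 2
  iw <- pmax(0, pmin(ax1, bx1) - pmax(ax0, bx0))
  ih <- pmax(0, pmin(ay1, by1) - pmax(ay0, by0))
  inter <- iw * ih
  union <- a$W * a$H + b$W * b$H - inter
  ifelse(union > 0, inter / union, 0)
}

#' Non-max suppression with a confidence floor
#'
#' Greedy by descending confidence (ties broken by X then Y): a box is
#' suppressed when its IoU with an already-kept box exceeds `iou`. Kept
#' boxes with `p <= confidence_floor` are then dropped — suppression first,
#' flooring second, so a low-confidence box never shields a better one.
#'
#' @param dets data frame with columns `X, Y, W, H, p` (and optionally
#'   `class`).
#' @param iou suppression threshold on IoU; default 0.5.
#' @param confidence_floor minimum surviving confidence (strict); default
#'   0.5.
#' @return the surviving rows, ordered by `(-p, X, Y)`.
#' @export
nms <- function(dets, iou = 0.5, confidence_floor = 0.5) {
  if (nrow(dets) == 0L) return(dets)
  ord <- order(-dets$p, dets$X, dets$Y)
  dets <- dets[ord, , drop = FALSE]
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    kept <- which(keep)
    if (length(kept) > 0L) {
      ious <- box_iou(dets[kept, , drop = FALSE], dets[i, , drop = FALSE])
      if (any(ious > iou)) next
    }
    keep[i] <- TRUE
  }
  out <- dets[keep & dets$p > confidence_floor, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate detections against ground truth
#'
#' Detections and truth boxes are matched one-to-one, greedily by
#' descending IoU, accepting matches with IoU >= `iou_floor`. Ghost lacunae
#' are excluded from the accuracy and recall denominators; a detection
#' matching a ghost counts as a detection error (false positive) unless
#' `ghost_tolerant` is set, in which case it is ignored entirely.
#'
#' `accuracy` is the joint detection-plus-classification accuracy: matched
#' non-ghost truth cells whose predicted class equals the true status,
#' divided by all non-ghost truth cells. A detection with no class counts
#' as misclassified.
#'
#' @param dets detection data frame (`X, Y, W, H, p`, optional `class`).
#' @param truth phantom ground-truth data frame (`X, Y, W, H, status`).
#' @param iou_floor minimum IoU for a match; default 0.5.
#' @param ghost_tolerant drop ghost-matching detections from the precision
#'   denominator instead of counting them as errors.
#' @return list with `precision`, `recall`, `accuracy`, and the underlying
#'   counts (`n_truth`, `n_det`, `n_matched`, `n_correct_class`,
#'   `n_ghost_matched`) plus the per-truth match table.
#' @export
evaluate_detections <- function(dets, truth, iou_floor = 0.5,
                                ghost_tolerant = FALSE) {
  n_d <- nrow(dets); n_t <- nrow(truth)
  nonghost <- truth$status != "ghost"
  match_det <- rep(NA_integer_, n_t)
  if (n_d > 0L && n_t > 0L) {
    iou <- matrix(0, n_d, n_t)
    for (j in seq_len(n_t))
      iou[, j] <- box_iou(dets, truth[j, , drop = FALSE])
    repeat {
      m <- which.max(iou)
      if (length(m) == 0L || iou[m] < iou_floor) break
      i <- (m - 1L) %% n_d + 1L
      j <- (m - 1L) %/% n_d + 1L
      match_det[j] <- i
      iou[i, ] <- -1; iou[, j] <- -1
    }
  }
  matched <- !is.na(match_det)
  n_matched_ng <- sum(matched & nonghost)
  n_ghost_matched <- sum(matched & !nonghost)
  cls <- if ("class" %in% names(dets)) dets$class else rep(NA_character_, n_d)
  correct <- matched & nonghost &
    !is.na(cls[ifelse(matched, match_det, 1L)]) &
    cls[ifelse(matched, match_det, 1L)] == truth$status
  n_correct <- sum(correct)
  denom_t <- sum(nonghost)
  denom_p <- if (ghost_tolerant) n_d - n_ghost_matched else n_d
  list(precision = if (denom_p > 0) n_matched_ng / denom_p else NA_real_,
       recall = if (denom_t > 0) n_matched_ng / denom_t else NA_real_,
       accuracy = if (denom_t > 0) n_correct / denom_t else NA_real_,
       n_truth = denom_t, n_det = n_d, n_matched = n_matched_ng,
       n_correct_class = n_correct, n_ghost_matched = n_ghost_matched,
       matches = data.frame(truth_row = seq_len(n_t), det_row = match_det))
}
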