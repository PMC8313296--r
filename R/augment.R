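# Training-set augmentation bookkeeping: deterministic transform grids,
# source-aware train/test splitting. Examples are transform-parameter
# records traceable to their source annotation; patches are materialized
# on demand, never eagerly.

#' Augmentation transform grid
#'
#' The grid is the cross product of a rotation list and a "jitter" list of
#' (scale, contrast, dx, dy) tuples. The jitter list holds the identity
#' plus one-factor-at-a-time perturbations — every scale alone, every
#' contrast alone, every translation alone — rather than their full cross
#' product, which keeps the grid compact while still covering each factor.
#' The default grid has 30 rotations x 53 jitters = 1,590 transforms, so
#' 629 seed annotations expand to 1,000,110 examples. The identity
#' transform is always a member.
#'
#' @param rotations rotation angles in degrees (must include 0).
#' @param scales non-identity scale factors (> 0).
#' @param contrasts non-identity contrast gains (> 0).
#' @param translations two-column matrix/data frame of non-zero pixel
#'   offsets `(dx, dy)`.
#' @return object of class `osteo_augmentation_spec` with a `jitters` data
#'   frame and `per_example_count = length(rotations) * nrow(jitters)`.
#' @export
augmentation_spec <- function(rotations = seq(0, 348, by = 12),
                              scales = c(0.80, 0.85, 0.90, 0.95,
                                         1.05, 1.10, 1.15, 1.20),
                              contrasts = c(0.70, 0.80, 0.90, 0.95,
                                            1.05, 1.10, 1.20, 1.30),
                              translations = as.matrix(expand.grid(
                                dx = c(-10, -6, -2, 2, 6, 10),
                                dy = c(-10, -6, -2, 2, 6, 10)))) {
  if (!0 %in% rotations) stop("the identity rotation (0 degrees) is required")
  if (any(scales <= 0)) stop("degenerate scale (<= 0) rejected")
  if (any(contrasts <= 0)) stop("degenerate contrast (<= 0) rejected")
  translations <- as.matrix(translations)
  if (ncol(translations) != 2L) stop("translations must be (dx, dy) pairs")
  ns <- length(scales); nc <- length(contrasts); nt <- nrow(translations)
  jitters <- data.frame(
    scale = c(1, scales, rep(1, nc), rep(1, nt)),
    contrast = c(1, rep(1, ns), contrasts, rep(1, nt)),
    dx = c(rep(0, 1 + ns + nc), translations[, 1L]),
    dy = c(rep(0, 1 + ns + nc), translations[, 2L]))
  structure(list(rotations = rotations, scales = scales,
                 contrasts = contrasts, translations = translations,
                 jitters = jitters,
                 per_example_count = length(rotations) * nrow(jitters)),
            class = "osteo_augmentation_spec")
}

#' Expand annotations into an augmented example table
#'
#' Every annotation is crossed with the full transform grid. The result is
#' a table of transform-parameter records — one row per training example —
#' each carrying its source annotation id and label, so counts and splits
#' can be verified without materializing a single image.
#'
#' @param annotations data frame with columns `annotation_id` and `label`
#'   (labels are invariant under the transforms).
#' @param spec an [augmentation_spec()].
#' @return data frame `example_id, source_id, label, rotation_deg, scale,
#'   contrast, dx_px, dy_px` of exactly
#'   `nrow(annotations) * spec$per_example_count` rows.
#' @export
augment <- function(annotations, spec = augmentation_spec()) {
  stopifnot(nrow(annotations) >= 1L,
            all(c("annotation_id", "label") %in% names(annotations)))
  nr <- length(spec$rotations); nj <- nrow(spec$jitters)
  n_a <- nrow(annotations)
  src <- rep(seq_len(n_a), each = nr * nj)
  rot <- rep(rep(spec$rotations, each = nj), times = n_a)
  jit <- spec$jitters[rep(seq_len(nj), times = nr * n_a), , drop = FALSE]
  out <- data.frame(
    example_id = seq_len(n_a * nr * nj),
    source_id = annotations$annotation_id[src],
    label = annotations$label[src],
    rotation_deg = rot,
    scale = jit$scale, contrast = jit$contrast,
    dx_px = jit$dx, dy_px = jit$dy,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Materialize one augmented patch
#'
#' Applies rotation, scale, contrast gain (about the background level) and
#' translation to an image patch. Only needed for visual inspection or a
#' learned backend; the bookkeeping pipeline works on parameter records.
#'
#' @param patch greyscale matrix.
#' @param rotation_deg,scale,contrast,dx_px,dy_px transform parameters.
#' @param background fill level for exposed borders.
#' @return transformed greyscale matrix of the same dimensions.
#' @export
apply_augmentation <- function(patch, rotation_deg = 0, scale = 1,
                               contrast = 1, dx_px = 0, dy_px = 0,
                               background = 200) {
  stopifnot(scale > 0, contrast > 0)
  img <- patch / 255
  bg <- background / 255
  if (rotation_deg != 0) {
    img <- EBImage::rotate(img, rotation_deg, bg.col = bg,
                           output.dim = dim(patch))
  }
  if (scale != 1) {
    sc <- EBImage::resize(img, w = max(1L, round(nrow(img) * scale)))
    out <- matrix(bg, nrow(patch), ncol(patch))
    # centre-crop or centre-pad back to the original frame
    src_h <- nrow(sc); src_w <- ncol(sc)
    h <- min(src_h, nrow(out)); w <- min(src_w, ncol(out))
    sr <- (src_h - h) %/% 2L; sc0 <- (src_w - w) %/% 2L
    dr <- (nrow(out) - h) %/% 2L; dc <- (ncol(out) - w) %/% 2L
    out[dr + seq_len(h), dc + seq_len(w)] <-
      as.matrix(sc)[sr + seq_len(h), sc0 + seq_len(w)]
    img <- out
  }
  if (dx_px != 0 || dy_px != 0) {
    # EBImage's first image dimension is this package's row (y) axis
    img <- EBImage::translate(img, c(dy_px, dx_px), bg.col = bg)
  }
  img <- as.matrix(img) * 255
  if (contrast != 1) img <- background + contrast * (img - background)
  clamp255(img)
}

#' Split augmented examples into train and test by source annotation
#'
#' All augmentations of one source annotation land on the same side of the
#' split, so no augmented copy of a test cell leaks into training.
#' `round(train_fraction * n_sources)` sources are assigned to training.
#'
#' @param examples example table from [augment()] (needs `source_id`).
#' @param train_fraction fraction of sources used for training; default
#'   0.75.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list with `train` and `test` example tables (disjoint,
#'   exhaustive) and the `train_sources` / `test_sources` vectors.
#' @export
split_examples <- function(examples, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            "source_id" %in% names(examples))
  sources <- unique(examples$source_id)
  if (length(sources) < 2L)
    stop("at least 2 source annotations are required for a split")
  n_train <- round(train_fraction * length(sources))
  n_train <- min(max(n_train, 1L), length(sources) - 1L)
  train_sources <- with_seed(seed, sample(sources, n_train))
  is_train <- examples$source_id %in% train_sources
  list(train = examples[is_train, , drop = FALSE],
       test = examples[!is_train, , drop = FALSE],
       train_sources = sort(train_sources),
       test_sources = sort(setdiff(sources, train_sources)))
}
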