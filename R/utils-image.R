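# Image helpers shared across modules.
#
# Convention: a greyscale image is a numeric matrix indexed [row = y, col = x]
# with values on the 8-bit scale 0..255. Pixel coordinates are 0-based with
# origin at the top-left corner, x rightward, y downward; pixel (x, y) lives
# at matrix element [y + 1, x + 1].

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Summed-area table of an image
#'
#' Returns the (H+1) x (W+1) cumulative-sum grid F with F[i+1, j+1] equal to
#' the sum of the top-left i x j sub-image, so any axis-aligned box sum is a
#' four-corner lookup.
#' @param img numeric matrix.
#' @return numeric matrix one row and column larger than `img`.
#' @keywords internal
integral_image <- function(img) {
  h <- nrow(img); w <- ncol(img)
  F <- matrix(0, h + 1L, w + 1L)
  F[-1L, -1L] <- apply(apply(img, 2L, cumsum), 1L, cumsum) |> t()
  F
}

# Evaluate the integral function at continuous coordinates (exact: the
# integral of a piecewise-constant image is piecewise bilinear).
# xs, ys are vectors of coordinates in [0, W] and [0, H]; returns a
# length(ys) x length(xs) matrix.
integral_at <- function(F, xs, ys) {
  W <- ncol(F) - 1L; H <- nrow(F) - 1L
  ix <- pmin(pmax(floor(xs), 0), W - 1L); fx <- xs - ix
  iy <- pmin(pmax(floor(ys), 0), H - 1L); fy <- ys - iy
  A <- F[iy + 1L, ix + 1L, drop = FALSE]
  B <- F[iy + 1L, ix + 2L, drop = FALSE]
  C <- F[iy + 2L, ix + 1L, drop = FALSE]
  D <- F[iy + 2L, ix + 2L, drop = FALSE]
  FX <- matrix(fx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  FY <- matrix(fy, nrow = length(ys), ncol = length(xs))
  (A * (1 - FX) + B * FX) * (1 - FY) + (C * (1 - FX) + D * FX) * FY
}

#' Area-averaging (box-filter) resize
#'
#' Each output pixel is the exact mean of the source rectangle it covers,
#' computed from a summed-area table, so fractional scale factors introduce
#' no aliasing. This is the resampling used when downscaling panoramas and
#' building pyramid levels.
#'
#' @param img numeric matrix (grey levels).
#' @param out_w,out_h target dimensions in pixels.
#' @return numeric matrix of dimensions `out_h` x `out_w`.
#' @export
resize_area <- function(img, out_w, out_h) {
  stopifnot(out_w >= 1, out_h >= 1)
  H <- nrow(img); W <- ncol(img)
  if (out_w == W && out_h == H) return(img)
  F <- integral_image(img)
  xs0 <- (0:(out_w - 1L)) * (W / out_w); xs1 <- (1:out_w) * (W / out_w)
  ys0 <- (0:(out_h - 1L)) * (H / out_h); ys1 <- (1:out_h) * (H / out_h)
  box <- integral_at(F, xs1, ys1) - integral_at(F, xs0, ys1) -
    integral_at(F, xs1, ys0) + integral_at(F, xs0, ys0)
  area <- outer(ys1 - ys0, xs1 - xs0)
  box / area
}

# 2x reduction by exact 2x2 block averaging; odd dimensions are padded with
# the background level before averaging.
halve_image <- function(img, background = 200) {
  H <- nrow(img); W <- ncol(img)
  H2 <- H + (H %% 2L); W2 <- W + (W %% 2L)
  if (H2 != H || W2 != W) {
    pad <- matrix(background, H2, W2)
    pad[seq_len(H), seq_len(W)] <- img
    img <- pad
  }
  (img[seq(1L, H2, 2L), seq(1L, W2, 2L), drop = FALSE] +
     img[seq(2L, H2, 2L), seq(1L, W2, 2L), drop = FALSE] +
     img[seq(1L, H2, 2L), seq(2L, W2, 2L), drop = FALSE] +
     img[seq(2L, H2, 2L), seq(2L, W2, 2L), drop = FALSE]) / 4
}

# Valid-mode cross-correlation of img with tpl via FFT (no kernel flip).
# Result[i, j] = sum(img[i..i+h-1, j..j+w-1] * tpl).
xcorr_valid <- function(img, tpl) {
  H <- nrow(img); W <- ncol(img); h <- nrow(tpl); w <- ncol(tpl)
  stopifnot(h <= H, w <= W)
  Ph <- stats::nextn(H + h - 1L, 2L); Pw <- stats::nextn(W + w - 1L, 2L)
  A <- matrix(0, Ph, Pw); A[seq_len(H), seq_len(W)] <- img
  B <- matrix(0, Ph, Pw); B[seq_len(h), seq_len(w)] <- tpl
  CC <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) / (Ph * Pw)
  CC[seq_len(H - h + 1L), seq_len(W - w + 1L), drop = FALSE]
}

# Sliding-window sums over h x w windows at all valid positions.
window_sums <- function(img, h, w) {
  F <- integral_image(img)
  H <- nrow(img); W <- ncol(img)
  i <- seq_len(H - h + 1L); j <- seq_len(W - w + 1L)
  F[i + h, j + w, drop = FALSE] - F[i, j + w, drop = FALSE] -
    F[i + h, j, drop = FALSE] + F[i, j, drop = FALSE]
}

#' Write a greyscale image as an 8-bit TIFF
#' @param img numeric matrix on the 0..255 scale.
#' @param path output file path.
#' @export
write_grey_tiff <- function(img, path) {
  tiff::writeTIFF(round(clamp255(img)) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a greyscale TIFF back to the 0..255 scale
#' @param path file path.
#' @return numeric matrix.
#' @export
read_grey_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * 255
}

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
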