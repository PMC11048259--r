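# One shared inverse-map bilinear sampler backs every geometric operation
# (resize, rotation, scaling, heat-map upsampling) so that pixel-center
# conventions, zero fill, and determinism are identical everywhere.
# Convention: pixel (i, j) has its center at coordinate (i, j); samples
# outside [1, nrow] x [1, ncol] read as `fill`.

bilinear_sample <- function(img, rows, cols, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  r0 <- floor(rows)
  c0 <- floor(cols)
  fr <- rows - r0
  fc <- cols - c0
  grab <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- rep(fill, length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  (1 - fr) * (1 - fc) * grab(r0, c0) +
    fr * (1 - fc) * grab(r0 + 1, c0) +
    (1 - fr) * fc * grab(r0, c0 + 1) +
    fr * fc * grab(r0 + 1, c0 + 1)
}

# Bilinear resize with the align-centers convention: output center u maps to
# input coordinate (u - 0.5) * (n_in / n_out) + 0.5.  Constant images stay
# constant and same-size resize is the identity.
resize_matrix <- function(img, out_h, out_w = out_h) {
  stopifnot(out_h >= 1, out_w >= 1)
  h <- nrow(img)
  w <- ncol(img)
  if (out_h == h && out_w == w) return(img)
  rows <- (seq_len(out_h) - 0.5) * (h / out_h) + 0.5
  cols <- (seq_len(out_w) - 0.5) * (w / out_w) + 0.5
  rg <- matrix(rows, out_h, out_w)
  cg <- matrix(cols, out_h, out_w, byrow = TRUE)
  # clamp to the valid range so edge pixels extend rather than fade to fill
  rg <- pmin(pmax(rg, 1), h)
  cg <- pmin(pmax(cg, 1), w)
  matrix(bilinear_sample(img, as.vector(rg), as.vector(cg)), out_h, out_w)
}

# Rotation (degrees, positive rotates displayed content counter-clockwise)
# combined with isotropic scaling about the image center; exposed border
# regions are filled with `fill` (anechoic black by default).
warp_rotate_scale <- function(img, angle_deg = 0, scale = 1, fill = 0) {
  stopifnot(scale > 0)
  if (angle_deg == 0 && scale == 1) return(img)
  h <- nrow(img)
  w <- ncol(img)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  th <- angle_deg * pi / 180
  # inverse map: destination offset rotated by -theta and divided by scale
  dst_r <- matrix(seq_len(h), h, w) - cy
  dst_c <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  src_r <- (cos(th) * dst_r - sin(th) * dst_c) / scale + cy
  src_c <- (sin(th) * dst_r + cos(th) * dst_c) / scale + cx
  matrix(bilinear_sample(img, as.vector(src_r), as.vector(src_c), fill = fill),
         h, w)
}

reflect_y <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

# Separable Gaussian blur via banded row/column operators, renormalized at
# the borders so constants are preserved.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  op <- function(n) {
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    k <- dnorm(-r:r, sd = sigma)
    B <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    B / rowSums(B)
  }
  op(nrow(img)) %*% img %*% t(op(ncol(img)))
}
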