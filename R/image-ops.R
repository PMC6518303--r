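# Bilinear geometry on (H, W) matrices or (H, W, C) arrays. Pixel centers sit
# at integer coordinates 1..H / 1..W; samples outside the grid read as 0.

bilinear_sample <- function(img, sy, sx) {
  d <- dim(img)
  H <- d[1]
  W <- d[2]
  C <- if (length(d) == 3L) d[3] else 1L
  if (length(d) == 2L) dim(img) <- c(H, W, 1L)
  y0 <- floor(sy)
  x0 <- floor(sx)
  fy <- sy - y0
  fx <- sx - x0
  gather <- function(ch, yi, xi) {
    ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
    v <- numeric(length(yi))
    v[ok] <- ch[yi[ok] + (xi[ok] - 1) * H]
    v
  }
  out <- array(0, c(dim(sy), C))
  for (c in seq_len(C)) {
    ch <- img[, , c]
    v <- (1 - fy) * (1 - fx) * gather(ch, y0, x0) +
      (1 - fy) * fx * gather(ch, y0, x0 + 1) +
      fy * (1 - fx) * gather(ch, y0 + 1, x0) +
      fy * fx * gather(ch, y0 + 1, x0 + 1)
    out[, , c] <- v
  }
  if (C == 1L && length(d) == 2L) dim(out) <- dim(sy)
  out
}

# Rotate the image content by `angle` degrees counter-clockwise about its
# center, then shift it by (tx, ty) pixels (positive = right / down).
affine_image <- function(img, angle = 0, tx = 0, ty = 0) {
  d <- dim(img)
  H <- d[1]
  W <- d[2]
  if (angle == 0 && tx == 0 && ty == 0) return(img)
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  th <- angle * pi / 180
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- r - ty - cy
  dx <- c - tx - cx
  # inverse map; rows grow downward, so the signs below make a positive
  # angle rotate the content counter-clockwise on screen
  sy <- cy + cos(th) * dy + sin(th) * dx
  sx <- cx - sin(th) * dy + cos(th) * dx
  bilinear_sample(img, sy, sx)
}

# Resample the axis-aligned window with top-left corner (r0, c0) and size
# (h, w) onto an out_h x out_w grid (area-aligned center mapping).
crop_resize <- function(img, r0, c0, h, w, out_h, out_w) {
  rr <- (seq_len(out_h) - 0.5) * h / out_h + (r0 - 1) + 0.5
  cc <- (seq_len(out_w) - 0.5) * w / out_w + (c0 - 1) + 0.5
  sy <- matrix(rr, out_h, out_w)
  sx <- matrix(cc, out_h, out_w, byrow = TRUE)
  bilinear_sample(img, sy, sx)
}

#' Bilinear image resize
#'
#' @param img an (H, W) matrix or (H, W, C) array with values in \[0, 1\].
#' @param out_h,out_w output dimensions; `out_w` defaults to `out_h`.
#' @return the resized image with the same channel count.
#' @export
resize_image <- function(img, out_h, out_w = out_h) {
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) return(img)
  crop_resize(img, 1, 1, d[1], d[2], out_h, out_w)
}
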