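#' Read and write dataset manifests
#'
#' A manifest is a CSV with header `path,class_id[,channels,...]`; paths are
#' stored relative to the manifest's directory. Class ids are 1-based.
#'
#' @param path manifest file.
#' @param strict error (rather than warn) when a referenced image file is
#'   missing.
#' @return data.frame with at least `path` and integer `class_id`; the
#'   attribute `base_dir` records the directory paths are relative to.
#' @export
read_manifest <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "class_id") %in% names(df))) {
    stop("manifest must have columns path and class_id")
  }
  df$class_id <- as.integer(df$class_id)
  base <- dirname(normalizePath(path))
  if (nrow(df)) {
    full <- file.path(base, df$path)
    missing <- !file.exists(full)
    if (any(missing)) {
      msg <- paste0("manifest references missing file(s): ",
                    paste(utils::head(df$path[missing], 3), collapse = ", "))
      if (strict) stop(msg) else warning(msg)
    }
  }
  attr(df, "base_dir") <- base
  df
}

#' @rdname read_manifest
#' @param manifest data.frame with `path` and `class_id`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("path", "class_id") %in% names(manifest)))
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and save images (PNG and BMP)
#'
#' Images are 8-bit PNG or uncompressed BMP; in memory they are numeric
#' arrays in \[0, 1\], either (H, W) for grayscale or (H, W, 3) for color.
#'
#' @param path image file; the extension selects the format.
#' @return the pixel array.
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                bmp = read_bmp(path),
                stop("unsupported image format: .", ext,
                     " (PNG and BMP are supported)"))
  d <- dim(img)
  if (length(d) == 3L && d[3] == 4L) img <- img[, , 1:3]  # drop alpha
  if (length(d) == 3L && dim(img)[3] == 1L) dim(img) <- d[1:2]
  img
}

#' @rdname load_image
#' @param img an (H, W) or (H, W, 3) array in \[0, 1\].
#' @export
save_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         bmp = write_bmp(img, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

# Minimal uncompressed BMP support: 24-bit BGR for color, 8-bit gray-palette
# for single-channel images; rows bottom-up and padded to 4 bytes.
write_bmp <- function(img, path) {
  d <- dim(img)
  H <- d[1]
  W <- d[2]
  color <- length(d) == 3L
  px <- round(pmin(pmax(img, 0), 1) * 255)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  bpp <- if (color) 24L else 8L
  row_bytes <- ((W * bpp / 8 + 3) %/% 4) * 4
  palette_bytes <- if (color) 0L else 1024L
  offset <- 14L + 40L + palette_bytes
  writeBin(charToRaw("BM"), con)
  w32(offset + row_bytes * H)
  w16(0); w16(0)
  w32(offset)
  w32(40); w32(W); w32(H); w16(1); w16(bpp)
  w32(0); w32(row_bytes * H); w32(2835); w32(2835)
  w32(if (color) 0 else 256); w32(0)
  if (!color) {
    pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
    pal[seq(4, 1024, 4)] <- as.raw(0)
    writeBin(pal, con)
  }
  for (r in H:1) {
    bytes <- if (color) {
      as.raw(rbind(px[r, , 3], px[r, , 2], px[r, , 1]))  # BGR order
    } else {
      as.raw(px[r, ])
    }
    writeBin(c(bytes, raw(row_bytes - length(bytes))), con)
  }
  invisible(path)
}

read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM")) stop("not a BMP file")
  r32(); r16(); r16()
  offset <- r32()
  hdr_size <- r32()
  W <- r32()
  H <- r32()
  r16()
  bpp <- r16()
  compression <- r32()
  if (compression != 0L) stop("compressed BMP is not supported")
  if (!bpp %in% c(8L, 24L)) stop("only 8- and 24-bit BMP are supported")
  seek(con, offset)
  row_bytes <- ((W * bpp / 8 + 3) %/% 4) * 4
  raw <- readBin(con, "raw", row_bytes * H)
  m <- matrix(as.integer(raw), nrow = row_bytes)
  if (bpp == 8L) {
    out <- matrix(0, H, W)
    for (r in seq_len(H)) out[H - r + 1, ] <- m[seq_len(W), r]
    return(out / 255)
  }
  out <- array(0, c(H, W, 3L))
  for (r in seq_len(H)) {
    row <- m[seq_len(3 * W), r]
    out[H - r + 1, , 1] <- row[seq(3, 3 * W, 3)]
    out[H - r + 1, , 2] <- row[seq(2, 3 * W, 3)]
    out[H - r + 1, , 3] <- row[seq(1, 3 * W, 3)]
  }
  out / 255
}

#' Load a manifest's images as a network-ready batch
#'
#' Reads every image, replicates grayscale to three channels, and resizes to
#' `side` x `side`.
#'
#' @param manifest data.frame from [read_manifest()] (or with a `base_dir`
#'   argument/attribute).
#' @param side target image side.
#' @param base_dir directory image paths are relative to.
#' @return list with `x` (side, side, 3, N array) and integer labels `y`.
#' @export
load_image_batch <- function(manifest, side, base_dir = NULL) {
  if (is.null(base_dir)) base_dir <- attr(manifest, "base_dir")
  if (is.null(base_dir)) base_dir <- "."
  N <- nrow(manifest)
  x <- array(NA_real_, c(side, side, 3L, N))
  for (i in seq_len(N)) {
    img <- gray_to_3channel(load_image(file.path(base_dir, manifest$path[i])))
    x[, , , i] <- resize_image(img, side)
  }
  list(x = x, y = as.integer(manifest$class_id))
}
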