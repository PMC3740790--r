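#' Serialize an admissible truth
#'
#' The region-label map is written as an 8-bit PNG (A=1, B=2, C=3, D=4 on
#' the 0..255 scale) and a JSON sidecar records the shift and the
#' label-to-admissible-set table, so the ground truth is fully recoverable
#' from plain files.
#'
#' @param truth an [admissible_truth].
#' @param png_path destination for the label map PNG.
#' @param json_path destination for the JSON metadata sidecar.
#' @return `png_path`, invisibly.
#' @export
write_truth <- function(truth, png_path, json_path) {
  stopifnot(inherits(truth, "admissible_truth"))
  codes <- c(A = 1L, B = 2L, C = 3L, D = 4L)
  lab <- matrix(codes[truth$label], nrow(truth$label), ncol(truth$label))
  png::writePNG(lab / 255, target = png_path)
  meta <- list(
    shift = truth$shift,
    height = nrow(truth$label), width = ncol(truth$label),
    label_codes = as.list(codes),
    admissible_sets = lapply(truth$sets, function(s) {
      if (nrow(s) == 0) list() else apply(s, 1, as.list, simplify = FALSE)
    })
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(png_path)
}

#' @rdname write_truth
#' @export
read_truth <- function(png_path, json_path) {
  meta <- jsonlite::read_json(json_path)
  lab <- round(png::readPNG(png_path) * 255)
  codes <- unlist(meta$label_codes)
  label <- matrix(names(codes)[match(lab, codes)], nrow(lab), ncol(lab))
  admissible_truth(label, shift = meta$shift)
}

#' Serialize a displacement field as float TIFF plus JSON sidecar
#'
#' The two components are written as a two-page 32-bit float TIFF. Each
#' channel is affinely mapped into [0, 1] for storage; the per-channel
#' `offset` and `scale` are recorded in a JSON sidecar and inverted on read
#' (`stored = (value - offset) / scale`). Round-trips are exact to float32
#' precision.
#'
#' @param field a [displacement_field].
#' @param tiff_path destination TIFF path.
#' @param json_path destination sidecar path; defaults to
#'   `<tiff_path>.json`.
#' @return `tiff_path`, invisibly.
#' @export
write_field <- function(field, tiff_path, json_path = paste0(tiff_path, ".json")) {
  stopifnot(inherits(field, "displacement_field"))
  enc <- function(m) {
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    list(stored = (m - lo) / scale, offset = lo, scale = scale)
  }
  ex <- enc(field$ux); ey <- enc(field$uy)
  tiff::writeTIFF(list(ex$stored, ey$stored), tiff_path,
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(channels = c("ux", "uy"),
         ux = list(offset = ex$offset, scale = ex$scale),
         uy = list(offset = ey$offset, scale = ey$scale)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_field
#' @export
read_field <- function(tiff_path, json_path = paste0(tiff_path, ".json")) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(json_path)
  dec <- function(stored, m) stored * m$scale + m$offset
  displacement_field(dec(pages[[1]], meta$ux), dec(pages[[2]], meta$uy))
}

#' Serialize a pixel permutation as a plain-text table
#'
#' Two tab-separated columns, `fixed_index` and `moving_index`, as 0-based
#' row-major pixel indices (language-neutral; converted from R's 1-based
#' column-major indexing on write and back on read).
#'
#' @param p a [pixel_permutation].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_permutation <- function(p, path) {
  stopifnot(inherits(p, "pixel_permutation"))
  d <- attr(p, "img_dim")
  to_rowmajor0 <- function(i) {
    xy <- index_to_xy(i, d)
    xy$y * d[2] + xy$x
  }
  df <- data.frame(fixed_index = to_rowmajor0(seq_along(p)),
                   moving_index = to_rowmajor0(unclass(p)))
  df <- df[order(df$fixed_index), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_permutation
#' @param dim image dimensions `c(height, width)`.
#' @export
read_permutation <- function(path, dim) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  from_rowmajor0 <- function(i) {
    y <- i %/% dim[2]
    x <- i %% dim[2]
    x * dim[1] + y + 1L
  }
  p <- integer(nrow(df))
  p[from_rowmajor0(df$fixed_index)] <- from_rowmajor0(df$moving_index)
  pixel_permutation(p, dim = dim)
}
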