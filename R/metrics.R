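#' Root residual mean squares (RRMS)
#'
#' Square root of the mean squared pixelwise intensity difference. A metric
#' on images: symmetric, zero iff the images are identical, and satisfying
#' the triangle inequality.
#'
#' @param a,b [gray_image]s (or matrices) of identical shape.
#' @return RRMS in intensity units, `>= 0`.
#' @export
rrms <- function(a, b) {
  assert_same_shape(a, b)
  sqrt(mean((img_mat(a) - img_mat(b))^2))
}

#' Cross correlation (CC)
#'
#' Pearson correlation of paired pixel intensities: dimensionless, in
#' `[-1, 1]`, invariant under positive affine intensity rescaling of either
#' image. Undefined (an error) when either image is constant.
#'
#' @inheritParams rrms
#' @return correlation in `[-1, 1]`.
#' @export
cc <- function(a, b) {
  assert_same_shape(a, b)
  va <- as.vector(img_mat(a)); vb <- as.vector(img_mat(b))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("cross correlation is undefined for a constant image (zero variance)",
         call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Entropy of image difference (EID)
#'
#' Shannon entropy of the normalized histogram of the difference image
#' `a - b`, with one bin per integer difference value by default
#' (`bin_width = 1`, exact and parameter-free for integer intensities).
#' Empty bins contribute zero. EID is zero iff the difference image is
#' constant, and invariant to adding a constant to either image.
#'
#' @inheritParams rrms
#' @param base logarithm base; 2 (the default) gives bits.
#' @param bin_width histogram bin width in intensity units; differences are
#'   assigned to bins by `round(d / bin_width)`.
#' @return entropy, `>= 0`.
#' @export
eid <- function(a, b, base = 2, bin_width = 1) {
  assert_same_shape(a, b)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  d <- round((img_mat(a) - img_mat(b)) / bin_width)
  # one bin per integer value in [-max, +max]; tabulate over the offset range
  offset <- max(abs(d)) + 1L
  counts <- tabulate(as.vector(d) + offset, nbins = 2L * offset + 1L)
  p <- counts[counts > 0] / length(d)
  -sum(p * log(p, base = base))
}

#' Similarity triple for one reformatted image
#'
#' Bundles the three similarity measures between a fixed image and a
#' reformatted moving image. Lower is better for RRMS and EID, higher is
#' better for CC, so a set of reports can rank methods by apparent
#' similarity.
#'
#' @param fixed,reformatted [gray_image]s of identical shape.
#' @param method optional method label for the `method` column.
#' @param eid_base,eid_bin_width options passed to [eid()].
#' @return a one-row tibble with columns `method`, `rrms`, `cc`, `eid`.
#' @export
similarity_report <- function(fixed, reformatted, method = NA_character_,
                              eid_base = 2, eid_bin_width = 1) {
  assert_same_shape(fixed, reformatted)
  tibble::tibble(
    method = method,
    rrms = rrms(fixed, reformatted),
    cc = cc(fixed, reformatted),
    eid = eid(fixed, reformatted, base = eid_base, bin_width = eid_bin_width)
  )
}

# rank a similarity table: 1 = most similar; average rank over the three
# metrics with their proper directions
similarity_ranks <- function(sim) {
  r <- (rank(sim$rrms) + rank(-sim$cc) + rank(sim$eid)) / 3
  rank(r, ties.method = "min")
}

#' Write a similarity table as plain text and JSON
#'
#' Emits one row per method with columns RRMS/CC/EID, as an aligned
#' plain-text table and, if `json_path` is given, as machine-readable JSON.
#'
#' @param sim a tibble as returned by [similarity_report()] (rows may be
#'   bound across methods).
#' @param path destination for the plain-text table.
#' @param json_path optional destination for the JSON rendering.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(sim, path, json_path = NULL) {
  df <- data.frame(Method = sim$method,
                   RRMS = sprintf("%.4f", sim$rrms),
                   CC = sprintf("%.4f", sim$cc),
                   EID = sprintf("%.4f", sim$eid))
  lines <- utils::capture.output(print(df, row.names = FALSE))
  writeLines(lines, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(sim, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
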