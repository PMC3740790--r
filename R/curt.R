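#' CURT: rank-order pixel permutation "registration"
#'
#' CURT sorts the pixels of each image in order of increasing intensity and
#' maps each fixed-image pixel to the moving-image pixel at the equivalent
#' index in the sort order. Image similarity is thereby maximized, but no
#' meaningful spatial transformation is computed — CURT is a null model for
#' registration evaluation, not a registration method.
#'
#' Ties among equal intensities are broken by ascending linear
#' (column-major) pixel index in both images via a stable sort, so the
#' result is deterministic; any tie rule yields identical similarity values.
#'
#' @param fixed,moving [gray_image]s (or matrices) with equal pixel counts.
#' @return a [pixel_permutation]: for each fixed pixel index `i` (linear,
#'   column-major), the matched moving pixel index `p[i]`.
#' @export
curt_register <- function(fixed, moving) {
  if (length(fixed) != length(moving)) {
    stop("`fixed` and `moving` must contain the same number of pixels",
         call. = FALSE)
  }
  # order() uses a stable radix sort: equal intensities keep index order
  of <- order(as.vector(img_mat(as_gray_image(fixed,  max(fixed, 255)))))
  om <- order(as.vector(img_mat(as_gray_image(moving, max(moving, 255)))))
  p <- integer(length(of))
  p[of] <- om
  pixel_permutation(p, dim = dim(fixed))
}

#' Pixel permutation between two same-size images
#'
#' A bijection from fixed-image pixel indices to moving-image pixel indices
#' (linear, column-major, 1-based).
#'
#' @param p integer vector; `p[i]` is the moving pixel matched to fixed
#'   pixel `i`. Must be a permutation of `1:length(p)`.
#' @param dim the image dimensions `c(height, width)`; `prod(dim)` must
#'   equal `length(p)`.
#' @export
pixel_permutation <- function(p, dim) {
  p <- as.integer(p)
  n <- length(p)
  if (length(dim) != 2 || prod(dim) != n) {
    stop("`dim` is inconsistent with the permutation length", call. = FALSE)
  }
  if (n == 0 || anyNA(p) || min(p) < 1L || max(p) > n || anyDuplicated(p)) {
    stop("`p` is not a bijection over pixel indices 1..n", call. = FALSE)
  }
  structure(p, class = "pixel_permutation", img_dim = as.integer(dim))
}

#' @export
print.pixel_permutation <- function(x, ...) {
  d <- attr(x, "img_dim")
  n_id <- sum(unclass(x) == seq_along(x))
  cat(sprintf("<pixel_permutation> %dx%d image (%d pixels), %d fixed points\n",
              d[1], d[2], length(x), n_id))
  invisible(x)
}

#' Per-pixel displacement field
#'
#' Real-valued displacements `(u_x, u_y)` on the fixed-image grid: the
#' moving-image location corresponding to fixed pixel `(x, y)` is
#' `(x + u_x, y + u_y)` (x = column increasing rightward, y = row
#' increasing downward).
#'
#' @param ux,uy numeric matrices of equal shape with finite values.
#' @export
displacement_field <- function(ux, uy) {
  if (!is.matrix(ux) || !is.matrix(uy)) {
    stop("`ux` and `uy` must be matrices", call. = FALSE)
  }
  assert_same_shape(ux, uy, "displacement components")
  if (!all(is.finite(ux)) || !all(is.finite(uy))) {
    stop("displacement values must all be finite", call. = FALSE)
  }
  structure(list(ux = ux, uy = uy), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %dx%d; |u| in [%.3g, %.3g]\n",
              nrow(x$ux), ncol(x$ux),
              sqrt(min(x$ux^2 + x$uy^2)), sqrt(max(x$ux^2 + x$uy^2))))
  invisible(x)
}

#' @rdname displacement_field
#' @param dim image dimensions `c(height, width)`.
#' @export
identity_field <- function(dim) {
  z <- matrix(0, dim[1], dim[2])
  displacement_field(z, z)
}

#' Pixel-level view of a displacement field
#' @param x a [displacement_field].
#' @param ... unused.
#' @return a tibble with 0-based `x`, `y` and the displacement components.
#' @exportS3Method generics::tidy
tidy.displacement_field <- function(x, ...) {
  h <- nrow(x$ux); w <- ncol(x$ux)
  tibble::tibble(
    x = rep(seq_len(w) - 1L, each = h),
    y = rep(seq_len(h) - 1L, times = w),
    ux = as.vector(x$ux),
    uy = as.vector(x$uy)
  )
}

# linear column-major index -> 0-based (x=col, y=row) coordinates
index_to_xy <- function(i, dim) {
  i0 <- i - 1L
  list(x = i0 %/% dim[1], y = i0 %% dim[1])
}

#' Express a pixel permutation as a displacement field
#'
#' At fixed pixel `(x, y)` matched to moving pixel `(x', y')` the field
#' value is `(x' - x, y' - y)`.
#'
#' @param p a [pixel_permutation].
#' @return a [displacement_field].
#' @export
permutation_to_field <- function(p) {
  stopifnot(inherits(p, "pixel_permutation"))
  d <- attr(p, "img_dim")
  fx <- index_to_xy(seq_along(p), d)
  mv <- index_to_xy(unclass(p), d)
  displacement_field(matrix(mv$x - fx$x, d[1], d[2]),
                     matrix(mv$y - fx$y, d[1], d[2]))
}

#' Read an integer-valued displacement field back as a pixel permutation
#'
#' Inverse of [permutation_to_field()] when every displaced location is an
#' in-bounds pixel and the map is one-to-one.
#'
#' @param field a [displacement_field] with integer-valued components.
#' @return a [pixel_permutation].
#' @export
field_to_permutation <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(field$ux)
  fx <- index_to_xy(seq_len(prod(d)), d)
  tx <- fx$x + as.vector(field$ux)
  ty <- fx$y + as.vector(field$uy)
  if (any(tx != round(tx)) || any(ty != round(ty))) {
    stop("field is not integer-valued; no permutation representation",
         call. = FALSE)
  }
  if (min(tx) < 0 || max(tx) >= d[2] || min(ty) < 0 || max(ty) >= d[1]) {
    stop("field maps pixels outside the image; no permutation representation",
         call. = FALSE)
  }
  pixel_permutation(round(tx) * d[1] + round(ty) + 1L, dim = d)
}

#' Reformat a moving image through a pixel permutation
#'
#' Output pixel at fixed index `i` holds the moving intensity at `p[i]`;
#' the output's intensity multiset equals the moving image's exactly.
#'
#' @param moving a [gray_image].
#' @param p a [pixel_permutation] over `moving`'s pixels.
#' @return a [gray_image].
#' @export
reformat_by_permutation <- function(moving, p) {
  stopifnot(inherits(p, "pixel_permutation"))
  moving <- as_gray_image(moving, max_intensity = max_intensity_of(moving))
  if (length(p) != length(moving)) {
    stop("permutation length does not match the moving image", call. = FALSE)
  }
  out <- matrix(as.vector(img_mat(moving))[unclass(p)],
                nrow(moving), ncol(moving))
  gray_image(out, max_intensity = max_intensity_of(moving))
}

#' Reformat a moving image through a displacement field
#'
#' Samples the moving image at `(x + u_x, y + u_y)` with nearest-neighbor
#' rounding. Coordinates falling outside the moving image are clamped to the
#' nearest edge pixel by default (`boundary = "clamp"`); the number of
#' clamped pixels is reported in the `n_clamped` attribute. A periodic
#' wraparound (`boundary = "periodic"`) is available for illustration only.
#'
#' @param moving a [gray_image].
#' @param field a [displacement_field] on the target grid (same shape).
#' @param boundary out-of-bounds handling, `"clamp"` or `"periodic"`.
#' @return a [gray_image] with attribute `n_clamped` (count of out-of-bounds
#'   samples; 0 under `"periodic"`).
#' @export
reformat_by_field <- function(moving, field, boundary = c("clamp", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(field, "displacement_field"))
  moving <- as_gray_image(moving, max_intensity = max_intensity_of(moving))
  assert_same_shape(moving, field$ux, "moving image and field")
  h <- nrow(moving); w <- ncol(moving)
  fx <- index_to_xy(seq_len(h * w), c(h, w))
  tx <- round(fx$x + as.vector(field$ux))
  ty <- round(fx$y + as.vector(field$uy))
  oob <- tx < 0 | tx >= w | ty < 0 | ty >= h
  if (boundary == "clamp") {
    tx <- pmin(pmax(tx, 0), w - 1)
    ty <- pmin(pmax(ty, 0), h - 1)
    n_clamped <- sum(oob)
  } else {
    tx <- tx %% w
    ty <- ty %% h
    n_clamped <- 0L
  }
  out <- matrix(as.vector(img_mat(moving))[tx * h + ty + 1L], h, w)
  out <- gray_image(out, max_intensity = max_intensity_of(moving))
  attr(out, "n_clamped") <- as.integer(n_clamped)
  out
}

#' Ground-truth oracle displacement field
#'
#' Picks one admissible displacement per pixel from the truth: `(0, 0)`
#' wherever admissible (regions A and D), `(shift, 0)` in region B. Region C
#' has no admissible displacement; `(0, 0)` is used there so the field can
#' still be applied for reformatting, and C is excluded from error
#' aggregation regardless.
#'
#' @param truth an [admissible_truth].
#' @return a [displacement_field].
#' @export
oracle_field <- function(truth) {
  stopifnot(inherits(truth, "admissible_truth"))
  ux <- matrix(0, nrow(truth$label), ncol(truth$label))
  ux[truth$label == "B"] <- truth$shift
  displacement_field(ux, matrix(0, nrow(ux), ncol(ux)))
}
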