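#' Color-coded deformation overlay
#'
#' Renders a displacement field over a grayscale background by color-coding
#' the two components: positive/negative `u_x` tints toward red/cyan,
#' positive/negative `u_y` toward yellow/blue, with the tint strength scaled
#' by displacement magnitude. Zero displacement leaves the background
#' unmodified. An optional white rectangle outline marks a region of
#' interest (e.g. the pasted copy).
#'
#' @param field a [displacement_field].
#' @param background a [gray_image] of the same shape.
#' @param box optional rectangle `c(row0, row1, col0, col1)` (0-based,
#'   inclusive) outlined in white.
#' @param max_displacement displacement magnitude mapped to full tint
#'   strength; defaults to the field's maximum component magnitude.
#' @param alpha maximum tint opacity in `[0, 1]`.
#' @return an `height x width x 3` RGB array with values in `[0, 1]`.
#' @export
render_overlay <- function(field, background, box = NULL,
                           max_displacement = NULL, alpha = 0.6) {
  stopifnot(inherits(field, "displacement_field"))
  assert_same_shape(field$ux, img_mat(background), "field and background")
  g <- img_mat(background) / max_intensity_of(background)
  mmax <- max_displacement %||% max(abs(c(field$ux, field$uy)), 1e-12)
  uxn <- pmin(pmax(field$ux / mmax, -1), 1)
  uyn <- pmin(pmax(field$uy / mmax, -1), 1)
  pos <- function(m) pmax(m, 0)
  neg <- function(m) pmax(-m, 0)
  # red/cyan for ux, yellow/blue for uy, additive then clipped
  r <- g + alpha * (pos(uxn) + 0.5 * pos(uyn))
  gr <- g + alpha * (neg(uxn) + 0.5 * pos(uyn))
  b <- g + alpha * (neg(uxn) + neg(uyn))
  out <- array(0, c(nrow(g), ncol(g), 3))
  out[, , 1] <- pmin(pmax(r, 0), 1)
  out[, , 2] <- pmin(pmax(gr, 0), 1)
  out[, , 3] <- pmin(pmax(b, 0), 1)
  if (!is.null(box)) {
    rows <- (box[1]:box[2]) + 1L
    cols <- (box[3]:box[4]) + 1L
    out[c(rows[1], rows[length(rows)]), cols, ] <- 1
    out[rows, c(cols[1], cols[length(cols)]), ] <- 1
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an RGB array (or grayscale image) as PNG
#'
#' @param x a `[0, 1]` RGB array or a [gray_image].
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(x, path) {
  if (is_gray_image(x)) x <- img_mat(x) / max_intensity_of(x)
  png::writePNG(x, target = path)
  invisible(path)
}

#' Plot a displacement field as a color overlay
#'
#' ggplot2 rendering of [render_overlay()].
#'
#' @param object a [displacement_field].
#' @param background a [gray_image]; defaults to mid-gray.
#' @param ... passed to [render_overlay()].
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.displacement_field <- function(object, background = NULL, ...) {
  if (is.null(background)) {
    background <- gray_image(matrix(128, nrow(object$ux), ncol(object$ux)))
  }
  rgb_arr <- render_overlay(object, background, ...)
  h <- dim(rgb_arr)[1]; w <- dim(rgb_arr)[2]
  df <- tibble::tibble(
    x = rep(seq_len(w) - 1L, each = h),
    y = rep(seq_len(h) - 1L, times = w),
    fill = grDevices::rgb(rgb_arr[, , 1], rgb_arr[, , 2], rgb_arr[, , 3])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Deformation overlay (red/cyan: u_x, yellow/blue: u_y)") +
    ggplot2::theme_minimal()
}

#' Plot a grayscale image
#'
#' @param object a [gray_image].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gray_image <- function(object, ...) {
  df <- tidy.gray_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, max_intensity_of(object))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a dissociation report
#'
#' Side-by-side view of the two scorecards: the three similarity metrics and
#' the correspondence fraction-correct, per method. A method that wins the
#' similarity panels while losing the correspondence panel is the
#' dissociation the report exists to expose.
#'
#' @param object a [dissociation_report].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dissociation_report <- function(object, ...) {
  sim <- object$similarity
  long <- tibble::tibble(
    method = rep(sim$method, 4),
    panel = rep(c("RRMS (lower = more similar)",
                  "CC (higher = more similar)",
                  "EID (lower = more similar)",
                  "fraction correct (higher = more accurate)"),
                each = nrow(sim)),
    value = c(sim$rrms, sim$cc, sim$eid, object$correspondence$fraction_correct)
  )
  long$panel <- factor(long$panel, levels = unique(long$panel))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Image similarity vs correspondence accuracy") +
    ggplot2::theme_minimal()
}
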