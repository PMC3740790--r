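#' Scene specification for the copy-shift-paste construction
#'
#' Describes the synthetic fixed image (a bright disk, the "ball", over a
#' textured background) and the copy-shift-paste edit that produces the
#' moving image: a `region_width` x `region_height` rectangle anchored at the
#' top-left corner is copied and pasted `shift` pixels to the right.
#'
#' Defaults reproduce the canonical construction: a 156x196 region shifted by
#' 50 pixels on a 206x256 (width x height) canvas, so the pasted copy lands
#' flush in the top-right corner.
#'
#' @param width,height canvas size in pixels.
#' @param region_width,region_height size of the copied rectangle in pixels.
#' @param shift horizontal shift in pixels; must be positive, and
#'   `region_width + shift <= width`.
#' @param texture background texture: `"smooth"` (band-limited random
#'   texture), `"unique-ramp"` (all pixel intensities distinct; uses an
#'   intensity range of one level per pixel), or `"flat"` (constant
#'   background).
#' @param ball_radius,ball_center_x,ball_center_y disk geometry in pixels
#'   (0-based center coordinates; defaults place the ball in the lower
#'   image half, outside the copied region).
#' @param ball_intensity peak disk intensity (8-bit scale).
#' @param background_range length-2 intensity range of the smoothed texture.
#' @param seed RNG seed driving all texture randomness.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 206, height = 256,
                       region_width = 156, region_height = 196,
                       shift = 50,
                       texture = c("smooth", "unique-ramp", "flat"),
                       ball_radius = 36,
                       ball_center_x = width / 2,
                       ball_center_y = height * 0.75,
                       ball_intensity = 230,
                       background_range = c(30, 130),
                       seed = 1L) {
  texture <- match.arg(texture)
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  stop_if(width < 1 || height < 1, "canvas dimensions must be positive")
  stop_if(region_width < 1 || region_height < 1,
          "copied-region dimensions must be positive")
  stop_if(shift <= 0, "`shift` must be > 0")
  stop_if(region_width + shift > width,
          "`region_width + shift` must not exceed `width`")
  stop_if(region_height > height, "`region_height` must not exceed `height`")
  stop_if(shift > region_width,
          "`shift` must not exceed `region_width` (the four-region geometry assumes a partial overlap)")
  stop_if(length(background_range) != 2 || background_range[1] >= background_range[2],
          "`background_range` must be an increasing length-2 range")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         region_width = as.integer(region_width),
         region_height = as.integer(region_height),
         shift = as.integer(shift), texture = texture,
         ball_radius = ball_radius,
         ball_center_x = ball_center_x, ball_center_y = ball_center_y,
         ball_intensity = ball_intensity,
         background_range = background_range,
         seed = as.integer(seed)),
    class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> canvas %dx%d, region %dx%d, shift %d, texture '%s', seed %d\n",
              x$width, x$height, x$region_width, x$region_height, x$shift,
              x$texture, x$seed))
  invisible(x)
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# circular Gaussian smoothing via FFT; adequate for background texture
smooth_matrix <- function(m, sigma) {
  h <- nrow(m); w <- ncol(m)
  gy <- stats::dnorm(pmin(0:(h - 1), h - (0:(h - 1))), sd = sigma)
  gx <- stats::dnorm(pmin(0:(w - 1), w - (0:(w - 1))), sd = sigma)
  k <- outer(gy, gx)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / (h * w)
}

#' Render the synthetic fixed image
#'
#' Deterministic given the spec (including its seed): the background texture
#' is band-limited random noise rescaled to `background_range`, and a bright
#' disk with mild radial shading is drawn on top. The `"unique-ramp"` texture
#' instead assigns every pixel a distinct intensity (0..n_pixels-1), with the
#' largest values concentrated inside the disk so the ball remains the
#' salient bright object.
#'
#' @param spec a [scene_spec].
#' @return a [gray_image] of size `height` x `width`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  xs <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1L, times = w), h, w)
  r2 <- (xs - spec$ball_center_x)^2 + (ys - spec$ball_center_y)^2
  inside <- r2 <= spec$ball_radius^2

  if (spec$texture == "unique-ramp") {
    n <- h * w
    vals <- seq_len(n) - 1L
    img <- matrix(0L, h, w)
    n_in <- sum(inside)
    # brightest levels go to the disk; ordering inside each group follows
    # the column-major scan so the result is deterministic
    img[inside] <- vals[(n - n_in + 1):n]
    img[!inside] <- vals[seq_len(n - n_in)]
    return(gray_image(img, max_intensity = n - 1))
  }

  bg <- if (spec$texture == "flat") {
    matrix(round(mean(spec$background_range)), h, w)
  } else {
    noise <- with_seed(spec$seed, matrix(stats::runif(h * w), h, w))
    sm <- smooth_matrix(noise, sigma = 2.5)
    rng <- range(sm)
    lo <- spec$background_range[1]; hi <- spec$background_range[2]
    round(lo + (sm - rng[1]) / (rng[2] - rng[1]) * (hi - lo))
  }
  img <- bg
  # radial shading keeps the disk from being one large constant region
  shade <- spec$ball_intensity - 30 * (r2[inside] / spec$ball_radius^2)
  img[inside] <- round(shade)
  img <- pmin(pmax(img, 0), 255)
  gray_image(img, max_intensity = 255)
}

#' Construct the moving image and its ground truth by copy-shift-paste
#'
#' Copies the top-left `region_width` x `region_height` rectangle of the
#' fixed image and pastes it `shift` pixels to the right, overwriting the
#' existing content. The resulting admissible ground-truth displacement field
#' has four regions (columns given 0-based, within the top `region_height`
#' rows):
#'
#' * A (`[0, shift)`): duplicated source content, two equally correct
#'   displacements `{(0,0), (shift,0)}`;
#' * B (`[shift, region_width)`): shifted content, `{(shift,0)}`;
#' * C (`[region_width, region_width+shift)`): content pasted over,
#'   correspondence undefined (empty set);
#' * D (everything else): unmoved, `{(0,0)}`.
#'
#' A displacement `u` at fixed pixel `(x, y)` means the corresponding moving
#' location is `(x + u_x, y + u_y)`; intensity constancy
#' `moving(x + u_x, y + u_y) = fixed(x, y)` holds exactly for every
#' admissible displacement.
#'
#' @param fixed a [gray_image] whose size matches `spec`.
#' @param spec a [scene_spec].
#' @return a list with elements `moving` (a [gray_image]) and `truth`
#'   (an [admissible_truth]).
#' @export
copy_shift_paste <- function(fixed, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  fixed <- as_gray_image(fixed, max_intensity = max_intensity_of(fixed))
  if (nrow(fixed) != spec$height || ncol(fixed) != spec$width) {
    stop("`fixed` dimensions do not match `spec`", call. = FALSE)
  }
  rw <- spec$region_width; rh <- spec$region_height; s <- spec$shift
  moving <- img_mat(fixed)
  rows <- seq_len(rh)
  moving[rows, (s + 1):(s + rw)] <- img_mat(fixed)[rows, seq_len(rw)]

  label <- matrix("D", spec$height, spec$width)
  label[rows, seq_len(s)] <- "A"
  if (rw > s) label[rows, (s + 1):rw] <- "B"
  label[rows, (rw + 1):(rw + s)] <- "C"

  truth <- admissible_truth(label, shift = s)
  list(moving = gray_image(moving, max_intensity = max_intensity_of(fixed)),
       truth = truth)
}

#' Admissible ground-truth displacement sets
#'
#' Stores the per-pixel region label (A/B/C/D) and the label-to-set table of
#' admissible displacements. Region C's set is empty: correspondence is
#' undefined where content was pasted over.
#'
#' @param label character matrix of labels in `{"A","B","C","D"}`.
#' @param shift the horizontal shift in pixels defining the non-zero
#'   admissible displacement.
#' @return an object of class `admissible_truth` with fields `label`,
#'   `shift` and `sets` (named list of n x 2 matrices of `(u_x, u_y)` rows;
#'   `C` is a 0 x 2 matrix).
#' @export
admissible_truth <- function(label, shift) {
  if (!is.matrix(label) || !all(label %in% c("A", "B", "C", "D"))) {
    stop("`label` must be a matrix of labels in {A, B, C, D}", call. = FALSE)
  }
  sets <- list(
    A = rbind(c(0, 0), c(shift, 0)),
    B = rbind(c(shift, 0)),
    C = matrix(numeric(0), 0, 2),
    D = rbind(c(0, 0))
  )
  structure(list(label = label, shift = shift, sets = sets),
            class = "admissible_truth")
}

#' @export
print.admissible_truth <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("A", "B", "C", "D")))
  cat(sprintf("<admissible_truth> %dx%d, shift %d; |A|=%d |B|=%d |C|=%d |D|=%d\n",
              nrow(x$label), ncol(x$label), x$shift,
              tab["A"], tab["B"], tab["C"], tab["D"]))
  invisible(x)
}

#' Region areas of an admissible truth
#'
#' @param truth an [admissible_truth].
#' @return a tibble with columns `region` and `n_pixels`.
#' @export
region_areas <- function(truth) {
  stopifnot(inherits(truth, "admissible_truth"))
  tab <- table(factor(truth$label, levels = c("A", "B", "C", "D")))
  tibble::tibble(region = names(tab), n_pixels = as.integer(tab))
}

#' Add clipped Gaussian intensity noise
#'
#' Off by default throughout the package: the copy-shift-paste construction
#' is exact, and the permutation-null identities require exact intensity
#' conservation. Provided for robustness experiments.
#'
#' @param image a [gray_image].
#' @param sigma noise standard deviation in intensity units; `sigma = 0`
#'   returns the input unchanged.
#' @param seed RNG seed.
#' @return a [gray_image] with the same intensity range, values rounded and
#'   clipped.
#' @export
add_noise <- function(image, sigma, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  image <- as_gray_image(image, max_intensity = max_intensity_of(image))
  if (sigma == 0) return(image)
  mi <- max_intensity_of(image)
  noisy <- with_seed(seed,
    img_mat(image) + matrix(stats::rnorm(length(image), sd = sigma),
                            nrow(image), ncol(image)))
  gray_image(pmin(pmax(round(noisy), 0), mi), max_intensity = mi)
}
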