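# Independent oracles and small fixture builders, kept deliberately
# separate from the package's code paths.

# strip class and non-dim attributes for raw matrix comparison
mat <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# all permutations of 1..n, one per row (n! x n matrix)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# exhaustive minimum sum of squared differences over every pairing of
# fixed pixels with moving pixels
brute_min_ssd <- function(fixed, moving) {
  f <- as.vector(fixed); m <- as.vector(moving)
  perms <- all_perms(length(f))
  min(apply(perms, 1, function(p) sum((f - m[p])^2)))
}

ssd_of_permutation <- function(fixed, moving, p) {
  sum((as.vector(fixed) - as.vector(moving)[as.integer(p)])^2)
}

# Shannon entropy by direct probability enumeration over observed values
entropy_enum <- function(values, base = 2) {
  p <- as.vector(table(values)) / length(values)
  -sum(p * log(p, base = base))
}

# Pearson correlation from first principles (sums only)
brute_cc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b); n <- length(a)
  sa <- sum(a); sb <- sum(b)
  cov_ab <- sum(a * b) / n - (sa / n) * (sb / n)
  va <- sum(a^2) / n - (sa / n)^2
  vb <- sum(b^2) / n - (sb / n)^2
  cov_ab / sqrt(va * vb)
}

# random integer-intensity image
rand_img <- function(h, w, seed, max_intensity = 255) {
  set.seed(seed)
  gray_image(matrix(sample(0:max_intensity, h * w, replace = TRUE), h, w),
             max_intensity = max_intensity)
}

# random image with all-distinct intensities
rand_distinct_img <- function(h, w, seed, max_intensity = 255) {
  set.seed(seed)
  gray_image(matrix(sample(0:max_intensity, h * w, replace = FALSE), h, w),
             max_intensity = max_intensity)
}

# outline of the destination-rectangle box drawn by render_overlay()
box_mask <- function(sp) {
  m <- matrix(FALSE, sp$height, sp$width)
  rows <- 1:sp$region_height
  cols <- (sp$shift + 1):(sp$shift + sp$region_width)
  m[c(rows[1], rows[length(rows)]), cols] <- TRUE
  m[rows, c(cols[1], cols[length(cols)])] <- TRUE
  m
}

# a small scene spec for fast pipeline tests
small_spec <- function(seed = 1L) {
  scene_spec(width = 64, height = 72, region_width = 40, region_height = 48,
             shift = 12, ball_radius = 10, ball_center_x = 32,
             ball_center_y = 56, seed = seed)
}
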