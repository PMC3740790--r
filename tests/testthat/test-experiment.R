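test_that("serialization round-trips: image, truth, field, permutation", {
  dir <- withr::local_tempdir()
  img <- rand_img(9, 11, seed = 50)
  p_png <- file.path(dir, "img.png")
  write_gray_image(img, p_png)
  expect_equal(mat(read_gray_image(p_png)), mat(img) + 0)

  sp <- small_spec()
  truth <- copy_shift_paste(render_scene(sp), sp)$truth
  write_truth(truth, file.path(dir, "lab.png"), file.path(dir, "truth.json"))
  back <- read_truth(file.path(dir, "lab.png"), file.path(dir, "truth.json"))
  expect_identical(back$label, truth$label)
  expect_equal(back$shift, truth$shift)
  expect_equal(back$sets, truth$sets)

  set.seed(51)
  field <- displacement_field(matrix(rnorm(20, sd = 30), 4, 5),
                              matrix(rnorm(20, sd = 30), 4, 5))
  write_field(field, file.path(dir, "f.tif"))
  fb <- read_field(file.path(dir, "f.tif"))
  expect_equal(fb$ux, field$ux, tolerance = 1e-6)  # float32 storage
  expect_equal(fb$uy, field$uy, tolerance = 1e-6)

  set.seed(52)
  perm <- pixel_permutation(sample(20), dim = c(4, 5))
  write_permutation(perm, file.path(dir, "p.tsv"))
  pb <- read_permutation(file.path(dir, "p.tsv"), dim = c(4, 5))
  expect_equal(as.integer(pb), as.integer(perm))
})

test_that("experiment config validates strictly and survives a file round-trip", {
  expect_error(experiment_config(methods = "warp"), "built-in")
  expect_error(experiment_config(tolerance = -1), "non-negative")
  expect_error(experiment_config(eid_bin_width = 0), "positive")

  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(
    list(scene = list(width = 64, height = 72, region_width = 40,
                      region_height = 48, shift = 12),
         methods = c("curt", "identity"), tolerance = 0.5, seed = 3),
    cfg_path, auto_unbox = TRUE)
  cfg <- read_experiment_config(cfg_path)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$scene$width, 64L)
  expect_equal(cfg$seed, 3L)

  # unknown keys are an error, never silently defaulted
  jsonlite::write_json(list(tollerance = 0.5), cfg_path, auto_unbox = TRUE)
  expect_error(read_experiment_config(cfg_path), "unknown config keys")
  jsonlite::write_json(list(scene = list(widht = 10)), cfg_path, auto_unbox = TRUE)
  expect_error(read_experiment_config(cfg_path), "unknown scene keys")
})

test_that("run_experiment writes the full artifact set reproducibly", {
  cfg <- experiment_config(scene = small_spec(), seed = 11)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  rep1 <- run_experiment(cfg, out_dir = dir1)
  rep2 <- run_experiment(cfg, out_dir = dir2)

  expected <- c("config.json", "fixed.png", "moving.png", "truth_labels.png",
                "truth.json", "similarity.txt", "similarity.json",
                "report.json", "permutation_curt.tsv",
                paste0("field_", c("curt", "identity", "oracle"), ".tif"),
                paste0("reformatted_", c("curt", "identity", "oracle"), ".png"),
                paste0("overlay_", c("curt", "identity", "oracle"), ".png"),
                paste0("difference_", c("curt", "identity", "oracle"), ".png"))
  expect_true(all(expected %in% list.files(dir1)))

  # bit-identical rerun
  for (f in c("fixed.png", "moving.png", "permutation_curt.tsv")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
  expect_equal(tidy(rep1), tidy(rep2))
  expect_true(glance(rep1)$dissociation)
})

test_that("experiment without noise keeps exact identities; noise breaks them gently", {
  cfg <- experiment_config(scene = small_spec(), methods = c("curt", "identity"))
  rep <- run_experiment(cfg)
  # without noise the moving image is a partial permutation of fixed, so
  # curt similarity is nearly perfect but not necessarily exactly zero
  sim <- rep$similarity
  expect_lt(sim$rrms[sim$method == "curt"], sim$rrms[sim$method == "identity"])

  cfgn <- experiment_config(scene = small_spec(), noise_sigma = 3,
                            methods = c("curt", "identity"))
  repn <- run_experiment(cfgn)
  simn <- repn$similarity
  expect_gt(simn$rrms[simn$method == "curt"], 0)
  expect_lt(simn$rrms[simn$method == "curt"], simn$rrms[simn$method == "identity"])
})

test_that("overlay rendering encodes displacement in color over the background", {
  sp <- small_spec()
  bg <- render_scene(sp)
  zero <- identity_field(c(sp$height, sp$width))
  arr <- render_overlay(zero, bg)
  g <- mat(bg) / 255
  expect_equal(arr[, , 1], g)  # zero displacement: untouched grayscale
  expect_equal(arr[, , 2], g)
  expect_equal(arr[, , 3], g)

  u <- displacement_field(matrix(10, sp$height, sp$width),
                          matrix(0, sp$height, sp$width))
  arr2 <- render_overlay(u, bg)
  # uniform positive u_x: red channel lifted everywhere, blue untouched
  expect_true(all(arr2[, , 1] >= g))
  expect_gt(mean(arr2[, , 1] - g), 0.3)
  expect_equal(arr2[, , 3], g)

  # truth-oracle field: tint differs between shifted rows and unmoved rows
  out <- copy_shift_paste(bg, sp)
  arr3 <- render_overlay(oracle_field(out$truth), bg,
                         box = c(0, sp$region_height - 1, sp$shift,
                                 sp$shift + sp$region_width - 1))
  b_px <- out$truth$label == "B"
  d_px <- out$truth$label == "D"
  expect_gt(mean(arr3[, , 1][b_px] - g[b_px]), 0.3)
  expect_equal(arr3[, , 1][d_px & !box_mask(sp)], g[d_px & !box_mask(sp)])
})

test_that("autoplot methods return ggplot objects", {
  sp <- small_spec()
  fixed <- render_scene(sp)
  out <- copy_shift_paste(fixed, sp)
  rep <- dissociation_report(fixed, out$moving, out$truth,
                             methods = c("curt", "identity"))
  expect_s3_class(autoplot(fixed), "ggplot")
  expect_s3_class(autoplot(oracle_field(out$truth), background = fixed), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("the command-line pipeline runs end to end", {
  cli <- system.file("cli", "regeval.R", package = "regeval")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- suppressWarnings(system2(
    rscript, c(cli, "run", "--seed", "3", "--out", dir,
               "--width", "64", "--height", "72", "--region-width", "40",
               "--region-height", "48", "--shift", "12"),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  expect_true(is.null(status) || status == 0)
  expect_true(file.exists(file.path(dir, "report.json")))
  report <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  expect_true(any(report$verdict$dissociated))
})
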