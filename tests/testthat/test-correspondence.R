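test_that("pointwise error scores the best admissible match and excludes undefined truth", {
  expect_equal(pointwise_error(c(0, 0), rbind(c(50, 0))), 50)
  expect_equal(pointwise_error(c(50, 0), rbind(c(0, 0), c(50, 0))), 0)
  expect_equal(pointwise_error(c(25, 0), rbind(c(0, 0), c(50, 0))), 25)
  expect_equal(pointwise_error(c(3, 4), rbind(c(0, 0))), 5)
  expect_true(is.na(pointwise_error(c(1, 1), matrix(numeric(0), 0, 2))))
  expect_true(is.na(pointwise_error(c(1, 1), NULL)))
  expect_error(pointwise_error(c(Inf, 0), rbind(c(0, 0))), "finite")
})

test_that("identity field scores exactly as the label geometry dictates", {
  sp <- small_spec()
  out <- copy_shift_paste(render_scene(sp), sp)
  areas <- region_areas(out$truth)
  a <- areas$n_pixels[areas$region == "A"]
  b <- areas$n_pixels[areas$region == "B"]
  d <- areas$n_pixels[areas$region == "D"]
  carea <- areas$n_pixels[areas$region == "C"]

  s <- summarize_errors(identity_field(c(sp$height, sp$width)), out$truth,
                        tolerance = 0.5)
  expect_equal(s$overall$n_excluded, carea)
  expect_equal(s$overall$n_evaluated, a + b + d)
  expect_equal(s$overall$fraction_correct, (a + d) / (a + b + d))
  by <- tidy(s)
  expect_equal(by$mean_error[by$region == "A"], 0)  # (0,0) is admissible in A
  expect_equal(by$mean_error[by$region == "B"], sp$shift)
  expect_equal(by$mean_error[by$region == "D"], 0)
  expect_equal(s$overall$max_error, sp$shift)
})

test_that("a uniform shift field is correct on A and B but wrong on D", {
  sp <- small_spec()
  out <- copy_shift_paste(render_scene(sp), sp)
  u <- displacement_field(matrix(sp$shift, sp$height, sp$width),
                          matrix(0, sp$height, sp$width))
  by <- tidy(summarize_errors(u, out$truth))
  expect_equal(by$fraction_correct[by$region %in% c("A", "B")], c(1, 1))
  expect_equal(by$mean_error[by$region == "D"], sp$shift)
})

test_that("an admissible field everywhere scores a perfect summary", {
  sp <- small_spec()
  out <- copy_shift_paste(render_scene(sp), sp)
  s <- glance(summarize_errors(oracle_field(out$truth), out$truth))
  expect_equal(s$mean_error, 0)
  expect_equal(s$max_error, 0)
  expect_equal(s$fraction_correct, 1)
})

test_that("error is zero exactly when the estimate is admissible", {
  sp <- small_spec()
  truth <- copy_shift_paste(render_scene(sp), sp)$truth
  set.seed(40)
  ux <- matrix(sample(c(0, sp$shift, 1, -3, 17), sp$height * sp$width, TRUE),
               sp$height, sp$width)
  uy <- matrix(sample(c(0, 2, -1), sp$height * sp$width, TRUE),
               sp$height, sp$width)
  field <- displacement_field(ux, uy)
  err <- regeval:::error_map(field, truth)
  admissible <- matrix(FALSE, sp$height, sp$width)
  for (lab in c("A", "B", "D")) {
    set <- truth$sets[[lab]]
    hit <- matrix(FALSE, sp$height, sp$width)
    for (k in seq_len(nrow(set))) {
      hit <- hit | (ux == set[k, 1] & uy == set[k, 2])
    }
    admissible[truth$label == lab] <- hit[truth$label == lab]
  }
  defined <- !is.na(err)
  expect_identical(err[defined] < 1e-9, admissible[defined])
})

test_that("fraction-correct is monotone non-decreasing in tolerance", {
  sp <- small_spec()
  out <- copy_shift_paste(render_scene(sp), sp)
  moving <- out$moving
  fixed <- render_scene(sp)
  field <- permutation_to_field(curt_register(fixed, moving))
  tols <- seq(0, 30, length.out = 10)
  fc <- vapply(tols, function(t)
    summarize_errors(field, out$truth, tolerance = t)$overall$fraction_correct,
    numeric(1))
  expect_true(all(diff(fc) >= 0))
})

test_that("dissociation report flags curt as similarity-best but correspondence-worse", {
  sp <- small_spec(seed = 5L)
  fixed <- render_scene(sp)
  out <- copy_shift_paste(fixed, sp)
  rep <- dissociation_report(fixed, out$moving, out$truth,
                             methods = c("curt", "identity"))
  sim <- rep$similarity
  expect_lt(sim$rrms[sim$method == "curt"], sim$rrms[sim$method == "identity"])
  expect_gt(sim$cc[sim$method == "curt"], sim$cc[sim$method == "identity"])
  expect_lt(sim$eid[sim$method == "curt"], sim$eid[sim$method == "identity"])
  corr <- rep$correspondence
  expect_lt(corr$fraction_correct[corr$method == "curt"],
            corr$fraction_correct[corr$method == "identity"])
  expect_true(all(rep$verdict$dissociated))
  expect_true(glance(rep)$dissociation)
})

test_that("the oracle method wins the correspondence ranking", {
  sp <- small_spec(seed = 6L)
  fixed <- render_scene(sp)
  out <- copy_shift_paste(fixed, sp)
  rep <- dissociation_report(fixed, out$moving, out$truth)
  corr <- rep$correspondence
  expect_equal(corr$mean_error[corr$method == "oracle"], 0)
  expect_equal(rep$verdict$correspondence_rank[rep$verdict$method == "oracle"], 1L)
})

test_that("a single-method report cannot disagree with itself", {
  sp <- small_spec(seed = 7L)
  fixed <- render_scene(sp)
  out <- copy_shift_paste(fixed, sp)
  rep <- dissociation_report(fixed, out$moving, out$truth, methods = "identity")
  expect_false(any(rep$verdict$dissociated))
  expect_equal(nrow(tidy(rep)), 1)
})
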