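#' Pointwise correspondence error against an admissible set
#'
#' The error of an estimated displacement at one pixel is the minimum
#' Euclidean distance from the estimate to any admissible ground-truth
#' displacement: a multi-valued truth scores the best admissible match. An
#' empty admissible set (region C, correspondence undefined) yields `NA`,
#' the excluded marker.
#'
#' @param estimate numeric length-2 displacement `(u_x, u_y)`; must be
#'   finite.
#' @param truth_set an n x 2 matrix of admissible displacements (rows), or a
#'   0 x 2 matrix / `NULL` for an undefined correspondence.
#' @return error in pixels, or `NA_real_` if excluded.
#' @export
pointwise_error <- function(estimate, truth_set) {
  if (length(estimate) != 2 || !all(is.finite(estimate))) {
    stop("`estimate` must be a finite length-2 displacement", call. = FALSE)
  }
  if (is.null(truth_set) || nrow(truth_set) == 0) return(NA_real_)
  min(sqrt((truth_set[, 1] - estimate[1])^2 + (truth_set[, 2] - estimate[2])^2))
}

# per-pixel error matrix; NA where the truth is undefined (region C)
error_map <- function(field, truth) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(truth, "admissible_truth"))
  assert_same_shape(field$ux, truth$label, "field and truth")
  err <- matrix(NA_real_, nrow(field$ux), ncol(field$ux))
  for (lab in c("A", "B", "D")) {
    idx <- truth$label == lab
    if (!any(idx)) next
    set <- truth$sets[[lab]]
    d <- Inf
    for (k in seq_len(nrow(set))) {
      d <- pmin(d, sqrt((field$ux[idx] - set[k, 1])^2 +
                        (field$uy[idx] - set[k, 2])^2))
    }
    err[idx] <- d
  }
  err
}

#' Summarize correspondence errors against the admissible ground truth
#'
#' Aggregates pointwise displacement errors over all pixels with a defined
#' correspondence (region C is excluded and counted separately). The
#' fraction-correct is the share of evaluated pixels with error at or below
#' `tolerance`.
#'
#' @param field a [displacement_field] (the estimated transformation).
#' @param truth an [admissible_truth] of the same shape.
#' @param tolerance correctness tolerance in pixels (default 0.5, the
#'   sub-pixel rounding bound).
#' @return an object of class `corr_error_summary`: a list with
#'   * `overall` — one-row tibble: `n_evaluated`, `n_excluded`, `mean_error`,
#'     `median_error`, `max_error`, `fraction_correct`, `tolerance`;
#'   * `by_region` — per-region (A/B/D) tibble with the same error columns.
#' @export
summarize_errors <- function(field, truth, tolerance = 0.5) {
  if (!is.numeric(tolerance) || tolerance < 0) {
    stop("`tolerance` must be non-negative", call. = FALSE)
  }
  err <- error_map(field, truth)
  ok <- !is.na(err)
  ev <- err[ok]
  overall <- tibble::tibble(
    n_evaluated = sum(ok),
    n_excluded = sum(!ok),
    mean_error = mean(ev),
    median_error = stats::median(ev),
    max_error = max(ev),
    fraction_correct = mean(ev <= tolerance),
    tolerance = tolerance
  )
  by_region <- do.call(rbind, lapply(c("A", "B", "D"), function(lab) {
    e <- err[truth$label == lab]
    tibble::tibble(region = lab, n = length(e),
                   mean_error = mean(e), median_error = stats::median(e),
                   max_error = max(e), fraction_correct = mean(e <= tolerance))
  }))
  structure(list(overall = overall, by_region = by_region),
            class = "corr_error_summary")
}

#' @export
print.corr_error_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<corr_error_summary> %d evaluated, %d excluded (undefined truth)\n",
    o$n_evaluated, o$n_excluded))
  cat(sprintf("  mean %.3f  median %.3f  max %.3f px; %.1f%% correct at tol %.2g px\n",
              o$mean_error, o$median_error, o$max_error,
              100 * o$fraction_correct, o$tolerance))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.corr_error_summary <- function(x, ...) x$by_region

#' @exportS3Method generics::glance
glance.corr_error_summary <- function(x, ...) x$overall

#' Similarity-versus-correspondence dissociation report
#'
#' Runs each candidate "registration" method on a fixed/moving pair, then
#' scores every method twice: by image similarity (RRMS/CC/EID on its
#' reformatted image) and by correspondence accuracy (displacement error
#' against the admissible ground truth). A method whose similarity rank and
#' correspondence rank disagree is flagged as dissociated — the failure mode
#' in which looking alike masquerades as registering well.
#'
#' Built-in methods:
#' * `"curt"` — the rank-order pixel permutation null model
#'   ([curt_register()]); similarity is computed on its permutation
#'   reformatting, correspondence on the equivalent displacement field.
#' * `"identity"` — the do-nothing alignment (all-zero field).
#' * `"oracle"` — an admissible ground-truth displacement at every defined
#'   pixel ([oracle_field()]).
#'
#' @param fixed,moving [gray_image]s of identical shape.
#' @param truth an [admissible_truth] for the pair.
#' @param methods character vector of method names to run (any of the
#'   built-ins above), or a named list mixing built-in names and custom
#'   [displacement_field] objects.
#' @param tolerance correctness tolerance in pixels.
#' @param eid_base,eid_bin_width EID options, see [eid()].
#' @return an object of class `dissociation_report`: a list with tibbles
#'   `similarity` (method, rrms, cc, eid), `correspondence` (method plus the
#'   overall error summary columns) and `verdict` (method,
#'   `similarity_rank`, `correspondence_rank`, `dissociated`).
#' @export
dissociation_report <- function(fixed, moving, truth,
                                methods = c("curt", "identity", "oracle"),
                                tolerance = 0.5,
                                eid_base = 2, eid_bin_width = 1) {
  assert_same_shape(fixed, moving)
  assert_same_shape(img_mat(fixed), truth$label, "images and truth")
  if (is.character(methods)) {
    methods <- stats::setNames(as.list(methods), methods)
  }
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("`methods` must be named", call. = FALSE)
  }

  runs <- lapply(names(methods), function(name) {
    m <- methods[[name]]
    if (inherits(m, "displacement_field")) {
      field <- m
      reformatted <- reformat_by_field(moving, field)
    } else if (identical(m, "curt")) {
      p <- curt_register(fixed, moving)
      field <- permutation_to_field(p)
      reformatted <- reformat_by_permutation(moving, p)
    } else if (identical(m, "identity")) {
      field <- identity_field(dim(fixed))
      reformatted <- reformat_by_field(moving, field)
    } else if (identical(m, "oracle")) {
      field <- oracle_field(truth)
      reformatted <- reformat_by_field(moving, field)
    } else {
      stop("unknown method: ", m, call. = FALSE)
    }
    list(name = name, field = field, reformatted = reformatted,
         similarity = similarity_report(fixed, reformatted, method = name,
                                        eid_base = eid_base,
                                        eid_bin_width = eid_bin_width),
         errors = summarize_errors(field, truth, tolerance = tolerance))
  })

  sim <- do.call(rbind, lapply(runs, `[[`, "similarity"))
  corr <- do.call(rbind, lapply(runs, function(r) {
    tibble::as_tibble(cbind(method = r$name, r$errors$overall))
  }))

  sim_rank <- similarity_ranks(sim)
  # 1 = most accurate; fraction-correct first, mean error breaks ties;
  # methods with identical scores share the smallest rank
  key <- paste(signif(corr$fraction_correct, 12), signif(corr$mean_error, 12))
  ord <- order(-corr$fraction_correct, corr$mean_error)
  corr_rank <- match(key, key[ord])
  verdict <- tibble::tibble(
    method = sim$method,
    similarity_rank = as.integer(sim_rank),
    correspondence_rank = as.integer(corr_rank),
    dissociated = sim_rank != corr_rank
  )
  structure(list(similarity = sim, correspondence = corr, verdict = verdict,
                 tolerance = tolerance,
                 fields = stats::setNames(lapply(runs, `[[`, "field"), sim$method),
                 reformatted = stats::setNames(lapply(runs, `[[`, "reformatted"),
                                               sim$method)),
            class = "dissociation_report")
}

#' @export
print.dissociation_report <- function(x, ...) {
  cat("<dissociation_report>\n\nImage similarity (lower RRMS/EID, higher CC = more similar):\n")
  print(as.data.frame(x$similarity), row.names = FALSE, digits = 4)
  cat("\nCorrespondence accuracy (tolerance", x$tolerance, "px; undefined-truth pixels excluded):\n")
  print(as.data.frame(x$correspondence[, c("method", "n_evaluated", "n_excluded",
                                           "mean_error", "median_error",
                                           "fraction_correct")]),
        row.names = FALSE, digits = 4)
  cat("\nVerdict:\n")
  print(as.data.frame(x$verdict), row.names = FALSE)
  if (any(x$verdict$dissociated)) {
    cat("\nDissociation detected: similarity and correspondence rank methods differently.\n")
  } else {
    cat("\nNo dissociation: similarity and correspondence agree on the ranking.\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dissociation_report <- function(x, ...) {
  out <- merge(merge(x$similarity, x$correspondence, by = "method"),
               x$verdict, by = "method")
  tibble::as_tibble(out[match(x$similarity$method, out$method), ])
}

#' @exportS3Method generics::glance
glance.dissociation_report <- function(x, ...) {
  tibble::tibble(
    n_methods = nrow(x$similarity),
    tolerance = x$tolerance,
    dissociation = any(x$verdict$dissociated)
  )
}
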