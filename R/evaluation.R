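#' Discrimination accuracy of identity calls against ground truth
#'
#' Overall accuracy is `100 * (1 - (FP + FN) / total)`, i.e. 100% minus the
#' percentage of misassigned flies; per-class accuracies are the fractions of
#' true GFP and true non-GFP flies called correctly.
#'
#' @param calls identity-call `data.frame` (`fly_id`, `label`).
#' @param truth named character vector of true labels keyed by fly id (see
#'   [read_truth()]) or `data.frame` with `fly_id` and `label`.
#' @return list with `overall`, `gfp`, `non_gfp` (percent).
#' @export
discrimination_accuracy <- function(calls, truth) {
  if (is.data.frame(truth)) truth <- stats::setNames(truth$label, truth$fly_id)
  key <- as.character(calls$fly_id)
  if (!all(key %in% names(truth))) {
    stop(sprintf("no truth label for fly id(s): %s",
                 paste(setdiff(key, names(truth)), collapse = ", ")), call. = FALSE)
  }
  tr <- check_labels(truth[key])
  correct <- calls$label == tr
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  list(overall = pct(correct),
       gfp = pct(correct[tr == "GFP"]),
       non_gfp = pct(correct[tr == "non-GFP"]))
}

#' Select which fluorescence images enter the metric average
#'
#' Fluorescence is acquired in a block before ("pre") and a block after
#' ("post") the behavioral experiment. `"alternate"` draws images alternately
#' from the front of the pre block and the front of the post block, starting
#' with the pre block (an odd `n` gives the extra image to the pre block);
#' drawing from both ends of the experiment exploits fly movement to average
#' out spatial inhomogeneity in fluorescence illumination. `"end_only"` takes
#' the first `n` frames of the post block, for rigs that illuminate only
#' after the experiment. When the pre block is empty the two modes coincide.
#'
#' @param stack an [image_stack()] whose `n_pre` field gives the pre-block
#'   length (overridable via `n_pre`).
#' @param n number of images to select.
#' @param mode `"alternate"` or `"end_only"`.
#' @param n_pre pre-block length override.
#' @return vector of trajectory frame indices.
#' @export
select_images <- function(stack, n, mode = c("alternate", "end_only"),
                          n_pre = stack$n_pre) {
  mode <- match.arg(mode)
  fi <- stack$frame_indices
  total <- length(fi)
  stopifnot(n >= 1)
  n_pre <- min(as.integer(n_pre), total)
  pre <- if (n_pre >= 1) fi[seq_len(n_pre)] else integer(0)
  post <- if (n_pre < total) fi[(n_pre + 1):total] else integer(0)
  if (!length(post)) { post <- pre; pre <- integer(0) }  # single-block stack
  if (mode == "end_only") {
    if (n > length(post)) stop(sprintf("requested %d images but the post block has %d",
                                       n, length(post)), call. = FALSE)
    return(post[seq_len(n)])
  }
  if (n > total) stop(sprintf("requested %d images but only %d available", n, total),
                      call. = FALSE)
  if (!length(pre)) return(post[seq_len(n)])
  n_from_pre <- min(length(pre), ceiling(n / 2))
  n_from_post <- n - n_from_pre
  if (n_from_post > length(post)) {  # rebalance if the post block is short
    n_from_pre <- n - length(post)
    n_from_post <- length(post)
  }
  out <- integer(n)
  take <- c(pre = 0L, post = 0L)
  from_pre <- TRUE
  for (i in seq_len(n)) {
    if ((from_pre && take["pre"] < n_from_pre) || take["post"] >= n_from_post) {
      take["pre"] <- take["pre"] + 1L
      out[i] <- pre[take["pre"]]
    } else {
      take["post"] <- take["post"] + 1L
      out[i] <- post[take["post"]]
    }
    from_pre <- !from_pre
  }
  out
}

classify_with <- function(metrics, calibration, w, theta, prior = NULL) {
  sc <- score_flies(metrics, calibration, w = w)
  if (is.null(prior)) classify_by_threshold(sc, theta)
  else classify_by_prior_count(sc, prior)
}

#' Accuracy as a function of the number of images averaged
#'
#' For each requested image count `n`, selects images with [select_images()],
#' aggregates the per-image features over exactly those images, scores flies
#' with the calibrated operating point and measures discrimination accuracy.
#' Averaging more images suppresses per-image noise in the metrics, so
#' accuracy typically rises with `n`. The calibration must come from
#' independent (homogeneous-group) data.
#'
#' @param stack fluorescence [image_stack()].
#' @param records trajectory `data.frame`.
#' @param truth true labels (named vector or `data.frame`).
#' @param calibration a `fluor_calibration`.
#' @param counts increasing vector of image counts.
#' @param mode image selection mode, see [select_images()].
#' @param prior expected number of GFP flies; `NULL` for threshold
#'   classification.
#' @param features optional precomputed [fly_image_features()] to reuse.
#' @return `data.frame` with `images, overall, gfp, non_gfp` (percent).
#' @export
accuracy_vs_image_count <- function(stack, records, truth, calibration,
                                    counts = c(1, 2, 4, 10, 20),
                                    mode = c("alternate", "end_only"),
                                    prior = NULL, features = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(diff(counts) > 0), all(counts >= 1))
  rp <- calibration$roi_params
  if (is.null(features)) {
    features <- fly_image_features(stack, records,
                                   length_scale = rp$length_scale,
                                   width_scale = rp$width_scale,
                                   front_fraction = rp$front_fraction,
                                   top_fraction = rp$top_fraction)
  }
  rows <- lapply(counts, function(n) {
    frames <- select_images(stack, n, mode)
    m <- aggregate_metrics(features, frames)
    calls <- classify_with(m, calibration, calibration$w, calibration$theta, prior)
    acc <- discrimination_accuracy(calls, truth)
    data.frame(images = n, overall = acc$overall, gfp = acc$gfp,
               non_gfp = acc$non_gfp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy heatmap over image counts and metric weights
#'
#' Recomputes classification accuracy on a grid of (number of images
#' averaged) x (metric weight). With `prior` given, every cell uses
#' prior-count classification; otherwise each weight uses its own calibrated
#' best threshold (`per_weight_theta` from the calibration). Normalization
#' ranges are those persisted with the calibration, shared by all cells.
#'
#' @inheritParams accuracy_vs_image_count
#' @param weight_grid weights to evaluate; default the calibration's grid.
#' @return matrix of accuracies (percent), rows = counts, columns = weights,
#'   with dimnames.
#' @export
accuracy_heatmap <- function(stack, records, truth, calibration,
                             weight_grid = calibration$weight_grid,
                             counts = c(1, 2, 4, 10, 20),
                             mode = c("alternate", "end_only"),
                             prior = NULL, features = NULL) {
  mode <- match.arg(mode)
  rp <- calibration$roi_params
  if (is.null(features)) {
    features <- fly_image_features(stack, records,
                                   length_scale = rp$length_scale,
                                   width_scale = rp$width_scale,
                                   front_fraction = rp$front_fraction,
                                   top_fraction = rp$top_fraction)
  }
  if (is.null(prior)) {
    wi <- match(round(weight_grid, 10), round(calibration$weight_grid, 10))
    if (anyNA(wi)) stop("threshold-mode heatmap weights must lie on the calibration grid",
                        call. = FALSE)
  }
  out <- matrix(NA_real_, length(counts), length(weight_grid),
                dimnames = list(images = counts, weight = weight_grid))
  for (i in seq_along(counts)) {
    frames <- select_images(stack, counts[i], mode)
    m <- aggregate_metrics(features, frames)
    for (j in seq_along(weight_grid)) {
      theta <- if (is.null(prior)) calibration$per_weight_theta[wi[j]] else NA
      calls <- classify_with(m, calibration, weight_grid[j], theta, prior)
      out[i, j] <- discrimination_accuracy(calls, truth)$overall
    }
  }
  out
}
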