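#' Per-fly, per-image ROI intensity features
#'
#' For every fly and every requested fluorescence frame, builds the Total ROI
#' from the fly's pose, splits it into Front and Rear halves, extracts the
#' three pixel samples and records the per-image ingredients of the
#' discrimination metrics: the top-5% means and single maxima of the Front and
#' Rear samples and the skewness of the Total sample. Time-aggregation into
#' per-fly metrics is done separately by [aggregate_metrics()], so metrics for
#' any subset of images can be formed without re-extracting pixels.
#'
#' @param stack fluorescence [image_stack()].
#' @param records trajectory `data.frame` (see [read_trajectories()]).
#' @param frames trajectory frame indices to use; default all frames of the
#'   stack.
#' @param length_scale,width_scale ROI scales, see [total_roi()].
#' @param front_fraction front/rear split fraction, see [split_roi()].
#' @param top_fraction brightest fraction for the ratio metric.
#' @return `data.frame` with one row per (fly, frame): `fly_id, frame,
#'   front_top, rear_top, front_max, rear_max, skew`.
#' @export
fly_image_features <- function(stack, records, frames = NULL,
                               length_scale = 1.2, width_scale = 1.2,
                               front_fraction = 0.5, top_fraction = 0.05) {
  if (is.null(frames)) frames <- stack$frame_indices
  frames <- sort(unique(as.integer(frames)))
  missing <- setdiff(frames, stack$frame_indices)
  if (length(missing)) {
    stop(sprintf("no image for trajectory frame(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  keep <- which(records$frame %in% frames)
  if (!length(keep)) stop("no trajectory records for the requested frames", call. = FALSE)
  n <- length(keep)
  front_top <- rear_top <- front_max <- rear_max <- skew <- numeric(n)
  fr_col <- records$frame[keep]
  img <- NULL; img_frame <- NA_integer_
  ord <- order(fr_col, records$fly_id[keep])
  keep <- keep[ord]; fr_col <- fr_col[ord]
  for (i in seq_len(n)) {
    k <- keep[i]
    if (!identical(img_frame, fr_col[i])) {
      img <- stack_frame(stack, fr_col[i])
      img_frame <- fr_col[i]
    }
    rec <- list(frame = records$frame[k], fly_id = records$fly_id[k],
                x = records$x[k], y = records$y[k], theta = records$theta[k],
                a = records$a[k], b = records$b[k])
    tot <- total_roi(rec, length_scale, width_scale)
    halves <- split_roi(tot, front_fraction)
    ps_tot <- extract_pixels(img, tot)
    ps_f <- extract_pixels(img, halves$front)
    ps_r <- extract_pixels(img, halves$rear)
    front_top[i] <- top_fraction_mean(ps_f, top_fraction)
    rear_top[i] <- top_fraction_mean(ps_r, top_fraction)
    front_max[i] <- max(ps_f$values)
    rear_max[i] <- max(ps_r$values)
    skew[i] <- skewness(ps_tot)
  }
  data.frame(fly_id = records$fly_id[keep], frame = fr_col,
             front_top = front_top, rear_top = rear_top,
             front_max = front_max, rear_max = rear_max, skew = skew)
}

#' Aggregate per-image features into per-fly metric values
#'
#' Applies each metric's time-averaging rule over the selected images:
#' `max5_ratio` (and `single_max_ratio`) average numerator and denominator
#' across images before dividing; `skewness` is the mean of per-image values.
#'
#' @param features output of [fly_image_features()].
#' @param frames optional subset of trajectory frame indices to aggregate
#'   over; default all frames present.
#' @return `data.frame` with one row per fly: `fly_id, max5_ratio,
#'   single_max_ratio, skewness, n_images`.
#' @export
aggregate_metrics <- function(features, frames = NULL) {
  if (!is.null(frames)) {
    features <- features[features$frame %in% frames, , drop = FALSE]
    if (!nrow(features)) stop("no features for the requested frames", call. = FALSE)
  }
  ids <- sort(unique(features$fly_id))
  res <- lapply(ids, function(id) {
    f <- features[features$fly_id == id, , drop = FALSE]
    rear_top <- mean(f$rear_top)
    rear_max <- mean(f$rear_max)
    if (rear_top == 0 || rear_max == 0) {
      stop(sprintf("time-averaged rear value is zero (fly_id=%s)", id), call. = FALSE)
    }
    data.frame(fly_id = id,
               max5_ratio = mean(f$front_top) / rear_top,
               single_max_ratio = mean(f$front_max) / rear_max,
               skewness = average_metric_over_images(f$skew),
               n_images = nrow(f))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compute per-fly metrics for a scene in one call
#'
#' Convenience wrapper: [fly_image_features()] then [aggregate_metrics()].
#'
#' @inheritParams fly_image_features
#' @return per-fly metric `data.frame`, see [aggregate_metrics()].
#' @export
fly_metrics <- function(stack, records, frames = NULL, length_scale = 1.2,
                        width_scale = 1.2, front_fraction = 0.5,
                        top_fraction = 0.05) {
  aggregate_metrics(fly_image_features(stack, records, frames, length_scale,
                                       width_scale, front_fraction,
                                       top_fraction))
}
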