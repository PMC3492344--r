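check_labels <- function(truth) {
  truth <- as.character(truth)
  bad <- setdiff(unique(truth), c("GFP", "non-GFP"))
  if (length(bad)) stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  truth
}

#' Sweep decision thresholds over a score range
#'
#' Evaluates `n_thresholds` evenly spaced thresholds over the observed score
#' range. A fly whose score is greater than or equal to the threshold is
#' called GFP (the boundary is inclusive on the GFP side), and accuracy is
#' `100 * (1 - (FP + FN) / total)`.
#'
#' If all scores are identical the sweep is degenerate: every threshold gets
#' the accuracy of calling everything GFP (the larger-class proportion when
#' the classes are balanced) and the result is flagged non-separable.
#'
#' @param scores numeric combined-metric scores, one per fly.
#' @param truth known labels, `"GFP"` / `"non-GFP"`, aligned with `scores`.
#' @param n_thresholds number of thresholds (>= 2; default 1000).
#' @return list with `thresholds`, `accuracy` (percent, same length) and
#'   `degenerate` flag.
#' @export
sweep_thresholds <- function(scores, truth, n_thresholds = 1000L) {
  truth <- check_labels(truth)
  stopifnot(length(scores) == length(truth), n_thresholds >= 2)
  if (!all(c("GFP", "non-GFP") %in% truth)) {
    stop("calibration needs at least one fly of each class", call. = FALSE)
  }
  is_gfp <- truth == "GFP"
  lo <- min(scores); hi <- max(scores)
  if (hi == lo) {
    acc <- 100 * mean(is_gfp)  # everything called GFP at every threshold
    return(list(thresholds = rep(lo, n_thresholds),
                accuracy = rep(max(acc, 100 - acc), n_thresholds),
                degenerate = TRUE))
  }
  thresholds <- seq(lo, hi, length.out = n_thresholds)
  pred_gfp <- outer(scores, thresholds, ">=")
  accuracy <- 100 * colMeans(pred_gfp == is_gfp)
  list(thresholds = thresholds, accuracy = accuracy, degenerate = FALSE)
}

# start, end and length of the longest run of TRUE; ties -> first run
longest_true_run <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  c(start = starts[best], end = ends[best], len = r$lengths[best])
}

#' Robust best threshold from a sweep
#'
#' Among thresholds attaining the maximum accuracy, returns the midpoint of
#' the longest contiguous run — the center of the widest accuracy plateau,
#' which is the most robust operating point against distribution shift
#' between calibration and application data. Equal-length runs break to the
#' first (lowest-threshold) run.
#'
#' @param thresholds,accuracy vectors from [sweep_thresholds()].
#' @return the selected threshold.
#' @export
best_threshold <- function(thresholds, accuracy) {
  stopifnot(length(thresholds) == length(accuracy), length(thresholds) >= 1)
  run <- longest_true_run(accuracy == max(accuracy))
  (thresholds[run["start"]] + thresholds[run["end"]]) / 2
}

#' Accuracy landscape over metric weights and thresholds
#'
#' For each weight `w` in the grid, combines the two per-fly metric values
#' into scores with [combined_score()] (normalization ranges fixed from this
#' calibration data) and sweeps `n_thresholds` thresholds over the combined
#' score range. The columns at `w = 0` and `w = 1` reproduce the
#' single-metric sweeps, so the landscape maximum can never fall below the
#' better single metric.
#'
#' @param m1_values,m2_values per-fly metric values (metric 1 = Max 5% Ratio,
#'   metric 2 = Skewness by convention).
#' @param truth labels aligned with the metric vectors.
#' @param weight_grid weights in `[0, 1]`; default 0 to 1 in steps of 0.01.
#' @param n_thresholds thresholds per weight (default 1000).
#' @param metric_names names recorded for the two metrics.
#' @return object of class `calibration_landscape`: list with `weights`,
#'   `thresholds` (matrix, weights x thresholds), `accuracy` (same shape,
#'   percent), `norm_ranges`, `metric_names`.
#' @export
weight_threshold_landscape <- function(m1_values, m2_values, truth,
                                       weight_grid = seq(0, 1, by = 0.01),
                                       n_thresholds = 1000L,
                                       metric_names = c("max5_ratio", "skewness")) {
  truth <- check_labels(truth)
  stopifnot(length(m1_values) == length(truth),
            length(m2_values) == length(truth),
            all(weight_grid >= 0 & weight_grid <= 1))
  r1 <- range(m1_values); r2 <- range(m2_values)
  if (r1[2] <= r1[1]) stop(sprintf("degenerate normalization range for %s",
                                   metric_names[1]), call. = FALSE)
  if (r2[2] <= r2[1]) stop(sprintf("degenerate normalization range for %s",
                                   metric_names[2]), call. = FALSE)
  nw <- length(weight_grid)
  acc <- matrix(NA_real_, nw, n_thresholds)
  thr <- matrix(NA_real_, nw, n_thresholds)
  for (i in seq_len(nw)) {
    scores <- combined_score(m1_values, m2_values, weight_grid[i], r1, r2)
    sw <- sweep_thresholds(scores, truth, n_thresholds)
    acc[i, ] <- sw$accuracy
    thr[i, ] <- sw$thresholds
  }
  structure(list(weights = weight_grid, thresholds = thr, accuracy = acc,
                 norm_ranges = stats::setNames(list(r1, r2), metric_names),
                 metric_names = metric_names),
            class = "calibration_landscape")
}

#' Select the robust operating point of a landscape
#'
#' Finds the global maximum accuracy, then for every weight attaining it
#' measures the longest contiguous threshold run at that accuracy and picks
#' the weight with the widest run — the largest cross-section of the
#' maximum-accuracy region, which tolerates the most threshold drift. Ties go
#' to the smaller weight; the threshold is the run's midpoint.
#'
#' @param landscape a `calibration_landscape`.
#' @return list `w`, `theta`, `accuracy` (the maximum, percent),
#'   `run_length` (cells).
#' @export
select_robust_operating_point <- function(landscape) {
  acc <- landscape$accuracy
  amax <- max(acc)
  best <- NULL
  for (i in seq_along(landscape$weights)) {
    run <- longest_true_run(acc[i, ] == amax)
    if (is.null(run)) next
    if (is.null(best) || run["len"] > best$run["len"]) {
      best <- list(i = i, run = run)
    }
  }
  thr <- landscape$thresholds[best$i, ]
  list(w = landscape$weights[best$i],
       theta = (thr[[best$run["start"]]] + thr[[best$run["end"]]]) / 2,
       accuracy = amax,
       run_length = unname(best$run["len"]))
}

#' Calibrate the combined-metric classifier on homogeneous-group data
#'
#' Takes per-fly metric values with known labels (from homogeneous groups,
#' where genotype identity is certain), builds the weight-by-threshold
#' accuracy landscape, and selects the robust operating point. The returned
#' calibration carries everything classification needs to be reproducible:
#' the normalization ranges, the selected `(w*, theta*)`, the per-weight best
#' thresholds (for weight-resolved evaluation), and the ROI/metric parameters
#' in use.
#'
#' @param metrics per-fly metric `data.frame` with columns `max5_ratio` and
#'   `skewness` (see [fly_metrics()]).
#' @param truth labels aligned with `metrics` rows.
#' @param weight_grid,n_thresholds grid parameters, see
#'   [weight_threshold_landscape()].
#' @param roi_params list of ROI/metric parameters to persist (defaults
#'   recorded as used by [fly_metrics()]).
#' @param keep_landscape keep the full accuracy matrix on the object.
#' @return object of class `fluor_calibration`.
#' @export
calibrate <- function(metrics, truth, weight_grid = seq(0, 1, by = 0.01),
                      n_thresholds = 1000L,
                      roi_params = list(length_scale = 1.2, width_scale = 1.2,
                                        front_fraction = 0.5,
                                        top_fraction = 0.05),
                      keep_landscape = FALSE) {
  land <- weight_threshold_landscape(metrics$max5_ratio, metrics$skewness,
                                     truth, weight_grid, n_thresholds)
  sel <- select_robust_operating_point(land)
  per_weight_theta <- vapply(seq_along(land$weights), function(i)
    best_threshold(land$thresholds[i, ], land$accuracy[i, ]), numeric(1))
  per_weight_acc <- apply(land$accuracy, 1, max)
  cal <- list(metric_names = land$metric_names,
              norm_ranges = land$norm_ranges,
              weight_grid = land$weights,
              n_thresholds = as.integer(n_thresholds),
              w = sel$w, theta = sel$theta,
              max_accuracy = sel$accuracy,
              run_length = sel$run_length,
              per_weight_theta = per_weight_theta,
              per_weight_accuracy = per_weight_acc,
              roi_params = roi_params,
              version = as.character(utils::packageVersion("fluorid")))
  if (keep_landscape) cal$landscape <- land
  structure(cal, class = "fluor_calibration")
}

#' @export
print.fluor_calibration <- function(x, ...) {
  cat(sprintf(paste0("combined-metric calibration: w* = %.2f (on %s), ",
                     "theta* = %.4f, max accuracy %.2f%% ",
                     "(plateau %d/%d thresholds)\n"),
              x$w, x$metric_names[1], x$theta, x$max_accuracy,
              x$run_length, x$n_thresholds))
  invisible(x)
}

#' Score flies with a calibration
#'
#' @param metrics per-fly metric `data.frame` (see [fly_metrics()]).
#' @param calibration a `fluor_calibration`.
#' @param w weight override; default the calibrated `w*`.
#' @return `data.frame` with `fly_id` and combined `score`.
#' @export
score_flies <- function(metrics, calibration, w = calibration$w) {
  nr <- calibration$norm_ranges
  data.frame(fly_id = metrics$fly_id,
             score = combined_score(metrics[[calibration$metric_names[1]]],
                                    metrics[[calibration$metric_names[2]]],
                                    w, nr[[1]], nr[[2]]))
}

#' Persist / load a calibration as JSON
#'
#' @param calibration a `fluor_calibration`.
#' @param path JSON path.
#' @export
write_calibration <- function(calibration, path) {
  obj <- unclass(calibration)
  obj$landscape <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$norm_ranges <- lapply(obj$norm_ranges, as.numeric)
  structure(obj, class = "fluor_calibration")
}
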