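#' Oriented per-fly region of interest
#'
#' An oriented rectangle in image coordinates: centered at `center`, its long
#' axis along the body orientation `theta` (head-ward), extending
#' `half_length` along the axis and `half_width` across it. `part` records
#' whether the box is the full body box (`"total"`) or one of the two halves
#' produced by [split_roi()] (`"front"` = head+thorax side, `"rear"` =
#' abdomen side).
#'
#' @param center numeric length-2, (x, y) in pixels.
#' @param theta body-axis orientation in radians (CCW from +x, head-ward).
#' @param half_length,half_width positive half-extents in pixels.
#' @param part `"total"`, `"front"` or `"rear"`.
#' @param source optional list `(fly_id, frame)` for error messages.
#' @return an object of class `oriented_roi`.
#' @export
oriented_roi <- function(center, theta, half_length, half_width,
                         part = "total", source = NULL) {
  stopifnot(length(center) == 2, is.finite(theta),
            half_length > 0, half_width > 0,
            part %in% c("total", "front", "rear"))
  structure(list(center = as.numeric(center), theta = as.numeric(theta),
                 half_length = as.numeric(half_length),
                 half_width = as.numeric(half_width),
                 part = part,
                 # which along-axis boundaries are inclusive; the split plane
                 # between front and rear is assigned to the front half so the
                 # two halves tile the total exactly
                 axis_open = c(lo = FALSE, hi = FALSE),
                 source = source),
            class = "oriented_roi")
}

#' Total body ROI from a trajectory record
#'
#' The box is centered on the tracked centroid, aligned with the body axis,
#' with half-extents `length_scale * a` along the axis and `width_scale * b`
#' across it. The default scale of 1.2 encloses the fitted body ellipse with a
#' small margin.
#'
#' @param record one trajectory row (list or 1-row `data.frame` with
#'   `x, y, theta, a, b`, optionally `fly_id, frame`).
#' @param length_scale,width_scale positive multipliers on the body semi-axes.
#' @return an `oriented_roi` with `part = "total"`.
#' @export
total_roi <- function(record, length_scale = 1.2, width_scale = 1.2) {
  stopifnot(length_scale > 0, width_scale > 0)
  src <- if (!is.null(record$fly_id)) list(fly_id = record$fly_id[1],
                                           frame = record$frame[1])
  oriented_roi(c(record$x[1], record$y[1]), record$theta[1],
               length_scale * record$a[1], width_scale * record$b[1],
               part = "total", source = src)
}

#' Split a total ROI into front and rear halves
#'
#' The split plane is perpendicular to the body axis. `front_fraction` is the
#' fraction of the box length assigned to the front (head-ward) half; the
#' default 0.5 puts the plane through the box center. Pixels whose centers lie
#' exactly on the split plane belong to the front half, so the rasterized
#' halves always tile the total box with no gap and no overlap.
#'
#' @param total an `oriented_roi` with `part == "total"`.
#' @param front_fraction fraction of the length given to the front half,
#'   in (0, 1).
#' @return list with elements `front` and `rear`.
#' @export
split_roi <- function(total, front_fraction = 0.5) {
  if (!inherits(total, "oriented_roi") || total$part != "total") {
    stop("split_roi() must be called on a total ROI", call. = FALSE)
  }
  stopifnot(front_fraction > 0, front_fraction < 1)
  hl <- total$half_length
  s <- hl * (1 - 2 * front_fraction)  # split plane along-axis coordinate
  dir <- c(cos(total$theta), sin(total$theta))
  front <- oriented_roi(total$center + dir * (s + hl) / 2, total$theta,
                        (hl - s) / 2, total$half_width, "front", total$source)
  rear <- oriented_roi(total$center + dir * (s - hl) / 2, total$theta,
                       (s + hl) / 2, total$half_width, "rear", total$source)
  rear$axis_open["hi"] <- TRUE  # boundary pixels on the split plane go front
  list(front = front, rear = rear)
}

#' Corner coordinates of an oriented ROI
#'
#' @param roi an `oriented_roi`.
#' @return 4x2 matrix of (x, y) corners in counterclockwise order starting
#'   from the rear-left corner.
#' @export
roi_corners <- function(roi) {
  ca <- cos(roi$theta); sa <- sin(roi$theta)
  hl <- roi$half_length; hw <- roi$half_width
  local <- rbind(c(-hl, -hw), c(hl, -hw), c(hl, hw), c(-hl, hw))
  rot <- local %*% rbind(c(ca, sa), c(-sa, ca))
  sweep(rot, 2, roi$center, "+")
}

# 0-based (row, col) indices of pixels whose centers fall inside the ROI,
# clipped to an nrow x ncol image. Pixel (row, col) has center (x = col,
# y = row). Membership is by pixel-center inclusion with tolerance `tol`;
# an along-axis boundary flagged open excludes centers on that boundary.
pixels_in_roi <- function(roi, nrow_img, ncol_img, tol = 1e-9) {
  corners <- roi_corners(roi)
  x0 <- max(0L, floor(min(corners[, 1]) - tol))
  x1 <- min(ncol_img - 1L, ceiling(max(corners[, 1]) + tol))
  y0 <- max(0L, floor(min(corners[, 2]) - tol))
  y1 <- min(nrow_img - 1L, ceiling(max(corners[, 2]) + tol))
  if (x0 > x1 || y0 > y1) {
    return(cbind(row = integer(0), col = integer(0)))
  }
  xs <- x0:x1
  ys <- y0:y1
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  dx <- px - roi$center[1]
  dy <- py - roi$center[2]
  ca <- cos(roi$theta); sa <- sin(roi$theta)
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  lo_ok <- if (roi$axis_open["lo"]) u >= -roi$half_length + tol else
    u >= -roi$half_length - tol
  hi_ok <- if (roi$axis_open["hi"]) u <= roi$half_length - tol else
    u <= roi$half_length + tol
  keep <- lo_ok & hi_ok & abs(v) <= roi$half_width + tol
  cbind(row = py[keep], col = px[keep])
}

#' Extract the pixel values covered by an ROI
#'
#' A pixel belongs to the sample when its center lies inside the oriented
#' rectangle and inside the image bounds. The value order is deterministic
#' for fixed inputs (column-major over the ROI's bounding box).
#'
#' @param image 2-D intensity matrix.
#' @param roi an `oriented_roi`.
#' @param tol boundary tolerance for pixel-center inclusion.
#' @return an object of class `pixel_sample`: list with `values` (numeric
#'   vector), `n`, and `source` (`fly_id`, `frame`, `part`).
#' @export
extract_pixels <- function(image, roi, tol = 1e-9) {
  stopifnot(is.matrix(image), length(image) > 0)
  idx <- pixels_in_roi(roi, nrow(image), ncol(image), tol)
  if (nrow(idx) == 0) {
    src <- roi$source
    where <- if (!is.null(src)) sprintf(" (fly_id=%s, frame=%s)",
                                        src$fly_id, src$frame) else ""
    stop(sprintf("ROI covers no pixel inside the image%s", where), call. = FALSE)
  }
  values <- image[idx[, "row"] + 1L + nrow(image) * idx[, "col"]]
  structure(list(values = as.numeric(values), n = nrow(idx),
                 source = c(roi$source, list(part = roi$part))),
            class = "pixel_sample")
}
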