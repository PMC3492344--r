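#' Write an identity overlay PNG
#'
#' Renders an IR frame to grayscale and overlays one filled triangle per fly
#' (apex at the head), colored blue for GFP calls and red for non-GFP — a
#' quick visual QC of the assignment.
#'
#' @param image 2-D intensity matrix (typically an IR frame).
#' @param records trajectory rows for one frame (`fly_id, x, y, theta, a, b`).
#' @param labels named character vector of labels keyed by fly id.
#' @param path output PNG path.
#' @param bits bit depth of `image` for display scaling.
#' @param alpha blend factor of the triangle over the image.
#' @export
write_overlay_png <- function(image, records, labels, path, bits = 8L,
                              alpha = 0.6) {
  g <- image / (2^bits - 1)
  rgb <- array(rep(g, 3), c(nrow(image), ncol(image), 3))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    lab <- labels[[as.character(rec$fly_id)]]
    col <- if (identical(lab, "GFP")) c(0.2, 0.4, 1) else c(1, 0.25, 0.2)
    ca <- cos(rec$theta); sa <- sin(rec$theta)
    vx <- c(rec$x + rec$a * ca,
            rec$x - rec$a * ca - rec$b * sa,
            rec$x - rec$a * ca + rec$b * sa)
    vy <- c(rec$y + rec$a * sa,
            rec$y - rec$a * sa + rec$b * ca,
            rec$y - rec$a * sa - rec$b * ca)
    x0 <- max(0, floor(min(vx))); x1 <- min(ncol(image) - 1, ceiling(max(vx)))
    y0 <- max(0, floor(min(vy))); y1 <- min(nrow(image) - 1, ceiling(max(vy)))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
    # barycentric point-in-triangle test
    d <- (vy[2] - vy[3]) * (vx[1] - vx[3]) + (vx[3] - vx[2]) * (vy[1] - vy[3])
    l1 <- ((vy[2] - vy[3]) * (px - vx[3]) + (vx[3] - vx[2]) * (py - vy[3])) / d
    l2 <- ((vy[3] - vy[1]) * (px - vx[3]) + (vx[1] - vx[3]) * (py - vy[3])) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= 0 & l2 >= 0 & l3 >= 0
    rr <- py[inside] + 1; cc <- px[inside] + 1
    for (ch in 1:3) {
      idx <- cbind(rr, cc, ch)
      rgb[idx] <- (1 - alpha) * rgb[idx] + alpha * col[ch]
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
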