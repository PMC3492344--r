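# Independent oracles, kept deliberately naive so they cannot share bugs
# with the implementation.

# brute-force point-in-oriented-rectangle rasterization over the full image
brute_roi_pixels <- function(center, theta, half_length, half_width,
                             nrow_img, ncol_img) {
  hits <- NULL
  for (row in 0:(nrow_img - 1)) {
    for (col in 0:(ncol_img - 1)) {
      dx <- col - center[1]
      dy <- row - center[2]
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      if (abs(u) <= half_length && abs(v) <= half_width) {
        hits <- rbind(hits, c(row, col))
      }
    }
  }
  if (is.null(hits)) hits <- matrix(integer(0), 0, 2)
  colnames(hits) <- c("row", "col")
  hits
}

pixel_key <- function(idx) sort(paste(idx[, "row"], idx[, "col"]))

# direct central-moment skewness
moment_skew <- function(v) {
  mu <- sum(v) / length(v)
  m2 <- sum((v - mu)^2) / length(v)
  m3 <- sum((v - mu)^3) / length(v)
  m3 / m2^(3 / 2)
}

# full-sort top-fraction mean
sort_top_mean <- function(v, fraction) {
  k <- max(1, ceiling(fraction * length(v)))
  mean(rev(sort(v))[1:k])
}

# small, fast scene configs for unit tests
tiny_config <- function(...) {
  args <- utils::modifyList(list(width = 160, height = 70, n_flies = 4,
                                 n_frames = 4, n_pre = 2), list(...))
  do.call(scene_config, args)
}

# one trajectory record as a list
rec <- function(x, y, theta, a, b, fly_id = 0L, frame = 0L) {
  list(frame = frame, fly_id = fly_id, x = x, y = y, theta = theta, a = a, b = b)
}

random_records <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    frame = seq_len(n) - 1L, fly_id = rep(0L, n),
    x = runif(n, 0, 100), y = runif(n, 0, 100),
    theta = runif(n, -pi, pi),
    a = runif(n, 2, 8), b = runif(n, 1, 2)))
}
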