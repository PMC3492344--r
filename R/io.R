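#' @keywords internal
"_PACKAGE"

TRAJ_COLUMNS <- c("frame", "fly_id", "x", "y", "theta", "a", "b")

#' Normalize an angle to [-pi, pi)
#'
#' @param theta angle(s) in radians.
#' @return angle(s) wrapped into `[-pi, pi)`.
#' @export
normalize_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% maps -pi to +pi-ish values exactly at the seam; force the half-open side
  out[out >= pi] <- out[out >= pi] - 2 * pi
  out
}

validate_trajectories <- function(df, source = "trajectories") {
  num_cols <- TRAJ_COLUMNS
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("%s: non-numeric value in column '%s' (row %d)",
                   source, cl, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("%s: missing or non-finite value in column '%s' (row %d)",
                   source, cl, which(!is.finite(v))[1]), call. = FALSE)
    }
  }
  if (any(df$frame < 0) || any(df$frame != floor(df$frame))) {
    stop(sprintf("%s: 'frame' must be a non-negative integer", source), call. = FALSE)
  }
  if (any(df$fly_id < 0) || any(df$fly_id != floor(df$fly_id))) {
    stop(sprintf("%s: 'fly_id' must be a non-negative integer", source), call. = FALSE)
  }
  bad <- which(!(df$a >= df$b & df$b > 0))
  if (length(bad)) {
    stop(sprintf("%s: body semi-axes must satisfy a >= b > 0 (row %d: a=%g, b=%g)",
                 source, bad[1], df$a[bad[1]], df$b[bad[1]]), call. = FALSE)
  }
  key <- paste(df$fly_id, df$frame)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("%s: duplicate (fly_id, frame) pair (%s)", source,
                 gsub(" ", ", ", d)), call. = FALSE)
  }
  df$frame <- as.integer(df$frame)
  df$fly_id <- as.integer(df$fly_id)
  df$theta <- normalize_angle(df$theta)
  df[order(df$frame, df$fly_id), , drop = FALSE]
}

#' Read per-fly trajectory records from CSV
#'
#' The canonical trajectory format is a comma-separated UTF-8 file with header
#' `frame,fly_id,x,y,theta,a,b`. Positions are in pixels (image convention:
#' origin at the top-left pixel, x rightward, y downward, 0-based indices),
#' `theta` is the head-ward body-axis orientation in radians measured
#' counterclockwise from the +x image axis, and `a`/`b` are the body
#' semi-major/semi-minor axes in pixels.
#'
#' Every row must satisfy the record invariants (`a >= b > 0`, unique
#' `(fly_id, frame)`, finite values); a violating row raises an error rather
#' than being silently dropped. `theta` is stored normalized to `[-pi, pi)`.
#'
#' @param path path to a trajectory CSV file.
#' @return a `data.frame` with columns `frame, fly_id, x, y, theta, a, b`,
#'   ordered by frame then fly.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop(sprintf("trajectory file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRAJ_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  validate_trajectories(df[TRAJ_COLUMNS], source = path)
}

#' Write trajectory records to CSV
#'
#' Continuous fields are serialized with enough significant digits that a
#' write/read round-trip agrees within 1e-9.
#'
#' @param records trajectory `data.frame` (see [read_trajectories()]).
#' @param path output path.
#' @export
write_trajectories <- function(records, path) {
  records <- validate_trajectories(as.data.frame(records)[TRAJ_COLUMNS])
  out <- data.frame(
    frame = records$frame, fly_id = records$fly_id,
    x = sprintf("%.12g", records$x), y = sprintf("%.12g", records$y),
    theta = sprintf("%.12g", records$theta),
    a = sprintf("%.12g", records$a), b = sprintf("%.12g", records$b),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an image stack
#'
#' @param frames list of 2-D integer intensity matrices, all of one shape.
#' @param channel `"FLUOR"` or `"IR"`.
#' @param frame_indices integers aligning stack frames to trajectory frames
#'   (default `0:(n-1)`); must be strictly increasing.
#' @param bits intensity bit depth, 8 or 16.
#' @param n_pre number of leading frames acquired before the behavioral
#'   experiment (the "pre" illumination block); the remainder form the "post"
#'   block. Used by [select_images()].
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, channel = c("FLUOR", "IR"),
                        frame_indices = NULL, bits = 8L, n_pre = 0L) {
  channel <- match.arg(channel)
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims)) {
      stop("all frames must be 2-D matrices of one shape", call. = FALSE)
    }
  }
  if (is.null(frame_indices)) frame_indices <- seq_along(frames) - 1L
  frame_indices <- as.integer(frame_indices)
  if (length(frame_indices) != length(frames) ||
      any(diff(frame_indices) <= 0)) {
    stop("frame_indices must be strictly increasing, one per frame", call. = FALSE)
  }
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16", call. = FALSE)
  structure(list(frames = frames, channel = channel,
                 frame_indices = frame_indices, bits = as.integer(bits),
                 n_pre = as.integer(n_pre)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d frame(s) of %dx%d, %s channel, %d-bit\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$channel, x$bits))
  invisible(x)
}

#' Fetch the stack frame aligned to a trajectory frame index
#' @param stack an [image_stack()].
#' @param frame trajectory frame index.
#' @return the 2-D intensity matrix.
#' @export
stack_frame <- function(stack, frame) {
  i <- match(frame, stack$frame_indices)
  if (is.na(i)) stop(sprintf("no image for trajectory frame %d", frame), call. = FALSE)
  stack$frames[[i]]
}

read_one_image <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    im <- png::readPNG(path)
    if (length(dim(im)) == 3) {
      stop(sprintf("%s: color image; supply single-channel (grayscale) input", path),
           call. = FALSE)
    }
    list(m = matrix(as.integer(round(im * 255)), nrow(im), ncol(im)), bits = 8L)
  } else {
    stop(sprintf("unsupported image file: %s", path), call. = FALSE)
  }
}

#' Read a fluorescence or IR image stack
#'
#' Accepts either a multi-page grayscale TIFF (8- or 16-bit) or a directory of
#' lexicographically ordered numbered PNG frames. Pixel values are preserved as
#' integers at the stored bit depth. Frame indices default to `0..n-1`; a
#' sidecar file `<path>.frames` (one integer per line) overrides them.
#'
#' @param path TIFF file or directory of PNG frames.
#' @param channel `"FLUOR"` or `"IR"`.
#' @param n_pre number of leading frames in the pre-experiment block.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, channel = c("FLUOR", "IR"), n_pre = 0L) {
  channel <- match.arg(channel)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop(sprintf("%s: no PNG frames found", path), call. = FALSE)
    reads <- lapply(files, read_one_image)
    frames <- lapply(reads, `[[`, "m")
    bits <- reads[[1]]$bits
  } else if (file.exists(path)) {
    info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
    if (any(info$samples.per.pixel != 1)) {
      stop(sprintf("%s: color image; supply single-channel (grayscale) input", path),
           call. = FALSE)
    }
    bits <- as.integer(info$bits.per.sample[1])
    frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (is.matrix(frames)) frames <- list(frames)
    frames <- lapply(frames, function(f) matrix(as.integer(f), nrow(f), ncol(f)))
  } else {
    stop(sprintf("image stack not found: %s", path), call. = FALSE)
  }
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop(sprintf("%s: frames have mixed shapes", path), call. = FALSE)
  }
  sidecar <- paste0(path, ".frames")
  fi <- if (file.exists(sidecar)) as.integer(readLines(sidecar)) else NULL
  image_stack(frames, channel, frame_indices = fi, bits = bits, n_pre = n_pre)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer pixel values round-trip exactly at the stack's bit depth. If the
#' stack's frame indices are not the default `0..n-1`, they are written to a
#' sidecar `<path>.frames` file that [read_image_stack()] picks up.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @export
write_image_stack <- function(stack, path) {
  scale <- 2^stack$bits - 1
  pages <- lapply(stack$frames, function(m) {
    if (min(m) < 0 || max(m) > scale) stop("pixel values outside dtype range", call. = FALSE)
    m / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bits)
  default_idx <- seq_along(stack$frames) - 1L
  if (!identical(stack$frame_indices, default_idx)) {
    writeLines(as.character(stack$frame_indices), paste0(path, ".frames"))
  }
  invisible(path)
}

#' Import a tracker export container
#'
#' Multi-fly trackers (Ctrax and derivatives) export per-frame flat arrays of
#' x position, y position, body angle and major/minor axis lengths. This
#' importer consumes that layout serialized as JSON with keys `x_pos`, `y_pos`,
#' `angle`, `maj_ax`, `min_ax` (flat, frame-major) plus either `ntargets`
#' (flies per frame) or `identity` with `frame` (per-entry assignment).
#' A binary `.mat` container is not read directly; convert it to this JSON
#' layout (e.g. with a one-line scipy script) or to the trajectory CSV.
#'
#' Field mapping: axis lengths are interpreted as body semi-axes after
#' multiplication by `axis_scale` (default 1; set to 0.5 if the export stores
#' full axis lengths, 2 for quarter-axis conventions); `angle` is assumed to be
#' radians and is normalized to the head-ward, counterclockwise-from-+x
#' convention in `[-pi, pi)`.
#'
#' @param path path to the JSON export.
#' @param axis_scale multiplicative factor converting exported axis lengths to
#'   semi-axes.
#' @return a trajectory `data.frame` satisfying all record invariants.
#' @export
import_ctrax_export <- function(path, axis_scale = 1) {
  if (!file.exists(path)) stop(sprintf("tracker export not found: %s", path), call. = FALSE)
  raw <- readBin(path, "raw", n = 8)
  dat <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(dat) || !is.list(dat)) {
    stop(sprintf(paste0("%s: unrecognized tracker container layout; convert the ",
                        "export to the JSON array layout or to trajectory CSV"),
                 path), call. = FALSE)
  }
  need <- c("x_pos", "y_pos", "angle", "maj_ax", "min_ax")
  missing <- setdiff(need, names(dat))
  if (length(missing)) {
    stop(sprintf(paste0("%s: unrecognized tracker container layout (missing %s); ",
                        "convert the export to the JSON array layout or to ",
                        "trajectory CSV"),
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- length(dat$x_pos)
  if (!all(vapply(dat[need], length, integer(1)) == n)) {
    stop(sprintf("%s: tracker arrays have unequal lengths", path), call. = FALSE)
  }
  if (!is.null(dat$ntargets)) {
    nt <- as.integer(dat$ntargets)
    if (sum(nt) != n) stop(sprintf("%s: ntargets does not sum to array length", path),
                           call. = FALSE)
    frame <- rep(seq_along(nt) - 1L, nt)
    fly_id <- unlist(lapply(nt, function(k) seq_len(k) - 1L), use.names = FALSE)
  } else if (!is.null(dat$identity) && !is.null(dat$frame)) {
    frame <- as.integer(dat$frame)
    fly_id <- as.integer(dat$identity)
  } else {
    stop(sprintf(paste0("%s: unrecognized tracker container layout (need ntargets ",
                        "or identity+frame); convert the export to the JSON array ",
                        "layout or to trajectory CSV"), path), call. = FALSE)
  }
  df <- data.frame(frame = frame, fly_id = fly_id,
                   x = as.numeric(dat$x_pos), y = as.numeric(dat$y_pos),
                   theta = normalize_angle(as.numeric(dat$angle)),
                   a = as.numeric(dat$maj_ax) * axis_scale,
                   b = as.numeric(dat$min_ax) * axis_scale)
  validate_trajectories(df, source = path)
}

#' Write per-fly identity calls to CSV
#'
#' @param calls `data.frame` with columns `fly_id, label, score, margin`;
#'   labels are `"GFP"` / `"non-GFP"`, one call per fly.
#' @param path output path.
#' @export
write_identity_calls <- function(calls, path) {
  calls <- as.data.frame(calls)
  stopifnot(nrow(calls) >= 1)
  need <- c("fly_id", "label", "score", "margin")
  missing <- setdiff(need, names(calls))
  if (length(missing)) stop(sprintf("identity calls missing column(s): %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(calls$fly_id)) {
    stop(sprintf("duplicate fly_id in identity calls: %d",
                 calls$fly_id[duplicated(calls$fly_id)][1]), call. = FALSE)
  }
  if (!all(calls$label %in% c("GFP", "non-GFP"))) {
    stop("labels must be 'GFP' or 'non-GFP'", call. = FALSE)
  }
  if (any(calls$margin < 0)) stop("margins must be >= 0", call. = FALSE)
  out <- data.frame(fly_id = as.integer(calls$fly_id), label = calls$label,
                    score = sprintf("%.12g", calls$score),
                    margin = sprintf("%.12g", calls$margin),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read identity calls written by [write_identity_calls()]
#' @param path CSV path.
#' @return `data.frame` with columns `fly_id, label, score, margin`.
#' @export
read_identity_calls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "label", "score", "margin")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop(sprintf("%s: missing column(s): %s", path,
                                    paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Read/write a truth table mapping fly ids to known labels
#' @param path CSV with header `fly_id,label`.
#' @return named character vector of labels keyed by fly id.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("fly_id", "label") %in% names(df))) {
    stop(sprintf("%s: truth file needs columns fly_id,label", path), call. = FALSE)
  }
  stats::setNames(df$label, df$fly_id)
}

#' @rdname read_truth
#' @param truth named character vector (names = fly ids) or `data.frame`
#'   with `fly_id` and `label`.
#' @export
write_truth <- function(truth, path) {
  if (!is.data.frame(truth)) {
    truth <- data.frame(fly_id = as.integer(names(truth)), label = unname(truth))
  }
  utils::write.csv(truth[c("fly_id", "label")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
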