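#' Synthetic scene configuration
#'
#' Describes a simulated group experiment: an arena of walking flies, half of
#' which (by default) carry a thoracic fluorescent transgene, imaged in a
#' fluorescence channel and an IR-backlight channel. The fluorescence forward
#' model gives every fly a dim body ellipse, a posterior (abdominal)
#' autofluorescence blob, and either a bright anterior (thoracic) blob for
#' labeled flies or two small anterior eye-marker spots for unlabeled flies —
#' the worst case for discrimination, mimicking transgene markers expressed
#' in the ocelli and eyes. Illumination inhomogeneity is modeled as a linear
#' gradient across the arena, plus additive Gaussian pixel noise.
#'
#' Amplitudes are in intensity counts of the output dtype (default 8-bit).
#' Frames split into a pre-experiment block (`n_pre`) and a post-experiment
#' block, mirroring rigs that image fluorescence briefly before and after the
#' behavioral recording.
#'
#' @param width,height arena size in pixels. The default 424 x 106 px is an
#'   80 x 20 mm walking arena at ~5.3 px/mm, the scale at which the default
#'   16 px body length corresponds to a ~3 mm adult fly.
#' @param n_flies number of flies (default 18, a typical group size).
#' @param gfp_fraction fraction of flies labeled; `round(gfp_fraction *
#'   n_flies)` flies are GFP.
#' @param n_frames total frames per channel.
#' @param n_pre frames in the pre-experiment block.
#' @param a_mean,b_mean mean body semi-axes in pixels.
#' @param size_jitter fractional per-fly jitter on the semi-axes.
#' @param thorax_gfp_amp peak thoracic fluorescence of labeled flies.
#' @param thorax_auto_amp peak thoracic cuticular autofluorescence of
#'   unlabeled flies (default 0). Setting it equal to `thorax_gfp_amp`
#'   removes all marker contrast — the null model in which the two classes
#'   render identically.
#' @param abdomen_auto_amp peak abdominal autofluorescence (all flies).
#' @param eye_auto_amp peak eye-marker fluorescence of unlabeled flies.
#' @param body_base_amp body-ellipse base fluorescence.
#' @param background_level arena background fluorescence.
#' @param arena_autofluor_amp amplitude of stationary arena autofluorescence
#'   patches.
#' @param n_autofluor_patches number of such patches.
#' @param noise_sd additive per-pixel Gaussian noise SD.
#' @param illum_gradient fractional illumination change across the arena
#'   width (0 = uniform).
#' @param step_sd per-frame step-length SD in pixels.
#' @param turn_sd per-frame heading change SD in radians.
#' @param bits output bit depth (8 or 16).
#' @param seed RNG seed; the whole scene is reproducible from the config.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(width = 424, height = 106, n_flies = 18,
                         gfp_fraction = 0.5, n_frames = 20, n_pre = 10,
                         a_mean = 8, b_mean = 3, size_jitter = 0.1,
                         thorax_gfp_amp = 120, thorax_auto_amp = 0,
                         abdomen_auto_amp = 50,
                         eye_auto_amp = 40, body_base_amp = 25,
                         background_level = 8, arena_autofluor_amp = 30,
                         n_autofluor_patches = 2, noise_sd = 3,
                         illum_gradient = 0.2, step_sd = 2, turn_sd = 0.3,
                         bits = 8L, seed = 1L) {
  cfg <- list(width = width, height = height, n_flies = n_flies,
              gfp_fraction = gfp_fraction, n_frames = n_frames, n_pre = n_pre,
              a_mean = a_mean, b_mean = b_mean, size_jitter = size_jitter,
              thorax_gfp_amp = thorax_gfp_amp,
              thorax_auto_amp = thorax_auto_amp,
              abdomen_auto_amp = abdomen_auto_amp,
              eye_auto_amp = eye_auto_amp, body_base_amp = body_base_amp,
              background_level = background_level,
              arena_autofluor_amp = arena_autofluor_amp,
              n_autofluor_patches = n_autofluor_patches, noise_sd = noise_sd,
              illum_gradient = illum_gradient, step_sd = step_sd,
              turn_sd = turn_sd, bits = as.integer(bits), seed = as.integer(seed))
  stopifnot(cfg$n_flies >= 1, cfg$n_frames >= 1,
            cfg$gfp_fraction >= 0, cfg$gfp_fraction <= 1,
            cfg$noise_sd >= 0, cfg$thorax_gfp_amp >= 0,
            cfg$abdomen_auto_amp >= 0, cfg$eye_auto_amp >= 0,
            cfg$thorax_auto_amp >= 0,
            cfg$a_mean >= cfg$b_mean, cfg$b_mean > 0,
            cfg$n_pre >= 0, cfg$n_pre <= cfg$n_frames,
            cfg$bits %in% c(8L, 16L))
  structure(cfg, class = "scene_config")
}

#' Noisy-regime scene configuration
#'
#' A stressed variant of [scene_config()]: thoracic amplitude only twice the
#' abdominal amplitude, additive noise SD equal to the abdominal amplitude,
#' and the eye marker on — a regime where single-image metrics are unreliable
#' and time-averaging across images matters.
#'
#' @param ... overrides passed to [scene_config()].
#' @export
noisy_scene_config <- function(...) {
  defaults <- list(thorax_gfp_amp = 100, abdomen_auto_amp = 50,
                   noise_sd = 50, eye_auto_amp = 40)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

#' Random-walk fly trajectories
#'
#' Each fly starts uniformly inside the arena (with a body-size margin) with
#' a uniform heading; per frame the heading receives Gaussian turn noise and
#' the fly steps along its heading by a Gaussian step length, reflecting at
#' the walls. Body semi-axes are jittered per fly and held constant.
#' Consumes the current RNG stream; [make_scene()] seeds it from the config.
#'
#' @param config a [scene_config()].
#' @return trajectory `data.frame` (one row per fly per frame).
#' @export
random_walk_poses <- function(config) {
  margin <- 2 * config$a_mean
  if (config$width <= 2 * margin || config$height <= 2 * margin) {
    stop("arena too small for the fly body margin", call. = FALSE)
  }
  n <- config$n_flies
  a <- config$a_mean * (1 + config$size_jitter * stats::runif(n, -1, 1))
  b <- config$b_mean * (1 + config$size_jitter * stats::runif(n, -1, 1))
  b <- pmin(b, 0.95 * a)
  lo_x <- margin; hi_x <- config$width - 1 - margin
  lo_y <- margin; hi_y <- config$height - 1 - margin
  # flies are solid: centers may not come closer than the sum of the two
  # semi-major axes, enforced by a few pair-repulsion relaxation sweeps
  separate <- function(x, y) {
    if (n == 1) return(list(x = x, y = y))
    for (iter in 1:8) {
      moved <- FALSE
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          sep <- a[i] + a[j]
          dx <- x[j] - x[i]; dy <- y[j] - y[i]
          d <- sqrt(dx^2 + dy^2)
          if (d < sep) {
            moved <- TRUE
            if (d < 1e-6) { dx <- 1; dy <- 0; d <- 1 }
            push <- (sep - d) / 2
            x[i] <- x[i] - push * dx / d; y[i] <- y[i] - push * dy / d
            x[j] <- x[j] + push * dx / d; y[j] <- y[j] + push * dy / d
          }
        }
      }
      x <- pmin(pmax(x, lo_x), hi_x)
      y <- pmin(pmax(y, lo_y), hi_y)
      if (!moved) break
    }
    list(x = x, y = y)
  }
  x <- stats::runif(n, margin, config$width - 1 - margin)
  y <- stats::runif(n, margin, config$height - 1 - margin)
  p <- separate(x, y)
  x <- p$x; y <- p$y
  h <- stats::runif(n, -pi, pi)
  out <- vector("list", config$n_frames)
  for (fr in seq_len(config$n_frames) - 1L) {
    out[[fr + 1L]] <- data.frame(frame = fr, fly_id = seq_len(n) - 1L,
                                 x = x, y = y, theta = normalize_angle(h),
                                 a = a, b = b)
    h <- h + stats::rnorm(n, 0, config$turn_sd)
    step <- stats::rnorm(n, 0, config$step_sd)
    x <- x + step * cos(h)
    y <- y + step * sin(h)
    # reflect at walls (margin inset) and mirror the heading component
    ref <- x < lo_x | x > hi_x
    x[x < lo_x] <- 2 * lo_x - x[x < lo_x]
    x[x > hi_x] <- 2 * hi_x - x[x > hi_x]
    h[ref] <- pi - h[ref]
    ref <- y < lo_y | y > hi_y
    y[y < lo_y] <- 2 * lo_y - y[y < lo_y]
    y[y > hi_y] <- 2 * hi_y - y[y > hi_y]
    h[ref] <- -h[ref]
    x <- pmin(pmax(x, lo_x), hi_x)
    y <- pmin(pmax(y, lo_y), hi_y)
    p <- separate(x, y)
    x <- p$x; y <- p$y
  }
  do.call(rbind, out)
}

#' Render one fly's fluorescence and IR intensity patch
#'
#' Fluorescence: filled oriented body ellipse at the base amplitude, an
#' anterior Gaussian blob (centered +0.5a along the heading, width ~ b/2) at
#' the thoracic amplitude for GFP flies, a posterior blob (-0.5a) at the
#' abdominal amplitude for all flies, and two small far-anterior spots at the
#' eye amplitude for non-GFP flies. IR: the body ellipse as a dark silhouette
#' mask. The label never affects the IR channel.
#'
#' @param record one trajectory row.
#' @param label `"GFP"` or `"non-GFP"`.
#' @param config a [scene_config()].
#' @return list with `fluo` and `ir_mask` patch matrices plus the 0-based
#'   pixel offsets `row0`, `col0` of the patch within the arena.
#' @export
render_fly <- function(record, label, config) {
  a <- record$a; b <- record$b
  r <- ceiling(1.3 * a + 3 * b)
  cx <- record$x; cy <- record$y
  x0 <- floor(cx) - r; x1 <- floor(cx) + r
  y0 <- floor(cy) - r; y1 <- floor(cy) + r
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(rep(xs, each = length(ys)), length(ys)) - cx
  dy <- matrix(rep(ys, times = length(xs)), length(ys)) - cy
  ca <- cos(record$theta); sa <- sin(record$theta)
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  body <- (u / a)^2 + (v / b)^2 <= 1
  blob <- function(u0, v0, sd, amp) amp * exp(-((u - u0)^2 + (v - v0)^2) / (2 * sd^2))
  fl <- config$body_base_amp * body
  fl <- fl + blob(-0.5 * a, 0, b / 2, config$abdomen_auto_amp)
  if (label == "GFP") {
    fl <- fl + blob(0.5 * a, 0, b / 2, config$thorax_gfp_amp)
  } else {
    if (config$thorax_auto_amp > 0) {
      fl <- fl + blob(0.5 * a, 0, b / 2, config$thorax_auto_amp)
    }
    if (config$eye_auto_amp > 0) {
      fl <- fl + blob(0.95 * a, 0.6 * b, b / 3, config$eye_auto_amp)
      fl <- fl + blob(0.95 * a, -0.6 * b, b / 3, config$eye_auto_amp)
    }
  }
  list(fluo = fl, ir_mask = body, row0 = y0, col0 = x0)
}

compose_patch <- function(canvas, patch, row0, col0, fun) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  pr <- nrow(patch); pc <- ncol(patch)
  r_idx <- (row0:(row0 + pr - 1))
  c_idx <- (col0:(col0 + pc - 1))
  keep_r <- r_idx >= 0 & r_idx < nr
  keep_c <- c_idx >= 0 & c_idx < nc
  if (!any(keep_r) || !any(keep_c)) return(canvas)
  canvas[r_idx[keep_r] + 1, c_idx[keep_c] + 1] <-
    fun(canvas[r_idx[keep_r] + 1, c_idx[keep_c] + 1],
        patch[keep_r, keep_c, drop = FALSE])
  canvas
}

#' Generate a complete synthetic scene
#'
#' Produces paired IR and fluorescence image stacks, the underlying
#' trajectories, and the ground-truth label of every fly, all reproducible
#' from `(config, seed)`. Flies are composed onto the background by maximum
#' intensity (so visually overlapping flies contaminate each other's ROIs,
#' as in real groups), the fluorescence background carries stationary arena
#' autofluorescence patches and a linear illumination gradient, and additive
#' Gaussian noise is applied per pixel before clipping to the dtype range.
#'
#' @param config a [scene_config()].
#' @return list with `ir` and `fluo` ([image_stack()]s), `trajectories`
#'   (`data.frame`), `truth` (named character vector by fly id) and `config`.
#' @export
make_scene <- function(config) {
  withr::with_seed(config$seed, {
    traj <- random_walk_poses(config)
    n_gfp <- round(config$gfp_fraction * config$n_flies)
    gfp_ids <- sort(sample(seq_len(config$n_flies) - 1L, n_gfp))
    truth <- stats::setNames(
      ifelse((seq_len(config$n_flies) - 1L) %in% gfp_ids, "GFP", "non-GFP"),
      seq_len(config$n_flies) - 1L)
    # stationary arena autofluorescence patches
    patches <- if (config$n_autofluor_patches > 0) {
      data.frame(x = stats::runif(config$n_autofluor_patches, 0, config$width - 1),
                 y = stats::runif(config$n_autofluor_patches, 0, config$height - 1),
                 sd = stats::runif(config$n_autofluor_patches,
                                   config$b_mean, 3 * config$b_mean))
    }
    xs <- seq_len(config$width) - 1L
    ys <- seq_len(config$height) - 1L
    bg <- matrix(config$background_level, config$height, config$width)
    if (!is.null(patches)) {
      px <- matrix(rep(xs, each = config$height), config$height)
      py <- matrix(rep(ys, times = config$width), config$height)
      for (k in seq_len(nrow(patches))) {
        bg <- bg + config$arena_autofluor_amp *
          exp(-((px - patches$x[k])^2 + (py - patches$y[k])^2) / (2 * patches$sd[k]^2))
      }
    }
    grad <- 1 + config$illum_gradient * (xs / max(1, config$width - 1) - 0.5)
    grad_m <- matrix(rep(grad, each = config$height), config$height)
    vmax <- 2^config$bits - 1
    quantize <- function(m) {
      m <- m + stats::rnorm(length(m), 0, config$noise_sd)
      matrix(as.integer(round(pmin(vmax, pmax(0, m)))), nrow(m), ncol(m))
    }
    fluo_frames <- vector("list", config$n_frames)
    ir_frames <- vector("list", config$n_frames)
    ir_bg_level <- 0.85 * vmax
    ir_body_level <- 0.15 * vmax
    for (fr in seq_len(config$n_frames) - 1L) {
      sub <- traj[traj$frame == fr, , drop = FALSE]
      fl <- bg
      ir <- matrix(ir_bg_level, config$height, config$width)
      for (i in seq_len(nrow(sub))) {
        p <- render_fly(sub[i, ], truth[[as.character(sub$fly_id[i])]], config)
        fl <- compose_patch(fl, p$fluo, p$row0, p$col0, pmax)
        ir <- compose_patch(ir, ifelse(p$ir_mask, ir_body_level, ir_bg_level),
                            p$row0, p$col0, pmin)
      }
      fluo_frames[[fr + 1L]] <- quantize(fl * grad_m)
      ir_frames[[fr + 1L]] <- quantize(ir)
    }
    list(ir = image_stack(ir_frames, "IR", bits = config$bits,
                          n_pre = config$n_pre),
         fluo = image_stack(fluo_frames, "FLUOR", bits = config$bits,
                            n_pre = config$n_pre),
         trajectories = traj, truth = truth, config = config)
  })
}

#' Write a scene to disk in the package's standard formats
#'
#' Writes `ir.tiff`, `fluo.tiff`, `trajectories.csv`, `truth.csv` and
#' `config.json` into `dir` (created if needed).
#'
#' @param scene output of [make_scene()].
#' @param dir output directory.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_image_stack(scene$ir, file.path(dir, "ir.tiff"))
  write_image_stack(scene$fluo, file.path(dir, "fluo.tiff"))
  write_trajectories(scene$trajectories, file.path(dir, "trajectories.csv"))
  write_truth(scene$truth, file.path(dir, "truth.csv"))
  jsonlite::write_json(unclass(scene$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#' @param dir scene directory.
#' @param truth_required error if `truth.csv` is absent.
#' @return list like [make_scene()]'s (config as plain list).
#' @export
read_scene <- function(dir, truth_required = FALSE) {
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  n_pre <- if (!is.null(cfg$n_pre)) cfg$n_pre else 0L
  truth_path <- file.path(dir, "truth.csv")
  if (truth_required && !file.exists(truth_path)) {
    stop(sprintf("%s: no truth.csv", dir), call. = FALSE)
  }
  list(ir = if (file.exists(file.path(dir, "ir.tiff")))
         read_image_stack(file.path(dir, "ir.tiff"), "IR", n_pre = n_pre),
       fluo = read_image_stack(file.path(dir, "fluo.tiff"), "FLUOR", n_pre = n_pre),
       trajectories = read_trajectories(file.path(dir, "trajectories.csv")),
       truth = if (file.exists(truth_path)) read_truth(truth_path),
       config = cfg)
}
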