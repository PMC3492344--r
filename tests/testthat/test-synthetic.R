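test_that("scenes are jointly reproducible from the config seed", {
  cfg <- tiny_config(seed = 42)
  s1 <- make_scene(cfg)
  s2 <- make_scene(cfg)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$fluo$frames, s2$fluo$frames)
  expect_identical(s1$ir$frames, s2$ir$frames)
  s3 <- make_scene(tiny_config(seed = 43))
  expect_false(identical(s1$fluo$frames, s3$fluo$frames))
})

test_that("random walks stay inside the arena and honor zero-motion configs", {
  cfg <- tiny_config(seed = 3, n_frames = 50)
  traj <- withr::with_seed(3, random_walk_poses(cfg))
  expect_true(all(traj$x >= 0 & traj$x <= cfg$width - 1))
  expect_true(all(traj$y >= 0 & traj$y <= cfg$height - 1))
  expect_true(all(traj$a >= traj$b & traj$b > 0))
  expect_equal(nrow(traj), cfg$n_flies * cfg$n_frames)

  still <- withr::with_seed(3, random_walk_poses(tiny_config(step_sd = 0,
                                                             turn_sd = 0)))
  for (id in unique(still$fly_id)) {
    sub <- still[still$fly_id == id, ]
    expect_equal(var(sub$x), 0)
    expect_equal(var(sub$y), 0)
  }
  expect_error(random_walk_poses(scene_config(width = 20, height = 20,
                                              n_flies = 1)),
               "arena too small")
})

test_that("labeled composition puts round(gfp_fraction * n) GFP flies in the truth", {
  s <- make_scene(tiny_config(n_flies = 18, gfp_fraction = 0.5, seed = 9,
                              width = 320, height = 90))
  expect_equal(sum(s$truth == "GFP"), 9)
  expect_equal(sum(make_scene(tiny_config(gfp_fraction = 0.3, n_flies = 10,
                                          seed = 9, width = 320,
                                          height = 90))$truth == "GFP"), 3)
})

test_that("the brightest rendered pixel sits in the labeled body half", {
  cfg <- tiny_config()
  pose <- rec(50, 30, 0.6, 8, 3)
  half_of <- function(patch, placement) {
    idx <- which(patch == max(patch), arr.ind = TRUE)[1, ]
    px <- placement$col0 + idx["col"] - 1
    py <- placement$row0 + idx["row"] - 1
    dxy <- c(px - pose$x, py - pose$y)
    sum(dxy * c(cos(pose$theta), sin(pose$theta)))
  }
  cfg_no_abd <- tiny_config(abdomen_auto_amp = 0)
  p <- render_fly(pose, "GFP", cfg_no_abd)
  expect_gt(half_of(p$fluo, p), 0)  # anterior half

  cfg_no_eye <- tiny_config(eye_auto_amp = 0)
  p2 <- render_fly(pose, "non-GFP", cfg_no_eye)
  expect_lt(half_of(p2$fluo, p2), 0)  # posterior half

  # the label never affects the IR silhouette
  expect_identical(render_fly(pose, "GFP", cfg)$ir_mask,
                   render_fly(pose, "non-GFP", cfg)$ir_mask)
})

test_that("thoracic contrast monotonically drives the ratio metric apart", {
  mean_gap <- function(amp) {
    gaps <- vapply(1:20, function(seed) {
      s <- make_scene(scene_config(n_flies = 6, width = 220, height = 80,
                                   n_frames = 2, n_pre = 1,
                                   thorax_gfp_amp = amp, seed = seed))
      m <- fly_metrics(s$fluo, s$trajectories)
      tr <- s$truth[as.character(m$fly_id)]
      mean(m$max5_ratio[tr == "GFP"]) - mean(m$max5_ratio[tr == "non-GFP"])
    }, numeric(1))
    mean(gaps)
  }
  gaps <- vapply(c(30, 80, 160), mean_gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("removing marker contrast makes the classes indistinguishable", {
  # null model: anterior autofluorescence of unlabeled flies matches the
  # labeled flies' thoracic amplitude, and both match the abdomen
  vals <- lapply(1:12, function(seed) {
    s <- make_scene(scene_config(n_flies = 6, width = 220, height = 80,
                                 n_frames = 2, n_pre = 1,
                                 thorax_gfp_amp = 50, thorax_auto_amp = 50,
                                 abdomen_auto_amp = 50,
                                 eye_auto_amp = 0, seed = seed + 600))
    m <- fly_metrics(s$fluo, s$trajectories)
    tr <- s$truth[as.character(m$fly_id)]
    list(gfp = m$max5_ratio[tr == "GFP"], non = m$max5_ratio[tr == "non-GFP"])
  })
  gfp <- unlist(lapply(vals, `[[`, "gfp"))
  non <- unlist(lapply(vals, `[[`, "non"))
  expect_gt(stats::wilcox.test(gfp, non)$p.value, 0.01)
})

test_that("scene files round-trip through the standard formats", {
  s <- make_scene(tiny_config(seed = 77))
  dir <- withr::local_tempdir()
  write_scene(s, dir)
  expect_setequal(list.files(dir), c("ir.tiff", "fluo.tiff",
                                     "trajectories.csv", "truth.csv",
                                     "config.json"))
  back <- read_scene(dir, truth_required = TRUE)
  expect_identical(back$fluo$frames, s$fluo$frames)
  expect_equal(back$truth[names(s$truth)], s$truth)
  expect_equal(back$fluo$n_pre, s$fluo$n_pre)
  expect_lt(max(abs(back$trajectories$x - s$trajectories$x)), 1e-9)
})
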