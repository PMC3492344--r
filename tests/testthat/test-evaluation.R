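test_that("discrimination accuracy counts misassignments symmetrically", {
  truth <- stats::setNames(rep(c("GFP", "non-GFP"), each = 9), 0:17)
  calls <- data.frame(fly_id = 0:17, label = unname(truth))
  expect_equal(discrimination_accuracy(calls, truth)$overall, 100)

  calls$label[1] <- "non-GFP"  # one false negative
  acc <- discrimination_accuracy(calls, truth)
  expect_equal(acc$overall, 100 * 17 / 18)
  expect_equal(acc$gfp, 100 * 8 / 9)
  expect_equal(acc$non_gfp, 100)

  expect_error(discrimination_accuracy(data.frame(fly_id = 99, label = "GFP"),
                                       truth), "99")
})

test_that("accuracy is invariant to consistent fly id relabeling", {
  withr::with_seed(37, {
    truth <- stats::setNames(sample(rep(c("GFP", "non-GFP"), 9)), 0:17)
    calls <- data.frame(fly_id = 0:17,
                        label = sample(rep(c("GFP", "non-GFP"), 9)))
    a1 <- discrimination_accuracy(calls, truth)
    remap <- stats::setNames(sample(100:117), 0:17)
    calls2 <- transform(calls, fly_id = remap[as.character(fly_id)])
    truth2 <- stats::setNames(unname(truth), remap[names(truth)])
    expect_equal(discrimination_accuracy(calls2, truth2), a1)
  })
})

test_that("image selection alternates pre/post blocks starting with pre", {
  fi <- c(0:199, 1000:1199)
  st <- image_stack(lapply(seq_along(fi), function(i) matrix(0L, 2, 2)),
                    "FLUOR", frame_indices = fi, n_pre = 200L)
  expect_equal(select_images(st, 2, "alternate"), c(0, 1000))
  expect_equal(select_images(st, 3, "alternate"), c(0, 1000, 1))
  expect_equal(select_images(st, 6, "alternate"), c(0, 1000, 1, 1001, 2, 1002))
  expect_equal(select_images(st, 1, "end_only"), 1000)
  expect_equal(select_images(st, 3, "end_only"), c(1000, 1001, 1002))
  expect_error(select_images(st, 201, "end_only"), "post block")
  expect_error(select_images(st, 1000, "alternate"), "available")
})

test_that("end_only equals alternate when the pre block is empty", {
  st <- image_stack(lapply(1:10, function(i) matrix(0L, 2, 2)), "FLUOR",
                    n_pre = 0L)
  for (n in c(1, 3, 7)) {
    expect_equal(select_images(st, n, "alternate"),
                 select_images(st, n, "end_only"))
  }
})

make_calibrated_pair <- function(seed = 101, cfg_fun = scene_config, ...) {
  gfp <- make_scene(cfg_fun(gfp_fraction = 1, seed = seed, ...))
  non <- make_scene(cfg_fun(gfp_fraction = 0, seed = seed + 1, ...))
  m <- rbind(fly_metrics(gfp$fluo, gfp$trajectories),
             fly_metrics(non$fluo, non$trajectories))
  truth <- rep(c("GFP", "non-GFP"), each = nrow(m) / 2)
  calibrate(m, truth, weight_grid = seq(0, 1, 0.05), n_thresholds = 300)
}

test_that("accuracy curves hit 100% at every count on a clean separable scene", {
  # noiseless separable fixture: no pixel noise, no arena autofluorescence,
  # roomy arena so ROIs never overlap
  clean <- function(...) tiny_config(width = 300, height = 80, noise_sd = 0,
                                     n_autofluor_patches = 0, n_frames = 8,
                                     n_pre = 4, ...)
  cal <- make_calibrated_pair(cfg_fun = clean)
  het <- make_scene(clean(seed = 300))
  curve <- accuracy_vs_image_count(het$fluo, het$trajectories, het$truth, cal,
                                   counts = c(1, 2, 4, 8))
  expect_equal(nrow(curve), 4)
  expect_true(all(curve$overall == 100))
  curve_prior <- accuracy_vs_image_count(het$fluo, het$trajectories, het$truth,
                                         cal, counts = c(1, 2, 4, 8),
                                         prior = sum(het$truth == "GFP"))
  expect_true(all(curve_prior$overall == 100))
})

test_that("using the full stack reproduces the all-images accuracy exactly", {
  cal <- make_calibrated_pair(cfg_fun = tiny_config, n_frames = 6, n_pre = 3)
  het <- make_scene(tiny_config(seed = 400, n_frames = 6, n_pre = 3,
                                noise_sd = 25))
  m_all <- fly_metrics(het$fluo, het$trajectories)
  calls_all <- classify_by_threshold(score_flies(m_all, cal), cal$theta)
  acc_all <- discrimination_accuracy(calls_all, het$truth)$overall
  curve <- accuracy_vs_image_count(het$fluo, het$trajectories, het$truth, cal,
                                   counts = c(1, 6))
  expect_equal(curve$overall[curve$images == 6], acc_all)
})

test_that("heatmaps have the requested shape and prior cells use the count rule", {
  cal <- make_calibrated_pair(cfg_fun = tiny_config, n_frames = 4, n_pre = 2)
  het <- make_scene(tiny_config(seed = 500, n_frames = 4, n_pre = 2))
  wg <- cal$weight_grid[c(1, 11, 21)]  # 0, 0.5, 1
  hm <- accuracy_heatmap(het$fluo, het$trajectories, het$truth, cal,
                         weight_grid = wg, counts = c(1, 2, 4),
                         prior = sum(het$truth == "GFP"))
  expect_equal(dim(hm), c(3, 3))
  expect_true(all(hm >= 0 & hm <= 100))
  # prior mode forces exactly n_gfp GFP calls in every cell, so a clean
  # scene is perfect across the whole weight band
  expect_true(all(hm[3, ] == 100))
  hm_thr <- accuracy_heatmap(het$fluo, het$trajectories, het$truth, cal,
                             weight_grid = wg, counts = c(4))
  expect_equal(dim(hm_thr), c(1, 3))
})
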