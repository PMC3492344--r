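test_that("threshold sweep achieves perfect separation when classes separate", {
  scores <- c(2, 3, 0, 1)
  truth <- c("GFP", "GFP", "non-GFP", "non-GFP")
  sw <- sweep_thresholds(scores, truth, 1000)
  expect_length(sw$thresholds, 1000)
  expect_equal(max(sw$accuracy), 100)
  expect_false(sw$degenerate)
  # exhaustive check over all 4!/(2!2!) assignments of these scores
  for (gfp_pair in list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
    tr <- rep("non-GFP", 4)
    tr[gfp_pair] <- "GFP"
    sw2 <- sweep_thresholds(c(0, 1, 2, 3), tr, 200)
    separable <- identical(sort(c(0, 1, 2, 3)[gfp_pair]), c(2, 3))
    expect_equal(max(sw2$accuracy) == 100, separable)
  }
})

test_that("identical scores yield the degenerate chance-level sweep", {
  sw <- sweep_thresholds(rep(1.5, 18), rep(c("GFP", "non-GFP"), 9), 100)
  expect_true(sw$degenerate)
  expect_true(all(sw$accuracy == 50))
})

test_that("the GFP call is inclusive at the threshold boundary", {
  sw <- sweep_thresholds(c(1, 2), c("non-GFP", "GFP"), 2)
  # at theta == 2 the score-2 fly is still GFP -> both correct
  expect_equal(sw$accuracy[2], 100)
})

test_that("best_threshold returns the widest-plateau midpoint", {
  thr <- seq(0, 1, length.out = 21)
  acc <- rep(50, 21)
  acc[8] <- 90
  expect_equal(best_threshold(thr, acc), thr[8])
  acc <- rep(50, 21)
  acc[11:21] <- 90
  expect_equal(best_threshold(thr, acc), thr[16])
  # plateaus of lengths 3 and 9: the long one wins
  acc <- rep(50, 21)
  acc[2:4] <- 90
  acc[10:18] <- 90
  expect_equal(best_threshold(thr, acc), thr[14])
})

test_that("label swap complements accuracy on tie-free scores", {
  withr::with_seed(31, {
    scores <- runif(40)
    truth <- sample(rep(c("GFP", "non-GFP"), 20))
    flipped <- ifelse(truth == "GFP", "non-GFP", "GFP")
    # evaluate off-grid thresholds so no score sits exactly on a threshold
    thr <- sort(runif(50, min(scores) + 1e-6, max(scores) - 1e-6))
    acc <- 100 * colMeans(outer(scores, thr, ">=") == (truth == "GFP"))
    acc_f <- 100 * colMeans(outer(scores, thr, ">=") == (flipped == "GFP"))
    expect_equal(acc + acc_f, rep(100, 50))
  })
})

test_that("landscape endpoints reproduce the single-metric sweeps", {
  withr::with_seed(8, {
    m1 <- c(rnorm(20, 5), rnorm(20, 2))
    m2 <- c(rnorm(20, 1), rnorm(20, 0.5))
    truth <- rep(c("GFP", "non-GFP"), each = 20)
    land <- weight_threshold_landscape(m1, m2, truth,
                                       weight_grid = c(0, 0.5, 1),
                                       n_thresholds = 300)
    expect_equal(dim(land$accuracy), c(3, 300))
    n2 <- normalize_metric(m2, range(m2))
    sw2 <- sweep_thresholds(n2, truth, 300)
    expect_equal(land$accuracy[1, ], sw2$accuracy)
    n1 <- normalize_metric(m1, range(m1))
    sw1 <- sweep_thresholds(n1, truth, 300)
    expect_equal(land$accuracy[3, ], sw1$accuracy)
    # combination never loses to the better single metric
    expect_gte(max(land$accuracy), max(sw1$accuracy))
    expect_gte(max(land$accuracy), max(sw2$accuracy))
  })
})

test_that("separable classes give a 100% landscape and a threshold between the classes", {
  m1 <- c(4, 5, 6, 1, 1.5, 2)
  m2 <- c(10, 12, 11, 3, 2, 4)
  truth <- rep(c("GFP", "non-GFP"), each = 3)
  land <- weight_threshold_landscape(m1, m2, truth, seq(0, 1, 0.1), 500)
  expect_true(all(apply(land$accuracy, 1, max) == 100))
  sel <- select_robust_operating_point(land)
  scores <- combined_score(m1, m2, sel$w, land$norm_ranges[[1]],
                           land$norm_ranges[[2]])
  expect_true(sel$theta > max(scores[truth == "non-GFP"]))
  expect_true(sel$theta <= min(scores[truth == "GFP"]))
  calls <- classify_by_threshold(data.frame(fly_id = 0:5, score = scores),
                                 sel$theta)
  expect_equal(discrimination_accuracy(calls,
                                       stats::setNames(truth, 0:5))$overall, 100)
})

test_that("operating-point selection prefers the widest maximum-accuracy run", {
  acc <- matrix(50, 3, 30)
  acc[1, 5:9] <- 95      # run of 5
  acc[2, 10:21] <- 95    # run of 12 -> winner
  thr <- matrix(rep(seq(0, 1, length.out = 30), each = 3), 3)
  land <- structure(list(weights = c(0.2, 0.4, 0.7), thresholds = thr,
                         accuracy = acc,
                         norm_ranges = list(a = c(0, 1), b = c(0, 1)),
                         metric_names = c("a", "b")),
                    class = "calibration_landscape")
  sel <- select_robust_operating_point(land)
  expect_equal(sel$w, 0.4)
  expect_equal(sel$run_length, 12)
  expect_equal(sel$theta, (thr[2, 10] + thr[2, 21]) / 2)

  # a uniformly maximal landscape ties down to the smallest weight and the
  # global threshold midpoint
  acc[] <- 100
  land$accuracy <- acc
  sel <- select_robust_operating_point(land)
  expect_equal(sel$w, 0.2)
  expect_equal(sel$theta, 0.5)

  # single global-max cell
  acc[] <- 50
  acc[3, 17] <- 99
  land$accuracy <- acc
  sel <- select_robust_operating_point(land)
  expect_equal(sel$w, 0.7)
  expect_equal(sel$theta, thr[3, 17])
})

test_that("calibration persists and reloads reproducibly as JSON", {
  withr::with_seed(12, {
    m <- data.frame(fly_id = 0:35,
                    max5_ratio = c(rnorm(18, 2.5, 0.2), rnorm(18, 0.8, 0.2)),
                    skewness = c(rnorm(18, 1.5, 0.3), rnorm(18, 0.7, 0.3)))
    truth <- rep(c("GFP", "non-GFP"), each = 18)
    cal <- calibrate(m, truth, weight_grid = seq(0, 1, 0.05), n_thresholds = 200)
    expect_s3_class(cal, "fluor_calibration")
    expect_equal(cal$max_accuracy, 100)
    path <- withr::local_tempfile(fileext = ".json")
    write_calibration(cal, path)
    back <- read_calibration(path)
    expect_equal(back$w, cal$w)
    expect_equal(back$theta, cal$theta)
    expect_equal(back$norm_ranges$max5_ratio, cal$norm_ranges$max5_ratio)
    s1 <- score_flies(m, cal)
    s2 <- score_flies(m, back)
    expect_equal(s1$score, s2$score)
  })
})

test_that("single-class calibration input is rejected", {
  expect_error(sweep_thresholds(1:4, rep("GFP", 4)), "each class")
})
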