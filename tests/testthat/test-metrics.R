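# Evaluation metrics: Dice, Hausdorff distances and the confusion panel.

test_that("dsc_metric handles identity, partial overlap, disjoint and empty
           masks", {
  m <- matrix(0L, 6, 6)
  a <- m; a[2:4, 2:4] <- 1L
  expect_equal(dsc_metric(a, a), 1)
  # |P| = 8, |L| = 10, |P inter L| = 6 -> 12/18
  p <- matrix(0L, 1, 20); l <- matrix(0L, 1, 20)
  p[1, 1:8] <- 1L; l[1, 3:12] <- 1L
  expect_equal(dsc_metric(p, l), 12 / 18)
  b <- m; b[5:6, 5:6] <- 1L
  expect_equal(dsc_metric(a, b), 0)
  expect_equal(dsc_metric(m, m), 1) # both empty
  expect_equal(dsc_metric(a, m), 0) # one empty
})

test_that("dsc equals 2 IoU / (1 + IoU) on binary masks", {
  set.seed(71)
  for (rep in 1:20) {
    p <- matrix(sample(0:1, 64, TRUE), 8)
    l <- matrix(sample(0:1, 64, TRUE), 8)
    if (sum(p) + sum(l) == 0) next
    iou <- confusion_metrics(p, l)$iou
    expect_equal(dsc_metric(p, l), 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("hausdorff: identity zero, 3-4-5 geometry, symmetry", {
  a <- matrix(0L, 8, 8); a[2:4, 2:4] <- 1L
  expect_equal(hausdorff(a, a), 0)
  p <- matrix(0L, 6, 6); l <- matrix(0L, 6, 6)
  p[1, 1] <- 1L; l[4, 5] <- 1L # single pixels at (0,0) and (3,4)
  expect_equal(hausdorff(p, l), 5)
  set.seed(72)
  x <- matrix(rbinom(100, 1, 0.3), 10)
  y <- matrix(rbinom(100, 1, 0.3), 10)
  expect_equal(hausdorff(x, y), hausdorff(y, x))
  expect_warning(h <- hausdorff(matrix(0L, 8, 8), a), "empty boundary")
  expect_true(is.na(h))
})

test_that("percentile Hausdorff is bounded by the maximum, against a
           brute-force oracle", {
  set.seed(73)
  for (rep in 1:40) {
    p <- matrix(rbinom(144, 1, 0.25), 12)
    l <- matrix(rbinom(144, 1, 0.25), 12)
    if (sum(p) == 0 || sum(l) == 0) next
    hd <- hausdorff(p, l, 100)
    hd95 <- hausdorff(p, l, 95)
    expect_lte(hd95, hd + 1e-12)
    # independent brute-force directed distances over boundary pixels
    bp <- boundary_points(p == 1); bl <- boundary_points(l == 1)
    dPL <- vapply(seq_len(nrow(bp)), function(i)
      sqrt(min((bp[i, 1] - bl[, 1])^2 + (bp[i, 2] - bl[, 2])^2)), 0)
    dLP <- vapply(seq_len(nrow(bl)), function(i)
      sqrt(min((bl[i, 1] - bp[, 1])^2 + (bl[i, 2] - bp[, 2])^2)), 0)
    expect_equal(hd, max(max(dPL), max(dLP)), tolerance = 1e-12)
    expect_equal(hd95, max(stats::quantile(dPL, 0.95, names = FALSE),
                           stats::quantile(dLP, 0.95, names = FALSE)),
                 tolerance = 1e-12)
  }
})

test_that("confusion metrics reproduce the counting oracle", {
  # TP = 8, FP = 2, FN = 1, TN = 89 on a 100-pixel image
  truth <- matrix(0L, 10, 10); truth[1, 1:9] <- 1L
  pred <- matrix(0L, 10, 10); pred[1, 1:8] <- 1L; pred[2, 1:2] <- 1L
  cm <- confusion_metrics(pred, truth)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(8L, 2L, 1L, 89L))
  expect_equal(cm$ac, 0.97)
  expect_equal(cm$pr, 0.8)
  expect_equal(cm$se, 0.8889, tolerance = 1e-4)
  expect_equal(cm$sp, 0.9780, tolerance = 1e-4)
  expect_equal(cm$iou, 0.7273, tolerance = 1e-4)
  perfect <- confusion_metrics(truth, truth)
  expect_true(all(unlist(perfect[c("ac", "pr", "se", "sp", "iou")]) == 1))
  allbg <- confusion_metrics(matrix(0L, 10, 10), truth)
  expect_equal(allbg$se, 0)
  expect_true(is.na(allbg$pr)) # no predicted positives
})

test_that("metrics are invariant under a simultaneous horizontal flip", {
  set.seed(74)
  p <- matrix(rbinom(144, 1, 0.3), 12)
  l <- matrix(rbinom(144, 1, 0.3), 12)
  fp <- p[, 12:1]; fl <- l[, 12:1]
  expect_equal(dsc_metric(p, l), dsc_metric(fp, fl))
  expect_equal(hausdorff(p, l), hausdorff(fp, fl))
  expect_equal(hausdorff(p, l, 95), hausdorff(fp, fl, 95))
  expect_equal(unlist(confusion_metrics(p, l)),
               unlist(confusion_metrics(fp, fl)))
})

test_that("segmentation_report covers per-slice and stacked-volume modes", {
  set.seed(75)
  masks <- lapply(1:4, function(i) {
    m <- matrix(0L, 8, 8); m[2:5, 2:5] <- 1L; m[6:7, 6:7] <- 2L; m
  })
  rep_ <- segmentation_report(masks, masks, num_classes = 3L)
  expect_identical(nrow(rep_), 4L * 2L) # num_classes - 1 foreground rows each
  expect_true(all(rep_$dsc == 1))
  expect_true(all(rep_$hd == 0))
  s <- summarize_report(rep_)
  expect_equal(s$mean_dsc, 1)
  vol <- segmentation_report(masks, masks, 3L, mode = "volume",
                             case_ids = c(1, 1, 2, 2))
  expect_identical(nrow(vol), 2L * 2L)
  expect_true(all(vol$dsc == 1))
  # spacing scales distances
  p <- matrix(0L, 6, 6); l <- matrix(0L, 6, 6)
  p[1, 1] <- 1L; l[1, 3] <- 1L
  expect_equal(hausdorff(p, l, spacing = c(1, 2.5)), 5)
})
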