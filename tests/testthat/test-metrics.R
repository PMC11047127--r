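test_that("binarize applies the inclusive 0.5 tie rule and validates the threshold", {
  expect_true(binarize(0.5))
  expect_false(binarize(0.4999))
  expect_true(all(binarize(array(1, c(2, 2, 2)))))
  expect_error(binarize(0.3, threshold = 0), class = "afms_validation_error")
  expect_error(binarize(0.3, threshold = 1), class = "afms_validation_error")
  expect_error(binarize(2), class = "afms_validation_error")
})

test_that("confusion counts and overlap metrics reproduce the hand-worked example", {
  # 10-voxel universe, pred = {1,2,3}, truth = {2,3,4}
  pred <- array(FALSE, c(10, 1, 1)); pred[1:3, , ] <- TRUE
  truth <- array(FALSE, c(10, 1, 1)); truth[2:4, , ] <- TRUE
  cc <- confusion_counts(pred, truth)
  expect_equal(cc$tp, 2); expect_equal(cc$fp, 1)
  expect_equal(cc$fn, 1); expect_equal(cc$tn, 6)
  om <- overlap_metrics(cc)
  expect_equal(om$accuracy, 0.8)
  expect_equal(om$precision, 2 / 3)
  expect_equal(om$recall, 2 / 3)
  expect_equal(om$dsc, 2 / 3)
  expect_equal(om$iou, 0.5)
})

test_that("confusion identities: equality and complement", {
  m <- array(runif(4^3) > 0.5, c(4, 4, 4))
  cc <- confusion_counts(m, m)
  expect_equal(cc$fp + cc$fn, 0)
  expect_equal(overlap_metrics(cc)$dsc, 1)
  expect_true(all(unlist(overlap_metrics(cc)[, c("accuracy", "precision", "recall", "dsc", "iou")]) == 1))
  cc2 <- confusion_counts(!m, m)
  expect_equal(cc2$tp + cc2$tn, 0)
  expect_error(confusion_counts(m, m[1:2, , ]), class = "afms_validation_error")
})

test_that("dsc = 2*iou/(1+iou) and dsc >= iou over random confusion counts", {
  set.seed(31)
  for (rep in 1:100) {
    cc <- list(tp = sample(0:50, 1), tn = sample(0:50, 1),
               fp = sample(0:50, 1), fn = sample(0:50, 1))
    if (sum(unlist(cc)) == 0) cc$tn <- 1
    om <- overlap_metrics(cc)
    expect_equal(om$dsc, 2 * om$iou / (1 + om$iou), tolerance = 1e-12)
    expect_gte(om$dsc, om$iou)
    if (cc$fp == 0 && cc$fn == 0) expect_equal(om$accuracy, 1)
    if (om$accuracy == 1) expect_equal(cc$fp + cc$fn, 0)
  }
  expect_error(overlap_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               class = "afms_validation_error")
})

test_that("average Hausdorff distance reproduces hand cases and respects spacing", {
  p1 <- matrix(c(0, 0, 0), 1)
  l1 <- matrix(c(3, 0, 0), 1)
  expect_equal(average_hausdorff(p1, l1), 3.0)
  p2 <- matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE)
  l2 <- matrix(c(1, 0, 0), 1)
  expect_equal(average_hausdorff(p2, l2), 0.25)  # 0.5*(0.5 + 0)
  expect_equal(average_hausdorff(p1, l1, spacing = c(2, 1, 1)), 6.0)
  expect_equal(average_hausdorff(p1, p1), 0)
})

test_that("AHD is symmetric and matches the brute-force double loop", {
  set.seed(32)
  for (rep in 1:50) {
    P <- unique(matrix(sample(0:9, 3 * sample(1:40, 1), replace = TRUE), ncol = 3))
    L <- unique(matrix(sample(0:9, 3 * sample(1:40, 1), replace = TRUE), ncol = 3))
    sp <- runif(3, 0.5, 2)
    a <- average_hausdorff(P, L, spacing = sp)
    expect_lt(abs(a - oracle_ahd(P, L, sp)), 1e-9)
    expect_equal(a, average_hausdorff(L, P, spacing = sp), tolerance = 1e-12)
  }
})

test_that("AHD degenerate conventions: empty sets flag and penalize", {
  m0 <- array(FALSE, c(4, 4, 4))
  m1 <- m0; m1[2, 2, 2] <- TRUE
  expect_warning(r00 <- average_hausdorff(m0, m0))
  expect_equal(as.numeric(r00), 0)
  expect_true(attr(r00, "degenerate"))
  expect_warning(r10 <- average_hausdorff(m1, m0))
  expect_equal(as.numeric(r10), sqrt(sum(c(4, 4, 4)^2)))  # grid diagonal
})

test_that("AHD mask mode equals coordinate mode, and surface mode drops interior voxels", {
  m <- array(FALSE, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- TRUE
  t <- array(FALSE, c(8, 8, 8)); t[4:7, 3:6, 3:6] <- TRUE
  co <- average_hausdorff(afmsnet:::mask_points(m), afmsnet:::mask_points(t))
  expect_equal(average_hausdorff(m, t), co, tolerance = 1e-12)
  expect_identical(average_hausdorff(m, m, mode = "surface"), 0)
  sv <- afmsnet:::surface_voxels(m)
  expect_equal(sum(sv), sum(m) - 2^3)  # 4^3 cube has a 2^3 interior
})

test_that("region masks follow the BraTS nesting and validate raw labels", {
  lab <- array(0L, c(4, 4, 4))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 2L; lab[3, 1, 1] <- 4L
  masks <- region_binary_masks(lab)
  expect_equal(sum(masks$WT), 3)
  expect_equal(sum(masks$TC), 2)            # NCR + ET
  expect_equal(sum(masks$ET), 1)
  expect_true(all(masks$ET[lab == 4]))
  # paper-literal TC definition: ED + NCR
  lit <- region_binary_masks(lab, brats_regions(tc_literal = TRUE))
  expect_true(lit$TC[1, 1, 1] && lit$TC[2, 1, 1] && !lit$TC[3, 1, 1])
  err <- tryCatch(region_binary_masks(array(7L, c(2, 2, 2))), error = identity)
  expect_s3_class(err, "afms_validation_error")
  expect_match(conditionMessage(err), "7")
  empty <- region_binary_masks(array(0L, c(2, 2, 2)))
  expect_true(all(!unlist(empty)))
  # singleton ET voxel
  one <- array(0L, c(2, 2, 2)); one[1, 1, 1] <- 4L
  ms <- region_binary_masks(one)
  expect_equal(sum(ms$ET), 1); expect_equal(sum(ms$TC), 1)
})

test_that("metrics_report aggregates classes and regions with mean IoU over foreground", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:4, 2:4, 2:4] <- 1L; lab[3, 3, 3] <- 2L
  pred <- lab; pred[4, 4, 4] <- 0L  # one missed voxel of class 1
  rep_ <- metrics_report(pred, lab)
  expect_s3_class(rep_, "afms_metrics_report")
  expect_setequal(rep_$unit, c("class_1", "class_2"))
  cls1 <- rep_[rep_$unit == "class_1", ]
  expect_lt(cls1$dsc, 1); expect_gt(cls1$dsc, 0.9)
  expect_equal(rep_$dsc[rep_$unit == "class_2"], 1)
  expect_equal(attr(rep_, "mean_iou"), mean(rep_$iou), tolerance = 1e-12)
  # identity report: everything perfect
  perfect <- metrics_report(lab, lab, regions = list(FG = c(1L, 2L)))
  expect_true(all(perfect$dsc == 1))
  expect_true(all(perfect$ahd == 0))
  g <- generics::glance(perfect)
  expect_equal(g$mean_iou, 1)
  # serialization round trip
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics_report(perfect, json = js, csv = csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(perfect))
  expect_equal(jsonlite::read_json(js)$mean_iou, 1)
})

test_that("metrics are invariant under a joint voxel permutation", {
  set.seed(33)
  pred <- array(runif(5^3) > 0.6, c(5, 5, 5))
  truth <- array(runif(5^3) > 0.6, c(5, 5, 5))
  perm <- sample(5^3)
  om1 <- overlap_metrics(confusion_counts(pred, truth))
  om2 <- overlap_metrics(confusion_counts(array(pred[perm], dim(pred)),
                                          array(truth[perm], dim(truth))))
  expect_equal(om1, om2)
})
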