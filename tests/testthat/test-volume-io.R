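test_that("NIfTI write/read round-trips arrays and spacing", {
  set.seed(41)
  rec <- volume_record(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1, 1.5, 2),
                       id = "rt")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(rec, path)
  back <- read_volume(path)
  expect_equal(array(back$image, c(8, 8, 8)), array(rec$image, c(8, 8, 8)))
  expect_equal(back$spacing, rec$spacing)
  # 4D multi-channel
  rec4 <- volume_record(array(rnorm(4^3 * 3), c(4, 4, 4, 3)))
  p4 <- tempfile(fileext = ".nii.gz")
  write_volume(rec4, p4)
  expect_equal(dim(read_volume(p4)$image), c(4, 4, 4, 3))
  err <- tryCatch(read_volume("/nonexistent/vol.nii.gz"), error = identity)
  expect_s3_class(err, "afms_io_error")
  expect_match(conditionMessage(err), "/nonexistent/vol.nii.gz", fixed = TRUE)
})

test_that("central crop keeps the stated half-open window, dropping the extra high voxel", {
  img <- array(seq_len(24^3), c(24, 24, 24))
  rec <- volume_record(img, labels = array(1L, c(24, 24, 24)))
  cr <- central_crop(rec, c(16, 16, 16))
  # kept 0-based range [4, 20) per axis -> 1-based 5:20
  expect_equal(array(cr$image, c(16, 16, 16)), img[5:20, 5:20, 5:20])
  expect_equal(dim(cr$labels), c(16, 16, 16))
  odd <- volume_record(array(seq_len(25^3), c(25, 25, 25)))
  cro <- central_crop(odd, c(16, 16, 16))
  expect_equal(array(cro$image, c(16, 16, 16)),
               array(odd$image, c(25, 25, 25))[5:20, 5:20, 5:20])
  same <- central_crop(rec, c(24, 24, 24))
  expect_equal(same$image, rec$image)
  expect_error(central_crop(rec, c(30, 16, 16)), class = "afms_validation_error")
})

test_that("central crop then symmetric pad restores the original window", {
  set.seed(42)
  rec <- volume_record(array(rnorm(12^3), c(12, 12, 12)),
                       labels = array(sample(0:2, 12^3, TRUE), c(12, 12, 12)))
  cr <- central_crop(rec, c(8, 8, 8))
  pd <- central_pad(cr, c(12, 12, 12))
  expect_equal(dim(pd$image)[1:3], c(12, 12, 12))
  expect_equal(pd$image[3:10, 3:10, 3:10, ], rec$image[3:10, 3:10, 3:10, ])
  expect_true(all(pd$image[1:2, , , ] == 0))
})

test_that("resampling: identity, constants, and the closed-form ramp", {
  rec <- volume_record(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1, 1, 1))
  same <- resample_volume(rec, target_spacing = c(1, 1, 1))
  expect_lt(max(abs(same$image - rec$image)), 1e-6)
  const <- volume_record(array(3.5, c(8, 8, 8)))
  down <- resample_volume(const, target_shape = c(4, 4, 4))
  expect_lt(max(abs(down$image - 3.5)), 1e-12)
  expect_equal(down$spacing, c(2, 2, 2))
  # linear ramp v[x] = x (0-based): trilinear value at coordinate c is c,
  # and output voxel i samples c = (i + 0.5) * S_in/S_out - 0.5
  ramp <- volume_record(array(rep(0:15, times = 16), c(16, 4, 4)))
  half <- resample_volume(ramp, target_shape = c(8, 4, 4))
  want <- (seq_len(8) - 0.5) * 2 - 0.5
  expect_equal(as.vector(half$image[, 1, 1, 1]), want, tolerance = 1e-12)
  # labels resample nearest-neighbour: no new values
  lab <- array(sample(c(0L, 1L, 4L), 8^3, TRUE), c(8, 8, 8))
  lrec <- volume_record(array(rnorm(8^3), c(8, 8, 8)), labels = lab)
  lres <- resample_volume(lrec, target_shape = c(5, 5, 5))
  expect_true(all(unique(as.vector(lres$labels)) %in% unique(as.vector(lab))))
  expect_error(resample_volume(rec, target_spacing = c(0, 1, 1)),
               class = "afms_validation_error")
  expect_error(resample_volume(rec), class = "afms_validation_error")
})

test_that("z-score normalization acts on the nonzero support and is idempotent", {
  set.seed(43)
  img <- array(0, c(8, 8, 8))
  sup <- sample(8^3, 300)
  img[sup] <- rnorm(300, mean = 5, sd = 2)
  rec <- normalize_volume(volume_record(img))
  v <- rec$image[, , , 1][sup]
  expect_lt(abs(mean(v)), 1e-5)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-5)
  expect_true(all(rec$image[, , , 1][-sup] == 0))
  again <- normalize_volume(rec)
  expect_lt(max(abs(again$image - rec$image)), 1e-5)
  expect_warning(z <- normalize_volume(volume_record(array(0, c(4, 4, 4)))))
  expect_true(all(z$image == 0))
})

test_that("Gaussian smoothing: identity at sigma 0, constants preserved, impulse matches dense oracle", {
  rec <- volume_record(array(rnorm(6^3), c(6, 6, 6)))
  expect_identical(gaussian_smooth(rec, 0)$image, rec$image)
  const <- volume_record(array(2.5, c(8, 8, 8)))
  expect_lt(max(abs(gaussian_smooth(const, 1.2)$image - 2.5)), 1e-12)
  # central unit impulse vs direct dense 3D convolution with the same kernel
  n <- 11
  imp <- array(0, c(n, n, n)); imp[6, 6, 6] <- 1
  sm <- gaussian_smooth(volume_record(imp), 1)$image[, , , 1]
  k1 <- afmsnet:::gauss_kernel(1)
  k3 <- outer(outer(k1, k1), k1)
  dim(k3) <- c(length(k1), length(k1), length(k1))
  r <- (length(k1) - 1) / 2
  want <- array(0, c(n, n, n))
  for (a in -r:r) for (b in -r:r) for (cc in -r:r)
    want[6 + a, 6 + b, 6 + cc] <- k3[a + r + 1, b + r + 1, cc + r + 1]
  expect_lt(max(abs(sm - want)), 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_error(gaussian_smooth(rec, -1), class = "afms_validation_error")
})

test_that("one-hot encoding remaps sparse raw labels and partitions unity", {
  lab <- array(c(0L, 1L, 2L, 4L, 4L, 0L, 1L, 2L), c(2, 2, 2))
  oh <- one_hot_labels(lab)
  expect_equal(dim(oh), c(2, 2, 2, 4))
  expect_true(all(apply(oh, 1:3, sum) == 1))
  expect_equal(oh[2, 2, 1, 4], 1)  # raw 4 -> channel 4 (class index 3)
  expect_equal(oh[1, 1, 2, 4], 1)
  expect_error(one_hot_labels(lab, label_values = c(0, 1, 2)),
               class = "afms_validation_error")
})

test_that("modality fusion stacks channels in declared order", {
  m <- lapply(1:3, function(i) array(i, c(4, 4, 4)))
  lab <- array(0L, c(4, 4, 4)); lab[1, 1, 1] <- 1L
  fused <- one_hot_and_fuse(m, lab)
  expect_equal(dim(fused$image), c(4, 4, 4, 3))
  for (i in 1:3) expect_true(all(fused$image[, , , i] == i))
  expect_true(all(apply(fused$onehot, 1:3, sum) == 1))
  m_bad <- c(m[1:2], list(array(0, c(5, 4, 4))))
  expect_error(one_hot_and_fuse(m_bad, lab), class = "afms_validation_error")
})

test_that("the low-label filter discards strictly-below-1% volumes and keeps the boundary", {
  mk <- function(nfg) {
    lab <- array(0L, c(10, 10, 10))
    if (nfg > 0) lab[seq_len(nfg)] <- 1L
    volume_record(array(0, c(10, 10, 10)), labels = lab, id = paste0("v", nfg))
  }
  recs <- list(mk(9), mk(10), mk(11), mk(1000))  # 0.9%, exactly 1%, 1.1%, 100%
  kept <- low_label_filter(recs, fraction = 0.01)
  expect_equal(vapply(kept, function(r) r$id, character(1)), c("v10", "v11", "v1000"))
  expect_equal(foreground_fraction(recs[[2]]), 0.01)
})

test_that("dataset splits are deterministic, disjoint, exhaustive, floor-then-remainder", {
  ids <- sprintf("case%02d", 1:10)
  sp <- dataset_split(ids, seed = 5)
  expect_equal(lengths(sp), c(train = 8L, validation = 1L, test = 1L))
  expect_identical(sp, dataset_split(ids, seed = 5))
  expect_false(identical(sp, dataset_split(ids, seed = 6)))
  expect_setequal(unlist(sp), ids)
  expect_equal(anyDuplicated(unlist(sp)), 0)
  big <- dataset_split(as.character(1:246), seed = 1)
  expect_equal(lengths(big), c(train = 198L, validation = 24L, test = 24L))
  expect_error(dataset_split(c("a", "b"), seed = 1), class = "afms_validation_error")
  expect_error(dataset_split(ids, fractions = c(0.5, 0.5, 0.5), seed = 1),
               class = "afms_validation_error")
})

test_that("transforms never invent label values", {
  set.seed(44)
  lab <- array(sample(c(0L, 1L, 2L), 12^3, TRUE, prob = c(.8, .1, .1)), c(12, 12, 12))
  rec <- volume_record(array(rnorm(12^3), c(12, 12, 12)), labels = lab)
  vals <- sort(unique(as.vector(lab)))
  chain <- gaussian_smooth(normalize_volume(central_crop(rec, c(8, 8, 8))), 0.5)
  expect_true(all(unique(as.vector(chain$labels)) %in% vals))
  res <- resample_volume(rec, target_shape = c(9, 9, 9))
  expect_true(all(unique(as.vector(res$labels)) %in% vals))
})
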