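tiny_phantom <- function(seed, grid = 16) {
  rec <- generate_phantom(phantom_spec(grid = rep(grid, 3), n_channels = 1,
                                       n_lesions = c(1, 1), radii = c(3, 4),
                                       nested_factors = 1, noise_sd = 0.05,
                                       seed = seed))
  normalize_volume(rec)
}

tiny_net <- function(seed = 1) {
  build_network(network_spec("SAEB", n_stages = 2, base_channels = 4,
                             n_classes = 2, input_channels = 1,
                             segpath_iterations = c(1, 0)), seed = seed)
}

test_that("a few Adam steps reduce the training loss on a tiny phantom", {
  rec <- tiny_phantom(1)
  net <- train_network(tiny_net(), list(rec), epochs = 12, lr = 1e-3)
  h <- attr(net, "history")
  expect_s3_class(h, "afms_history")
  expect_equal(nrow(h), 12)
  expect_lt(h$train_loss[12], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
})

test_that("training configuration is validated", {
  rec <- tiny_phantom(1)
  expect_error(train_network(tiny_net(), list(rec), epochs = 0),
               class = "afms_validation_error")
  expect_error(train_network(tiny_net(), list(rec), epochs = 1, lr = 0),
               class = "afms_validation_error")
  expect_error(train_network(tiny_net(), list(rec), epochs = 1, weight_decay = -1),
               class = "afms_validation_error")
  norec <- tiny_phantom(1); norec$labels <- NULL
  expect_error(train_network(tiny_net(), list(norec), epochs = 1),
               class = "afms_validation_error")
})

test_that("the returned checkpoint is the best-validation one", {
  tr <- tiny_phantom(2)
  vr <- tiny_phantom(3)
  net <- train_network(tiny_net(), list(tr), list(vr), epochs = 8, lr = 1e-3)
  h <- attr(net, "history")
  # recompute validation loss of the returned parameters
  pr <- afmsnet:::record_to_pair(vr, 2, 0:1)
  P <- afmsnet:::net_forward(net, pr$x, training = FALSE)
  vbest <- total_loss(pr$g, P)
  expect_lte(vbest, min(h$val_loss) + 1e-8)
  expect_lte(vbest, h$val_loss[nrow(h)] + 1e-8)
})

test_that("prediction is deterministic, normalized, and maps back to raw label values", {
  rec <- tiny_phantom(4)
  net <- tiny_net()
  invisible(network_forward(net, afmsnet:::record_to_pair(rec, 2, 0:1)$x,
                            training = TRUE))  # populate running stats
  p1 <- predict_volume(net, rec, label_values = c(0L, 4L))
  p2 <- predict_volume(net, rec, label_values = c(0L, 4L))
  expect_identical(p1, p2)
  expect_true(all(p1$labels %in% c(0L, 4L)))
  sums <- apply(p1$prob, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_equal(dim(p1$labels), dim(rec$labels))
  wrong <- generate_phantom(phantom_spec(grid = c(16, 16, 16), n_channels = 2,
                                         radii = c(3, 4), seed = 1))
  expect_error(predict_volume(net, wrong), class = "afms_validation_error")
})

test_that("evaluation aggregates match hand recomputation and the identity case is perfect", {
  recs <- lapply(5:6, tiny_phantom)
  net <- tiny_net()
  ev <- evaluate_network(net, recs)
  expect_equal(nrow(ev$per_case), 2)
  expect_equal(ev$macro$dsc_mean[ev$macro$unit == "class_1"],
               mean(ev$per_case$dsc[ev$per_case$unit == "class_1"]),
               tolerance = 1e-12)
  cc_pool <- colSums(ev$per_case[ev$per_case$unit == "class_1", c("tp", "tn", "fp", "fn")])
  micro <- ev$micro[ev$micro$unit == "class_1", ]
  expect_equal(micro$iou,
               as.numeric(cc_pool["tp"] / (cc_pool["tp"] + cc_pool["fp"] + cc_pool["fn"])),
               tolerance = 1e-12)
  # ground truth against itself
  self_rep <- metrics_report(recs[[1]]$labels, recs[[1]]$labels)
  expect_true(all(self_rep$dsc == 1))
  expect_true(all(self_rep$iou == 1))
  expect_true(all(self_rep$ahd == 0))
  norec <- recs; norec[[1]]$labels <- NULL
  expect_error(evaluate_network(net, norec), class = "afms_validation_error")
})

test_that("run configuration files parse into the package specs", {
  cfgfile <- tempfile(fileext = ".yaml")
  writeLines(c(
    "network:",
    "  variant: DAEB",
    "  n_stages: 2",
    "  base_channels: 4",
    "  n_classes: 2",
    "  input_channels: 1",
    "  spatial_kernel: 3",
    "loss:",
    "  gamma: 2.0",
    "phantom:",
    "  grid: [16, 16, 16]",
    "  n_channels: 1",
    "  radii: [3, 4]",
    "  seed: 3",
    "train:",
    "  lr: 0.0001",
    "  weight_decay: 0.0005",
    "  epochs: 2",
    "preprocess:",
    "  normalize: true",
    "  smooth_sigma: 0.5"), cfgfile)
  cfg <- read_run_config(cfgfile)
  expect_s3_class(cfg$network, "afms_spec")
  expect_identical(cfg$network$variant, "DAEB")
  expect_equal(cfg$loss$gamma, 2)
  expect_s3_class(cfg$phantom, "afms_phantom_spec")
  expect_equal(cfg$train$lr, 1e-4)
  rec <- generate_phantom(cfg$phantom)
  pp <- apply_preprocess(rec, cfg$preprocess)
  expect_equal(dim(pp$image), dim(rec$image))
  expect_error(read_run_config(tempfile()), class = "afms_io_error")
})

test_that("training history plots without error", {
  rec <- tiny_phantom(7)
  net <- train_network(tiny_net(), list(rec), epochs = 3, lr = 1e-3)
  p <- ggplot2::autoplot(attr(net, "history"))
  expect_s3_class(p, "ggplot")
  g <- generics::glance(net)
  expect_equal(g$n_parameters, count_parameters(net))
})
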