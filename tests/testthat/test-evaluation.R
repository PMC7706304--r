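test_that("confusion tallies match hand counts on small fixtures", {
  truth <- binary_mask(matrix(0L, 4, 4))
  truth[1, 1] <- truth[1, 2] <- truth[2, 1] <- truth[2, 2] <- 1L
  pred <- binary_mask(matrix(0L, 4, 4))
  pred[1, 1] <- pred[2, 2] <- 1L   # 2 of the 4 spikes
  pred[4, 4] <- 1L                 # 1 background pixel marked spike
  cc <- confusion_counts(pred, truth)
  expect_equal(cc$tp[2], 2)
  expect_equal(cc$fp[2], 1)
  expect_equal(cc$fn[2], 2)
  expect_equal(iou(cc, 1L), 2 / 5)

  # identical masks: no errors in any class
  cc2 <- confusion_counts(truth, truth)
  expect_equal(cc2$fp, c(0, 0)); expect_equal(cc2$fn, c(0, 0))
  expect_equal(global_accuracy(cc2), 1)
  expect_equal(as.numeric(mean_class_accuracy(cc2)), 1)
  expect_equal(as.numeric(mean_iou(cc2)), 1)
  expect_error(confusion_counts(pred, binary_mask(matrix(0L, 3, 3))),
               "mismatch")
})

test_that("metrics equal the brute-force double-loop oracle exactly", {
  withr::local_seed(2024)
  for (rep in 1:200) {
    truth <- random_mask(32, 32, runif(1, 0, 0.6))
    pred <- random_mask(32, 32, runif(1, 0, 0.6))
    want <- oracle_metrics(pred, truth)
    cc <- confusion_counts(pred, truth)
    expect_identical(global_accuracy(cc), want$GA)
    suppressWarnings({
      expect_identical(as.numeric(mean_class_accuracy(cc)), want$MA)
      expect_identical(as.numeric(mean_iou(cc)), want$MIoU)
      for (k in 0:1) {
        expect_identical(class_accuracy(cc, k), want$class_acc[k + 1])
        expect_identical(iou(cc, k), want$class_iou[k + 1])
      }
    })
  }
})

test_that("class imbalance divorces GA from spike IoU", {
  # all-background prediction on q-prevalence truth: GA = 1-q, spike IoU = 0
  for (q in c(0.01, 0.1, 0.37)) {
    n <- 100 * 100
    truth <- matrix(0L, 100, 100)
    truth[seq_len(q * n)] <- 1L
    cc <- confusion_counts(binary_mask(matrix(0L, 100, 100)),
                           binary_mask(truth))
    expect_equal(global_accuracy(cc), 1 - q)
    expect_equal(class_accuracy(cc, 1L), 0)
    expect_equal(class_accuracy(cc, 0L), 1)
    expect_equal(as.numeric(mean_class_accuracy(cc)), 0.5)
    expect_equal(iou(cc, 1L), 0)
    expect_equal(cc$tp[1], n * (1 - q))
  }
})

test_that("undefined classes are excluded from means with a flag", {
  truth <- binary_mask(matrix(0L, 5, 5))  # no spikes anywhere
  pred <- binary_mask(matrix(0L, 5, 5))
  cc <- confusion_counts(pred, truth)
  ma <- mean_class_accuracy(cc)
  expect_equal(as.numeric(ma), 1)        # background accuracy alone
  expect_equal(attr(ma, "excluded"), 1L) # spike class flagged
  expect_warning(class_accuracy(cc, 1L), "undefined")
  mi <- mean_iou(cc)
  expect_equal(attr(mi, "excluded"), 1L)
  expect_warning(iou(cc, 1L), "undefined")
})

test_that("precision-recall curves pool pixels and behave monotonically", {
  withr::local_seed(5)
  truth <- random_mask(100, 100, 0.3)
  # perfect probabilities: precision = recall = 1 at interior thresholds
  perfect <- matrix(as.numeric(unclass(truth)), 100, 100)
  pr <- precision_recall_curve(list(perfect), list(truth),
                               thresholds = c(0.25, 0.5, 0.75))
  expect_true(all(pr$precision == 1))
  expect_true(all(pr$recall == 1))
  # threshold 0 predicts everything spike: recall 1
  rnd <- matrix(runif(1e4), 100, 100)
  pr2 <- precision_recall_curve(list(rnd), list(truth))
  expect_equal(pr2$recall[1], 1)
  expect_equal(pr2$threshold[1], 0)
  # recall non-increasing in threshold
  expect_true(all(diff(pr2$recall) <= 1e-12))
  # uniform-random probabilities: precision ~ prevalence at t = 0.5
  expect_lt(abs(pr2$precision[pr2$threshold == 0.5] - mean(truth)), 0.03)
  # no positive pixels: recall undefined, flagged
  expect_warning(
    pr3 <- precision_recall_curve(list(rnd), list(binary_mask(matrix(0L, 100, 100)))),
    "no spike pixels")
  expect_true(attr(pr3, "no_positives"))
})

test_that("dataset evaluation pools confusion, not group means", {
  # two constant-probability stubs cannot express this; use hand confusions
  perfect <- confusion_counts(binary_mask(matrix(1L, 10, 10)),
                              binary_mask(matrix(1L, 10, 10)))
  allwrong <- confusion_counts(binary_mask(matrix(0L, 10, 10)),
                               binary_mask(matrix(1L, 10, 10)))
  pooled <- pool_confusion(perfect, allwrong)
  expect_equal(global_accuracy(pooled), 0.5)
  expect_equal(global_accuracy(perfect), 1)
  expect_equal(global_accuracy(allwrong), 0)

  # stage groups with unequal spike prevalence: pooled MA differs from the
  # unweighted mean of stage MAs (the aggregation the field tables use)
  t1 <- binary_mask(rbind(matrix(1L, 2, 20), matrix(0L, 18, 20)))  # 10% spike
  p1 <- binary_mask(matrix(0L, 20, 20)); p1[1, ] <- 1L
  t2 <- binary_mask(rbind(matrix(1L, 10, 20), matrix(0L, 10, 20))) # 50% spike
  p2 <- binary_mask(rbind(matrix(1L, 8, 20), matrix(0L, 12, 20)))
  c1 <- confusion_counts(p1, t1); c2 <- confusion_counts(p2, t2)
  ma_pooled <- as.numeric(mean_class_accuracy(pool_confusion(c1, c2)))
  ma_avg <- mean(c(as.numeric(mean_class_accuracy(c1)),
                   as.numeric(mean_class_accuracy(c2))))
  expect_false(isTRUE(all.equal(ma_pooled, ma_avg)))
})

test_that("evaluate_dataset groups by stage and reports the pooled overall", {
  d <- withr::local_tempdir()
  man <- load_manifest(write_tiny_dataset(
    d, n = 4, h = 64, w = 64,
    stages = c("booting", "heading", "flowering", "flowering")),
    validate = FALSE)
  stub <- constant_stub(0.7)  # predicts all spike everywhere
  rep <- evaluate_dataset(stub, man, window = 64, group_by = "stage")
  expect_true("overall" %in% rep$group)
  expect_setequal(setdiff(rep$group, "overall"),
                  c("booting", "heading", "flowering"))
  per_img <- attr(rep, "per_image")
  expect_equal(nrow(per_img), 4L)
  # single-image dataset: overall equals that image's report
  rep1 <- evaluate_dataset(stub, man[1, ], window = 64, group_by = "image")
  expect_equal(rep1[rep1$group == "overall", -1],
               rep1[rep1$group == man$id[1], -1], ignore_attr = TRUE)
})

test_that("activation maps expose the pooled block features", {
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 8)), seed = 5)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  maps <- activation_maps(net, x, blocks = c(1, 3, 5))
  expect_named(maps, c("P1", "P3", "P5"))
  expect_equal(dim(maps$P1), c(32, 32, 8))   # 64/8 filters at width 1/8
  expect_equal(dim(maps$P3), c(8, 8, 32))
  expect_equal(dim(maps$P5), c(2, 2, 64))
  expect_error(activation_maps(net, x, blocks = 6), "subset of 1..5")
  # full-width channel depths follow the 64/256/512 block depths
  cfg <- arch_config(width = 1)
  expect_equal(cfg$filters[c(1, 3, 5)], c(64L, 256L, 512L))
  d <- withr::local_tempdir()
  render_activation_grid(maps$P1, file.path(d, "grid.png"))
  expect_true(file.exists(file.path(d, "grid.png")))
})
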