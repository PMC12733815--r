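test_that("the forest separates well-separated geometry clusters", {
  dat <- separable_rf_data()
  model <- train_rf(dat, dat$class, seed = 42)
  expect_gte(model$meta$train_accuracy, 0.99)
  expect_equal(model$meta$ntree, 100L)
  expect_equal(dim(model$meta$confusion), c(3L, 3L))
})

test_that("a fixed seed gives identical predictions across runs", {
  dat <- separable_rf_data(n_per_class = 40)
  probe <- separable_rf_data(n_per_class = 15, seed = 123)
  m1 <- train_rf(dat, dat$class, seed = 42)
  m2 <- train_rf(dat, dat$class, seed = 42)
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("single-class training data is rejected", {
  dat <- separable_rf_data(n_per_class = 20)
  one <- dat[dat$class == 2L, ]
  expect_error(train_rf(one, one$class), "single class")
})

# a forest trained on the step-function data predicts known classes for
# probes placed deep inside each region, letting refine() be exercised
# with controlled outcomes
.probe_measures <- function(lengths, widths = lengths / 2) {
  # pct_large deep inside each class region (image 100x100, 1 mm/px,
  # half size 50 mm -> pct_large = length_mm * 20)
  data.frame(id = seq_along(lengths) - 1L,
             length_mm = lengths, width_mm = widths,
             p1X = 10L, p1Y = 10L, p2X = 40L, p2Y = 40L)
}

rf_fixed <- local({
  dat <- separable_rf_data()
  train_rf(dat, dat$class, seed = 42)
})

test_that("refine drops noise and keeps singles unchanged", {
  # lengths 3, 20 and 45 mm land at pct_large 60, 400 and 900:
  # the class-0, class-1 and class-2 regions of the training data
  meas <- .probe_measures(lengths = c(20, 3, 22))
  feats <- rf_features(meas, 100, 100, 1)
  expect_identical(predict(rf_fixed, feats), c(1L, 0L, 1L))
  out <- refine(rf_fixed, meas, feats)
  expect_equal(out$length_mm, c(20, 22))
  expect_equal(out$final_class, c("1", "1"))
})

test_that("a fused group splits into two halves of exact total length", {
  meas <- .probe_measures(lengths = 45, widths = 20)
  feats <- rf_features(meas, 100, 100, 1)
  expect_identical(predict(rf_fixed, feats), 2L)
  out <- refine(rf_fixed, meas, feats)
  expect_equal(nrow(out), 2L)
  expect_equal(out$length_mm, c(22.5, 22.5))
  expect_equal(out$width_mm, c(20, 20))                # width unchanged
  expect_equal(sum(out$length_mm), 45)                 # exact conservation
  expect_equal(out$final_class, rep("2-split", 2))
  expect_equal(out$source_id, c(0L, 0L))
})

test_that("output size is #class1 + 2 * #class2 and order is stable", {
  lens <- c(20, 3, 45, 22, 2, 47)                      # 1 0 2 1 0 2
  meas <- .probe_measures(lengths = lens, widths = lens / 2.5)
  feats <- rf_features(meas, 100, 100, 1)
  cls <- predict(rf_fixed, feats)
  expect_identical(cls, c(1L, 0L, 2L, 1L, 0L, 2L))
  out <- refine(rf_fixed, meas, feats)
  expect_equal(nrow(out), sum(cls == 1L) + 2L * sum(cls == 2L))
  expect_equal(out$source_id, c(0L, 2L, 2L, 3L, 5L, 5L))
  expect_identical(refine(rf_fixed, meas[0, ], feats[0, ])$id, integer())
})

test_that("refine is idempotent when all survivors stay class 1", {
  meas <- .probe_measures(lengths = c(20, 24))
  feats <- rf_features(meas, 100, 100, 1)
  once <- refine(rf_fixed, meas, feats)
  again <- refine(rf_fixed,
                  data.frame(id = once$id, length_mm = once$length_mm,
                             width_mm = once$width_mm, p1X = 10L, p1Y = 10L,
                             p2X = 40L, p2Y = 40L),
                  rf_features(data.frame(id = once$id,
                                         length_mm = once$length_mm,
                                         width_mm = once$width_mm,
                                         p1X = 10L, p1Y = 10L,
                                         p2X = 40L, p2Y = 40L),
                              100, 100, 1))
  expect_equal(again$length_mm, once$length_mm)
  expect_equal(nrow(again), nrow(once))
})
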