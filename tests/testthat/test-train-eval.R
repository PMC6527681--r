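# Training harness, detection behavior, agreement metrics, the
# size x threshold grid, and batch resampling.

test_that("training reduces the multibox loss on synthetic scenes", {
  m <- tiny_model()
  expect_length(m$loss_history, 12L)
  expect_lt(m$loss_history[12], m$loss_history[1])
})

test_that("fine-tuning with zero epochs returns the basal weights", {
  m <- tiny_model()
  ft <- fine_tune(m, tiny_test_scenes(), epochs = 0, seed = 99)
  expect_identical(ft$net, m$net)
  expect_match(ft$provenance, "fine-tuned")
  # architecture mismatch is refused
  other <- ssd_config(input_size = 60L)
  expect_error(train_detector(tiny_test_scenes()[1:2], epochs = 0,
                              config = other, basal = m),
               "architecture")
})

test_that("flip augmentation trains deterministically under a seed", {
  scenes <- tiny_test_scenes()[1:4]
  m1 <- train_detector(scenes, epochs = 2, seed = 11, augment = TRUE,
                       config = tiny_config())
  m2 <- train_detector(scenes, epochs = 2, seed = 11, augment = TRUE,
                       config = tiny_config())
  expect_identical(m1$loss_history, m2$loss_history)
  expect_true(all(is.finite(m1$loss_history)))
})

test_that("detection counts are non-increasing in the confidence threshold", {
  m <- tiny_model()
  scenes <- tiny_test_scenes()[1:3]
  for (sc in scenes) {
    counts <- vapply(c_st_axis(), function(ct) count_stomata(sc, m, ct),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detection sets are nested as the threshold rises", {
  m <- tiny_model()
  sc <- tiny_test_scenes()[[1]]
  prev <- detect(sc, m, 0.10)
  for (ct in c(0.3, 0.5, 0.7)) {
    cur <- detect(sc, m, ct)
    if (nrow(cur)) {
      key <- function(d) sprintf("%.9f_%.9f_%.9f", d$xmin, d$ymin, d$score)
      expect_true(all(key(cur) %in% key(prev)))
    }
    prev <- cur
  }
  expect_error(detect(sc, m, 0), "0, 1")
})

test_that("agreement metrics match the textbook formulas", {
  # exact agreement
  r <- regression_metrics(c(100, 120, 140), c(100, 120, 140))
  expect_equal(r$r2, 1)
  expect_equal(r$rmse, 0)
  # constant offset: perfect correlation, RMSE equal to the offset
  r <- regression_metrics(c(100, 120, 140), c(110, 130, 150))
  expect_equal(r$r2, 1)
  expect_equal(r$rmse, 10)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 10)
  # closed-form oracle computed from first principles
  x <- c(100, 120, 140); y <- c(105, 118, 145)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r2_oracle <- sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rmse_oracle <- sqrt(mean((y - x)^2))
  r <- regression_metrics(x, y)
  expect_equal(r$r2, r2_oracle)
  expect_equal(r$rmse, rmse_oracle)
  expect_equal(r$slope, sxy / sum((x - mean(x))^2))
  expect_error(regression_metrics(c(1, 1, 1), c(1, 2, 3)), "variance")
  # permutation invariance
  set.seed(13)
  perm <- sample(3)
  expect_equal(regression_metrics(x[perm], y[perm])$r2, r$r2)
})

test_that("the default threshold axis spans 0.10 to 0.95 in 18 steps", {
  expect_equal(c_st_axis(), seq(0.10, 0.95, by = 0.05))
  expect_length(c_st_axis(), 18L)
})

test_that("grid evaluation fills every cell and selects the optimum", {
  m <- tiny_model()
  test <- tiny_test_scenes()
  manual <- vapply(test, function(s) s$truth$sd, numeric(1))
  grid <- grid_evaluate(m, c_st_axis(), test, manual, tiny_area())
  expect_equal(nrow(grid), 18L)
  expect_false(anyNA(grid$r2))
  expect_true(all(grid$rmse >= 0))
  expect_true(all(grid$r2 <= 1))
  best <- select_optimum(grid)
  expect_gte(best$r2, max(grid$r2) - 0.01)
  plateau <- grid[grid$r2 >= max(grid$r2) - 0.01, ]
  expect_equal(best$rmse, min(plateau$rmse))
  # grid round-trips losslessly through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(grid), path, row.names = FALSE)
  back <- read.csv(path)
  expect_equal(back$r2, grid$r2)
  expect_equal(back$rmse, grid$rmse)
})

test_that("optimum selection breaks R2 ties by lower RMSE", {
  grid <- data.frame(size = c(100, 100, 200), c_st = c(0.2, 0.3, 0.3),
                     r2 = c(0.9, 0.95, 0.95), rmse = c(5, 7, 6))
  class(grid) <- c("evaluation_grid", "data.frame")
  best <- select_optimum(grid)
  expect_equal(best$size, 200)
  expect_equal(best$rmse, 6)
  # with zero tolerance the rule is a pure R2 argmax
  strict <- select_optimum(grid, r2_tol = 0)
  expect_equal(strict$rmse, 6)
  # near-indistinguishable R2 cells are ranked by RMSE
  grid$r2 <- c(0.950, 0.944, 0.9501)
  expect_equal(select_optimum(grid)$rmse, 5)
  expect_equal(select_optimum(grid, r2_tol = 0)$rmse, 6)
})

test_that("batch resampling yields C(k,2) pairs and reproducible draws", {
  set.seed(41)
  manual <- runif(150, 90, 170)
  auto <- sapply(1:8, function(m) manual + rnorm(150, sd = m))
  colnames(auto) <- paste0("size", c(25, 50, 75, 100, 125, 150, 175, 200))
  bc <- batch_resample_evaluate(auto, manual_sd = manual, n_batches = 10,
                                batch_size = 50, seed = 5)
  expect_equal(nrow(bc$tukey_r2$pairs), choose(8, 2))
  expect_equal(nrow(bc$metrics), 80L)
  bc2 <- batch_resample_evaluate(auto, manual_sd = manual, n_batches = 10,
                                 batch_size = 50, seed = 5)
  expect_identical(bc$metrics, bc2$metrics)
  expect_error(batch_resample_evaluate(auto, manual_sd = manual,
                                       n_batches = 1, batch_size = 50),
               "two batches")
  # disjoint mode partitions the pool
  bc3 <- batch_resample_evaluate(auto[, 1:2], manual_sd = manual,
                                 n_batches = 3, batch_size = 50, seed = 2,
                                 disjoint = TRUE)
  expect_equal(nrow(bc3$metrics), 6L)
})

test_that("identical model outputs show no significant Tukey pair", {
  set.seed(42)
  manual <- runif(60, 90, 170)
  one <- manual + rnorm(60, sd = 5)
  auto <- cbind(a = one, b = one)
  bc <- batch_resample_evaluate(auto, manual_sd = manual, n_batches = 5,
                                batch_size = 30, seed = 3)
  expect_false(any(bc$tukey_r2$pairs$significant))
  expect_false(any(bc$tukey_rmse$pairs$significant))
})

test_that("model checkpoints round-trip through JSON", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$net$base, m$net$base, tolerance = 1e-12)
  sc <- tiny_test_scenes()[[1]]
  expect_equal(detect(sc, back, 0.3), detect(sc, m, 0.3))
})
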