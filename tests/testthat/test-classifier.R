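## feature matrix with a perfectly separable feature plus noise
separable_fm <- function(n_per_class = 40, seed = 13) {
  set.seed(seed)
  lab <- rep(c("differentiated", "undifferentiated"), each = n_per_class)
  x <- cbind(sep = c(rnorm(n_per_class, 10, 0.5), rnorm(n_per_class, 0, 0.5)),
             matrix(rnorm(2 * n_per_class * 5), ncol = 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  structure(list(x = x,
                 meta = data.frame(cell_id = paste0("c", seq_along(lab)),
                                   label = lab, stringsAsFactors = FALSE),
                 mode = "motility"), class = "feature_matrix")
}

test_that("training on separable features gives a perfect classifier", {
  fm <- separable_fm()
  m <- train_classifier(fm, cv_folds = 5, seed = 1, select = FALSE)
  ev <- evaluate(m, fm)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$accuracy, 1.0)
  s <- predict_scores(m, fm)
  expect_true(all(s[fm$meta$label == "differentiated"] > 0.5))
  expect_true(all(s[fm$meta$label == "undifferentiated"] < 0.5))
})

test_that("a one-point grid equals a direct fit with those parameters", {
  fm <- separable_fm()
  grid <- data.frame(max_depth = 12L, min_node = 1L, num_trees = 100L)
  m <- train_classifier(fm, grid = grid, seed = 5, select = FALSE)
  keep <- !is.na(fm$meta$label)
  y <- factor(fm$meta$label[keep], levels = c("undifferentiated", "differentiated"))
  direct <- myoscore:::fit_forest(as.data.frame(fm$x[keep, , drop = FALSE]), y,
                                  grid[1, ], seed = 5)
  p1 <- predict_scores(m, fm)
  p2 <- predict(direct, data = as.data.frame(fm$x))$predictions[, "differentiated"]
  expect_equal(p1, unname(p2))
  expect_identical(m$best, as.list(grid[1, ]))
})

test_that("prediction contracts hold: duplicates, round-trips, missing columns", {
  fm <- separable_fm()
  m <- train_classifier(fm, seed = 2, select = FALSE)

  dup <- fm
  dup$x <- fm$x[c(1, 1, 2), , drop = FALSE]
  dup$meta <- fm$meta[c(1, 1, 2), ]
  s <- predict_scores(m, dup)
  expect_identical(s[1], s[2])

  p <- withr::local_tempfile(fileext = ".rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(predict_scores(m2, fm), predict_scores(m, fm))

  broken <- fm
  broken$x <- fm$x[, -1, drop = FALSE]
  expect_error(predict_scores(m, broken), "sep")
})

test_that("rank AUC agrees with pROC and flags single-class sets", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:5) {
    s <- rnorm(60)
    lab <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.4, 0.6))
    expect_equal(auc_rank(s, lab),
                 as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE, direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(auc_rank(rnorm(5), rep(TRUE, 5)), "both classes")
})

test_that("score trajectories have the documented length and timestamps", {
  st <- small_study()
  ts <- st$ts_test
  one <- unique(ts$tracks$cell_id[ts$tracks$condition == "ERKi"])[1]

  # a 100-frame track yields 70 scores, the first at the 31st frame's time
  short <- ts
  short$tracks <- short$tracks[short$tracks$cell_id == one &
                                 short$tracks$frame < 100, ]
  traj <- score_trajectory(st$model, short, one)
  expect_identical(nrow(traj), 70L)
  expect_equal(traj$t_hours[1], 1.5 + 30 * 5 / 60)
  expect_true(all(diff(traj$t_hours) > 0))
  expect_true(all(traj$score >= 0 & traj$score <= 1))

  # a 31-frame track yields exactly one score
  tiny <- ts
  tiny$tracks <- tiny$tracks[tiny$tracks$cell_id == one & tiny$tracks$frame < 31, ]
  expect_identical(nrow(score_trajectory(st$model, tiny, one)), 1L)

  # shorter than one segment: empty trajectory with a warning
  stub <- ts
  stub$tracks <- stub$tracks[stub$tracks$cell_id == one & stub$tracks$frame < 10, ]
  expect_warning(empty <- score_trajectory(st$model, stub, one), "shorter|empty")
  expect_identical(nrow(empty), 0L)
})

test_that("simulated controls score low under a model trained on simulation", {
  st <- small_study()
  ctl <- unique(st$ts_test$tracks$cell_id[st$ts_test$tracks$condition == "DMSO"])[1:5]
  traj <- suppressWarnings(score_trajectories(st$model, st$ts_test, cells = ctl))
  expect_lt(mean(traj$score), 0.5)
})

test_that("evaluation metrics follow their definitions at the extremes", {
  fm <- separable_fm()
  m <- train_classifier(fm, seed = 3, select = FALSE)
  ev <- evaluate(m, fm)  # separable: perfect scores
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  one_class <- fm
  one_class$meta$label <- "differentiated"
  expect_error(evaluate(m, one_class), "single class")
})

test_that("condition-discrimination AUC is low early and high late", {
  st <- small_study()
  aot <- suppressWarnings(auc_over_time(st$model, st$ts_test, times = c(4, 18)))
  expect_identical(nrow(aot), 2L)
  expect_lt(aot$auc[aot$t_hours == 4], 0.75)
  expect_gt(aot$auc[aot$t_hours == 18], 0.9)
  expect_gt(aot$auc[aot$t_hours == 18], aot$auc[aot$t_hours == 4])
})

test_that("impurity importances are normalized and rank the informative feature first", {
  fm <- separable_fm()
  m <- train_classifier(fm, seed = 4, select = FALSE)
  imp <- feature_importance(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_identical(imp$feature[1], "sep")

  # single-feature model: that feature carries all the importance
  fm1 <- fm
  fm1$x <- fm$x[, "sep", drop = FALSE]
  m1 <- train_classifier(fm1, seed = 4, select = FALSE)
  imp1 <- feature_importance(m1)
  expect_equal(imp1$importance, 1)
})
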