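toy_xy <- function(n = 20, gap = 5) {
  withr::with_seed(3, {
    x <- rbind(matrix(rnorm(n * 3), n, 3),
               matrix(rnorm(n * 3) + gap, n, 3))
    list(x = x, y = rep(c(0L, 2L), each = n))
  })
}

test_that("classifier configs carry the canonical defaults", {
  knn <- classifier_config("knn")
  expect_equal(knn$hyperparameters,
               list(n_neighbors = 5L, weights = "uniform", p = 2))
  xgb <- classifier_config("xgb")
  expect_equal(xgb$hyperparameters,
               list(learning_rate = 0.3, n_estimators = 650L, max_depth = 3L))
  svm <- classifier_config("svm")
  expect_equal(svm$hyperparameters$kernel, "poly")
  expect_equal(svm$hyperparameters$C, 1)
  lgbm <- classifier_config("lgbm")
  expect_equal(lgbm$hyperparameters,
               list(learning_rate = 0.1, n_estimators = 500L, max_depth = 2L))
  expect_error(classifier_config("forest"),
               class = "pdmil_error_unknown_algorithm")
})

test_that("knn and svm separate a linear toy problem; backends missing for gbms", {
  d <- toy_xy()
  for (algo in c("knn", "svm")) {
    m <- train_classifier(classifier_config(algo), d$x, d$y)
    expect_equal(predict(m, d$x), d$y, label = algo)
  }
  m1 <- train_classifier(classifier_config("knn", n_neighbors = 1L), d$x, d$y)
  expect_equal(predict(m1, d$x), d$y)
  expect_error(train_classifier(classifier_config("knn"), d$x[1:20, ],
                                d$y[1:20]),
               class = "pdmil_error_single_class")
  expect_error(train_classifier(classifier_config("xgb"), d$x, d$y),
               class = "pdmil_error_backend_unavailable")
  expect_error(train_classifier(classifier_config("lgbm"), d$x, d$y),
               class = "pdmil_error_backend_unavailable")
})

test_that("metrics match their definitions on worked examples", {
  m <- compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1), classes = 0:1)
  expect_equal(m$accuracy, 0.75)
  expect_equal(unname(m$weighted["recall"]), 0.75)
  expect_equal(m$per_class$recall, c(0.5, 1.0))
  perfect <- compute_metrics(0:3, 0:3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$weighted), c(1, 1, 1))
  expect_error(compute_metrics(0:2, 0:3), class = "pdmil_error_length_mismatch")
  expect_warning(compute_metrics(c(0, 1, 2), c(0, 1, 1)),
                 class = "pdmil_warning_zero_division")
})

test_that("weighted recall equals accuracy on random label sets", {
  # independent oracle: one-vs-rest tallies implemented from scratch
  withr::with_seed(14, {
    for (i in 1:300) {
      n <- sample(5:50, 1)
      true <- sample(0:3, n, replace = TRUE)
      pred <- sample(0:3, n, replace = TRUE)
      m <- suppressWarnings(compute_metrics(true, pred))
      acc_oracle <- mean(true == pred)
      wrec_oracle <- 0
      for (cl in 0:3) {
        sup <- sum(true == cl)
        if (sup > 0)
          wrec_oracle <- wrec_oracle +
            (sup / n) * (sum(true == cl & pred == cl) / sup)
      }
      expect_equal(m$accuracy, acc_oracle, tolerance = 1e-12)
      expect_equal(unname(m$weighted["recall"]), wrec_oracle,
                   tolerance = 1e-12)
      expect_equal(unname(m$weighted["recall"]), m$accuracy,
                   tolerance = 1e-12)
    }
  })
})

small_cfg <- function(seed = 1L)
  pipeline_config(activities = 2:3, k = 4L, t = 2L, seed = seed)

test_that("loocv produces one prediction per subject and is reproducible", {
  co <- small_cohort()
  rep1 <- suppressWarnings(loocv(co, small_cfg()))
  expect_s3_class(rep1, "pd_report")
  expect_equal(nrow(rep1$folds), 12L)
  expect_equal(sort(rep1$folds$subject_id), sort(co$subjects$subject_id))
  expect_true(all(!is.na(rep1$folds$pred)))
  expect_true(rep1$accuracy >= 0 && rep1$accuracy <= 1)
  expect_equal(unname(rep1$weighted["recall"]), rep1$accuracy)
  rep2 <- suppressWarnings(loocv(co, small_cfg()))
  expect_identical(rep1, rep2)
})

test_that("fold models are invariant to held-out-subject perturbation", {
  fx <- small_features()
  cfg <- small_cfg()
  train <- setdiff(unique(fx$subject_id), "S012")
  b1 <- pdmil:::fit_fold_model(fx, train, cfg)
  fx2 <- fx
  cols <- pdmil:::feature_columns(fx)
  fx2[fx2$subject_id == "S012", cols] <-
    5 * fx2[fx2$subject_id == "S012", cols] + 1
  b2 <- pdmil:::fit_fold_model(fx2, train, cfg)
  expect_identical(b1$codebooks, b2$codebooks)
  expect_identical(b1$lda$phi, b2$lda$phi)
  expect_identical(b1$model, b2$model)
})

test_that("augmented folds draw parents from the training fold only", {
  fx <- small_features()
  cfg <- small_cfg()
  cfg$augment$enabled <- TRUE
  held <- "S001"
  bundle <- pdmil:::fit_fold_model(fx, setdiff(unique(fx$subject_id), held),
                                   cfg)
  y <- bundle$model$fit$y
  expect_gt(length(y), 11L)  # synthetic bags were added
  # no synthetic bag may descend from the held-out subject
  docs <- suppressWarnings(augment_training_set(
    pdmil:::encode_documents(pdmil:::prepare_bag_cache(fx),
                             bundle$codebooks)[
                               setdiff(unique(fx$subject_id), held)],
    pdmil:::derive_seed(cfg$seed, 17L)))
  for (d in docs)
    if (!is.null(d$parents)) expect_false(held %in% d$parents)
})

test_that("instance and SimpleMI baselines run and aggregate correctly", {
  co <- small_cohort()
  inst <- suppressWarnings(instance_baseline(co, small_cfg()))
  expect_equal(nrow(inst$folds), 12L)
  for (agg in c("mean", "median", "minmax")) {
    r <- suppressWarnings(simplemi_baseline(co, agg, small_cfg()))
    expect_equal(nrow(r$folds), 12L)
    expect_equal(r$aggregation, agg)
  }
})

test_that("SimpleMI aggregations reduce to the window features for 1-window bags", {
  # duration 1.5 s -> exactly one window per recording
  profs <- list(subject_profile("A", 0L, c("2" = 3), 0, 1, 0, 1L),
                subject_profile("B", 3L, c("2" = 5), 2, 0.5, 1, 2L))
  recs <- list()
  for (p in profs)
    recs[[paste0(p$subject_id, "_2")]] <-
      generate_subject(p, 2L, duration = 1.5)[[1]]
  co <- structure(list(
    subjects = data.frame(subject_id = c("A", "B"), severity = c(0L, 3L)),
    recordings = recs,
    config = list(activities = 2L, sample_rate = 200, duration = 1.5,
                  preset = "default", seed = 1L)), class = "pd_cohort")
  fx <- cohort_features(co)
  cols <- pdmil:::feature_columns(fx)
  expect_equal(nrow(fx), 2L)
  m <- as.matrix(fx[, cols])
  expect_equal(colMeans(m[1, , drop = FALSE]), m[1, ])   # mean = the window
  expect_equal(c(matrixStats::colMins(m[1, , drop = FALSE]),
                 matrixStats::colMaxs(m[1, , drop = FALSE])),
               rep(m[1, ], 2), ignore_attr = TRUE)       # min = max
})

test_that("a 1x1 grid reproduces a single loocv run; grids must be non-empty", {
  co <- small_cohort()
  cfg <- small_cfg()
  tab <- suppressWarnings(grid_search(co, k_grid = 4L, t_grid = 2L, config = cfg))
  expect_equal(nrow(tab), 1L)
  ref <- suppressWarnings(loocv(co, cfg))
  expect_equal(tab$accuracy, ref$accuracy)
  expect_equal(tab$f1, unname(ref$weighted["f1"]))
  expect_error(grid_search(co, integer(0), 2L, cfg),
               class = "pdmil_error_empty_grid")
  # default grids span 14 x 7 = 98 cells (arithmetic, not executed)
  expect_equal(nrow(expand.grid(4:17, 4:10)), 98L)
})
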