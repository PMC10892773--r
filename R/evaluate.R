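#' Default pipeline configuration
#'
#' Central knobs of the severity-staging pipeline.  The default activity
#' subset {2, 3, 4, 5} (clench/open, rapid alternating hand movements,
#' left/right hand rotation) is the hand-movement bag that performs best
#' for this task; codebook size `k = 8` and `t = 4` topics are the
#' selected operating point.
#'
#' @param ... overrides merged over the defaults (nested lists allowed,
#'   e.g. `augment = list(enabled = TRUE)`).
#' @return nested configuration list.
#' @export
pipeline_config <- function(...) {
  merge_config(list(
    activities = c(2L, 3L, 4L, 5L),
    k = 8L, t = 4L, use_lda = TRUE, counts_norm = "raw",
    seed = 1L,
    filter = list(low_hz = 0.3, high_hz = 20, order = 4L),
    window = list(samples = 300L, overlap = 0.5),
    features = list(correlation_scope = "triad"),
    classifier = list(algorithm = "knn"),
    augment = list(enabled = FALSE, policy = "balance",
                   methods = c("mix", "shuffle"), neighbors_per_subject = 1L)),
    list(...))
}

# Cache the per-activity feature matrices and subject bookkeeping so each
# CV fold only has to refit codebooks and re-assign clusters (matrix ops)
# instead of re-slicing data frames.
prepare_bag_cache <- function(features) {
  cols <- feature_columns(features)
  acts <- sort(unique(features$activity_id))
  per_act <- lapply(acts, function(a) {
    rows <- features[features$activity_id == a, , drop = FALSE]
    rows <- rows[order(rows$subject_id, rows$window_index), , drop = FALSE]
    list(x = as.matrix(rows[, cols, drop = FALSE]),
         subject = rows$subject_id, window_index = rows$window_index)
  })
  names(per_act) <- as.character(acts)
  subjects <- unique(features$subject_id)
  labels <- features$severity[match(subjects, features$subject_id)]
  list(activities = acts, per_act = per_act, subjects = subjects,
       labels = stats::setNames(as.integer(labels), subjects))
}

# Encode every subject's document under the given (fold-fitted) codebooks.
# Pure transform: equivalent to build_documents() but vectorized over the
# whole cohort.
encode_documents <- function(cache, codebooks) {
  vocab <- length(codebooks$activities) * codebooks$k
  parts <- lapply(cache$subjects, function(s) list())
  names(parts) <- cache$subjects
  for (a in cache$activities) {
    pa <- cache$per_act[[as.character(a)]]
    cl <- assign_clusters(pa$x, codebooks$books[[as.character(a)]])
    rank0 <- match(a, codebooks$activities) - 1L
    df <- data.frame(activity_id = a, window_index = pa$window_index,
                     cluster_id = cl, word_id = rank0 * codebooks$k + cl)
    for (s in unique(pa$subject)) {
      idx <- pa$subject == s
      parts[[s]][[as.character(a)]] <- df[idx, , drop = FALSE]
    }
  }
  out <- lapply(cache$subjects, function(s) {
    words <- do.call(rbind, c(parts[[s]], list(make.row.names = FALSE)))
    structure(list(subject_id = s, label = cache$labels[[s]],
                   words = words, vocab_size = vocab),
              class = "pd_document")
  })
  stats::setNames(out, cache$subjects)
}

# Fit every trainable component on the training-fold subjects only:
# codebooks -> documents -> LDA -> optional bag augmentation -> classifier.
# Returns the fitted bundle; nothing in it depends on held-out subjects.
fit_fold_model <- function(features, train_ids, cfg) {
  codebooks <- fit_activity_codebooks(features, cfg$k,
                                      derive_seed(cfg$seed, 11L), train_ids)
  docs_train <- build_documents(features, codebooks, train_ids)
  lda <- NULL
  if (cfg$use_lda) {
    dtm <- document_term_matrix(docs_train, docs_train[[1]]$vocab_size)
    lda <- fit_topic_model(dtm, cfg$t, derive_seed(cfg$seed, 13L))
  }
  if (isTRUE(cfg$augment$enabled))
    docs_train <- suppressWarnings(augment_training_set(
      docs_train, derive_seed(cfg$seed, 17L), cfg$augment$policy,
      cfg$augment$methods, cfg$augment$neighbors_per_subject))
  x <- bag_vector_matrix(docs_train, lda, cfg$use_lda, cfg$counts_norm)
  y <- vapply(docs_train, `[[`, integer(1), "label")
  clf <- do.call(classifier_config,
                 c(list(algorithm = cfg$classifier$algorithm,
                        seed = derive_seed(cfg$seed, 19L)),
                   cfg$classifier[setdiff(names(cfg$classifier), "algorithm")]))
  model <- train_classifier(clf, x, y)
  list(codebooks = codebooks, lda = lda, model = model, config = cfg)
}

predict_subject <- function(bundle, features, subject_id) {
  doc <- build_document(features, subject_id, bundle$codebooks,
                        features$severity[match(subject_id,
                                                features$subject_id)])
  x <- bag_vector_matrix(list(doc), bundle$lda, bundle$config$use_lda,
                         bundle$config$counts_norm)
  predict(bundle$model, x)[1]
}

make_report <- function(folds, cfg, extra = list()) {
  m <- compute_metrics(folds$true, folds$pred)
  structure(c(list(folds = folds, accuracy = m$accuracy,
                   weighted = m$weighted, per_class = m$per_class,
                   confusion = m$confusion,
                   fingerprint = cfg), extra),
            class = "pd_report")
}

#' @export
print.pd_report <- function(x, ...) {
  cat(sprintf(
    "pd_report: %d folds | accuracy %.4f | weighted P %.4f R %.4f F1 %.4f\n",
    nrow(x$folds), x$accuracy, x$weighted["precision"],
    x$weighted["recall"], x$weighted["f1"]))
  invisible(x)
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' For each subject, all trainable components (per-activity codebooks,
#' topic model, optional bag augmentation, classifier) are refit on the
#' remaining subjects and the held-out subject is predicted from its
#' fused bag vector.  Fitting never sees the held-out subject, so the
#' reported accuracy is free of transform-time leakage.  Subjects with no
#' windows in the in-scope activities are excluded with a warning.
#'
#' @param cohort a `pd_cohort`.
#' @param config a [pipeline_config()] (or overrides passed to it).
#' @return `pd_report` with per-fold predictions and summary metrics.
#' @export
loocv <- function(cohort, config = pipeline_config()) {
  cfg <- merge_config(pipeline_config(), config)
  features <- cohort_features(cohort, cfg$activities, cfg)
  subjects <- cohort$subjects$subject_id
  have <- subjects %in% features$subject_id
  if (any(!have)) {
    pd_warn(sprintf("excluding subject(s) with no windows: %s",
                    paste(subjects[!have], collapse = ",")),
            "pdmil_warning_excluded_subject")
    subjects <- subjects[have]
  }
  if (length(subjects) < 2)
    pd_stop("need at least 2 subjects", "pdmil_error_too_few_subjects")
  folds <- data.frame(subject_id = subjects,
                      true = cohort$subjects$severity[
                        match(subjects, cohort$subjects$subject_id)],
                      pred = NA_integer_, stringsAsFactors = FALSE)
  cache <- prepare_bag_cache(features)
  for (i in seq_along(subjects)) {
    train_ids <- setdiff(subjects, subjects[i])
    codebooks <- fit_activity_codebooks(features, cfg$k,
                                        derive_seed(cfg$seed, 11L), train_ids)
    docs <- encode_documents(cache, codebooks)
    docs_train <- docs[train_ids]
    lda <- NULL
    if (cfg$use_lda) {
      dtm <- document_term_matrix(docs_train, docs_train[[1]]$vocab_size)
      lda <- fit_topic_model(dtm, cfg$t, derive_seed(cfg$seed, 13L))
    }
    if (isTRUE(cfg$augment$enabled))
      docs_train <- suppressWarnings(augment_training_set(
        docs_train, derive_seed(cfg$seed, 17L), cfg$augment$policy,
        cfg$augment$methods, cfg$augment$neighbors_per_subject))
    x <- bag_vector_matrix(docs_train, lda, cfg$use_lda, cfg$counts_norm)
    y <- vapply(docs_train, `[[`, integer(1), "label")
    clf <- classifier_config(cfg$classifier$algorithm,
                             seed = derive_seed(cfg$seed, 19L))
    model <- train_classifier(clf, x, y)
    xtest <- bag_vector_matrix(docs[subjects[i]], lda, cfg$use_lda,
                               cfg$counts_norm)
    folds$pred[i] <- predict(model, xtest)[1]
  }
  make_report(folds, cfg)
}

#' Instance-level baseline (bag label propagated to every window)
#'
#' Each window inherits its subject's severity label and a classifier is
#' trained directly on window features; a held-out subject's prediction
#' is the majority vote over its windows (tie -> lower class id).
#' Subject-level leave-one-out as in [loocv()].
#'
#' @inheritParams loocv
#' @return `pd_report`.
#' @export
instance_baseline <- function(cohort, config = pipeline_config()) {
  cfg <- merge_config(pipeline_config(), config)
  features <- cohort_features(cohort, cfg$activities, cfg)
  subjects <- intersect(cohort$subjects$subject_id, features$subject_id)
  cols <- feature_columns(features)
  clf <- classifier_config(cfg$classifier$algorithm,
                           seed = derive_seed(cfg$seed, 19L))
  folds <- data.frame(subject_id = subjects,
                      true = cohort$subjects$severity[
                        match(subjects, cohort$subjects$subject_id)],
                      pred = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(subjects)) {
    tr <- features$subject_id != subjects[i]
    model <- train_classifier(clf, as.matrix(features[tr, cols]),
                              features$severity[tr])
    wpred <- predict(model, as.matrix(features[!tr, cols]))
    votes <- tabulate(wpred + 1L, nbins = 4L)
    folds$pred[i] <- which.max(votes) - 1L
  }
  make_report(folds, cfg)
}

#' SimpleMI baseline (per-subject aggregation of window features)
#'
#' The bag vector is the element-wise mean, median, or concatenated
#' min/max of the subject's window features, followed by subject-level
#' leave-one-out classification.
#'
#' @inheritParams loocv
#' @param aggregation `"mean"`, `"median"` or `"minmax"`.
#' @return `pd_report`.
#' @export
simplemi_baseline <- function(cohort, aggregation = c("mean", "median", "minmax"),
                              config = pipeline_config()) {
  aggregation <- match.arg(aggregation)
  cfg <- merge_config(pipeline_config(), config)
  features <- cohort_features(cohort, cfg$activities, cfg)
  subjects <- intersect(cohort$subjects$subject_id, features$subject_id)
  cols <- feature_columns(features)
  agg <- t(vapply(subjects, function(s) {
    m <- as.matrix(features[features$subject_id == s, cols, drop = FALSE])
    switch(aggregation,
           mean = colMeans(m),
           median = matrixStats::colMedians(m),
           minmax = c(matrixStats::colMins(m), matrixStats::colMaxs(m)))
  }, numeric(if (aggregation == "minmax") 2 * length(cols) else length(cols))))
  y <- cohort$subjects$severity[match(subjects, cohort$subjects$subject_id)]
  clf <- classifier_config(cfg$classifier$algorithm,
                           seed = derive_seed(cfg$seed, 19L))
  folds <- data.frame(subject_id = subjects, true = y, pred = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(subjects)) {
    model <- train_classifier(clf, agg[-i, , drop = FALSE], y[-i])
    folds$pred[i] <- predict(model, agg[i, , drop = FALSE])[1]
  }
  make_report(folds, cfg, list(aggregation = aggregation))
}

#' Grid search over codebook size and topic count
#'
#' Full Cartesian sweep of `k_grid` x `t_grid`; each cell is a complete
#' leave-one-out run of the pipeline.  The canonical grids are
#' `k = 4..17` and `t = 4..10` (98 cells).
#'
#' @inheritParams loocv
#' @param k_grid,t_grid integer grids.
#' @return data.frame `(k, t, accuracy, f1)` sorted by F1, best first.
#' @export
grid_search <- function(cohort, k_grid = 4:17, t_grid = 4:10,
                        config = pipeline_config()) {
  if (length(k_grid) == 0 || length(t_grid) == 0)
    pd_stop("grids must be non-empty", "pdmil_error_empty_grid")
  cfg <- merge_config(pipeline_config(), config)
  grid <- expand.grid(k = as.integer(k_grid), t = as.integer(t_grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$k <- grid$k[i]
    cfg_i$t <- grid$t[i]
    rep_i <- loocv(cohort, cfg_i)
    data.frame(k = grid$k[i], t = grid$t[i], accuracy = rep_i$accuracy,
               f1 = as.numeric(rep_i$weighted["f1"]))
  })
  out <- do.call(rbind, res)
  out[order(-out$f1, out$k, out$t), , drop = FALSE]
}
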