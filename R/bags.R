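#' Per-activity k-means codebooks
#'
#' Window features of the same activity, pooled across the training
#' subjects, are standardized (per-dimension z-score over the training
#' windows; parameters stored for transform-time reuse) and clustered with
#' k-means.  A window's cluster label, qualified by its activity, is the
#' symbolic "word" from which subject documents are built: cluster 2 of
#' activity 3 and cluster 2 of activity 5 are different words.
#'
#' @param features cohort feature table from [cohort_features()].
#' @param k clusters per activity (>= 2; default 8).
#' @param seed integer; k-means uses 10 restarts under this seed.
#' @param subjects ids of the training subjects; only their windows are
#'   used for fitting (defaults to all subjects in `features`).
#' @return object of class `pd_codebooks`.
#' @export
fit_activity_codebooks <- function(features, k = 8L, seed = 1L,
                                   subjects = NULL) {
  if (k < 2) pd_stop("k must be >= 2", "pdmil_error_k")
  subjects <- subjects %||% unique(features$subject_id)
  cols <- feature_columns(features)
  train <- features[features$subject_id %in% subjects, , drop = FALSE]
  acts <- sort(unique(features$activity_id))
  books <- list()
  for (a in acts) {
    x <- as.matrix(train[train$activity_id == a, cols, drop = FALSE])
    if (nrow(x) < k)
      pd_stop(sprintf("activity %d has %d training windows; need >= k = %d",
                      a, nrow(x), k), "pdmil_error_too_few_windows")
    mu <- colMeans(x)
    sdev <- matrixStats::colSds(x)
    sdev[sdev == 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
    km <- withr::with_seed(derive_seed(seed, a), {
      for (try in 1:5) {
        res <- tryCatch(stats::kmeans(xs, centers = k, nstart = 10,
                                      iter.max = 100),
                        error = function(e) NULL)
        if (!is.null(res)) break
      }
      res
    })
    if (is.null(km))
      pd_stop(sprintf("k-means failed to converge for activity %d", a),
              "pdmil_error_kmeans")
    books[[as.character(a)]] <- list(activity_id = a, k = as.integer(k),
                                     centroids = km$centers,
                                     center_mean = mu, center_sd = sdev)
  }
  structure(list(activities = acts, k = as.integer(k), books = books,
                 feature_cols = cols, fit_subject_ids = sort(subjects),
                 seed = as.integer(seed)),
            class = "pd_codebooks")
}

# nearest-centroid assignment in the codebook's standardized space;
# ties resolve to the lowest cluster id (which.min takes the first)
assign_clusters <- function(x, book) {
  xs <- sweep(sweep(x, 2, book$center_mean), 2, book$center_sd, "/")
  d2 <- outer(rowSums(xs^2), rowSums(book$centroids^2), "+") -
    2 * xs %*% t(book$centroids)
  max.col(-d2, ties.method = "first") - 1L   # 0-based cluster ids
}

#' Build a subject's symbolic document
#'
#' Every window is mapped to the nearest centroid of its activity's
#' codebook and the resulting words are ordered chronologically within
#' activity, activities in ascending id order.  Works for subjects unseen
#' at codebook-fitting time (held-out folds); an activity with no windows
#' for this subject simply contributes no words.
#'
#' @param features feature table rows (any subjects).
#' @param subject_id the subject to encode.
#' @param codebooks a `pd_codebooks`.
#' @param label severity label to attach (optional).
#' @return object of class `pd_document` with a `words` data.frame
#'   (`activity_id`, `window_index`, `cluster_id` in `[0, k)`, and the
#'   global `word_id = activity_rank * k + cluster_id` in `[0, A * k)`).
#' @export
build_document <- function(features, subject_id, codebooks, label = NA_integer_) {
  rows <- features[features$subject_id == subject_id, , drop = FALSE]
  acts_here <- sort(unique(rows$activity_id))
  missing <- setdiff(acts_here, codebooks$activities)
  if (length(missing) > 0)
    pd_stop(sprintf("no codebook for activity %s",
                    paste(missing, collapse = ",")),
            "pdmil_error_no_codebook")
  words <- list()
  for (a in acts_here) {
    sub <- rows[rows$activity_id == a, , drop = FALSE]
    sub <- sub[order(sub$window_index), , drop = FALSE]
    cl <- assign_clusters(as.matrix(sub[, codebooks$feature_cols,
                                        drop = FALSE]),
                          codebooks$books[[as.character(a)]])
    rank0 <- match(a, codebooks$activities) - 1L
    words[[as.character(a)]] <- data.frame(
      activity_id = a, window_index = sub$window_index,
      cluster_id = cl, word_id = rank0 * codebooks$k + cl)
  }
  words <- if (length(words)) do.call(rbind, c(words, list(make.row.names = FALSE)))
  else data.frame(activity_id = integer(0), window_index = integer(0),
                  cluster_id = integer(0), word_id = integer(0))
  structure(list(subject_id = subject_id, label = label, words = words,
                 vocab_size = length(codebooks$activities) * codebooks$k),
            class = "pd_document")
}

#' Build documents for many subjects
#'
#' @param features feature table (must carry a `severity` column).
#' @param codebooks a `pd_codebooks`.
#' @param subjects subject ids (default all in `features`).
#' @return named list of `pd_document`.
#' @export
build_documents <- function(features, codebooks, subjects = NULL) {
  subjects <- subjects %||% unique(features$subject_id)
  sev <- features$severity[match(subjects, features$subject_id)]
  out <- lapply(seq_along(subjects), function(i)
    build_document(features, subjects[i], codebooks, sev[i]))
  stats::setNames(out, subjects)
}

#' Word-count vector of a document
#'
#' @param document a `pd_document`.
#' @param vocab_size vocabulary size `A * k` (default from the document).
#' @return integer vector of word multiplicities, summing to the document
#'   length.
#' @export
word_count_vector <- function(document, vocab_size = document$vocab_size) {
  counts <- integer(vocab_size)
  if (nrow(document$words) > 0) {
    tab <- tabulate(document$words$word_id + 1L, nbins = vocab_size)
    counts <- as.integer(tab)
  }
  counts
}

document_term_matrix <- function(documents, vocab_size) {
  m <- t(vapply(documents, word_count_vector, integer(vocab_size),
                vocab_size = vocab_size))
  storage.mode(m) <- "integer"
  m
}

#' @export
print.pd_document <- function(x, ...) {
  cat(sprintf("pd_document %s: %d words over %d activities (label %s)\n",
              x$subject_id, nrow(x$words),
              length(unique(x$words$activity_id)), x$label))
  invisible(x)
}
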