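# feature table with two well-separated Gaussian blobs per activity
blob_features <- function(n_per = 30, seed = 4) {
  withr::with_seed(seed, {
    cols <- feature_names()
    mk <- function(center, subj, act, offset) {
      m <- matrix(rnorm(n_per * 54, sd = 0.05), n_per, 54)
      m[, 1:5] <- m[, 1:5] + center
      df <- data.frame(subject_id = subj, activity_id = act,
                       window_index = seq_len(n_per) - 1L + offset,
                       severity = 1L)
      cbind(df, as.data.frame(stats::setNames(as.data.frame(m), cols)))
    }
    rbind(mk(0, "A", 2L, 0L), mk(5, "B", 2L, 0L))
  })
}

test_that("k-means codebooks recover well-separated blobs (ARI = 1)", {
  fx <- blob_features()
  cb <- fit_activity_codebooks(fx, k = 2L, seed = 1L)
  cl <- pdmil:::assign_clusters(
    as.matrix(fx[, cb$feature_cols]), cb$books[["2"]])
  truth <- rep(c(0, 1), each = 30)
  expect_equal(rand_index_adj(cl, truth), 1)
})

test_that("codebook preconditions and determinism hold", {
  fx <- blob_features()
  expect_error(fit_activity_codebooks(fx, k = 1L), class = "pdmil_error_k")
  expect_error(fit_activity_codebooks(fx, k = 100L),
               class = "pdmil_error_too_few_windows")
  cb1 <- fit_activity_codebooks(fx, k = 3L, seed = 42L)
  cb2 <- fit_activity_codebooks(fx, k = 3L, seed = 42L)
  expect_identical(cb1, cb2)
})

test_that("documents are chronological, activity-qualified and total", {
  docs <- small_documents()
  d <- docs[["S001"]]
  expect_s3_class(d, "pd_document")
  # ordered by (activity rank, window index)
  expect_true(!is.unsorted(d$words$activity_id))
  for (a in unique(d$words$activity_id))
    expect_true(!is.unsorted(d$words$window_index[d$words$activity_id == a]))
  # bijection: word_id = rank0 * k + cluster_id stays in [0, A*k)
  expect_true(all(d$words$word_id >= 0 & d$words$word_id < d$vocab_size))
  expect_equal(d$words$word_id %% 4L, d$words$cluster_id)
  # word count equals total windows over in-scope activities
  fx <- small_features()
  expect_equal(nrow(d$words), sum(fx$subject_id == "S001"))
})

test_that("document building rejects uncovered activities", {
  fx <- small_features()
  cb <- fit_activity_codebooks(fx[fx$activity_id == 2L, ], k = 4L, seed = 1L)
  expect_error(build_document(fx, "S001", cb),
               class = "pdmil_error_no_codebook")
})

test_that("centroid ties break to the lowest cluster id", {
  fx <- blob_features()
  cb <- fit_activity_codebooks(fx, k = 2L, seed = 1L)
  book <- cb$books[["2"]]
  # query exactly between both centroids (standardized space)
  mid <- colMeans(book$centroids)
  q <- sweep(sweep(matrix(mid, 1), 2, book$center_sd, "*"), 2,
             book$center_mean, "+")
  expect_equal(pdmil:::assign_clusters(q, book), 0L)
  # query exactly at a centroid is assigned that centroid
  at1 <- sweep(sweep(book$centroids[2, , drop = FALSE], 2,
                     book$center_sd, "*"), 2, book$center_mean, "+")
  expect_equal(pdmil:::assign_clusters(at1, book), 1L)
})

test_that("word counts follow the document and ignore order", {
  d <- doc_from_words(c(3L, 3L, 7L), k = 16L)
  v <- word_count_vector(d, 16L)
  expect_equal(v[4], 2L); expect_equal(v[8], 1L); expect_equal(sum(v), 3L)
  empty <- doc_from_words(integer(0), k = 16L)
  expect_equal(word_count_vector(empty, 16L), integer(16))
  perm <- doc_from_words(c(7L, 3L, 3L), k = 16L)
  expect_equal(word_count_vector(perm, 16L), v)
})

test_that("vectorized encoding equals the reference document builder", {
  fx <- small_features()
  cb <- fit_activity_codebooks(fx, k = 4L, seed = 5L)
  ref <- build_documents(fx, cb)
  fast <- pdmil:::encode_documents(pdmil:::prepare_bag_cache(fx), cb)
  for (s in names(ref)) {
    expect_equal(fast[[s]]$words$word_id, ref[[s]]$words$word_id, label = s)
    expect_equal(fast[[s]]$label, unname(ref[[s]]$label))
  }
})

test_that("topic model recovers disjoint-vocabulary topics (ARI >= 0.9)", {
  hits <- vapply(1:10, function(s) {
    dtm <- withr::with_seed(s, {
      n_doc <- 30
      topic <- rep(0:1, each = n_doc / 2)
      t(sapply(topic, function(z) {
        counts <- integer(8)
        words <- sample(if (z == 0) 1:4 else 5:8, 40, replace = TRUE)
        counts[as.integer(names(table(words)))] <- as.integer(table(words))
        counts
      }))
    })
    lda <- fit_topic_model(dtm, t = 2L, seed = s)
    dominant <- max.col(lda$theta)
    rand_index_adj(dominant, rep(0:1, each = 15))
  }, 0)
  expect_gte(mean(hits), 0.9)
})

test_that("topic vectors live on the simplex and handle degenerate docs", {
  docs <- small_documents()
  dtm <- pdmil:::document_term_matrix(docs, docs[[1]]$vocab_size)
  lda <- fit_topic_model(dtm, t = 3L, seed = 2L)
  for (d in docs) {
    tv <- topic_vector(lda, word_count_vector(d))
    expect_true(all(tv >= 0))
    expect_lt(abs(sum(tv) - 1), 1e-9)
  }
  expect_warning(tv0 <- topic_vector(lda, integer(lda$vocab_size)),
                 class = "pdmil_warning_empty_document")
  expect_equal(tv0, rep(1 / 3, 3))
  expect_error(fit_topic_model(dtm, t = 1L), class = "pdmil_error_t")
  expect_error(fit_topic_model(dtm[1:2, ], t = 3L),
               class = "pdmil_error_too_few_documents")
})

test_that("fused bag vectors have the documented shape", {
  counts <- c(rep(2L, 16), rep(1L, 16))           # A = 4, k = 8
  topics <- c(1, 0, 0, 0)
  bv <- fuse_bag_vector(counts, topics)
  expect_length(bv$fused, 36L)
  expect_equal(tail(bv$fused, 4), c(1, 0, 0, 0))
  expect_length(fuse_bag_vector(counts, use_lda = FALSE)$fused, 32L)
  expect_error(fuse_bag_vector(counts, c(0.5, 0.4)),
               class = "pdmil_error_simplex")
})

test_that("transforming held-out subjects never mutates fitted models", {
  fx <- small_features()
  train <- sprintf("S%03d", 1:10)
  cb <- fit_activity_codebooks(fx, k = 4L, seed = 3L, subjects = train)
  docs <- build_documents(fx, cb, train)
  lda <- fit_topic_model(pdmil:::document_term_matrix(docs, docs[[1]]$vocab_size),
                         t = 2L, seed = 3L)
  cb_snapshot <- unserialize(serialize(cb, NULL))
  lda_snapshot <- unserialize(serialize(lda, NULL))
  # encode the unseen marker subjects and transform their counts
  for (s in c("S011", "S012")) {
    d <- build_document(fx, s, cb)
    invisible(topic_vector(lda, word_count_vector(d)))
  }
  expect_identical(cb, cb_snapshot)
  expect_identical(lda, lda_snapshot)
})

test_that("model bundles and documents round-trip through plain text", {
  fx <- small_features()
  cb <- fit_activity_codebooks(fx, k = 4L, seed = 5L)
  docs <- build_documents(fx, cb)
  dtm <- pdmil:::document_term_matrix(docs, docs[[1]]$vocab_size)
  lda <- fit_topic_model(dtm, t = 2L, seed = 2L)
  d <- withr::local_tempdir()
  save_model_bundle(list(codebooks = cb, lda = lda,
                         config = list(k = 4L, t = 2L)), d)
  back <- load_model_bundle(d)
  # reloaded codebooks encode identically
  doc1 <- build_document(fx, "S005", cb)
  doc2 <- build_document(fx, "S005", back$codebooks)
  expect_equal(doc2$words$word_id, doc1$words$word_id)
  expect_equal(back$lda$phi, lda$phi, tolerance = 1e-12)
  expect_equal(topic_vector(back$lda, word_count_vector(doc1)),
               topic_vector(lda, word_count_vector(doc1)))
  # plain-text document export, one subject per line
  f <- file.path(d, "docs.txt")
  write_documents(docs, f)
  lines <- readLines(f)
  expect_length(lines, length(docs))
  first <- strsplit(lines[1], " ")[[1]]
  expect_equal(first[1], docs[[1]]$subject_id)
  expect_equal(as.integer(first[-(1:2)]), docs[[1]]$words$word_id)
})
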