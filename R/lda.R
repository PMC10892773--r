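#' Fit a latent Dirichlet allocation topic model
#'
#' Collapsed Gibbs sampling with symmetric Dirichlet priors over a
#' document-term count matrix of codebook words.  The fitted topic-word
#' distribution is the posterior mean averaged over the second half of the
#' chain; the model is deterministic given `seed` (the sampler uses its
#' own PRNG, independent of R's RNG state).
#'
#' @param dtm documents x vocabulary matrix of non-negative integer counts.
#' @param t number of topics (>= 2).
#' @param seed integer seed.
#' @param alpha document-topic prior (default `1/t`).
#' @param beta topic-word prior (default 0.01).
#' @param n_iter Gibbs sweeps (default 200; the codebook vocabularies are
#'   small, so the chain mixes in a few dozen sweeps).
#' @return object of class `pd_lda` with `phi` (t x V), training `theta`
#'   and the priors.
#' @export
fit_topic_model <- function(dtm, t, seed = 1L, alpha = 1 / t, beta = 0.01,
                            n_iter = 200L) {
  if (t < 2) pd_stop("t must be >= 2", "pdmil_error_t")
  dtm <- as.matrix(dtm)
  if (any(dtm < 0) || any(dtm != round(dtm)))
    pd_stop("dtm must contain non-negative integers", "pdmil_error_dtm")
  if (nrow(dtm) < t)
    pd_stop(sprintf("need at least t = %d training documents, got %d",
                    t, nrow(dtm)), "pdmil_error_too_few_documents")
  storage.mode(dtm) <- "integer"
  fit <- lda_gibbs_fit(dtm, as.integer(t), alpha, beta, as.integer(n_iter),
                       as.integer(seed))
  structure(list(phi = fit$phi, theta = fit$theta, t = as.integer(t),
                 vocab_size = ncol(dtm), alpha = alpha, beta = beta,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "pd_lda")
}

#' Posterior topic distribution of a (possibly unseen) document
#'
#' Fold-in Gibbs sampling holding the fitted topic-word distribution
#' fixed; the training corpus is never touched, so transforming held-out
#' subjects cannot leak into the model.  An all-zero count vector yields
#' the uniform distribution with a warning.
#'
#' @param model a `pd_lda`.
#' @param counts integer word-count vector of length `vocab_size`.
#' @param n_iter fold-in Gibbs sweeps (default 80).
#' @return numeric vector of length `t`, non-negative, summing to 1.
#' @export
topic_vector <- function(model, counts, n_iter = 80L) {
  if (length(counts) != model$vocab_size)
    pd_stop(sprintf("counts has length %d; vocabulary is %d",
                    length(counts), model$vocab_size),
            "pdmil_error_length_mismatch")
  if (sum(counts) == 0) {
    pd_warn("empty document: returning uniform topic distribution",
            "pdmil_warning_empty_document")
    return(rep(1 / model$t, model$t))
  }
  lda_gibbs_transform(model$phi, as.integer(counts), model$alpha,
                      as.integer(n_iter), derive_seed(model$seed, 101L))
}

#' Fuse word counts and topic probabilities into a bag vector
#'
#' The classifier input for one subject: the word-count histogram
#' (local, per-activity cluster structure) horizontally bound with the
#' topic distribution (global, cross-activity structure).  With
#' `use_lda = FALSE` only the counts are emitted (the counts-only
#' ablation).
#'
#' @param counts length `A * k` count vector.
#' @param topics length `t` probability vector (ignored when
#'   `use_lda = FALSE`).
#' @param use_lda include the topic block?
#' @param subject_id,label optional metadata.
#' @return object of class `pd_bag_vector` with the `fused` numeric vector.
#' @export
fuse_bag_vector <- function(counts, topics = NULL, use_lda = TRUE,
                            subject_id = NA_character_, label = NA_integer_) {
  if (use_lda) {
    if (is.null(topics))
      pd_stop("topics required when use_lda = TRUE", "pdmil_error_length_mismatch")
    if (abs(sum(topics) - 1) > 1e-6 || any(topics < 0))
      pd_stop("topics must be a probability vector", "pdmil_error_simplex")
    fused <- c(as.numeric(counts), as.numeric(topics))
  } else {
    fused <- as.numeric(counts)
  }
  structure(list(subject_id = subject_id, label = label,
                 counts = as.numeric(counts),
                 topics = if (use_lda) as.numeric(topics) else NULL,
                 fused = fused),
            class = "pd_bag_vector")
}

# Fused bag-vector matrix for a list of documents under a fitted model
# (lda may be NULL for the counts-only ablation).  Because the default
# classifier (kNN) is scale-sensitive, the unit-sum topic block is
# rescaled to the same units as the count block before classification:
# with raw counts the topics are multiplied by the bag length (expected
# words per topic), with relative counts they are left on the simplex.
# fuse_bag_vector() itself always binds the literal [counts | theta].
bag_vector_matrix <- function(documents, lda = NULL, use_lda = !is.null(lda),
                              counts_norm = "raw") {
  vs <- documents[[1]]$vocab_size
  rows <- lapply(documents, function(d) {
    counts <- word_count_vector(d, vs)
    scale <- if (counts_norm == "relative" || sum(counts) == 0) 1
    else sum(counts)
    if (counts_norm == "relative" && sum(counts) > 0)
      counts <- counts / sum(counts)
    tp <- if (use_lda) topic_vector(lda, word_count_vector(d, vs)) else NULL
    bv <- fuse_bag_vector(counts, tp, use_lda, d$subject_id, d$label)$fused
    if (use_lda)
      bv[(vs + 1):length(bv)] <- bv[(vs + 1):length(bv)] * scale
    bv
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(documents, `[[`, character(1), "subject_id")
  m
}
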