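#' Hamming distance between word sequences
#'
#' Position-wise mismatch count.  For plain vectors, unequal lengths are
#' truncated to the common chronological prefix.  For two `pd_document`s
#' the distance is computed per shared activity (each activity's words in
#' chronological order) and summed; a pair sharing no activity words is
#' incomparable and rejected.
#'
#' @param a,b integer word vectors or `pd_document`s.
#' @return integer distance.
#' @export
hamming_distance <- function(a, b) {
  if (inherits(a, "pd_document") && inherits(b, "pd_document")) {
    acts <- intersect(unique(a$words$activity_id), unique(b$words$activity_id))
    total <- 0L
    n_common <- 0L
    for (act in acts) {
      wa <- a$words$word_id[a$words$activity_id == act]
      wb <- b$words$word_id[b$words$activity_id == act]
      n <- min(length(wa), length(wb))
      if (n == 0) next
      total <- total + sum(wa[seq_len(n)] != wb[seq_len(n)])
      n_common <- n_common + n
    }
    if (n_common == 0L)
      pd_stop(sprintf("documents %s and %s share no comparable positions",
                      a$subject_id, b$subject_id),
              "pdmil_error_incomparable")
    return(as.integer(total))
  }
  if (length(a) == 0 || length(b) == 0)
    pd_stop("sequences must be non-empty", "pdmil_error_incomparable")
  n <- min(length(a), length(b))
  as.integer(sum(a[seq_len(n)] != b[seq_len(n)]))
}

#' Select Hamming-similar same-class document pairs
#'
#' For every subject, its nearest same-class neighbours by
#' [hamming_distance()] (ties broken by subject id order); duplicate
#' unordered pairs are removed.  Singleton classes yield no pairs.
#'
#' @param documents named list of labelled `pd_document`s.
#' @param neighbors_per_subject nearest neighbours kept per subject.
#' @return data.frame with columns `subject_a`, `subject_b`, `label`,
#'   `distance` (possibly zero rows).
#' @export
select_similar_pairs <- function(documents, neighbors_per_subject = 1L) {
  labs <- vapply(documents, `[[`, integer(1), "label")
  ids <- names(documents)
  out <- list()
  for (cl in sort(unique(labs))) {
    members <- ids[labs == cl]
    if (length(members) < 2) {
      pd_warn(sprintf("class %d has a single subject; no pairs", cl),
              "pdmil_warning_singleton_class")
      next
    }
    d <- matrix(Inf, length(members), length(members),
                dimnames = list(members, members))
    for (i in seq_along(members))
      for (j in seq_along(members))
        if (i < j)
          d[i, j] <- d[j, i] <- hamming_distance(documents[[members[i]]],
                                                 documents[[members[j]]])
    for (i in seq_along(members)) {
      ord <- order(d[i, ], seq_along(members))  # id order breaks ties
      nb <- ord[seq_len(min(neighbors_per_subject, length(members) - 1))]
      for (j in nb) {
        key <- paste(sort(c(members[i], members[j])), collapse = "|")
        out[[key]] <- data.frame(
          subject_a = sort(c(members[i], members[j]))[1],
          subject_b = sort(c(members[i], members[j]))[2],
          label = cl, distance = d[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(subject_a = character(0), subject_b = character(0),
                      label = integer(0), distance = integer(0)))
  res <- do.call(rbind, c(out[sort(names(out))], list(make.row.names = FALSE)))
  res
}

#' Cross two similar same-class documents into a synthetic document
#'
#' Position-wise parent crossover per activity: at each chronological
#' position of the common prefix the child's word comes from parent A or
#' parent B with probability 1/2; positions beyond the common prefix (and
#' activities present in only one parent) are copied from the longer /
#' present parent.  The label is the shared class.
#'
#' @param doc_a,doc_b same-class `pd_document`s.
#' @param seed integer seed.
#' @param mix_prob probability of drawing from parent A (default 0.5).
#' @return synthetic `pd_document` whose `subject_id` is marked
#'   `syn_mix_<a>+<b>` and which records its parents in `$parents`.
#' @export
mix_pair <- function(doc_a, doc_b, seed = 1L, mix_prob = 0.5) {
  if (is.na(doc_a$label) || doc_a$label != doc_b$label)
    pd_stop("parents must share a label", "pdmil_error_label_mismatch")
  hamming_distance(doc_a, doc_b)  # rejects incomparable pairs
  acts <- sort(union(unique(doc_a$words$activity_id),
                     unique(doc_b$words$activity_id)))
  pieces <- withr::with_seed(seed, lapply(acts, function(act) {
    wa <- doc_a$words[doc_a$words$activity_id == act, , drop = FALSE]
    wb <- doc_b$words[doc_b$words$activity_id == act, , drop = FALSE]
    wa <- wa[order(wa$window_index), , drop = FALSE]
    wb <- wb[order(wb$window_index), , drop = FALSE]
    n <- min(nrow(wa), nrow(wb))
    long <- if (nrow(wa) >= nrow(wb)) wa else wb
    child <- long
    if (n > 0) {
      from_a <- stats::runif(n) < mix_prob
      child$word_id[seq_len(n)] <- ifelse(from_a, wa$word_id[seq_len(n)],
                                          wb$word_id[seq_len(n)])
      child$cluster_id[seq_len(n)] <- ifelse(from_a, wa$cluster_id[seq_len(n)],
                                             wb$cluster_id[seq_len(n)])
    }
    child
  }))
  words <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  structure(list(subject_id = paste0("syn_mix_", doc_a$subject_id, "+",
                                     doc_b$subject_id, "_s", seed),
                 label = doc_a$label, words = words,
                 vocab_size = doc_a$vocab_size,
                 parents = c(doc_a$subject_id, doc_b$subject_id),
                 synthetic = TRUE),
            class = "pd_document")
}

#' Shuffle instance order within each activity of a bag
#'
#' Words are permuted uniformly at random within their activity block
#' (activity membership defines the vocabulary, so it is never
#' corrupted); the word multiset and the label are unchanged.
#'
#' @param document a `pd_document`.
#' @param seed integer seed.
#' @return synthetic `pd_document` (subject id marked `syn_shuf_...`).
#' @export
shuffle_bag <- function(document, seed = 1L) {
  if (nrow(document$words) == 0)
    pd_stop("document is empty", "pdmil_error_empty_document")
  words <- document$words
  words <- withr::with_seed(seed, {
    for (act in unique(words$activity_id)) {
      idx <- which(words$activity_id == act)
      perm <- sample(length(idx))
      words$word_id[idx] <- words$word_id[idx][perm]
      words$cluster_id[idx] <- words$cluster_id[idx][perm]
    }
    words
  })
  structure(list(subject_id = paste0("syn_shuf_", document$subject_id,
                                     "_s", seed),
                 label = document$label, words = words,
                 vocab_size = document$vocab_size,
                 parents = document$subject_id, synthetic = TRUE),
            class = "pd_document")
}

#' Augment a training set of documents to class balance
#'
#' Synthetic bags are generated by crossing Hamming-similar same-class
#' pairs ([mix_pair()]) and by within-activity instance shuffling
#' ([shuffle_bag()]), alternating between the enabled methods, until every
#' minority class reaches the majority-class subject count (default
#' policy) or the original count times `factor`.  Originals are always
#' retained; every synthetic bag records its parents.
#'
#' @param documents named list of labelled training `pd_document`s.
#' @param seed integer seed.
#' @param policy `"balance"` (default) or a positive numeric factor: each
#'   class is grown to `ceiling(factor * n_class)` bags.
#' @param methods subset of `c("mix", "shuffle")`.
#' @param neighbors_per_subject passed to [select_similar_pairs()].
#' @return named list: originals followed by synthetic documents.
#' @export
augment_training_set <- function(documents, seed = 1L, policy = "balance",
                                 methods = c("mix", "shuffle"),
                                 neighbors_per_subject = 1L) {
  stopifnot(all(methods %in% c("mix", "shuffle")))
  labs <- vapply(documents, `[[`, integer(1), "label")
  sizes <- table(factor(labs, levels = sort(unique(labs))))
  targets <- if (identical(policy, "balance")) {
    stats::setNames(rep(max(sizes), length(sizes)), names(sizes))
  } else {
    f <- as.numeric(policy)
    if (is.na(f) || f < 0)
      pd_stop("policy must be 'balance' or a non-negative factor",
              "pdmil_error_policy")
    stats::setNames(ceiling(f * as.numeric(sizes)), names(sizes))
  }
  pairs <- suppressWarnings(select_similar_pairs(documents,
                                                 neighbors_per_subject))
  out <- documents
  syn_i <- 0L
  for (cl in names(sizes)) {
    need <- targets[[cl]] - sizes[[cl]]
    if (need <= 0) next
    cl_int <- as.integer(cl)
    cl_pairs <- pairs[pairs$label == cl_int, , drop = FALSE]
    cl_docs <- documents[labs == cl_int]
    use_mix <- "mix" %in% methods && nrow(cl_pairs) > 0
    use_shuffle <- "shuffle" %in% methods
    if (!use_mix && !use_shuffle)
      pd_stop(sprintf("class %s cannot be augmented with the chosen methods",
                      cl), "pdmil_error_policy")
    if (!use_mix && "mix" %in% methods)
      pd_warn(sprintf("class %s has no pairs; using shuffle only", cl),
              "pdmil_warning_singleton_class")
    gen_i <- 0L
    while (need > 0) {
      gen_i <- gen_i + 1L
      syn_i <- syn_i + 1L
      s <- derive_seed(seed, 1000L * cl_int, syn_i)
      take_mix <- use_mix && (!use_shuffle || gen_i %% 2L == 1L)
      child <- if (take_mix) {
        p <- cl_pairs[((gen_i - 1L) %/% (if (use_shuffle) 2L else 1L)) %%
                        nrow(cl_pairs) + 1L, ]
        mix_pair(documents[[p$subject_a]], documents[[p$subject_b]], s)
      } else {
        d <- cl_docs[[(gen_i - 1L) %% length(cl_docs) + 1L]]
        shuffle_bag(d, s)
      }
      out[[child$subject_id]] <- child
      need <- need - 1L
    }
  }
  out
}
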