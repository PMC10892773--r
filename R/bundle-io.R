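#' Export documents as plain text for inspection
#'
#' One subject per line: `subject_id label w1 w2 w3 ...` with global
#' word ids whitespace-separated in chronological order.
#'
#' @param documents named list of `pd_document`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_documents <- function(documents, path) {
  lines <- vapply(documents, function(d)
    paste(c(d$subject_id, d$label, d$words$word_id), collapse = " "), "")
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a fitted model bundle to a directory
#'
#' Plain-text layout: per-activity codebook centroids and standardizer
#' (`codebook_<a>.csv`), the topic-word matrix (`lda_phi.csv`) and a
#' JSON fingerprint of the configuration, seeds and training subjects.
#'
#' @param bundle result of an internal fold fit (codebooks + optional
#'   lda + config), e.g. as embedded in pipeline runs.
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_model_bundle <- function(bundle, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  cb <- bundle$codebooks
  for (a in cb$activities) {
    b <- cb$books[[as.character(a)]]
    df <- data.frame(rbind(b$centroids, mean = b$center_mean,
                           sd = b$center_sd))
    names(df) <- cb$feature_cols
    data.table::fwrite(cbind(row = rownames(df), df),
                       file.path(directory, sprintf("codebook_%d.csv", a)))
  }
  if (!is.null(bundle$lda))
    data.table::fwrite(as.data.frame(bundle$lda$phi),
                       file.path(directory, "lda_phi.csv"))
  fp <- list(k = cb$k, activities = cb$activities, seed = cb$seed,
             fit_subject_ids = cb$fit_subject_ids,
             t = bundle$lda$t, alpha = bundle$lda$alpha,
             beta = bundle$lda$beta, lda_seed = bundle$lda$seed,
             config = bundle$config)
  jsonlite::write_json(fp, file.path(directory, "fingerprint.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Load a model bundle saved by [save_model_bundle()]
#'
#' @param directory directory written by [save_model_bundle()].
#' @return list with `codebooks` (usable by [build_document()]) and, if
#'   present, `lda` (usable by [topic_vector()]).
#' @export
load_model_bundle <- function(directory) {
  fp <- jsonlite::read_json(file.path(directory, "fingerprint.json"),
                            simplifyVector = TRUE)
  books <- list()
  for (a in fp$activities) {
    df <- data.table::fread(file.path(directory,
                                      sprintf("codebook_%d.csv", a)))
    m <- as.matrix(df[, -1])
    rownames(m) <- df$row
    nk <- nrow(m) - 2L
    books[[as.character(a)]] <- list(
      activity_id = a, k = as.integer(fp$k),
      centroids = m[seq_len(nk), , drop = FALSE],
      center_mean = m["mean", ], center_sd = m["sd", ])
  }
  codebooks <- structure(
    list(activities = fp$activities, k = as.integer(fp$k), books = books,
         feature_cols = names(books[[1]]$center_mean),
         fit_subject_ids = fp$fit_subject_ids, seed = fp$seed),
    class = "pd_codebooks")
  lda <- NULL
  if (file.exists(file.path(directory, "lda_phi.csv"))) {
    phi <- as.matrix(data.table::fread(file.path(directory, "lda_phi.csv")))
    dimnames(phi) <- NULL
    lda <- structure(list(phi = phi, theta = NULL, t = as.integer(fp$t),
                          vocab_size = ncol(phi), alpha = fp$alpha,
                          beta = fp$beta, seed = fp$lda_seed),
                     class = "pd_lda")
  }
  list(codebooks = codebooks, lda = lda, config = fp$config)
}

#' Audit table of synthetic bag parentage
#'
#' @param documents a (possibly augmented) named list of `pd_document`.
#' @return data.frame with one row per synthetic bag: id, label, method
#'   (`mix`/`shuffle`) and its parent subject ids.
#' @export
augmentation_audit <- function(documents) {
  syn <- Filter(function(d) isTRUE(d$synthetic), documents)
  if (length(syn) == 0)
    return(data.frame(subject_id = character(0), label = integer(0),
                      method = character(0), parents = character(0)))
  data.frame(
    subject_id = vapply(syn, `[[`, "", "subject_id"),
    label = vapply(syn, `[[`, 0L, "label"),
    method = ifelse(grepl("^syn_mix_", names(syn)), "mix", "shuffle"),
    parents = vapply(syn, function(d) paste(d$parents, collapse = "+"), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
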