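# Shared fixtures, generated in code and cached for the test run.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# 12-subject, 2-activity default-preset cohort: cheap all-rounder
small_cohort <- function() {
  cached("small", generate_cohort(c(3L, 3L, 3L, 3L), seed = 101L,
                                  activities = 2:3, duration = 20))
}

small_features <- function() {
  cached("small_fx", cohort_features(small_cohort()))
}

# codebooks + documents on the small cohort
small_documents <- function() {
  cached("small_docs", {
    fx <- small_features()
    cb <- fit_activity_codebooks(fx, k = 4L, seed = 5L)
    build_documents(fx, cb)
  })
}

# synthetic recording with known content
tone_recording <- function(freqs = rep(2, 6), amps = rep(1, 6),
                           duration = 10, fs = 200, offset = 0,
                           noise_sd = 0) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  m <- sapply(seq_len(6), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t) +
      if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0)
  m <- m + offset
  colnames(m) <- c("ax", "ay", "az", "gx", "gy", "gz")
  structure(list(subject_id = "T01", activity_id = 2L, sample_rate = fs,
                 duration = duration, data = m),
            class = "pd_recording")
}

# hand-built document from a word-id vector (single activity, k words)
doc_from_words <- function(word_ids, subject_id = "D01", label = 1L,
                           activity_id = 2L, k = 8L, n_activities = 1L) {
  structure(list(
    subject_id = subject_id, label = as.integer(label),
    words = data.frame(activity_id = rep(activity_id, length(word_ids)),
                       window_index = seq_along(word_ids) - 1L,
                       cluster_id = as.integer(word_ids) %% k,
                       word_id = as.integer(word_ids)),
    vocab_size = as.integer(n_activities * k)),
    class = "pd_document")
}

# adjusted Rand index (independent oracle for cluster agreement)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ij <- sum_i * sum_j / n
  (sum_ij - exp_ij) / ((sum_i + sum_j) / 2 - exp_ij)
}

# 3-12 Hz band power of one channel via raw periodogram
bandpower <- function(x, fs = 200, lo = 3, hi = 12) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (0:(n - 1)) * fs / n
  sum(sp[f >= lo & f <= hi & f <= fs / 2])
}
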