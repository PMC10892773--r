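#' Write a cohort to disk
#'
#' One CSV per subject x activity (`<subject>_<activity>.csv`, header
#' `t,ax,ay,az,gx,gy,gz`) plus a `manifest.json` listing subjects, labels,
#' activities and the sampling rate.  Numeric columns are written with 9
#' significant digits (beyond float32 precision), so a round trip through
#' [read_cohort()] reproduces signals within float32 tolerance and output
#' is byte-identical for identical cohorts.
#'
#' @param cohort a `pd_cohort`.
#' @param directory output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (key in names(cohort$recordings)) {
    rec <- cohort$recordings[[key]]
    fn <- sprintf("%s_%d.csv", rec$subject_id, rec$activity_id)
    df <- data.table::data.table(
      t = signif((seq_len(nrow(rec$data)) - 1) / rec$sample_rate, 9))
    for (ch in CHANNEL_NAMES) df[[ch]] <- signif(rec$data[, ch], 9)
    data.table::fwrite(df, file.path(directory, fn))
    files <- c(files, fn)
  }
  manifest <- list(
    sample_rate = cohort$config$sample_rate,
    duration = cohort$config$duration,
    preset = cohort$config$preset,
    seed = cohort$config$seed,
    activities = cohort$config$activities,
    subjects = lapply(seq_len(nrow(cohort$subjects)), function(i) {
      s <- cohort$subjects[i, ]
      list(subject_id = s$subject_id, severity = s$severity,
           tremor_amp = s$tremor_amp, brady_factor = s$brady_factor,
           duty_cycle = s$duty_cycle,
           files = grep(paste0("^", s$subject_id, "_"), files, value = TRUE))
    }))
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory holding `manifest.json` and the CSVs.
#' @return a `pd_cohort` (profiles are not reconstructed; subjects, labels
#'   and signals are).
#' @export
read_cohort <- function(directory) {
  path <- file.path(directory, "manifest.json")
  if (!file.exists(path))
    pd_stop(sprintf("manifest not found: %s", path),
            "pdmil_error_missing_manifest")
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  recordings <- list()
  subjects <- data.frame()
  for (s in manifest$subjects) {
    subjects <- rbind(subjects, data.frame(
      subject_id = s$subject_id, severity = as.integer(s$severity),
      tremor_amp = s$tremor_amp, brady_factor = s$brady_factor,
      duty_cycle = s$duty_cycle, stringsAsFactors = FALSE))
    for (fn in unlist(s$files)) {
      fp <- file.path(directory, fn)
      if (!file.exists(fp))
        pd_stop(sprintf("recording file listed in manifest is missing: %s", fn),
                "pdmil_error_missing_file")
      df <- data.table::fread(fp)
      if (!identical(names(df), c("t", CHANNEL_NAMES)))
        pd_stop(sprintf(
          "%s: expected columns t,%s but found %s", fn,
          paste(CHANNEL_NAMES, collapse = ","), paste(names(df), collapse = ",")),
          "pdmil_error_bad_schema")
      tv <- df$t
      if (any(diff(tv) <= 0))
        pd_stop(sprintf("%s: time column is not strictly increasing", fn),
                "pdmil_error_bad_time")
      activity_id <- as.integer(sub(".*_(\\d+)\\.csv$", "\\1", fn))
      m <- as.matrix(df[, CHANNEL_NAMES, with = FALSE])
      colnames(m) <- CHANNEL_NAMES
      recordings[[paste0(s$subject_id, "_", activity_id)]] <-
        structure(list(subject_id = s$subject_id, activity_id = activity_id,
                       sample_rate = manifest$sample_rate,
                       duration = nrow(m) / manifest$sample_rate, data = m),
                  class = "pd_recording")
    }
  }
  structure(list(subjects = subjects, profiles = NULL,
                 recordings = recordings,
                 config = list(sample_rate = manifest$sample_rate,
                               duration = manifest$duration,
                               preset = manifest$preset %||% "default",
                               seed = manifest$seed %||% NA_integer_,
                               activities = as.integer(unlist(manifest$activities)))),
            class = "pd_cohort")
}
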