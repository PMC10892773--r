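#' Synthetic Parkinson's wearable-IMU cohort generator
#'
#' Emulates the structure of a wrist-worn IMU severity-staging study: each
#' subject performs up to 12 scripted activities while a 200 Hz 6-channel
#' sensor (tri-axial accelerometer, m/s^2; tri-axial gyroscope, rad/s)
#' records.  Severity is a subject-level 4-class label (0 = healthy,
#' 1 = mild, 2 = moderate, 3 = severe).  Symptoms are intermittent:
#' severity-graded tremor in the clinical bands (rest 3-6 Hz, postural
#' 4-12 Hz, kinetic 2-7 Hz) switches on and off in contiguous multi-second
#' blocks covering roughly `duty_cycle` of the recording, and bradykinesia
#' scales both the amplitude and the rate of the voluntary base movement.
#'
#' @name simulate
NULL

PD_ACTIVITIES <- 1:12
# clinical tremor band per activity: activities are mostly voluntary
# (kinetic); arms-out / finger-to-nose are postural; slow object
# interactions treated as rest-dominated
PD_ACTIVITY_TYPE <- c("rest", "kinetic", "kinetic", "kinetic", "kinetic",
                      "postural", "postural", "postural", "kinetic",
                      "rest", "rest", "rest")
PD_TREMOR_BAND <- list(rest = c(3, 6), postural = c(4, 12), kinetic = c(2, 7))

# voluntary-movement fundamental per activity, Hz (0.5-3 Hz range)
PD_BASE_FREQ <- round(seq(0.6, 2.8, length.out = 12), 2)

CHANNEL_NAMES <- c("ax", "ay", "az", "gx", "gy", "gz")
GRAVITY <- 9.81

# Class-conditional symptom parameter ranges -- the generator's stated
# world.  Severity acts mainly through symptom LOAD: the fraction of the
# recording spent in the symptomatic ON state grows with stage
# (duty anchor is the severe class; stages 1..3 take 1/3, 2/3 and 1 of
# it, with per-subject jitter), while per-episode tremor amplitude and
# bradykinesia ranges OVERLAP between adjacent stages.  A single window
# is therefore genuinely ambiguous (instances of different stages can
# look alike, and OFF instances look healthy) but the composition of a
# subject's whole bag is informative -- the weak-label structure this
# pipeline is built for.  Presets trade duty separation and noise level
# against overlap.
pd_presets <- function(preset = c("default", "easy", "hard")) {
  preset <- match.arg(preset)
  switch(preset,
    easy = list(
      tremor_amp  = list(c(0, 0), c(0.8, 1.4), c(1.4, 2.2), c(2.2, 3.2)),
      brady       = list(c(1, 1), c(0.75, 0.95), c(0.60, 0.80), c(0.45, 0.65)),
      duty_cycle  = 0.9, duty_jitter = 0.03, noise_sd = 0.3,
      intensity_jitter = 0.25),
    hard = list(
      tremor_amp  = list(c(0, 0), c(0.3, 1.2), c(0.5, 1.8), c(0.8, 2.4)),
      brady       = list(c(1, 1), c(0.65, 1.00), c(0.50, 0.95), c(0.40, 0.90)),
      duty_cycle  = 0.3, duty_jitter = 0.05, noise_sd = 0.5,
      intensity_jitter = 0.6),
    default = list(
      tremor_amp  = list(c(0, 0), c(0.5, 1.5), c(1.0, 2.5), c(1.5, 3.5)),
      brady       = list(c(1, 1), c(0.70, 0.95), c(0.55, 0.85), c(0.40, 0.75)),
      duty_cycle  = 0.6, duty_jitter = 0.05, noise_sd = 0.4,
      intensity_jitter = 0.45))
}

# stage-wise duty multiplier on the preset's severe-class anchor
PD_DUTY_GRADE <- c(0, 0.5, 0.75, 1)

#' Create a subject profile
#'
#' @param subject_id character id.
#' @param severity integer 0-3.
#' @param tremor_freq named numeric vector, one frequency (Hz) per activity
#'   id as character name; must lie in the activity's clinical band.
#' @param tremor_amp tremor gain relative to unit base motion; must be 0
#'   for severity 0.
#' @param brady_factor base-motion amplitude/rate multiplier in (0, 1];
#'   1 for severity 0.
#' @param duty_cycle fraction of the recording in the symptomatic ON state.
#' @param rng_seed integer seed making the subject's signals reproducible.
#' @return object of class `pd_subject_profile`.
#' @export
subject_profile <- function(subject_id, severity, tremor_freq, tremor_amp,
                            brady_factor, duty_cycle, rng_seed) {
  severity <- as.integer(severity)
  if (!severity %in% 0:3)
    pd_stop("severity must be in 0..3", "pdmil_error_profile")
  if (severity == 0L && (tremor_amp != 0 || brady_factor != 1))
    pd_stop("severity 0 requires tremor_amp = 0 and brady_factor = 1",
            "pdmil_error_profile")
  if (duty_cycle < 0 || duty_cycle > 1)
    pd_stop("duty_cycle must be in [0, 1]", "pdmil_error_profile")
  if (brady_factor <= 0 || brady_factor > 1)
    pd_stop("brady_factor must be in (0, 1]", "pdmil_error_profile")
  for (a in names(tremor_freq)) {
    band <- PD_TREMOR_BAND[[PD_ACTIVITY_TYPE[as.integer(a)]]]
    if (severity > 0 &&
        (tremor_freq[[a]] < band[1] || tremor_freq[[a]] > band[2]))
      pd_stop(sprintf("tremor_freq %.2f Hz outside band [%g, %g] for activity %s",
                      tremor_freq[[a]], band[1], band[2], a),
              "pdmil_error_profile")
  }
  structure(list(subject_id = subject_id, severity = severity,
                 tremor_freq = tremor_freq, tremor_amp = tremor_amp,
                 brady_factor = brady_factor, duty_cycle = duty_cycle,
                 rng_seed = as.integer(rng_seed)),
            class = "pd_subject_profile")
}

# Draw a class-conditional profile.  By default the symptomatic ON
# fraction is severity-graded (PD_DUTY_GRADE times the preset's
# severe-class anchor); an explicit `duty_override` fixes the same ON
# fraction for every symptomatic stage (used to study the weak-label
# regime where stages differ only in symptom expression, not load).
random_profile <- function(subject_id, severity, preset, seed,
                           activities = PD_ACTIVITIES, duty_override = NULL) {
  pp <- pd_presets(preset)
  withr::with_seed(seed, {
    amp <- stats::runif(1, pp$tremor_amp[[severity + 1]][1],
                        pp$tremor_amp[[severity + 1]][2])
    brady <- stats::runif(1, pp$brady[[severity + 1]][1],
                          pp$brady[[severity + 1]][2])
    duty <- (if (is.null(duty_override))
      pp$duty_cycle * PD_DUTY_GRADE[severity + 1] else duty_override) +
      stats::runif(1, -pp$duty_jitter, pp$duty_jitter)
    tf <- vapply(activities, function(a) {
      band <- PD_TREMOR_BAND[[PD_ACTIVITY_TYPE[a]]]
      stats::runif(1, band[1], band[2])
    }, numeric(1))
  })
  names(tf) <- as.character(activities)
  if (severity == 0L) { amp <- 0; brady <- 1; duty <- 0 }
  subject_profile(subject_id, severity, tf, amp, brady,
                  min(1, max(0.02, duty)), seed)
}

#' Simulate all recordings for one subject
#'
#' Signal model per channel: a voluntary base oscillation at the
#' activity's fundamental (axis-specific phases) + white Gaussian noise;
#' gravity offset on the accelerometer z axis.  The whole motion signal
#' carries a random per-recording gain (sensor placement and posture make
#' absolute amplitudes incomparable across sessions -- the reason the
#' pipeline z-scores per recording).  Symptoms are episodic: during ON
#' blocks (contiguous 3 s segments, `round(duty_cycle *
#' n_blocks)` of them) the base motion is bradykinesia-scaled in both
#' amplitude and rate and a tremor sinusoid, shared in phase across the
#' axes of a sensor triad (so inter-axis correlation grows with tremor
#' share), is added.  OFF blocks look like healthy motion — the
#' weak-label structure this generator emulates is precisely that many
#' instances from a symptomatic subject resemble healthy instances.
#' Deterministic given `profile$rng_seed`.
#'
#' @param profile a [subject_profile()].
#' @param activities integer activity ids (subset of 1..12).
#' @param duration seconds per recording (>= 20, mirroring the study's
#'   exclusion of shorter activities).
#' @param sample_rate Hz, default 200.
#' @param noise_sd white-noise standard deviation.
#' @param intensity_jitter half-width of the per-episode symptom-intensity
#'   multiplier `U(1 - j, 1 + j)`: tremor amplitude and slowing fluctuate
#'   between ON blocks, so one window measures the subject's mean symptom
#'   load only noisily.
#' @return list of `pd_recording` objects, one per activity, each holding a
#'   `length x 6` matrix of channels `ax ay az gx gy gz`.
#' @export
generate_subject <- function(profile, activities = PD_ACTIVITIES,
                             duration = 30, sample_rate = 200,
                             noise_sd = 0.4, intensity_jitter = 0.45) {
  if (!all(activities %in% PD_ACTIVITIES))
    pd_stop(sprintf("unknown activity id(s): %s",
                    paste(setdiff(activities, PD_ACTIVITIES), collapse = ",")),
            "pdmil_error_unknown_activity")
  if (duration * sample_rate < 300)
    pd_stop("duration shorter than one 300-sample window",
            "pdmil_error_duration")
  lapply(activities, function(a)
    simulate_recording(profile, a, duration, sample_rate, noise_sd,
                       intensity_jitter))
}

simulate_recording <- function(profile, activity_id, duration, sample_rate,
                               noise_sd, intensity_jitter = 0.45) {
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  seed <- derive_seed(profile$rng_seed, 7919L * activity_id)
  f_base <- PD_BASE_FREQ[activity_id]
  f_trem <- profile$tremor_freq[[as.character(activity_id)]]
  # axis gains: tremor projects coherently on all axes with decaying gain
  trem_gain <- c(1, 0.8, 0.6, 0.9, 0.7, 0.5)
  base_amp <- c(1, 0.9, 0.8, 1, 0.85, 0.7)
  x <- withr::with_seed(seed, {
    g <- on_off_gate(n, sample_rate, profile$duty_cycle)
    # symptom expression fluctuates between episodes: each ON block gets
    # its own tremor-intensity and slowing multiplier, so a single window
    # is a noisy measurement of the subject's mean symptom load
    u <- stats::runif(max(1, max(g$block)), 1 - intensity_jitter,
                      1 + intensity_jitter)
    v <- stats::runif(max(1, max(g$block)), 1 - intensity_jitter,
                      1 + intensity_jitter)
    amp_t <- profile$tremor_amp * g$gate *
      u[pmax(g$block, 1L)]
    # bradykinesia acts only during symptomatic episodes: amplitude and
    # instantaneous rate of the voluntary movement shrink
    slow <- pmax(0.15, 1 - g$gate * (1 - profile$brady_factor) *
                   v[pmax(g$block, 1L)])
    phase_inc <- cumsum(2 * pi * f_base * slow / sample_rate)
    phase_base <- stats::runif(6, 0, 2 * pi)
    phase_trem <- stats::runif(2, 0, 2 * pi)  # one per sensor triad
    session_gain <- stats::runif(1, 0.6, 1.5)
    m <- matrix(stats::rnorm(n * 6, sd = noise_sd), n, 6)
    for (c_ in 1:6) {
      ph_t <- if (c_ <= 3) phase_trem[1] else phase_trem[2]
      m[, c_] <- m[, c_] + session_gain *
        (slow * base_amp[c_] * sin(phase_inc + phase_base[c_]) +
           amp_t * trem_gain[c_] * sin(2 * pi * f_trem * t + ph_t))
    }
    m[, 3] <- m[, 3] + GRAVITY
    m
  })
  colnames(x) <- CHANNEL_NAMES
  structure(list(subject_id = profile$subject_id, activity_id = activity_id,
                 sample_rate = sample_rate, duration = duration, data = x),
            class = "pd_recording")
}

# ON/OFF gate built from 3 s blocks: round(duty_cycle * n_blocks) blocks
# are ON, arranged as one or two contiguous episodes at random positions.
# Few episode boundaries keep the fraction of windows that touch the ON
# state close to duty_cycle (every boundary dilates window coverage by up
# to one window length).  Returns the 0/1 gate and each sample's block
# index so per-episode intensities can be attached.
on_off_gate <- function(n, sample_rate, duty_cycle, block_s = 3) {
  block <- round(block_s * sample_rate)
  n_blocks <- max(1L, floor(n / block))
  idx <- pmin(ceiling(seq_len(n) / block), n_blocks)
  if (duty_cycle <= 0)
    return(list(gate = numeric(n), block = idx))
  if (duty_cycle >= 1)
    return(list(gate = rep(1, n), block = idx))
  n_on <- min(max(round(duty_cycle * n_blocks), 1L), n_blocks - 1L)
  n_runs <- if (n_on <= 2L) 1L else 2L
  lens <- if (n_runs == 1L) n_on else c(ceiling(n_on / 2), floor(n_on / 2))
  # distribute the OFF blocks into the gaps around/between the episodes
  gaps <- stats::rmultinom(1, n_blocks - n_on, rep(1, n_runs + 1))[, 1]
  on <- integer(0)
  pos <- 0L
  for (r in seq_len(n_runs)) {
    pos <- pos + gaps[r]
    on <- c(on, pos + seq_len(lens[r]))
    pos <- pos + lens[r]
  }
  list(gate = as.numeric(idx %in% on), block = idx)
}

#' Simulate a labelled cohort
#'
#' Subject counts per class default to the demographic split of the study
#' population this generator emulates (15 healthy / 41 mild / 17 moderate /
#' 12 severe).  Within-class symptom parameters are drawn per subject from
#' class-conditional ranges, so subjects of one stage differ individually.
#'
#' @param class_sizes integer vector of length 4 (healthy, mild, moderate,
#'   severe).
#' @param seed master seed; every subject derives its own stream from it.
#' @param activities activity ids each subject performs.
#' @param duration seconds per recording.
#' @param preset `"default"`, `"easy"` (strong separation, duty 0.9) or
#'   `"hard"` (overlapping classes, duty 0.3).
#' @param sample_rate Hz.
#' @param duty_cycle optional uniform ON-fraction override applied to all
#'   symptomatic stages (by default the ON fraction is severity-graded:
#'   0.5/0.75/1 times the preset anchor).
#' @return object of class `pd_cohort`: `subjects` data.frame (id, severity
#'   and symptom parameters), `recordings` (named list, one entry per
#'   subject x activity), and the generating `config`.
#' @export
generate_cohort <- function(class_sizes = c(15L, 41L, 17L, 12L), seed = 1L,
                            activities = PD_ACTIVITIES, duration = 30,
                            preset = "default", sample_rate = 200,
                            duty_cycle = NULL) {
  if (length(class_sizes) != 4 || any(class_sizes < 0))
    pd_stop("class_sizes must be 4 non-negative integers",
            "pdmil_error_class_sizes")
  pp <- pd_presets(preset)
  sev <- rep(0:3, times = class_sizes)
  ids <- sprintf("S%03d", seq_along(sev))
  profiles <- recordings <- list()
  for (i in seq_along(sev)) {
    prof <- random_profile(ids[i], sev[i], preset, derive_seed(seed, i),
                           activities, duty_cycle)
    profiles[[ids[i]]] <- prof
    recs <- generate_subject(prof, activities, duration, sample_rate,
                             noise_sd = pp$noise_sd,
                             intensity_jitter = pp$intensity_jitter)
    for (r in recs)
      recordings[[paste0(r$subject_id, "_", r$activity_id)]] <- r
  }
  subjects <- data.frame(
    subject_id = ids, severity = sev,
    tremor_amp = vapply(profiles, `[[`, numeric(1), "tremor_amp"),
    brady_factor = vapply(profiles, `[[`, numeric(1), "brady_factor"),
    duty_cycle = vapply(profiles, `[[`, numeric(1), "duty_cycle"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(subjects = subjects, profiles = profiles,
                 recordings = recordings,
                 config = list(class_sizes = as.integer(class_sizes),
                               seed = as.integer(seed),
                               activities = as.integer(activities),
                               duration = duration, preset = preset,
                               sample_rate = sample_rate,
                               duty_cycle = duty_cycle)),
            class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf("pd_cohort: %d subjects (%s), %d recordings, %g s @ %g Hz, preset '%s'\n",
              nrow(x$subjects),
              paste(tabulate(x$subjects$severity + 1L, 4L), collapse = "/"),
              length(x$recordings), x$config$duration,
              x$config$sample_rate, x$config$preset))
  invisible(x)
}

#' @export
print.pd_recording <- function(x, ...) {
  cat(sprintf("pd_recording %s activity %d: %d samples x 6 channels @ %g Hz\n",
              x$subject_id, x$activity_id, nrow(x$data), x$sample_rate))
  invisible(x)
}
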