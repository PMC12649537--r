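#' Frequency bands used by the synthetic generator
#' @return Named list of band edges in Hz (all inside the 4-47 Hz analysis band).
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 45))
}

#' Default class-conditional band-power signatures
#'
#' Physiologically motivated (but synthetic) cluster-level spectral targets
#' for the four-quadrant scheme: high valence is expressed as a left-right
#' alpha-power asymmetry over temporal/parietal clusters (reduced on the
#' left, elevated on the right; reversed for low valence), and high arousal
#' as elevated beta and gamma power in frontal, central and mid-parietal
#' clusters. `contrast` scales the class effect multiplicatively
#' (`contrast = 0` collapses all classes onto the base spectrum).
#'
#' @param scheme labelling scheme (currently `"quadrant"`, `"valence2"` or
#'   `"arousal2"`).
#' @param contrast non-negative effect-strength dial.
#' @return Named list: class name -> 9 x 4 matrix of band-power targets
#'   (rows clusters, columns theta/alpha/beta/gamma, units uV^2).
#' @export
default_signatures <- function(scheme = "quadrant", contrast = 1) {
  base <- matrix(rep(c(theta = 4, alpha = 10, beta = 5, gamma = 2), each = 9L),
                 nrow = 9L, dimnames = list(cluster_order(), names(eeg_bands())))
  left <- c("left_temporal", "left_parietal")
  right <- c("right_temporal", "right_parietal")
  arous <- c("frontal", "central", "mid_parietal")
  apply_effects <- function(hv, ha) {
    m <- base
    if (!is.na(hv)) {
      lo <- 0.4^contrast; hi <- 2.0^contrast
      if (hv) { m[left, "alpha"] <- m[left, "alpha"] * lo
                m[right, "alpha"] <- m[right, "alpha"] * hi }
      else    { m[left, "alpha"] <- m[left, "alpha"] * hi
                m[right, "alpha"] <- m[right, "alpha"] * lo }
    }
    if (!is.na(ha)) {
      f <- if (ha) 2.5^contrast else 0.6^contrast
      m[arous, "beta"] <- m[arous, "beta"] * f
      m[arous, "gamma"] <- m[arous, "gamma"] * f
    }
    m
  }
  switch(scheme,
    quadrant = list(HVHA = apply_effects(TRUE, TRUE),
                    LVHA = apply_effects(FALSE, TRUE),
                    LVLA = apply_effects(FALSE, FALSE),
                    HVLA = apply_effects(TRUE, FALSE)),
    valence2 = list(Low = apply_effects(FALSE, NA), High = apply_effects(TRUE, NA)),
    arousal2 = list(Low = apply_effects(NA, FALSE), High = apply_effects(NA, TRUE)),
    stop("no default signatures for scheme: ", scheme))
}

#' Specification of the class-conditional synthetic EEG generator
#'
#' Each generated channel is a sum of per-band narrowband oscillations whose
#' power follows the class x cluster signature, a 1/f background, and
#' Poisson-timed blink transients on prefrontal channels. Per-subject
#' variability enters as a multiplicative band gain and a peak-frequency
#' jitter, both drawn once per subject from the spec seed.
#'
#' @param n_subjects,trials_per_subject cohort size.
#' @param fs sampling rate in Hz (>= 64).
#' @param trial_seconds trial length in seconds.
#' @param montage_name montage of the shipped default maps.
#' @param class_scheme labelling scheme (see [ratings_to_class()]).
#' @param signatures class signatures, default [default_signatures()].
#' @param noise_exponent 1/f spectral exponent of the background.
#' @param noise_amplitude background standard deviation in uV (0 disables).
#' @param blink_rate blinks per minute on fronto-polar channels.
#' @param blink_amplitude blink peak amplitude in uV.
#' @param subject_gain_sd sd of the per-subject log band gain.
#' @param subject_freq_jitter_sd sd (Hz) of the per-subject peak-frequency jitter.
#' @param seed master seed; everything downstream is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 6L, trials_per_subject = 16L, fs = 128,
                           trial_seconds = 20, montage_name = "toy-9ch",
                           class_scheme = "quadrant",
                           signatures = default_signatures(class_scheme),
                           noise_exponent = 1, noise_amplitude = 2,
                           blink_rate = 6, blink_amplitude = 40,
                           subject_gain_sd = 0.1, subject_freq_jitter_sd = 0.5,
                           seed = 42L) {
  if (fs < 64) stop("fs must be >= 64 Hz")
  stopifnot(all(vapply(signatures, function(m) all(m >= 0), TRUE)))
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 fs = fs, trial_seconds = trial_seconds,
                 montage_name = montage_name, class_scheme = class_scheme,
                 signatures = signatures, noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude, blink_rate = blink_rate,
                 blink_amplitude = blink_amplitude,
                 subject_gain_sd = subject_gain_sd,
                 subject_freq_jitter_sd = subject_freq_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic per-subject gain / frequency-jitter draws
subject_profile <- function(spec, subject_index) {
  withr_seed(spec$seed + 7919L * subject_index, {
    bands <- names(eeg_bands())
    list(gain = stats::setNames(exp(stats::rnorm(4, sd = spec$subject_gain_sd)), bands),
         fjit = stats::setNames(stats::rnorm(4, sd = spec$subject_freq_jitter_sd), bands))
  })
}

one_over_f_noise <- function(n, fs, exponent, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  mag <- f^(-exponent / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec_half <- mag * exp(1i * phase)
  full <- complex(n)
  full[2:(nf + 1L)] <- spec_half
  if (n %% 2L == 0L) full[nf + 1L] <- Re(full[nf + 1L])
  full[seq(n, n - nf + 2L)] <- Conj(spec_half[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

# Band-limited Gaussian oscillation: complex-Gaussian spectrum restricted to
# `band`, softly peaked at the (subject-jittered) centre frequency fc, and
# scaled so the time-domain variance equals `power` exactly. A stochastic
# narrowband process is closer to real EEG rhythms than a pure tone: its
# amplitude and instantaneous frequency wander within the band.
narrowband_oscillation <- function(n, fs, band, fc, power) {
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) return(numeric(n))
  shape <- numeric(nf)
  shape[sel] <- 1 + 2 * exp(-(f[sel] - fc)^2 / (2 * 1.5^2))
  re <- stats::rnorm(nf) * shape
  im <- stats::rnorm(nf) * shape
  spec_half <- complex(real = re, imaginary = im)
  full <- complex(n)
  full[2:(nf + 1L)] <- spec_half
  if (n %% 2L == 0L) full[nf + 1L] <- Re(full[nf + 1L])
  full[seq(n, n - nf + 2L)] <- Conj(spec_half[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * sqrt(power) / stats::sd(x)
}

blink_template <- function(fs) {
  n <- round(0.3 * fs)                       # 300-ms raised cosine
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

ratings_for_class <- function(scheme, class_idx) {
  pick <- function(lo, hi) sample(lo:hi, 1L)
  r <- list(valence = pick(1, 9), arousal = pick(1, 9), dominance = pick(1, 9))
  if (scheme == "quadrant") {
    cls <- quadrant_classes()[class_idx + 1L]
    r$valence <- if (substr(cls, 1, 2) == "HV") pick(6, 9) else pick(1, 5)
    r$arousal <- if (substr(cls, 3, 4) == "HA") pick(6, 9) else pick(1, 5)
  } else if (scheme %in% c("valence2", "arousal2", "dominance2")) {
    dimn <- sub("2$", "", scheme)
    r[[dimn]] <- if (class_idx == 1L) pick(6, 9) else pick(1, 5)
  } else if (scheme %in% c("valence3", "arousal3", "dominance3")) {
    dimn <- sub("3$", "", scheme)
    r[[dimn]] <- pick(1 + 3 * class_idx, 3 + 3 * class_idx)
  } else if (scheme == "seed3") {
    r <- list(valence = class_idx - 1L)
  }
  r
}

#' Generate one synthetic trial
#'
#' @param spec a [synthetic_spec()].
#' @param subject subject index (1-based).
#' @param class_idx 0-based class index under the spec's scheme.
#' @param seed RNG seed for this trial.
#' @return A [raw_recording()] whose ratings map back to `class_idx` under
#'   the spec's labelling scheme.
#' @export
generate_trial <- function(spec, subject, class_idx, seed) {
  map <- default_cluster_map(spec$montage_name)
  labels <- unlist(map$clusters, use.names = FALSE)
  cl_of <- rep(names(map$clusters), vapply(map$clusters, length, 1L))
  sig <- spec$signatures[[class_idx + 1L]]
  prof <- subject_profile(spec, subject)
  n <- round(spec$trial_seconds * spec$fs)
  tt <- seq_len(n) / spec$fs
  bands <- eeg_bands()
  withr_seed(seed, {
    data <- matrix(0, length(labels), n)
    for (ch in seq_along(labels)) {
      x <- numeric(n)
      for (b in names(bands)) {
        target <- sig[cl_of[ch], b] * prof$gain[[b]]
        if (target <= 0) next
        fc <- mean(bands[[b]]) + prof$fjit[[b]]
        x <- x + narrowband_oscillation(n, spec$fs, bands[[b]], fc, target)
      }
      x <- x + one_over_f_noise(n, spec$fs, spec$noise_exponent, spec$noise_amplitude)
      data[ch, ] <- x
    }
    # blink transients on prefrontal channels
    pf <- which(cl_of == "prefrontal")
    n_blinks <- stats::rpois(1, spec$blink_rate * spec$trial_seconds / 60)
    if (n_blinks > 0 && length(pf) > 0) {
      tpl <- blink_template(spec$fs) * spec$blink_amplitude
      for (i in seq_len(n_blinks)) {
        s <- sample.int(n - length(tpl), 1L)
        for (ch in pf) data[ch, s:(s + length(tpl) - 1L)] <-
          data[ch, s:(s + length(tpl) - 1L)] + tpl
      }
    }
    ratings <- ratings_for_class(spec$class_scheme, class_idx)
    raw_recording(data, spec$fs, labels,
                  subject_id = sprintf("s%02d", subject),
                  trial_id = sprintf("s%02d_t%03d_seed%d", subject, class_idx, seed),
                  ratings = ratings)
  })
}

#' Generate a full synthetic dataset
#'
#' Classes are balanced per subject (round-robin over the trial index); every
#' trial is reproducible from `(spec, spec$seed)` alone.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `recordings`, a `manifest` data frame (subject, trial,
#'   class index and name, ratings) and the `spec`.
#' @export
generate_dataset <- function(spec) {
  n_classes <- length(spec$signatures)
  recs <- list()
  rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (t in seq_len(spec$trials_per_subject)) {
      cls <- (t - 1L) %% n_classes
      tr_seed <- spec$seed + 100003L * s + 17L * t
      rec <- generate_trial(spec, s, cls, tr_seed)
      rec$trial_id <- sprintf("s%02d_t%03d", s, t)
      recs[[length(recs) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subject_id, trial_id = rec$trial_id,
        class_idx = cls, class_name = names(spec$signatures)[cls + 1L],
        valence = rec$ratings$valence %||% NA,
        arousal = rec$ratings$arousal %||% NA,
        dominance = rec$ratings$dominance %||% NA)
    }
  }
  list(recordings = recs, manifest = do.call(rbind, rows), spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a generated trial against its spectral signature
#'
#' Welch band powers are averaged over the channels of each cluster and
#' compared to the subject-gain-adjusted class targets.
#'
#' @param recording a generated [raw_recording()].
#' @param spec the [synthetic_spec()] it came from.
#' @param class_idx 0-based class index to check against.
#' @param subject subject index used at generation (for the gain profile).
#' @param tolerance relative tolerance on each band power.
#' @return List with `pass`, and a `report` data frame (cluster, band,
#'   target, measured, relative error).
#' @export
verify_spectral_signature <- function(recording, spec, class_idx, subject = 1L,
                                      tolerance = 0.25) {
  map <- default_cluster_map(spec$montage_name)
  sig <- spec$signatures[[class_idx + 1L]]
  prof <- subject_profile(spec, subject)
  bands <- eeg_bands()
  rows <- list()
  # analytic band share of the 1/f background (its total variance is known)
  n <- ncol(recording$data)
  fgrid <- seq_len(n %/% 2L) * recording$fs / n
  wgt <- fgrid^(-spec$noise_exponent)
  noise_in_band <- function(band) {
    if (spec$noise_amplitude <= 0) return(0)
    spec$noise_amplitude^2 * sum(wgt[fgrid >= band[1] & fgrid <= band[2]]) / sum(wgt)
  }
  for (cl in names(map$clusters)) {
    chans <- map$clusters[[cl]]
    for (b in names(bands)) {
      target <- sig[cl, b] * prof$gain[[b]] + noise_in_band(bands[[b]])
      measured <- mean(vapply(chans, function(ch)
        band_power(recording$data[ch, ], recording$fs, bands[[b]],
                   n_seg = min(1024L, ncol(recording$data))), 1.0))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, band = b, target = target, measured = measured,
        rel_error = if (target > 0) abs(measured - target) / target else NA_real_)
    }
  }
  report <- do.call(rbind, rows)
  ok <- is.na(report$rel_error) | report$rel_error <= tolerance
  list(pass = all(ok), report = report)
}
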