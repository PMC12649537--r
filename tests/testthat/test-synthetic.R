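test_that("generated ratings map back to the generating class (round trip)", {
  spec <- synthetic_spec(n_subjects = 2, trials_per_subject = 8, trial_seconds = 4,
                         seed = 11)
  ds <- generate_dataset(spec)
  for (i in seq_along(ds$recordings)) {
    expect_identical(ratings_to_class(ds$recordings[[i]]$ratings, "quadrant"),
                     ds$manifest$class_idx[i])
  }
  # three-level scheme round trip
  spec3 <- synthetic_spec(n_subjects = 1, trials_per_subject = 6, trial_seconds = 4,
                          class_scheme = "valence3",
                          signatures = default_signatures("valence2")[c(1, 2, 1)],
                          seed = 12)
  ds3 <- generate_dataset(spec3)
  for (i in seq_along(ds3$recordings)) {
    expect_identical(ratings_to_class(ds3$recordings[[i]]$ratings, "valence3"),
                     ds3$manifest$class_idx[i])
  }
})

test_that("generation is deterministic in (spec, seed) and varies across seeds", {
  spec <- synthetic_spec(trial_seconds = 4, seed = 5)
  a <- generate_trial(spec, subject = 2, class_idx = 1, seed = 77)
  b <- generate_trial(spec, subject = 2, class_idx = 1, seed = 77)
  expect_identical(a$data, b$data)
  expect_identical(a$ratings, b$ratings)
  c_ <- generate_trial(spec, subject = 2, class_idx = 1, seed = 78)
  expect_gt(max(abs(a$data - c_$data)), 0)
  # dataset-level: same spec twice -> identical manifests and waveforms
  sp <- synthetic_spec(n_subjects = 2, trials_per_subject = 4, trial_seconds = 4, seed = 9)
  d1 <- generate_dataset(sp)
  d2 <- generate_dataset(sp)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$recordings[[3]]$data, d2$recordings[[3]]$data)
})

test_that("datasets are balanced per subject with a complete manifest", {
  spec <- synthetic_spec(n_subjects = 6, trials_per_subject = 16, trial_seconds = 4,
                         seed = 21)
  ds <- generate_dataset(spec)
  expect_length(ds$recordings, 96L)
  tab <- table(ds$manifest$class_idx)
  expect_equal(unname(as.vector(tab)), rep(24L, 4))
  per_subj <- table(ds$manifest$subject_id, ds$manifest$class_idx)
  expect_true(all(per_subj == 4L))
  expect_setequal(names(ds$manifest),
                  c("subject_id", "trial_id", "class_idx", "class_name",
                    "valence", "arousal", "dominance"))
})

test_that("alpha band power in the designated cluster is within 25% of target (60-s trial)", {
  spec <- synthetic_spec(trial_seconds = 60, seed = 31)
  # HVLA: right-parietal alpha is boosted, left-parietal suppressed
  rec <- generate_trial(spec, subject = 1, class_idx = 3, seed = 100)
  prof <- c2geeg:::subject_profile(spec, 1)
  sig <- spec$signatures[["HVLA"]]
  for (cl in c("right_parietal", "left_parietal", "occipital")) {
    ch <- default_cluster_map("toy-9ch")$clusters[[cl]]
    measured <- band_power(rec$data[ch, ], 128, c(8, 13), n_seg = 512)
    target <- sig[cl, "alpha"] * prof$gain[["alpha"]]
    # subtract nothing: the 1/f background contributes < 10% here
    expect_lt(abs(measured - target) / target, 0.25,
              label = sprintf("alpha power in %s", cl))
  }
})

test_that("spectral verification passes for matching class and fails for a disjoint one", {
  spec <- synthetic_spec(trial_seconds = 60, seed = 41)
  rec <- generate_trial(spec, subject = 2, class_idx = 0, seed = 55)  # HVHA
  ok <- verify_spectral_signature(rec, spec, class_idx = 0, subject = 2)
  expect_true(ok$pass)
  # LVLA inverts the alpha asymmetry and damps beta/gamma: clear mismatch
  bad <- verify_spectral_signature(rec, spec, class_idx = 2, subject = 2)
  expect_false(bad$pass)
  # zero-noise spec tightens to 10% and still passes
  spec0 <- synthetic_spec(trial_seconds = 60, noise_amplitude = 0,
                          blink_rate = 0, seed = 42)
  rec0 <- generate_trial(spec0, subject = 1, class_idx = 1, seed = 60)
  ok0 <- verify_spectral_signature(rec0, spec0, class_idx = 1, subject = 1,
                                   tolerance = 0.10)
  expect_true(ok0$pass)
})

test_that("blink transients land on prefrontal channels at the configured rate", {
  spec <- synthetic_spec(trial_seconds = 60, blink_rate = 30, blink_amplitude = 80,
                         noise_amplitude = 0.5, seed = 51)
  rec <- generate_trial(spec, subject = 1, class_idx = 0, seed = 70)
  specq <- synthetic_spec(trial_seconds = 60, blink_rate = 0, blink_amplitude = 0,
                          noise_amplitude = 0.5, seed = 51)
  recq <- generate_trial(specq, subject = 1, class_idx = 0, seed = 70)
  # low-frequency (sub-theta) energy on Fp1 is dominated by blinks
  lf_blink <- band_power(rec$data["Fp1", ], 128, c(0.3, 3), n_seg = 1024)
  lf_quiet <- band_power(recq$data["Fp1", ], 128, c(0.3, 3), n_seg = 1024)
  expect_gt(lf_blink, 5 * lf_quiet)
  # non-prefrontal channels are blink-free
  lf_cz <- band_power(rec$data["Cz", ], 128, c(0.3, 3), n_seg = 1024)
  expect_lt(lf_cz, lf_blink / 5)
})

test_that("stronger class contrast raises plug-in linear separability (dial property)", {
  accs <- vapply(c(0, 0.5, 1), function(ct) {
    spec <- synthetic_spec(n_subjects = 2, trials_per_subject = 16,
                           trial_seconds = 8,
                           signatures = default_signatures("quadrant", contrast = ct),
                           seed = 61)
    ds <- generate_dataset(spec)
    bands <- eeg_bands()
    X <- t(vapply(ds$recordings, function(r) {
      as.vector(vapply(bands, function(bd)
        vapply(seq_len(9), function(ch) band_power(r$data[ch, ], r$fs, bd, 512), 1.0),
        numeric(9)))
    }, numeric(36)))
    y <- ds$manifest$class_idx
    tr <- ds$manifest$subject_id == "s01"
    # nearest-class-centroid plug-in classifier on log band powers
    Xl <- log(X)
    cent <- vapply(0:3, function(k) colMeans(Xl[tr & y == k, , drop = FALSE]),
                   numeric(36))
    pred <- apply(Xl[!tr, ], 1L, function(z) which.min(colSums((cent - z)^2)) - 1L)
    mean(pred == y[!tr])
  }, 1.0)
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})
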