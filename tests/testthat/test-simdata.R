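test_that("class oscillators land in their spectral bands", {
  # PD default band 4-6 Hz: periodogram peak stays inside over seeds
  pd <- class_signal_model("PD")
  et <- class_signal_model("ET")
  pd_peaks <- et_peaks <- numeric(8)
  for (i in 1:8) {
    spd <- generate_angle_signal(pd, duration = 13, seed = 100 + i)
    pg <- stats::spec.pgram(stats::ts(spd, frequency = 100), plot = FALSE,
                            spans = 5)
    pd_peaks[i] <- pg$freq[which.max(pg$spec)]
    set_ <- generate_angle_signal(et, duration = 13, seed = 200 + i)
    pg2 <- stats::spec.pgram(stats::ts(set_, frequency = 100), plot = FALSE,
                             spans = 5)
    et_peaks[i] <- pg2$freq[which.max(pg2$spec)]
  }
  expect_true(all(pd_peaks >= 3.5 & pd_peaks <= 6.5))
  expect_true(all(et_peaks >= 7.5 & et_peaks <= 11.5))
  # class-conditional separation: PD dominant frequency below ET
  expect_lt(median(pd_peaks), median(et_peaks))
})

test_that("a degenerate model collapses to a pure sinusoid", {
  m <- class_signal_model("ET", band = c(5, 5), amplitude = 0.04,
                          jitter = 0, am_depth = 0, noise = 0, pink = 0)
  s <- generate_angle_signal(m, duration = 10, seed = 1)
  t <- seq_along(s) / 100
  # phase-continuous 5 Hz oscillator at fixed amplitude
  expect_equal(mean_square_power(s), 0.04^2 / 2, tolerance = 1e-3)
  pg <- stats::spec.pgram(stats::ts(s, frequency = 100), plot = FALSE)
  expect_equal(pg$freq[which.max(pg$spec)], 5, tolerance = 0.05)

  # different seeds decorrelate
  a <- generate_angle_signal(class_signal_model("PD"), 13, seed = 5)
  b <- generate_angle_signal(class_signal_model("PD"), 13, seed = 6)
  expect_lt(abs(stats::cor(a, b)), 0.5)
  # same seed reproduces
  expect_identical(a, generate_angle_signal(class_signal_model("PD"), 13, seed = 5))
})

test_that("quaternion encoding inverts through the displacement map", {
  expect_error(encode_quaternion_stream(rep(0, 10), axis = c(0, 0, 2)), "unit length")
  z <- encode_quaternion_stream(rep(0, 10))
  expect_true(all(z$q[, 1] == 1))

  # small angles about z: displacement magnitude approximates |theta|
  theta <- 0.05 * sin(2 * pi * 5 * (0:199) / 100)
  st <- encode_quaternion_stream(theta, axis = c(0, 0, 1))
  expect_equal(quat_norm(st$q), rep(1, 200), tolerance = 1e-12)
  d <- displacement_series(st)
  expect_lt(max(abs(d$magnitude - abs(theta))) / max(abs(theta)), 0.01)

  # quarter-turn about z maps the reference point per the passive convention
  q90 <- encode_quaternion_stream(pi / 2, axis = c(0, 0, 1))
  expect_equal(unname(rotate_reference(q90$q[1, ])), c(0, -1, 0), tolerance = 1e-12)
})

test_that("subclinical calibration lands in the target interval and scales predictably", {
  rec <- simulate_recording("PD", class_signal_model("PD"), sim_config(), seed = 31)
  expect_lt(rec$rating, 0.5)
  expect_gte(rec$rating, 0.2 - 1e-6)
  expect_lte(rec$rating, 0.4 + 1e-6)
  expect_true(is_subclinical(rec$rating))

  # doubling every amplitude raises the rating by (sum of coefficients) * log10(4)
  cfg <- preprocess_config()
  powers <- vapply(rec$angles[c("WFE", "WAA", "EPS", "EFE")],
                   function(a) mean_square_power(bandpass(a, cfg)), numeric(1))
  r1 <- tremor_rating(powers)
  r2 <- tremor_rating(powers * 4)  # amplitude x2 -> mean square x4
  expect_equal(r2 - r1, (0.3071 + 0.0731 + 0.1843 + 0.0988) * log10(4),
               tolerance = 1e-9)
  expect_equal(r1, rec$rating, tolerance = 1e-6)

  # recalibrating a calibrated recording is (nearly) the identity
  draft <- rec
  draft$streams <- lapply(draft$streams, fill_gaps_pchip)
  recal <- calibrate_subclinical(draft)
  ratio <- max(abs(recal$angles$WFE)) / max(abs(rec$angles$WFE))
  expect_lt(abs(ratio - 1), 0.01)
})

test_that("transmission dropout removes the contracted interior sample count", {
  theta <- 0.03 * sin(2 * pi * 6 * (0:1399) / 100)
  st <- encode_quaternion_stream(theta)
  expect_identical(apply_dropout(st, 0, seed = 1), st)

  th <- apply_dropout(st, 0.02, seed = 2)
  expect_equal(length(st$time_s) - length(th$time_s), 28L)  # round(0.02 * 1400)
  # endpoints survive
  expect_equal(th$time_s[1], st$time_s[1])
  expect_equal(th$time_s[length(th$time_s)], st$time_s[length(st$time_s)])
  # gap detection recovers exactly the removed grid indices
  removed <- setdiff(round(st$time_s * 100), round(th$time_s * 100))
  expect_setequal(detect_gaps(th), removed)

  expect_error(apply_dropout(st, 0.6), "0.5")
})

test_that("dataset generation is seeded, grouped by subject, and all-subclinical", {
  recs <- simulate_dataset(c(PD = 6, ET = 5), config = sim_config(), seed = 77)
  expect_length(recs, 11L)
  labs <- vapply(recs, `[[`, integer(1), "label")
  expect_equal(sum(labs == 1), 6L)
  expect_equal(sum(labs == 2), 5L)
  expect_true(all(vapply(recs, function(r) is_subclinical(r$rating), logical(1))))
  # subjects contribute at most two recordings
  subj <- vapply(recs, `[[`, character(1), "subject")
  expect_lte(max(table(subj)), 2L)
  # determinism: identical ids, ratings and signals on rerun
  recs2 <- simulate_dataset(c(PD = 6, ET = 5), config = sim_config(), seed = 77)
  expect_identical(names(recs), names(recs2))
  expect_identical(vapply(recs, `[[`, numeric(1), "rating"),
                   vapply(recs2, `[[`, numeric(1), "rating"))
  expect_identical(recs[[1]]$streams$hand$q, recs2[[1]]$streams$hand$q)
  expect_false(identical(
    recs[[1]]$streams$hand$q,
    simulate_dataset(c(PD = 6, ET = 5), seed = 78)[[1]]$streams$hand$q))
})

test_that("the study-composition preset emits 122/83/30 readings", {
  # counts and grouping only; signal content is exercised elsewhere, so the
  # per-recording synthesis is the only heavy step and stays un-run here
  cfg <- sim_config()
  paper <- simulate_dataset(preset = "paper", config = cfg, seed = 9)
  labs <- vapply(paper, `[[`, integer(1), "label")
  expect_length(paper, 235L)
  expect_equal(unname(table(labs)), c(122L, 83L, 30L), ignore_attr = TRUE)
  expect_true(all(vapply(paper, function(r) is_subclinical(r$rating), logical(1))))
  expect_lte(max(table(vapply(paper, `[[`, character(1), "subject"))), 2L)

  recs <- simulate_dataset(c(normal = 4, PD = 3, ET = 2), config = cfg, seed = 9)
  tab <- table(vapply(recs, `[[`, integer(1), "label"))
  expect_equal(unname(c(tab["0"], tab["1"], tab["2"])), c(4L, 3L, 2L))

  path <- tempfile(fileext = ".json")
  write_manifest(recs, path, seed = 9)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(man$n, 9L)
  expect_true(all(man$recordings$subclinical))
  expect_setequal(man$recordings$id, names(recs))
})
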