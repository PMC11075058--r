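test_that("quantile thresholds follow the linear-interpolation convention", {
  v <- seq(0, 1, length.out = 1000)
  th <- compute_thresholds(v, v, quantile = 0.2)
  expect_equal(th$s_low, 0.2, tolerance = 1 / 999)
  expect_equal(th$s_high, 0.8, tolerance = 1 / 999)

  # degenerate: all equal
  thc <- compute_thresholds(rep(3, 10), rep(3, 10))
  expect_identical(thc$s_low, thc$s_high)

  # sort-and-index oracle on 1..10 at q = 0.2: exactly two values strictly
  # below the low threshold (type-7 quantile = 2.8)
  th10 <- compute_thresholds(1:10, 1:10, quantile = 0.2)
  expect_identical(sum(1:10 < th10$s_low), 2L)

  expect_error(compute_thresholds(1:3, 1:10), "at least 5")
  expect_error(compute_thresholds(1:10, 1:10, quantile = 0.6), "quantile")
})

test_that("classification covers the 2x2 final cells and the mid band", {
  th <- fake_thresholds(s_low = 1, s_high = 3, u_low = 1, u_high = 2)
  # all four positions below both lows
  expect_identical(
    classify_progression(fake_profile(c(0.5, 0.5, 0.5, 0.5),
                                      c(0.5, 0.5, 0.5, 0.5)), th),
    "sLuL-sLuL")
  # low context, high-surprise low-uncertainty final
  expect_identical(
    classify_progression(fake_profile(c(0.5, 0.5, 0.5, 4),
                                      c(0.5, 0.5, 0.5, 0.5)), th),
    "sLuL-sHuL")
  expect_identical(
    classify_progression(fake_profile(c(0.5, 0.5, 0.5, 0.5),
                                      c(0.5, 0.5, 0.5, 2.5)), th),
    "sLuL-sLuH")
  expect_identical(
    classify_progression(fake_profile(c(4, 4, 4, 4), c(2.5, 2.5, 2.5, 2.5)),
                         th),
    "sHuH-sHuH")
  # boundary values are closed: exactly at the cut point counts low/high
  expect_identical(
    classify_progression(fake_profile(c(1, 1, 1, 3), c(1, 1, 1, 1)), th),
    "sLuL-sHuL")
  # any mid-band value refuses classification
  expect_identical(
    classify_progression(fake_profile(c(0.5, 2, 0.5, 0.5),
                                      c(0.5, 0.5, 0.5, 0.5)), th),
    NA_character_)
  # mixed context refuses classification
  expect_identical(
    classify_progression(fake_profile(c(0.5, 4, 0.5, 0.5),
                                      c(0.5, 2.5, 0.5, 0.5)), th),
    NA_character_)
  expect_error(
    classify_progression(fake_profile(c(1, 1, 1), c(1, 1, 1)), th),
    "exactly 4")
})

test_that("the structured corpus yields exact dyadic thresholds", {
  fx <- structured_fixture()
  expect_identical(fx$thresholds$s_low, 1)
  expect_identical(fx$thresholds$s_high, 3)
  expect_identical(fx$thresholds$u_low, 1)
  expect_identical(fx$thresholds$u_high, 2)
})

test_that("generated stimuli of every type round-trip through the classifier", {
  fx <- structured_fixture()
  for (ty in progression_types()) {
    got <- generate_progressions(fx$model, ty, count = 1, seed = 99,
                                 thresholds = fx$thresholds)
    expect_length(got, 1)
    expect_identical(
      classify_progression(profile_progression(fx$model, got[[1]]),
                           fx$thresholds),
      ty)
  }
})

test_that("stimulus generation is deterministic and honest about shortfalls", {
  fx <- structured_fixture()
  a <- generate_progressions(fx$model, "sHuH-sHuH", 5, seed = 5,
                             thresholds = fx$thresholds)
  b <- generate_progressions(fx$model, "sHuH-sHuH", 5, seed = 5,
                             thresholds = fx$thresholds)
  expect_identical(a, b)
  expect_identical(anyDuplicated(vapply(a, paste, "", collapse = " ")), 0L)

  # a 2-symbol deterministic model cannot realise high-surprise types
  md <- fit_transition_model(chord_corpus(list(rep(c("A", "B"), 10))))
  pools <- pool_information(md, chord_corpus(list(rep(c("A", "B"), 10))))
  thd <- compute_thresholds(pools$surprisal, pools$uncertainty)
  expect_warning(
    out <- generate_progressions(md, "sHuH-sHuH", 1, seed = 1,
                                 thresholds = thd, max_attempts = 200),
    "found 0")
  expect_length(out, 0)
  expect_error(
    generate_progressions(md, "sHuH-sHuH", 1, seed = 1, thresholds = thd,
                          max_attempts = 200, strict = TRUE),
    "found 0")
})

test_that("enlarging the quantile never shrinks the classifiable set", {
  fx <- structured_fixture()
  th_narrow <- fx$thresholds
  th_wide <- compute_thresholds(fx$pools$surprisal, fx$pools$uncertainty,
                                quantile = 0.35)
  set.seed(31)
  succ <- apply(fx$model$counts > 0, 1, which, simplify = FALSE)
  vocab <- fx$model$vocabulary
  n_checked <- 0
  for (i in 1:300) {
    s <- character(4)
    s[1] <- sample(vocab, 1)
    ok <- TRUE
    for (j in 2:4) {
      nx <- succ[[s[j - 1]]]
      if (!length(nx)) { ok <- FALSE; break }
      s[j] <- vocab[nx[sample.int(length(nx), 1)]]
    }
    if (!ok) next
    pr <- profile_progression(fx$model, s)
    if (!is.na(classify_progression(pr, th_narrow))) {
      expect_false(is.na(classify_progression(pr, th_wide)))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("design_stimuli assembles thresholds and per-type stimulus lists", {
  fx <- structured_fixture()
  d <- suppressWarnings(design_stimuli(fx$model, fx$corpus, per_type = 1,
                                       seed = 3))
  expect_identical(names(d$stimuli), progression_types())
  expect_true(all(lengths(d$stimuli) >= 1))
  expect_identical(d$thresholds$s_high, 3)
})
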