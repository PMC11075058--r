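test_that("maximum-likelihood fit reproduces hand-counted pair ratios", {
  m <- fit_transition_model(chord_corpus(list(c("A", "B"), c("A", "B"))))
  expect_identical(m$cond_prob["A", "B"], 1)

  m2 <- fit_transition_model(toy_corpus())
  expect_equal(m2$cond_prob["A", "B"], 0.5)
  expect_equal(m2$cond_prob["A", "C"], 0.5)
  expect_equal(sum(m2$counts), 3)

  # marginal is plain token frequency
  expect_equal(m2$marginal[["A"]], 2 / 4)
  expect_equal(sum(m2$marginal), 1)
})

test_that("pseudo-count smoothing follows (c + a) / (n + a|S|)", {
  m <- fit_transition_model(chord_corpus(list(c("A", "B"))),
                            smoothing_alpha = 1)
  expect_equal(m$cond_prob["A", "B"], 2 / 3)
  expect_equal(m$cond_prob["A", "A"], 1 / 3)
  expect_equal(rowSums(m$cond_prob), c(A = 1, B = 1))
})

test_that("degenerate corpora are refused", {
  expect_error(fit_transition_model(chord_corpus(list("A", "B"))),
               "insufficient transitions")
  expect_error(chord_corpus(list()))
  expect_error(chord_corpus(list(c("A", ""))))
})

test_that("alpha = 0 fit matches a brute-force pair-counting oracle", {
  set.seed(42)
  for (rep in 1:20) {
    cp <- random_corpus(n_songs = sample(2:5, 1), len = sample(5:10, 1))
    m <- fit_transition_model(cp)
    # oracle: count pairs with an explicit double loop
    vocab <- cp$vocabulary
    cnt <- matrix(0, length(vocab), length(vocab),
                  dimnames = list(vocab, vocab))
    for (song in cp$songs)
      for (i in seq_len(length(song) - 1))
        cnt[song[i], song[i + 1]] <- cnt[song[i], song[i + 1]] + 1
    expect_equal(unname(m$counts), unname(cnt))
    for (a in vocab) {
      if (sum(cnt[a, ]) == 0) next
      expect_equal(m$cond_prob[a, ], cnt[a, ] / sum(cnt[a, ]))
    }
  }
})

test_that("surprisal matches closed forms and rejects unseen transitions", {
  m1 <- fit_transition_model(chord_corpus(list(c("A", "B"), c("A", "B"))))
  expect_identical(surprisal(m1, "A", "B"), 0)      # P = 1
  m2 <- fit_transition_model(toy_corpus())
  expect_identical(surprisal(m2, "A", "B"), 1)      # P = 1/2
  m3 <- fit_transition_model(uniform4_corpus())
  expect_identical(surprisal(m3, "A", "B"), 2)      # P = 1/4
  expect_error(surprisal(m2, "B", "C"), "unseen transition")
  expect_error(surprisal(m2, "Z", "A"), "not in the model vocabulary")
})

test_that("entropy matches closed forms", {
  expect_identical(entropy(fit_transition_model(uniform4_corpus()), "A"), 2)
  expect_identical(
    entropy(fit_transition_model(chord_corpus(list(c("A", "B"), c("A", "B")))),
            "A"), 0)
  expect_identical(entropy(fit_transition_model(mixed_corpus()), "A"), 1.5)
  m <- fit_transition_model(toy_corpus())
  expect_error(entropy(m, "C"), "no outgoing transitions")
})

test_that("expected surprisal equals entropy over random models", {
  set.seed(7)
  for (rep in 1:100) {
    cp <- random_corpus(n_songs = 3, len = 15,
                        vocab = LETTERS[1:sample(3:6, 1)])
    m <- fit_transition_model(cp, smoothing_alpha = sample(c(0, 0.5, 1), 1))
    for (ctx in m$vocabulary) {
      p <- m$cond_prob[ctx, ]
      if (anyNA(p) || sum(p) == 0) next
      esurp <- sum(p[p > 0] * (-log2(p[p > 0])))
      expect_equal(esurp, entropy(m, ctx), tolerance = 1e-9)
      expect_gte(entropy(m, ctx), 0)
      expect_lte(entropy(m, ctx), log2(length(m$vocabulary)) + 1e-12)
    }
  }
})

test_that("surprisal is strictly decreasing in probability", {
  m <- fit_transition_model(mixed_corpus())
  expect_lt(surprisal(m, "A", "B"), surprisal(m, "A", "C"))  # 1/2 vs 1/4
})

test_that("progression profiles score position 1 from the marginal", {
  m <- fit_transition_model(toy_corpus())  # A B A C
  pr <- profile_progression(m, c("A", "B"))
  expect_equal(pr$surprisal[2], 1)      # P(B|A) = 1/2
  expect_equal(pr$uncertainty[2], 1)    # H(A) = 1 bit
  expect_equal(pr$surprisal[1], -log2(m$marginal[["A"]]))
  expect_equal(pr$uncertainty[1], -sum(m$marginal * log2(m$marginal)))
  expect_identical(pr$first_chord_convention, "marginal")

  # length-1 sequence: marginal-based by convention
  p1 <- profile_progression(m, "B")
  expect_length(p1$surprisal, 1)

  # deterministic cycle: zero surprise and uncertainty beyond position 1
  md <- fit_transition_model(chord_corpus(list(rep(c("A", "B"), 6))))
  pd <- profile_progression(md, c("A", "B", "A", "B"))
  expect_identical(pd$surprisal[2:4], c(0, 0, 0))
  expect_identical(pd$uncertainty[2:4], c(0, 0, 0))

  expect_error(profile_progression(m, c("A", "Z")), "'Z'")
})

test_that("corpus round-trips through disk formats", {
  cp <- structured_fixture()$corpus
  f <- tempfile(fileext = ".txt")
  write_chord_corpus(cp, f)
  cp2 <- read_chord_corpus(f)
  expect_identical(cp2$songs, cp$songs)

  # delimited-table layout
  tab <- do.call(rbind, lapply(seq_along(cp$songs)[1:5], function(i)
    data.frame(song_id = i, position = seq_along(cp$songs[[i]]),
               chord_label = cp$songs[[i]])))
  f2 <- tempfile(fileext = ".tsv")
  write.table(tab, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  cp3 <- read_chord_corpus(f2, format = "table")
  expect_identical(cp3$songs, cp$songs[1:5])

  fj <- tempfile(fileext = ".json")
  write_model_json(structured_fixture()$model, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_identical(back$vocabulary, structured_fixture()$model$vocabulary)
})
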