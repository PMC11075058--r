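# small corpora and models shared across tests

toy_corpus <- function() chord_corpus(list(c("A", "B", "A", "C")))

# context A: successors B,C,D,E equally often (2 bits); context B: always A
uniform4_corpus <- function() {
  chord_corpus(list(c("A", "B", "A", "C", "A", "D", "A", "E", "A")))
}

# A -> (B x2, C x1, D x1): probabilities (0.5, 0.25, 0.25)
mixed_corpus <- function() {
  chord_corpus(list(c("A", "B"), c("A", "B"), c("A", "C"), c("A", "D")))
}

# random corpus with a closed vocabulary, for property tests
random_corpus <- function(n_songs = 4, len = 12, vocab = LETTERS[1:5]) {
  chord_corpus(lapply(seq_len(n_songs), function(i)
    sample(vocab, len, replace = TRUE)))
}

# reference structured corpus + fitted model + thresholds (computed once)
structured_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cp <- make_structured_corpus(vocab_size = 8, songs = 200, seed = 1)
      m <- fit_transition_model(cp)
      pools <- pool_information(m, cp)
      th <- compute_thresholds(pools$surprisal, pools$uncertainty, 0.2)
      cache <<- list(corpus = cp, model = m, pools = pools, thresholds = th)
    }
    cache
  }
})

# hand-built info_profile for classifier unit tests
fake_profile <- function(I, H) {
  structure(list(sequence = paste0("x", seq_along(I)),
                 surprisal = I, uncertainty = H,
                 first_chord_convention = "marginal"),
            class = "info_profile")
}

fake_thresholds <- function(s_low, s_high, u_low, u_high, q = 0.2) {
  structure(list(s_low = s_low, s_high = s_high, u_low = u_low,
                 u_high = u_high, quantile = q),
            class = "info_thresholds")
}
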