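#' Fit a first-order chord transition model
#'
#' Tallies consecutive within-song chord pairs (never across song boundaries)
#' and converts them to conditional probabilities
#' \eqn{P(e_{n+1} = j \mid e_n = i)}. With pseudo-count smoothing
#' \eqn{\alpha}, row probabilities are
#' \eqn{(c_{ij} + \alpha) / (c_{i\cdot} + \alpha |S|)}. The zeroth-order
#' marginal is the relative frequency of each symbol over all tokens.
#'
#' @param corpus a [chord_corpus()].
#' @param smoothing_alpha non-negative pseudo-count added to every cell;
#'   the default 0 is the maximum-likelihood fit, under which unseen
#'   transitions have probability zero and [surprisal()] refuses them.
#' @return An object of class `transition_model`: `vocabulary` (ordered symbol
#'   set), `counts` (integer matrix), `cond_prob` (row-stochastic matrix for
#'   rows with outgoing mass), `marginal` (named numeric summing to 1) and
#'   `smoothing_alpha`.
#' @examples
#' m <- fit_transition_model(chord_corpus(list(c("A", "B", "A", "C"))))
#' m$cond_prob["A", ]
#' @export
fit_transition_model <- function(corpus, smoothing_alpha = 0) {
  stopifnot(inherits(corpus, "chord_corpus"))
  if (smoothing_alpha < 0) stop("'smoothing_alpha' must be non-negative")
  vocab <- corpus$vocabulary
  k <- length(vocab)
  counts <- matrix(0L, k, k, dimnames = list(vocab, vocab))
  npairs <- 0L
  for (song in corpus$songs) {
    L <- length(song)
    if (L < 2L) next
    from <- factor(song[-L], levels = vocab)
    to <- factor(song[-1L], levels = vocab)
    counts <- counts + table(from, to)
    npairs <- npairs + (L - 1L)
  }
  if (npairs == 0L) stop("insufficient transitions: no within-song chord pair")
  counts <- matrix(as.integer(counts), k, k, dimnames = list(vocab, vocab))
  rowtot <- rowSums(counts)
  cond <- (counts + smoothing_alpha) /
    (rowtot + smoothing_alpha * k)
  # rows with no outgoing mass and no smoothing stay NA rather than 0/0
  if (smoothing_alpha == 0) cond[rowtot == 0, ] <- NA_real_
  tok <- unlist(corpus$songs)
  marginal <- as.numeric(table(factor(tok, levels = vocab))) / length(tok)
  names(marginal) <- vocab
  structure(
    list(vocabulary = vocab, counts = counts, cond_prob = cond,
         marginal = marginal, smoothing_alpha = smoothing_alpha),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("transition_model:", length(x$vocabulary), "symbols,",
      sum(x$counts), "transitions, alpha =", x$smoothing_alpha, "\n")
  invisible(x)
}

.check_symbol <- function(model, sym, what = "symbol") {
  if (!sym %in% model$vocabulary)
    stop(sprintf("%s '%s' is not in the model vocabulary", what, sym))
}

#' Surprisal (information content) of a chord transition
#'
#' \eqn{I(e_{n+1}) = -\log_2 P(e_{n+1} \mid e_n)}, in bits. High surprisal
#' means an improbable, surprising continuation.
#'
#' @param model a [fit_transition_model()] result.
#' @param context,next_sym chord labels in the model vocabulary.
#' @return surprisal in bits (non-negative).
#' @export
surprisal <- function(model, context, next_sym) {
  .check_symbol(model, context, "context")
  .check_symbol(model, next_sym, "next symbol")
  p <- model$cond_prob[context, next_sym]
  if (is.na(p) || p <= 0)
    stop(sprintf("unseen transition '%s' -> '%s' (probability 0; refit with smoothing_alpha > 0 to score it)",
                 context, next_sym))
  -log2(p)
}

#' Entropy (uncertainty) of the next chord given a context
#'
#' \eqn{H = -\sum_e p(e \mid e_n)\log_2 p(e \mid e_n)}, in bits, with
#' \eqn{0 \log 0 := 0}. Bounded by \eqn{\log_2 |S|}.
#'
#' @inheritParams surprisal
#' @return entropy in bits.
#' @export
entropy <- function(model, context) {
  .check_symbol(model, context, "context")
  p <- model$cond_prob[context, ]
  if (anyNA(p))
    stop(sprintf("context '%s' has no outgoing transitions", context))
  .entropy_bits(p)
}

# entropy of a probability vector, 0 log 0 = 0
.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Surprisal/entropy profile of a chord sequence
#'
#' For positions \eqn{n \ge 2}, surprisal and entropy come from the
#' first-order model conditioned on the preceding chord. A first-order model
#' defines no transition into position 1; by convention it is scored from the
#' zeroth-order marginal (\eqn{I_1 = -\log_2 p_0(e_1)}, \eqn{H_1} = entropy of
#' the marginal), and the convention used is recorded in the result.
#'
#' @param model a [fit_transition_model()] result.
#' @param sequence character vector of chord labels (length >= 1).
#' @return An object of class `info_profile`: `sequence`, `surprisal`,
#'   `uncertainty` (bits, same length as the sequence) and
#'   `first_chord_convention` (`"marginal"`).
#' @export
profile_progression <- function(model, sequence) {
  sequence <- as.character(sequence)
  if (length(sequence) < 1L) stop("sequence must have length >= 1")
  for (s in sequence) .check_symbol(model, s)
  n <- length(sequence)
  I <- H <- numeric(n)
  p1 <- model$marginal[sequence[1L]]
  if (p1 <= 0) stop(sprintf("symbol '%s' has zero marginal probability", sequence[1L]))
  I[1L] <- -log2(p1)
  H[1L] <- .entropy_bits(model$marginal)
  if (n >= 2L) {
    for (i in 2:n) {
      I[i] <- surprisal(model, sequence[i - 1L], sequence[i])
      H[i] <- entropy(model, sequence[i - 1L])
    }
  }
  structure(
    list(sequence = sequence, surprisal = unname(I), uncertainty = unname(H),
         first_chord_convention = "marginal"),
    class = "info_profile"
  )
}

#' @export
print.info_profile <- function(x, ...) {
  print(data.frame(chord = x$sequence,
                   surprisal = round(x$surprisal, 3),
                   uncertainty = round(x$uncertainty, 3)))
  invisible(x)
}

#' Pooled surprisal and entropy values over a corpus
#'
#' Every observed within-song transition contributes its surprisal to the
#' surprise pool, and every token with a successor contributes its context
#' entropy to the uncertainty pool. These pools are what the quantile
#' thresholds are computed from.
#'
#' @param model a fitted [fit_transition_model()].
#' @param corpus the corpus the model was fitted to (or any compatible one).
#' @return list with numeric vectors `surprisal` and `uncertainty`.
#' @export
pool_information <- function(model, corpus) {
  stopifnot(inherits(corpus, "chord_corpus"))
  Ivals <- -log2(model$cond_prob)
  Hrow <- vapply(seq_along(model$vocabulary), function(i) {
    p <- model$cond_prob[i, ]
    if (anyNA(p)) NA_real_ else .entropy_bits(p)
  }, numeric(1))
  names(Hrow) <- model$vocabulary
  Ipool <- Hpool <- vector("list", length(corpus$songs))
  for (si in seq_along(corpus$songs)) {
    song <- corpus$songs[[si]]
    L <- length(song)
    if (L < 2L) next
    Ipool[[si]] <- Ivals[cbind(song[-L], song[-1L])]
    Hpool[[si]] <- Hrow[song[-L]]
  }
  list(surprisal = unlist(Ipool, use.names = FALSE),
       uncertainty = unlist(Hpool, use.names = FALSE))
}

#' Export a transition model to JSON
#'
#' @param model a [fit_transition_model()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(vocabulary = model$vocabulary,
              counts = model$counts,
              cond_prob = model$cond_prob,
              marginal = model$marginal,
              smoothing_alpha = model$smoothing_alpha)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
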