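# Integer transition multigraph underlying the structured synthetic corpus.
#
# Three context classes, chosen so that the pooled 20% quantile thresholds
# fall on exact dyadic values and every one of the 8 progression types is
# realisable from the fitted model:
#   A  near-deterministic (P(main) = 8/9;  H ~ 0.50 bits, rare I = log2 9)
#   C  coin-flip pair     (two 1/2 outcomes; H = 1 bit,   I = 1 bit)
#   B  diffuse trio       (main 1/2 + four 1/8 spreads;  H = 2 bits, I = 3)
# The unit edge counts below are balanced (in-degree = out-degree for every
# symbol), so the whole multigraph decomposes into closed walks and each
# emitted song realises the design ratios exactly.
.structured_unit <- function() {
  syms <- c("A1", "C1", "C2", "B1", "B2", "B3")
  a <- 24L; c1 <- 170L; c2 <- 119L; b1 <- 45L; b2 <- 29L; b3 <- 23L
  N <- matrix(0L, 6L, 6L, dimnames = list(syms, syms))
  N["A1", "C1"] <- 8L * a; N["A1", "B1"] <- a
  N["C1", "C2"] <- c1;     N["C1", "B1"] <- c1
  N["C2", "C1"] <- c2;     N["C2", "A1"] <- c2
  N["B1", "B2"] <- 4L * b1
  N["B1", c("B1", "B3", "A1", "C2")] <- b1
  N["B2", "B3"] <- 4L * b2
  N["B2", c("B2", "B1", "A1", "C1")] <- b2
  N["B3", "B1"] <- 4L * b3
  N["B3", c("B3", "B2", "A1", "C2")] <- b3
  stopifnot(identical(rowSums(N), colSums(N)))
  N
}

# Seeded Hierholzer: one Eulerian circuit over a balanced, strongly connected
# integer multigraph. Returns the circuit as a vector of symbol indices
# (first == last). Edge orders are shuffled per node, so the circuit varies
# with the seed while the traversed edge multiset is fixed.
.euler_circuit <- function(N, start) {
  k <- nrow(N)
  adj <- vector("list", k)
  for (i in seq_len(k)) {
    tg <- rep.int(seq_len(k), N[i, ])
    adj[[i]] <- if (length(tg)) sample(tg) else integer(0)
  }
  ptr <- rep.int(1L, k)
  stack <- integer(sum(N) + 1L)
  stack[1L] <- start
  top <- 1L
  path <- integer(sum(N) + 1L)
  np <- 0L
  while (top > 0L) {
    v <- stack[top]
    if (ptr[v] <= length(adj[[v]])) {
      w <- adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      top <- top + 1L
      stack[top] <- w
    } else {
      np <- np + 1L
      path[np] <- v
      top <- top - 1L
    }
  }
  rev(path[seq_len(np)])
}

#' Generate a structured synthetic chord corpus
#'
#' Emits a corpus whose fitted first-order model has two planted context
#' blocks: near-deterministic low-entropy contexts and diffuse high-entropy
#' contexts, bridged by intermediate coin-flip contexts. Songs are closed
#' walks that partition a seeded Eulerian circuit of a balanced integer
#' transition multigraph, so the corpus realises the designed conditional
#' probabilities exactly and, after fitting and 20% quantile thresholding,
#' all 8 progression types are reachable by [generate_progressions()].
#'
#' @param vocab_size number of distinct chords, >= 6. The first 6 carry the
#'   designed structure; extras appear in a separate deterministic cycle song
#'   of negligible mass.
#' @param songs how many songs to split the corpus into (capped by the number
#'   of closed-walk boundaries available).
#' @param seed integer seed; identical seeds give byte-identical corpora.
#' @param scale positive integer; the transition multigraph is replicated
#'   this many times (default 1 gives 1570 core transitions).
#' @return a [chord_corpus()].
#' @export
make_structured_corpus <- function(vocab_size = 8L, songs = 200L, seed = 1L,
                                   scale = 1L) {
  if (vocab_size < 6L)
    stop("vocab too small to realize both context blocks (need >= 6)")
  if (songs < 1L) stop("'songs' must be >= 1")
  if (scale < 1L) stop("'scale' must be >= 1")
  core_labels <- c("C", "G", "F", "Am", "Dm", "Em")
  extra_pool <- c("E7", "A7", "D7", "Bb", "Ab", "Eb", "Fm", "Cm", "Gm",
                  "B7", "Db", "Gb", "F#m", "C#m", "G#m", "Bm", "Bdim", "Caug")
  n_extra <- vocab_size - 6L
  if (n_extra > length(extra_pool))
    extra_pool <- c(extra_pool,
                    paste0("X", seq_len(n_extra - length(extra_pool))))
  set.seed(seed)
  N <- .structured_unit() * as.integer(scale)
  start <- 2L  # C1, a high-degree node, gives many closed-walk boundaries
  circuit <- .euler_circuit(N, start)
  # split the circuit at revisits of the start node: every segment is a
  # closed walk, so pooled pair counts stay exactly the design counts
  hits <- which(circuit == start)
  n_seg <- length(hits) - 1L
  k <- min(as.integer(songs), n_seg)
  cuts <- hits[unique(round(seq(1L, length(hits), length.out = k + 1L)))]
  song_idx <- mapply(function(from, to) circuit[from:to],
                     cuts[-length(cuts)], cuts[-1L], SIMPLIFY = FALSE)
  songs_out <- lapply(song_idx, function(ix) core_labels[ix])
  if (n_extra == 1L) {
    songs_out <- c(songs_out, list(rep(extra_pool[1L], 3L)))
  } else if (n_extra > 1L) {
    xs <- extra_pool[seq_len(n_extra)]
    songs_out <- c(songs_out, list(c(xs, xs[1L])))
  }
  chord_corpus(songs_out)
}
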