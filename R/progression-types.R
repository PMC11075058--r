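#' The eight surprise-by-uncertainty progression types
#'
#' A type label pairs a 3-chord context class (`sLuL` or `sHuH`) with a
#' final-chord class from the 2x2 of surprise (s) and uncertainty (u), each
#' Low or High: `sLuL`, `sHuL`, `sLuH`, `sHuH`.
#'
#' @return character vector of the 8 labels in canonical order.
#' @export
progression_types <- function() {
  finals <- c("sLuL", "sHuL", "sLuH", "sHuH")
  c(paste0("sLuL-", finals), paste0("sHuH-", finals))
}

#' Quantile thresholds for low/high surprise and uncertainty
#'
#' Low and high cut points are the empirical `q` and `1 - q` quantiles
#' (linear-interpolation convention, `stats::quantile` type 7) of the pooled
#' surprise and uncertainty values, computed separately for each pool.
#'
#' @param surprisal numeric pool of surprisal values (bits), length >= 5.
#' @param uncertainty numeric pool of entropy values (bits), length >= 5.
#' @param quantile fraction in (0, 0.5); default 0.20, i.e. the top and
#'   bottom 20 percent of each pool define High and Low.
#' @return object of class `info_thresholds` with `s_low`, `s_high`, `u_low`,
#'   `u_high`, `quantile`.
#' @export
compute_thresholds <- function(surprisal, uncertainty, quantile = 0.20) {
  if (length(surprisal) < 5L || length(uncertainty) < 5L)
    stop("need at least 5 pooled values for each of surprise and uncertainty")
  if (!(quantile > 0 && quantile < 0.5))
    stop("'quantile' must be in (0, 0.5)")
  qs <- stats::quantile(surprisal, c(quantile, 1 - quantile),
                        names = FALSE, type = 7)
  qu <- stats::quantile(uncertainty, c(quantile, 1 - quantile),
                        names = FALSE, type = 7)
  structure(
    list(s_low = qs[1L], s_high = qs[2L], u_low = qu[1L], u_high = qu[2L],
         quantile = quantile),
    class = "info_thresholds"
  )
}

#' @export
print.info_thresholds <- function(x, ...) {
  cat(sprintf("info_thresholds (q = %.2f): surprise [%.3f, %.3f], uncertainty [%.3f, %.3f] bits\n",
              x$quantile, x$s_low, x$s_high, x$u_low, x$u_high))
  invisible(x)
}

# band of a single (I, H) pair: "L" / "H" / NA (mid band). Cut points are
# closed: a value exactly at a threshold counts as low (resp. high).
.band <- function(value, low, high) {
  if (value <= low) "L" else if (value >= high) "H" else NA_character_
}

#' Classify a 4-chord profile into one of the eight progression types
#'
#' The context class requires every scored context position to be jointly low
#' (`sLuL`) or jointly high (`sHuH`) in both surprise and uncertainty; the
#' final class is the 2x2 cell of the 4th chord's surprise and uncertainty.
#' Any value in the open middle band, or a mixed context, yields `NA`.
#'
#' A first-order model only defines transitions into positions 2..4, so the
#' scored context positions default to 2:3; `context_positions = 1:3`
#' additionally scores position 1 under the marginal convention of
#' [profile_progression()].
#'
#' @param profile an `info_profile` of length 4.
#' @param thresholds an [compute_thresholds()] result.
#' @param context_positions which of positions 1..3 must satisfy the context
#'   class; default `2:3`.
#' @return a type label from [progression_types()], or `NA_character_`.
#' @export
classify_progression <- function(profile, thresholds, context_positions = 2:3) {
  stopifnot(inherits(profile, "info_profile"))
  if (length(profile$sequence) != 4L)
    stop("profile must cover exactly 4 chords")
  if (!all(context_positions %in% 1:3))
    stop("'context_positions' must be within 1:3")
  I <- profile$surprisal
  H <- profile$uncertainty
  sb <- vapply(context_positions,
               function(i) .band(I[i], thresholds$s_low, thresholds$s_high),
               character(1))
  ub <- vapply(context_positions,
               function(i) .band(H[i], thresholds$u_low, thresholds$u_high),
               character(1))
  ctx <- if (!anyNA(sb) && !anyNA(ub) && all(sb == "L") && all(ub == "L")) {
    "sLuL"
  } else if (!anyNA(sb) && !anyNA(ub) && all(sb == "H") && all(ub == "H")) {
    "sHuH"
  } else {
    return(NA_character_)
  }
  s4 <- .band(I[4L], thresholds$s_low, thresholds$s_high)
  u4 <- .band(H[4L], thresholds$u_low, thresholds$u_high)
  if (is.na(s4) || is.na(u4)) return(NA_character_)
  paste0(ctx, "-", paste0("s", s4, "u", u4))
}

#' Generate 4-chord progressions of a requested type
#'
#' Seeded rejection sampling over the model's observed-transition graph: the
#' first chord is drawn uniformly from symbols with outgoing transitions, each
#' following chord uniformly from the observed successors of the previous one,
#' and the candidate is kept when it round-trips through
#' [classify_progression()] to the requested type. Returned sequences are
#' unique and the search is deterministic for a fixed seed.
#'
#' @param model a fitted [fit_transition_model()].
#' @param type a label from [progression_types()].
#' @param count number of distinct progressions wanted.
#' @param seed integer seed for the search.
#' @param thresholds an [compute_thresholds()] result for this model.
#' @param max_attempts rejection-sampling budget.
#' @param context_positions passed to [classify_progression()].
#' @param strict if `TRUE`, finding fewer than `count` progressions is an
#'   error; otherwise the partial set is returned with a warning.
#' @return list of character vectors of length 4.
#' @export
generate_progressions <- function(model, type, count, seed, thresholds,
                                  max_attempts = 20000L,
                                  context_positions = 2:3,
                                  strict = FALSE) {
  if (!type %in% progression_types())
    stop("unknown progression type: ", type)
  if (count < 1L) stop("'count' must be >= 1")
  succ <- apply(model$counts > 0, 1L, function(r) which(r), simplify = FALSE)
  starts <- names(succ)[lengths(succ) > 0L]
  if (length(starts) == 0L) stop("model has no observed transitions")
  vocab <- model$vocabulary
  found <- list()
  keys <- character(0)
  set.seed(seed)
  for (att in seq_len(max_attempts)) {
    seqc <- character(4L)
    seqc[1L] <- starts[sample.int(length(starts), 1L)]
    ok <- TRUE
    for (i in 2:4) {
      s <- succ[[seqc[i - 1L]]]
      if (length(s) == 0L) { ok <- FALSE; break }
      seqc[i] <- vocab[s[sample.int(length(s), 1L)]]
    }
    if (!ok) next
    key <- paste(seqc, collapse = "\r")
    if (key %in% keys) next
    cls <- classify_progression(profile_progression(model, seqc), thresholds,
                                context_positions = context_positions)
    if (identical(cls, type)) {
      found[[length(found) + 1L]] <- seqc
      keys <- c(keys, key)
      if (length(found) == count) break
    }
  }
  if (length(found) < count) {
    msg <- sprintf("found %d of %d requested '%s' progressions within %d attempts",
                   length(found), count, type, max_attempts)
    if (strict) stop(msg) else warning(msg)
  }
  found
}

#' Design a stimulus set: progressions for all eight types
#'
#' Fits thresholds from the corpus pools and generates `per_type` distinct
#' progressions of each of the 8 types.
#'
#' @param model fitted transition model.
#' @param corpus the corpus (for threshold pools).
#' @param per_type integer vector of length 1 or 8: progressions per type.
#' @param seed integer seed.
#' @param quantile threshold quantile, default 0.20.
#' @param ... passed to [generate_progressions()].
#' @return object of class `stimulus_design`: list with `thresholds` and
#'   `stimuli` (named list of progression lists, one entry per type).
#' @export
design_stimuli <- function(model, corpus, per_type = 5L, seed = 1L,
                           quantile = 0.20, ...) {
  pools <- pool_information(model, corpus)
  th <- compute_thresholds(pools$surprisal, pools$uncertainty, quantile)
  types <- progression_types()
  per_type <- rep_len(per_type, length(types))
  stim <- vector("list", length(types))
  names(stim) <- types
  for (i in seq_along(types)) {
    stim[[i]] <- generate_progressions(model, types[i], per_type[i],
                                       seed = seed + i, thresholds = th, ...)
  }
  structure(list(thresholds = th, stimuli = stim), class = "stimulus_design")
}

#' @export
print.stimulus_design <- function(x, ...) {
  print(x$thresholds)
  n <- vapply(x$stimuli, length, integer(1))
  cat("stimuli per type:\n")
  print(n)
  invisible(x)
}
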