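#' Effect configuration for the synthetic cohort
#'
#' Defines the planted truth the simulator draws from: per-region baseline
#' click rates, per-condition log-rate offsets, participant random
#' intercepts, per-condition valence/arousal shifts, a planted mediation
#' path (condition -> valence -> cardiac clicks) and per-condition emotion
#' selection propensities. Defaults mirror the study design: 527
#' participants x 8 conditions, abdominal sensation concentrated in
#' sLuL-sLuL, cardiac in sLuL-sHuL, head in the sLuH conditions, positive
#' valence for the predictable contexts, and a positive
#' condition -> valence -> cardiac mediation for sLuL-sHuL.
#'
#' @param n_participants number of participants (>= 2).
#' @param base_rate named per-region mean click counts (baseline condition).
#' @param condition_effects 8 x 3 matrix of log-rate offsets
#'   (rows = conditions in [progression_types()] order; columns cardiac,
#'   abdominal, head).
#' @param random_intercept_sd SD of the participant log-rate intercept.
#' @param valence_effects,arousal_effects per-condition latent shifts
#'   (9-point scale centred at 5).
#' @param rating_sd SD of the latent rating noise.
#' @param mediation_a planted condition -> valence path (latent units added
#'   to the target condition).
#' @param mediation_b planted valence -> cardiac path (log-rate per latent
#'   valence point above 5).
#' @param mediation_target condition carrying the planted `a` path.
#' @param emotion_weights 33 x 8 matrix of selection propensities
#'   (rows = [emotion_categories()], columns = conditions); the default gives
#'   23 placeholder categories near-zero weight so they trip the sparse
#'   filter.
#' @param progressions_per_type integer vector of length 8: how many distinct
#'   progression exemplars each type has (defaults to the study's stimulus
#'   counts, 92 in total).
#' @param spatial_noise fraction of region clicks relocated uniformly on the
#'   canvas (default 0, so planted region counts are exact).
#' @param seed integer seed.
#' @return object of class `effect_config` (a list of the above).
#' @export
effect_config <- function(n_participants = 527L,
                          base_rate = c(cardiac = 1.0, abdominal = 0.8,
                                        head = 1.5, other = 2.0),
                          condition_effects = NULL,
                          random_intercept_sd = 0.35,
                          valence_effects = NULL,
                          arousal_effects = NULL,
                          rating_sd = 1.8,
                          mediation_a = 0.5,
                          mediation_b = 0.08,
                          mediation_target = "sLuL-sHuL",
                          emotion_weights = NULL,
                          progressions_per_type = c(14L, 14L, 12L, 8L, 18L,
                                                    14L, 3L, 9L),
                          spatial_noise = 0,
                          seed = 1L) {
  types <- progression_types()
  if (n_participants < 2L) stop("need at least 2 participants")
  if (any(base_rate < 0)) stop("click rates must be non-negative")
  if (is.null(condition_effects)) {
    condition_effects <- matrix(
      0, 8L, 3L, dimnames = list(types, c("cardiac", "abdominal", "head")))
    condition_effects["sLuL-sHuL", "cardiac"] <- 0.30
    condition_effects["sLuL-sLuL", "abdominal"] <- 0.35
    condition_effects["sHuH-sLuH", "abdominal"] <- -0.20
    condition_effects[c("sLuL-sLuH", "sHuH-sLuH"), "head"] <- 0.30
    condition_effects[c("sLuL-sLuL", "sLuL-sHuL"), "head"] <- -0.20
  }
  if (!identical(dim(condition_effects), c(8L, 3L)))
    stop("condition_effects must be 8 x 3 (conditions x cardiac/abdominal/head)")
  if (is.null(valence_effects)) {
    valence_effects <- stats::setNames(
      c(1.0, 0.6, -0.2, -0.4, -0.3, -0.5, -0.2, -0.6), types)
  }
  if (is.null(arousal_effects)) {
    arousal_effects <- stats::setNames(
      c(-0.8, -0.6, 0.2, 0.4, 0.2, 0.4, 0.3, 0.5), types)
  }
  if (length(valence_effects) != 8L || length(arousal_effects) != 8L)
    stop("rating effects must have one entry per condition")
  if (is.null(emotion_weights)) {
    cats <- emotion_categories()
    emotion_weights <- matrix(0.02, length(cats), 8L,
                              dimnames = list(cats, types))
    core <- cats[1:10]
    emotion_weights[core, ] <- 1
    calmset <- c("calmness", "relief", "satisfaction", "nostalgia", "empathy")
    emotion_weights[calmset, c("sLuL-sLuL", "sLuL-sHuL")] <- 3
    emotion_weights["aesthetic appreciation", c("sLuL-sLuL", "sLuL-sHuL")] <- 4
    tenseset <- c("anxiety", "awkward", "confusion")
    emotion_weights[tenseset, grep("^sHuH", types)] <- 2.5
    emotion_weights[tenseset, c("sLuL-sLuL", "sLuL-sHuL")] <- 0.4
  }
  if (!identical(dim(emotion_weights), c(33L, 8L)))
    stop("emotion_weights must be 33 x 8")
  if (length(progressions_per_type) != 8L || any(progressions_per_type < 1L))
    stop("progressions_per_type must be 8 positive counts")
  if (!mediation_target %in% types) stop("unknown mediation_target")
  structure(
    list(n_participants = as.integer(n_participants), base_rate = base_rate,
         condition_effects = condition_effects,
         random_intercept_sd = random_intercept_sd,
         valence_effects = valence_effects, arousal_effects = arousal_effects,
         rating_sd = rating_sd, mediation_a = mediation_a,
         mediation_b = mediation_b, mediation_target = mediation_target,
         emotion_weights = emotion_weights,
         progressions_per_type = as.integer(progressions_per_type),
         spatial_noise = spatial_noise, seed = as.integer(seed)),
    class = "effect_config"
  )
}

# uniform integer pixel inside a closed mask interval
.runif_in <- function(n, lo, hi) floor(stats::runif(n, lo, hi + 1))

#' Expected per-condition region click means under a configuration
#'
#' Closed-form expectations of the simulator's log-linear count model,
#' marginalised over the participant intercept and rating noise; used to
#' check generator honesty.
#'
#' @param config an [effect_config()].
#' @return 8 x 4 matrix (conditions x cardiac/abdominal/head/other).
#' @export
expected_region_means <- function(config) {
  types <- progression_types()
  regions <- names(config$base_rate)
  out <- matrix(NA_real_, 8L, length(regions),
                dimnames = list(types, regions))
  vshift <- config$valence_effects +
    ifelse(types == config$mediation_target, config$mediation_a, 0)
  for (r in regions) {
    eff <- if (r %in% colnames(config$condition_effects))
      config$condition_effects[, r] else rep(0, 8L)
    lam <- config$base_rate[[r]] * exp(eff) *
      exp(config$random_intercept_sd^2 / 2)
    if (r == "cardiac")
      lam <- lam * exp(config$mediation_b * vshift +
                       (config$mediation_b * config$rating_sd)^2 / 2)
    out[, r] <- lam
  }
  out
}

#' Simulate a synthetic participant cohort
#'
#' Draws, for every participant x condition trial: region click counts from
#' a log-linear Poisson model with a shared participant random intercept
#' (cardiac additionally shifted by the planted valence mediation path);
#' click coordinates uniform inside the assigned region's pixel bounds;
#' 9-point valence/arousal ratings as the rounded, clipped latent value; and
#' a ranked top-5 emotion selection by propensity-weighted sequential
#' sampling without replacement (Plackett-Luce).
#'
#' @param config an [effect_config()].
#' @param masks region masks used for click placement.
#' @return object of class `synthetic_cohort`: data.frames `clicks`
#'   (participant, condition, progression, x, y), `ratings` (participant,
#'   condition, progression, valence, arousal, valence_latent), `rankings`
#'   (participant, condition, progression, rank, category) and `truth` (the
#'   config).
#' @export
simulate_cohort <- function(config, masks = default_region_masks()) {
  stopifnot(inherits(config, "effect_config"))
  set.seed(config$seed)
  types <- progression_types()
  cats <- rownames(config$emotion_weights)
  n <- config$n_participants
  cv <- body_canvas()
  prog_ids <- lapply(seq_along(types), function(i)
    sprintf("%s/%02d", types[i], seq_len(config$progressions_per_type[i])))
  names(prog_ids) <- types
  b <- stats::rnorm(n, 0, config$random_intercept_sd)

  grid <- expand.grid(participant = seq_len(n), condition = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  grid$progression <- vapply(grid$condition, function(cc) {
    ids <- prog_ids[[cc]]
    ids[sample.int(length(ids), 1L)]
  }, character(1))

  vlat <- 5 + config$valence_effects[grid$condition] +
    ifelse(grid$condition == config$mediation_target, config$mediation_a, 0) +
    stats::rnorm(m, 0, config$rating_sd)
  alat <- 5 + config$arousal_effects[grid$condition] +
    stats::rnorm(m, 0, config$rating_sd)
  clip9 <- function(x) pmin(9L, pmax(1L, as.integer(floor(x + 0.5))))
  ratings <- data.frame(grid,
                        valence = clip9(vlat), arousal = clip9(alat),
                        valence_latent = vlat)

  regions <- names(config$base_rate)
  counts <- matrix(0L, m, length(regions), dimnames = list(NULL, regions))
  for (r in regions) {
    eff <- if (r %in% colnames(config$condition_effects))
      config$condition_effects[grid$condition, r] else rep(0, m)
    loglam <- log(config$base_rate[[r]]) + eff + b[grid$participant]
    if (r == "cardiac") loglam <- loglam + config$mediation_b * (vlat - 5)
    counts[, r] <- stats::rpois(m, exp(loglam))
  }
  # respect the interface's 100-click budget
  tot <- rowSums(counts)
  over <- tot > 100L
  if (any(over))
    counts[over, ] <- floor(counts[over, ] * (100 / tot[over]))

  click_parts <- vector("list", length(regions))
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    k <- counts[, r]
    trial <- rep.int(seq_len(m), k)
    ntot <- length(trial)
    if (ntot == 0L) next
    if (r %in% names(masks)) {
      mk <- masks[[r]]
      xs <- .runif_in(ntot, mk$x[1], mk$x[2])
      ys <- .runif_in(ntot, mk$y[1], mk$y[2])
    } else {
      # "other": uniform on canvas, rejecting mask interiors in bulk
      xs <- ys <- integer(ntot); got <- 0L
      while (got < ntot) {
        need <- ntot - got
        px <- .runif_in(2L * need, 0L, cv$width - 1L)
        py <- .runif_in(2L * need, 0L, cv$height - 1L)
        ok <- assign_region(px, py, masks) == "other"
        take <- min(sum(ok), need)
        if (take > 0L) {
          xs[got + seq_len(take)] <- px[ok][seq_len(take)]
          ys[got + seq_len(take)] <- py[ok][seq_len(take)]
          got <- got + take
        }
      }
    }
    click_parts[[ri]] <- data.frame(
      participant = grid$participant[trial],
      condition = grid$condition[trial],
      progression = grid$progression[trial],
      x = xs, y = ys)
  }
  clicks <- do.call(rbind, click_parts[!vapply(click_parts, is.null,
                                               logical(1))])
  if (config$spatial_noise > 0 && nrow(clicks)) {
    mv <- stats::runif(nrow(clicks)) < config$spatial_noise
    if (any(mv)) {
      clicks$x[mv] <- .runif_in(sum(mv), 0L, cv$width - 1L)
      clicks$y[mv] <- .runif_in(sum(mv), 0L, cv$height - 1L)
    }
  }
  clicks <- clicks[order(clicks$participant, clicks$condition), ]
  rownames(clicks) <- NULL

  rankings <- vector("list", m)
  for (i in seq_len(m)) {
    w <- config$emotion_weights[, grid$condition[i]]
    sel <- sample.int(length(cats), 5L, replace = FALSE, prob = w)
    rankings[[i]] <- data.frame(participant = grid$participant[i],
                                condition = grid$condition[i],
                                progression = grid$progression[i],
                                rank = 1:5, category = cats[sel])
  }
  rankings <- do.call(rbind, rankings)
  rownames(rankings) <- NULL

  structure(list(clicks = clicks, ratings = ratings, rankings = rankings,
                 truth = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$truth$n_participants, "participants x 8 conditions;",
      nrow(x$clicks), "clicks,", nrow(x$rankings), "ranking rows\n")
  invisible(x)
}

#' Write a synthetic cohort as delimited text plus metadata
#'
#' Writes `clicks.tsv`, `ratings.tsv`, `rankings.tsv` and a `metadata.json`
#' echoing the seed and scalar configuration.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wf <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wf(cohort$clicks, "clicks.tsv")
  wf(cohort$ratings, "ratings.tsv")
  wf(cohort$rankings, "rankings.tsv")
  tr <- cohort$truth
  meta <- list(seed = tr$seed, n_participants = tr$n_participants,
               random_intercept_sd = tr$random_intercept_sd,
               mediation_a = tr$mediation_a, mediation_b = tr$mediation_b,
               mediation_target = tr$mediation_target,
               rating_sd = tr$rating_sd, spatial_noise = tr$spatial_noise)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
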