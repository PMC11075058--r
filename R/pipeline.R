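#' Default pipeline configuration
#'
#' Returns the configuration list understood by [run_pipeline()]. Every
#' field can be overridden via a YAML file ([read_run_config()]) or by
#' editing the returned list. In synthetic mode (`responses = "synthetic"`)
#' the cohort is simulated; otherwise `clicks`, `ratings` and `rankings`
#' must name delimited files with the documented schemas.
#'
#' @param output_dir where stage outputs are written.
#' @param seed master seed; per-stage seeds are derived deterministically
#'   from it.
#' @return named list of settings.
#' @export
default_run_config <- function(output_dir = tempfile("chordmaps_run_"),
                               seed = 1L) {
  list(
    corpus = "structured",          # or a path to a one-song-per-line file
    vocab_size = 8L, songs = 200L,
    responses = "synthetic",        # or list(clicks=, ratings=, rankings=)
    n_participants = 120L,
    quantile = 0.20,
    per_type = 1L,
    filter_threshold = 0.75,
    grouping = "valence",
    felt_rule = "any",
    heatmap_factor = 40L,
    n_boot = 1000L,
    glmm_family = "poisson",
    embed = TRUE,
    n_neighbors = 15L,
    seed = as.integer(seed),
    output_dir = output_dir
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error; missing keys take the defaults of
#' [default_run_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# deterministic per-stage seeds derived from the master seed
.stage_seed <- function(master, stage_index) {
  (as.integer(master) * 131L + stage_index * 7919L) %% .Machine$integer.max
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: fit the transition model; design stimuli
#' into the 8 types; obtain responses (simulate the synthetic cohort or read
#' tables); body-map region counting and heat maps; emotion scoring and
#' sparse-category filtering; the statistical battery (Friedman + post hoc
#' per measure, Spearman correlations, paired contrasts, GLMM, mediation for
#' the planted target condition); and the 2-D embedding. Every stage writes
#' its outputs to `output_dir` before the next starts, and the returned
#' manifest records output file hashes and per-stage seeds, so identical
#' config + seed reproduce identical tabular outputs.
#'
#' @param config list from [default_run_config()] or [read_run_config()].
#' @return object of class `run_manifest`: per-stage list with `outputs`
#'   (named md5 hashes), `seed`, plus `warnings` and the echoed config.
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list(stages = list(), warnings = character(0), config = config)
  note <- function(stage, files, seed = NA_integer_) {
    manifest$stages[[stage]] <<- list(
      outputs = tools::md5sum(files), seed = seed)
  }

  # 1. corpus + transition model ------------------------------------------
  s1 <- .stage_seed(config$seed, 1L)
  corpus <- if (identical(config$corpus, "structured")) {
    make_structured_corpus(config$vocab_size, config$songs, seed = s1)
  } else {
    if (!file.exists(config$corpus)) stop("corpus path not found: ", config$corpus)
    read_chord_corpus(config$corpus)
  }
  model <- fit_transition_model(corpus)
  write_chord_corpus(corpus, out("corpus.txt"))
  write_model_json(model, out("model.json"))
  note("fit_model", c(out("corpus.txt"), out("model.json")), s1)

  # 2. stimulus design -----------------------------------------------------
  s2 <- .stage_seed(config$seed, 2L)
  design <- suppressWarnings(
    design_stimuli(model, corpus, per_type = config$per_type, seed = s2,
                   quantile = config$quantile))
  stim_tab <- do.call(rbind, lapply(names(design$stimuli), function(ty) {
    if (!length(design$stimuli[[ty]])) return(NULL)
    data.frame(type = ty,
               index = seq_along(design$stimuli[[ty]]),
               chords = vapply(design$stimuli[[ty]], paste, character(1),
                               collapse = " "))
  }))
  .write_tsv(stim_tab, out("stimuli.tsv"))
  note("design_stimuli", out("stimuli.tsv"), s2)

  # 3. responses ------------------------------------------------------------
  s3 <- .stage_seed(config$seed, 3L)
  if (identical(config$responses, "synthetic")) {
    cohort <- simulate_cohort(effect_config(
      n_participants = config$n_participants, seed = s3))
    clicks <- cohort$clicks; ratings <- cohort$ratings
    rankings <- cohort$rankings
    write_cohort(cohort, out("cohort"))
    note("responses", file.path(out("cohort"),
                                c("clicks.tsv", "ratings.tsv", "rankings.tsv")),
         s3)
  } else {
    clicks <- load_clicks(config$responses$clicks)
    ratings <- utils::read.table(config$responses$ratings, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
    rankings <- utils::read.table(config$responses$rankings, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
    note("responses", unlist(config$responses))
  }

  # 4. body map -------------------------------------------------------------
  counts <- count_region_clicks(clicks)
  .write_tsv(counts, out("region_counts.tsv"))
  hm_files <- character(0)
  for (ty in unique(as.character(clicks$condition))) {
    hm <- build_heatmap(clicks, factor = config$heatmap_factor, condition = ty)
    f <- out(paste0("heatmap_", gsub("[^A-Za-z]", "_", ty), ".tsv"))
    utils::write.table(hm$grid, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    hm_files <- c(hm_files, f)
  }
  note("bodymap", c(out("region_counts.tsv"), hm_files))

  # 5. emotion scoring ------------------------------------------------------
  scores <- ranks_to_scores(rankings)
  scores <- merge(scores, ratings[, c("participant", "condition", "valence",
                                      "arousal")],
                  by = c("participant", "condition"))
  if ("progression" %in% names(rankings))
    scores <- merge(scores,
                    unique(rankings[, c("participant", "condition",
                                        "progression")]),
                    by = c("participant", "condition"))
  scores <- merge(scores, counts[, c("participant", "condition", "cardiac",
                                     "abdominal")],
                  by = c("participant", "condition"))
  filt <- zero_rate_filter(scores, threshold = config$filter_threshold,
                           categories = emotion_categories())
  .write_tsv(scores, out("scores.tsv"))
  write_filter_json(filt, out("filter.json"))
  note("score_emotions", c(out("scores.tsv"), out("filter.json")))

  # 6. statistics -----------------------------------------------------------
  s6 <- .stage_seed(config$seed, 6L)
  types <- progression_types()
  wide <- function(col) {
    w <- stats::reshape(scores[, c("participant", "condition", col)],
                        idvar = "participant", timevar = "condition",
                        direction = "wide")
    m <- as.matrix(w[, -1L]); colnames(m) <- sub("^.*\\.", "", colnames(m))
    m[, types, drop = FALSE]
  }
  stats_rows <- list(); posthoc_rows <- list()
  for (meas in c("valence", "arousal", "aesthetic appreciation",
                 "cardiac", "abdominal")) {
    mat <- wide(meas)
    fr <- friedman_rank_test(mat)
    stats_rows[[meas]] <- data.frame(measure = meas, test = "friedman",
                                     statistic = fr$statistic, df = fr$df,
                                     p_value = fr$p_value, n = fr$n)
    ph <- durbin_conover_posthoc(mat)
    ph <- cbind(measure = meas, ph)
    posthoc_rows[[meas]] <- ph
  }
  # contrasts: each region against the rest, per condition of interest
  cmat <- wide("cardiac"); amat <- wide("abdominal")
  ct_card <- paired_contrast(cmat[, "sLuL-sHuL"],
                             cmat[, setdiff(types, "sLuL-sHuL")])
  ct_abd <- paired_contrast(amat[, "sLuL-sLuL"],
                            amat[, setdiff(types, "sLuL-sLuL")])
  contrasts <- data.frame(
    measure = c("cardiac sLuL-sHuL vs rest", "abdominal sLuL-sLuL vs rest"),
    statistic = c(ct_card$statistic, ct_abd$statistic),
    df = c(ct_card$df, ct_abd$df),
    p_value = c(ct_card$p_value, ct_abd$p_value),
    cohens_d = c(ct_card$cohens_d, ct_abd$cohens_d))
  # correlations of region clicks with ratings, pooled across conditions
  sp <- spearman_with_fdr(list(
    cardiac_valence = list(x = scores$cardiac, y = scores$valence),
    abdominal_valence = list(x = scores$abdominal, y = scores$valence),
    cardiac_arousal = list(x = scores$cardiac, y = scores$arousal)))
  # GLMM: abdominal on cardiac clicks with participant intercepts
  gl <- fit_random_intercept_model(scores$abdominal, scores$cardiac,
                                   scores$participant,
                                   family = config$glmm_family)
  glmm_tab <- data.frame(model = "abdominal ~ cardiac + (1|participant)",
                         coefficient = gl$coefficient, se = gl$se, z = gl$z,
                         p_value = gl$p_value,
                         ranef_variance = gl$ranef_variance,
                         ranef_sd = gl$ranef_sd, family = gl$family)
  # mediation: target condition -> valence -> cardiac clicks
  target <- "sLuL-sHuL"
  med <- mediation(x = as.integer(scores$condition == target),
                   m = scores$valence, y = scores$cardiac,
                   n_boot = config$n_boot, seed = s6)
  med_tab <- data.frame(x = target, mediator = "valence", outcome = "cardiac",
                        a = med$a, b = med$b, indirect = med$indirect,
                        direct = med$direct, total = med$total,
                        ci_low = med$ci[1], ci_high = med$ci[2],
                        n_boot = med$n_boot, seed = med$seed)
  .write_tsv(do.call(rbind, stats_rows), out("friedman.tsv"))
  .write_tsv(do.call(rbind, posthoc_rows), out("posthoc.tsv"))
  .write_tsv(contrasts, out("contrasts.tsv"))
  .write_tsv(sp, out("correlations.tsv"))
  .write_tsv(glmm_tab, out("glmm.tsv"))
  .write_tsv(med_tab, out("mediation.tsv"))
  note("stats", out(c("friedman.tsv", "posthoc.tsv", "contrasts.tsv",
                      "correlations.tsv", "glmm.tsv", "mediation.tsv")), s6)

  # 7. embedding ------------------------------------------------------------
  if (isTRUE(config$embed)) {
    grouped <- group_average_by_progression(scores, config$grouping,
                                            felt_rule = config$felt_rule)
    emb <- embed_2d(build_embedding_input(grouped, filt),
                    n_neighbors = config$n_neighbors)
    write_embedding(emb, out("embedding.tsv"))
    note("embed", c(out("embedding.tsv"), out("embedding.json")))
  }

  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", length(x$stages), "stages ->", x$config$output_dir, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-16s %d output file(s)\n", nm,
                length(x$stages[[nm]]$outputs)))
  invisible(x)
}

#' Collate a pipeline run into a single markdown report
#'
#' Gathers the run's test tables, mediation results and embedding summary
#' into one human-readable document, echoing the configuration. Missing
#' stage outputs are noted rather than fatal.
#'
#' @param manifest a [run_pipeline()] manifest.
#' @param path output file (default `report.md` in the run directory).
#' @return `path`, invisibly.
#' @export
make_report <- function(manifest,
                        path = file.path(manifest$config$output_dir,
                                         "report.md")) {
  dirp <- manifest$config$output_dir
  lines <- c("# chordmaps pipeline report", "",
             paste0("Master seed: ", manifest$config$seed), "")
  section <- function(title, file, reader = NULL) {
    f <- file.path(dirp, file)
    if (!file.exists(f)) return(c(paste0("## ", title), "",
                                  "*(stage output missing)*", ""))
    tab <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
    c(paste0("## ", title), "", "```",
      utils::capture.output(print(tab, digits = 4)), "```", "")
  }
  lines <- c(lines,
             section("Friedman tests", "friedman.tsv"),
             section("Paired contrasts", "contrasts.tsv"),
             section("Spearman correlations", "correlations.tsv"),
             section("Random-intercept model", "glmm.tsv"),
             section("Mediation", "mediation.tsv"))
  hm <- list.files(dirp, pattern = "^heatmap_.*\\.tsv$")
  lines <- c(lines, "## Heat maps", "",
             if (length(hm)) paste0("- ", hm) else "*(none)*", "")
  emb <- file.path(dirp, "embedding.tsv")
  lines <- c(lines, "## Embedding", "",
             if (file.exists(emb)) paste0("Coordinates: ", basename(emb))
             else "*(not run)*", "")
  writeLines(lines, path)
  invisible(path)
}
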