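#' The 33-category emotion list
#'
#' Ten categories are fixed by the analysis (aesthetic appreciation,
#' amusement, relief, empathy, calmness, anxiety, awkward, confusion,
#' satisfaction, nostalgia); the remaining 23 follow the wider taxonomy of
#' higher-order emotion categories and are configurable.
#'
#' @return character vector of 33 category names.
#' @export
emotion_categories <- function() {
  core <- c("aesthetic appreciation", "amusement", "relief", "empathy",
            "calmness", "anxiety", "awkward", "confusion", "satisfaction",
            "nostalgia")
  rest <- c("admiration", "adoration", "anger", "awe", "boredom", "craving",
            "disgust", "excitement", "fear", "horror", "interest", "joy",
            "romance", "sadness", "surprise", "sympathy", "triumph", "envy",
            "entrancement", "pain", "desire", "dreaminess", "tension")
  c(core, rest)
}

#' Convert ranked top-5 selections to 33-category score vectors
#'
#' Rank r maps to score 6 - r (rank 1 -> 5 points ... rank 5 -> 1 point);
#' unselected categories score 0. Input is a long table of rankings.
#'
#' @param rankings data.frame with columns `participant`, `condition`,
#'   `rank` (1..5) and `category`.
#' @param categories the full category list (defines the score columns).
#' @return data.frame: `participant`, `condition`, then one integer score
#'   column per category.
#' @export
ranks_to_scores <- function(rankings, categories = emotion_categories()) {
  need <- c("participant", "condition", "rank", "category")
  if (!all(need %in% names(rankings)))
    stop("rankings must have columns: ", paste(need, collapse = ", "))
  if (!all(rankings$category %in% categories))
    stop("unknown emotion category: ",
         setdiff(rankings$category, categories)[1L])
  key <- paste(rankings$participant, rankings$condition, sep = "\r")
  for (k in unique(key)) {
    blk <- rankings[key == k, ]
    if (nrow(blk) != 5L || !setequal(blk$rank, 1:5))
      stop("each participant x condition block needs exactly ranks 1..5")
    if (anyDuplicated(blk$category))
      stop("duplicate category within a ranking block")
  }
  ids <- unique(rankings[, c("participant", "condition")])
  ids <- ids[order(ids$participant, ids$condition), ]
  scores <- matrix(0L, nrow(ids), length(categories),
                   dimnames = list(NULL, categories))
  idkey <- paste(ids$participant, ids$condition, sep = "\r")
  row <- match(key, idkey)
  col <- match(rankings$category, categories)
  scores[cbind(row, col)] <- 6L - as.integer(rankings$rank)
  cbind(ids, as.data.frame(scores, check.names = FALSE))
}

#' Sparse-category exclusion filter
#'
#' Computes, per category, the fraction of responses that are zero, and
#' excludes categories whose zero fraction is strictly above the threshold
#' ("over 75% zero"); a category zero in exactly 75% of rows is retained.
#'
#' @param scores a [ranks_to_scores()] table.
#' @param threshold exclusion boundary, default 0.75.
#' @param categories which columns to assess (default: all category columns).
#' @return object of class `category_filter`: `zero_fraction` (named),
#'   `retained`, `excluded`, `threshold`.
#' @export
zero_rate_filter <- function(scores, threshold = 0.75,
                             categories = NULL) {
  if (is.null(categories))
    categories <- setdiff(names(scores),
                          c("participant", "condition", "valence", "arousal",
                            "progression"))
  if (nrow(scores) < 1L) stop("need at least one score row")
  zf <- vapply(categories, function(cc) mean(scores[[cc]] == 0), numeric(1))
  structure(
    list(zero_fraction = zf,
         retained = categories[zf <= threshold],
         excluded = categories[zf > threshold],
         threshold = threshold),
    class = "category_filter"
  )
}

#' @export
print.category_filter <- function(x, ...) {
  cat(sprintf("category_filter: %d retained, %d excluded (zero fraction > %.2f)\n",
              length(x$retained), length(x$excluded), x$threshold))
  invisible(x)
}

#' Write a category filter report as JSON
#' @param filter a [zero_rate_filter()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_json <- function(filter, path) {
  jsonlite::write_json(unclass(filter), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Per-progression group averages of emotion scores
#'
#' Supports the three grouping rules used downstream of the score table:
#' `"valence"` splits trials into high (valence > 6) and low (valence < 4),
#' dropping 4--6; `"cardiac"` and `"abdominal"` split into felt (count >= 1,
#' or > 1 under `felt_rule = "strict"`) versus none (count 0). Scores are
#' averaged per unique progression (falling back to the condition label when
#' no `progression` column is present) within each group; empty groups are
#' omitted.
#'
#' @param scores score table; must carry `valence` (for the valence rule) or
#'   the relevant region count column (for the click rules), e.g. after
#'   merging with [count_region_clicks()] output.
#' @param grouping one of `"valence"`, `"cardiac"`, `"abdominal"`.
#' @param categories score columns to average (default: all categories).
#' @param felt_rule `"any"` (felt = count >= 1, exhaustive) or `"strict"`
#'   (felt = count > 1; single-click trials belong to neither group).
#' @return data.frame: `progression`, `condition`, `group`, `n`, then one
#'   mean per category.
#' @export
group_average_by_progression <- function(scores,
                                         grouping = c("valence", "cardiac",
                                                      "abdominal"),
                                         categories = NULL,
                                         felt_rule = c("any", "strict")) {
  grouping <- match.arg(grouping)
  felt_rule <- match.arg(felt_rule)
  if (is.null(categories))
    categories <- intersect(emotion_categories(), names(scores))
  if (!length(categories)) stop("no score columns found")
  if (!"progression" %in% names(scores))
    scores$progression <- as.character(scores$condition)
  grp <- switch(grouping,
    valence = {
      if (!"valence" %in% names(scores)) stop("no 'valence' column")
      ifelse(scores$valence > 6, "high",
             ifelse(scores$valence < 4, "low", NA_character_))
    },
    cardiac = ,
    abdominal = {
      if (!grouping %in% names(scores))
        stop("no '", grouping, "' click-count column")
      cnt <- scores[[grouping]]
      felt_min <- if (felt_rule == "any") 1L else 2L
      ifelse(cnt >= felt_min, "felt", ifelse(cnt == 0L, "none", NA_character_))
    })
  keep <- !is.na(grp)
  sc <- scores[keep, , drop = FALSE]
  grp <- grp[keep]
  if (!nrow(sc)) stop("no trials fall in any group under rule '", grouping, "'")
  f <- interaction(sc$progression, grp, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(sc)), f), function(ix) {
    data.frame(progression = sc$progression[ix[1L]],
               condition = as.character(sc$condition[ix[1L]]),
               group = grp[ix[1L]],
               n = length(ix),
               t(colMeans(sc[ix, categories, drop = FALSE])),
               check.names = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$progression, out$group), ]
}
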