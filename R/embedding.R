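#' Assemble the matrix fed to the 2-D embedding
#'
#' Restricts a [group_average_by_progression()] table to the categories
#' retained by the sparse filter; rows are labelled by progression,
#' condition and group. Row order is canonicalised so the construction is
#' invariant to input order.
#'
#' @param grouped a grouped-average table.
#' @param filter a [zero_rate_filter()] result (its `retained` set defines
#'   the columns).
#' @return object of class `embedding_input`: `matrix` (rows x retained
#'   categories), `labels` (data.frame progression/condition/group).
#' @export
build_embedding_input <- function(grouped, filter) {
  retained <- intersect(filter$retained, names(grouped))
  if (!length(retained)) stop("no retained emotion categories to embed")
  grouped <- grouped[order(grouped$progression, grouped$group), ]
  mat <- as.matrix(grouped[, retained, drop = FALSE])
  rownames(mat) <- paste(grouped$progression, grouped$group, sep = " | ")
  structure(
    list(matrix = mat,
         labels = data.frame(progression = grouped$progression,
                             condition = grouped$condition,
                             group = grouped$group)),
    class = "embedding_input"
  )
}

#' Two-dimensional UMAP embedding of emotion profiles
#'
#' Delegates to `uwot::umap` with the analysis defaults: 2 components,
#' random state 42, minimum distance 0.001, spread 10. The neighbourhood
#' size (not reported with the original parameters) defaults to 15 and is
#' capped at one less than the number of rows. Runs single-threaded so a
#' fixed random state reproduces coordinates exactly.
#'
#' @param input an [build_embedding_input()] result.
#' @param n_neighbors neighbourhood size.
#' @param min_dist,spread,n_components embedding parameters.
#' @param random_state integer seed recorded in the result.
#' @return object of class `embedding_result`: `coordinates` (n x 2 matrix),
#'   `labels`, `parameters`.
#' @export
embed_2d <- function(input, n_neighbors = 15L, min_dist = 0.001,
                     spread = 10, n_components = 2L, random_state = 42L) {
  stopifnot(inherits(input, "embedding_input"))
  n <- nrow(input$matrix)
  if (n <= 2L)
    stop("too few rows to embed; supply more groups or a smaller neighbourhood size")
  nn <- min(as.integer(n_neighbors), n - 1L)
  set.seed(random_state)
  xy <- uwot::umap(input$matrix, n_neighbors = nn, n_components = n_components,
                   min_dist = min_dist, spread = spread,
                   n_threads = 1, n_sgd_threads = 1, batch = FALSE,
                   seed = random_state)
  dimnames(xy) <- list(rownames(input$matrix), c("dim1", "dim2"))
  structure(
    list(coordinates = xy, labels = input$labels,
         parameters = list(n_components = n_components,
                           random_state = as.integer(random_state),
                           min_dist = min_dist, spread = spread,
                           n_neighbors = nn)),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("embedding_result: %d rows; n_neighbors=%d min_dist=%g spread=%g random_state=%d\n",
              nrow(x$coordinates), p$n_neighbors, p$min_dist, p$spread,
              p$random_state))
  invisible(x)
}

#' Write embedding coordinates and a JSON parameter sidecar
#'
#' @param emb an [embed_2d()] result.
#' @param path output TSV path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  out <- cbind(emb$labels, as.data.frame(emb$coordinates))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(emb$parameters, paste0(tools::file_path_sans_ext(path),
                                              ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
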