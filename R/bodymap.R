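#' The body-silhouette canvas
#'
#' Click coordinates live on an 871 x 1920 pixel canvas, origin at the
#' top-left corner, x rightward, y downward (screen convention). Valid clicks
#' satisfy `0 <= x < width`, `0 <= y < height`.
#'
#' @return list with `width` and `height` in pixels.
#' @export
body_canvas <- function() list(width = 871L, height = 1920L)

#' Anatomical region masks in canvas pixels
#'
#' The cardiac and abdominal bounds follow the published pixel ranges
#' (cardiac x 360--550, y 390--620; abdominal x 360--510, y 650--850). No
#' head bounds were published; the default head mask (x 300--570, y 40--330)
#' is a package default sized to the silhouette's head and is fully
#' configurable. All intervals are closed: a click exactly on a boundary
#' belongs to the region.
#'
#' @param head_x,head_y length-2 closed pixel intervals for the head mask.
#' @return named list of masks, each `list(x = c(lo, hi), y = c(lo, hi))`.
#' @export
default_region_masks <- function(head_x = c(300, 570), head_y = c(40, 330)) {
  masks <- list(
    cardiac   = list(x = c(360, 550), y = c(390, 620)),
    abdominal = list(x = c(360, 510), y = c(650, 850)),
    head      = list(x = head_x, y = head_y)
  )
  .check_masks(masks)
  masks
}

.check_masks <- function(masks) {
  cv <- body_canvas()
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!all(c("x", "y") %in% names(m)) || length(m$x) != 2L || length(m$y) != 2L)
      stop("mask '", nm, "' must have x and y intervals of length 2")
    if (m$x[1] > m$x[2] || m$y[1] > m$y[2])
      stop("mask '", nm, "' has a reversed interval")
    if (m$x[1] < 0 || m$x[2] >= cv$width || m$y[1] < 0 || m$y[2] >= cv$height)
      stop("mask '", nm, "' exceeds the canvas")
  }
  nm <- names(masks)
  for (i in seq_along(masks)) for (j in seq_len(i - 1L)) {
    a <- masks[[i]]; b <- masks[[j]]
    if (a$x[1] <= b$x[2] && b$x[1] <= a$x[2] &&
        a$y[1] <= b$y[2] && b$y[1] <= a$y[2])
      stop("masks '", nm[i], "' and '", nm[j], "' overlap")
  }
  invisible(TRUE)
}

#' Load a click table from delimited text
#'
#' Expects columns `participant`, `condition`, `x`, `y`. Rows outside the
#' canvas are dropped with a warning naming the offending row numbers.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame of validated click records.
#' @export
load_clicks <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("participant", "condition", "x", "y")
  if (!all(need %in% names(tab)))
    stop("click table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("empty click table")
    return(tab[, need])
  }
  cv <- body_canvas()
  bad <- which(!(tab$x >= 0 & tab$x < cv$width &
                 tab$y >= 0 & tab$y < cv$height) | is.na(tab$x) | is.na(tab$y))
  if (length(bad)) {
    warning("dropping ", length(bad), " out-of-canvas click row(s): ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ..." else "")
    tab <- tab[-bad, , drop = FALSE]
  }
  tab[, need]
}

#' Assign clicks to anatomical regions
#'
#' Each click gets the name of the (unique, by the non-overlap check) mask
#' whose closed intervals contain it, or `"other"` when no mask matches.
#'
#' @param x,y click coordinates (vectors of equal length).
#' @param masks region masks as from [default_region_masks()].
#' @return character vector of region names.
#' @export
assign_region <- function(x, y, masks = default_region_masks()) {
  .check_masks(masks)
  out <- rep("other", length(x))
  for (nm in names(masks)) {
    m <- masks[[nm]]
    hit <- x >= m$x[1] & x <= m$x[2] & y >= m$y[1] & y <= m$y[2]
    out[hit] <- nm
  }
  out
}

#' Per-trial region click counts
#'
#' One row per participant x condition, zero-filled for trials without
#' clicks (the full participant x condition grid is taken from the data's
#' levels). A trial with more than `max_clicks` clicks is an error.
#'
#' @param clicks data.frame with `participant`, `condition`, `x`, `y`.
#' @param masks region masks.
#' @param max_clicks per-trial click budget (study interface capped at 100).
#' @return data.frame with columns `participant`, `condition`, one count per
#'   mask, `other` and `total`.
#' @export
count_region_clicks <- function(clicks, masks = default_region_masks(),
                                max_clicks = 100L) {
  .check_masks(masks)
  parts <- sort(unique(clicks$participant))
  conds <- sort(unique(as.character(clicks$condition)))
  grid <- expand.grid(participant = parts, condition = conds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  region <- assign_region(clicks$x, clicks$y, masks)
  key <- interaction(clicks$participant, clicks$condition, drop = FALSE)
  regions <- c(names(masks), "other")
  counts <- as.data.frame.matrix(
    table(key, factor(region, levels = regions)))
  counts$key <- rownames(counts)
  grid$key <- paste(grid$participant, grid$condition, sep = ".")
  out <- merge(grid, counts, by = "key", all.x = TRUE, sort = FALSE)
  out$key <- NULL
  out[regions][is.na(out[regions])] <- 0L
  out$total <- as.integer(rowSums(out[regions]))
  over <- out$total > max_clicks
  if (any(over))
    stop("trial exceeds ", max_clicks, " clicks: participant ",
         out$participant[which(over)[1L]], ", condition ",
         out$condition[which(over)[1L]])
  out <- out[order(out$participant, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Downsampled heat-map grid of click positions
#'
#' Cell `(i, j)` (1-based; row i = y band, column j = x band) counts clicks
#' with `floor(y / f) == i - 1` and `floor(x / f) == j - 1`. At the default
#' factor 40 the 871 x 1920 canvas gives a 48 x 22 grid (rows x columns).
#' The raw grid is what statistics would use; an optional bilinear upsample
#' is provided for display only.
#'
#' @param clicks data.frame with `x`, `y` (optionally pre-filtered to one
#'   condition).
#' @param factor integer downsampling factor >= 1 (default 40).
#' @param condition optional label stored with the grid; when given and the
#'   click table has a `condition` column, rows are filtered to it.
#' @return object of class `heatmap_grid`: `grid` (matrix), `factor`,
#'   `condition`, `n_clicks`.
#' @export
build_heatmap <- function(clicks, factor = 40L, condition = NULL) {
  if (factor < 1L) stop("'factor' must be >= 1")
  if (!is.null(condition) && "condition" %in% names(clicks))
    clicks <- clicks[clicks$condition == condition, , drop = FALSE]
  cv <- body_canvas()
  nx <- ceiling(cv$width / factor)
  ny <- ceiling(cv$height / factor)
  g <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(clicks)) {
    ix <- floor(clicks$x / factor) + 1L
    iy <- floor(clicks$y / factor) + 1L
    for (k in seq_along(ix)) g[iy[k], ix[k]] <- g[iy[k], ix[k]] + 1L
  }
  structure(list(grid = g, factor = as.integer(factor),
                 condition = condition, n_clicks = nrow(clicks)),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("heatmap_grid: %d x %d cells (factor %d), %d clicks%s\n",
              nrow(x$grid), ncol(x$grid), x$factor, x$n_clicks,
              if (is.null(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' Bilinear upsample of a heat-map grid (display only)
#'
#' @param hm a [build_heatmap()] result.
#' @param times integer upsampling multiple per axis.
#' @return numeric matrix of size `times * dim(hm$grid)`.
#' @export
smooth_heatmap <- function(hm, times = 4L) {
  g <- hm$grid
  ny <- nrow(g); nx <- ncol(g)
  yo <- seq(1, ny, length.out = ny * times)
  xo <- seq(1, nx, length.out = nx * times)
  y0 <- pmin(floor(yo), ny - 1L); x0 <- pmin(floor(xo), nx - 1L)
  fy <- yo - y0; fx <- xo - x0
  out <- matrix(0, length(yo), length(xo))
  for (i in seq_along(yo)) {
    a <- g[y0[i], ] * (1 - fy[i]) + g[y0[i] + 1L, ] * fy[i]
    out[i, ] <- a[x0] * (1 - fx) + a[x0 + 1L] * fx
  }
  out
}
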