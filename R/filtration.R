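#' @useDynLib persiseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Build the dual adjacency graph of the cubical complex of an image under
# the max rule (pixels are vertices, each edge/square takes the extreme of
# its pixel values).  Order-1 homology of the level-set complex is computed
# through planar duality: a hole in the level-set complex is a bounded
# component of its complement, and the complement is tracked on the grid of
# unit squares plus one node for the unbounded outside region.  Two squares
# communicate through a shared complex edge (weight = extreme of its two
# pixels) or a shared vertex (weight = that pixel); border squares
# communicate with the outside through the border edges of the rectangle.
#
# For the sublevel (ascending) filtration the extreme is the maximum; for
# the superlevel (descending) filtration, the minimum.
dual_graph <- function(u, direction) {
  H <- nrow(u); W <- ncol(u)
  agg <- if (direction == "sublevel") pmax else pmin
  nsqr <- H - 1L; nsqc <- W - 1L
  sq_id <- function(i, j) (j - 1L) * nsqr + i

  sq_val <- agg(u[-H, -W], u[-1, -W], u[-H, -1], u[-1, -1])

  ei <- ej <- integer(0); ew <- numeric(0)
  add <- function(i1, j1, i2, j2, w) {
    ei <<- c(ei, sq_id(i1, j1)); ej <<- c(ej, sq_id(i2, j2)); ew <<- c(ew, w)
  }
  # squares sharing a horizontal complex edge (vertical neighbours)
  if (nsqr >= 2L) {
    g <- expand.grid(i = seq_len(nsqr - 1L), j = seq_len(nsqc))
    w <- agg(u[cbind(g$i + 1L, g$j)], u[cbind(g$i + 1L, g$j + 1L)])
    add(g$i, g$j, g$i + 1L, g$j, w)
  }
  # squares sharing a vertical complex edge (horizontal neighbours)
  if (nsqc >= 2L) {
    g <- expand.grid(i = seq_len(nsqr), j = seq_len(nsqc - 1L))
    w <- agg(u[cbind(g$i, g$j + 1L)], u[cbind(g$i + 1L, g$j + 1L)])
    add(g$i, g$j, g$i, g$j + 1L, w)
  }
  # squares sharing a single pixel (diagonal neighbours)
  if (nsqr >= 2L && nsqc >= 2L) {
    g <- expand.grid(i = seq_len(nsqr - 1L), j = seq_len(nsqc - 1L))
    add(g$i, g$j, g$i + 1L, g$j + 1L, u[cbind(g$i + 1L, g$j + 1L)])
    add(g$i + 1L, g$j, g$i, g$j + 1L, u[cbind(g$i + 1L, g$j + 1L)])
  }
  # border squares against the outside node
  outside <- nsqr * nsqc + 1L
  j <- seq_len(nsqc)
  ei <- c(ei, sq_id(rep(1L, nsqc), j), sq_id(rep(nsqr, nsqc), j))
  ej <- c(ej, rep(outside, 2L * nsqc))
  ew <- c(ew, agg(u[1L, -W], u[1L, -1L]), agg(u[H, -W], u[H, -1L]))
  i <- seq_len(nsqr)
  ei <- c(ei, sq_id(i, rep(1L, nsqr)), sq_id(i, rep(nsqc, nsqr)))
  ej <- c(ej, rep(outside, 2L * nsqr))
  ew <- c(ew, agg(u[-H, 1L], u[-1L, 1L]), agg(u[-H, W], u[-1L, W]))

  node_val <- c(as.numeric(sq_val),
                if (direction == "sublevel") Inf else -Inf)
  list(node_val = node_val, ei = ei, ej = ej, ew = ew,
       nsqr = nsqr, nsqc = nsqc, outside = outside)
}

h1_diagram <- function(image, direction, pad_border = FALSE) {
  image <- as_intensity_image(image, normalize = FALSE)
  u <- image$values
  offset <- 0L
  if (pad_border) {
    fill <- if (direction == "sublevel") min(u) else max(u)
    up <- matrix(fill, nrow(u) + 2L, ncol(u) + 2L)
    up[2:(nrow(u) + 1L), 2:(ncol(u) + 1L)] <- u
    u <- up
    offset <- 1L
  }
  g <- dual_graph(u, direction)
  # deterministic order: filtration value first, then construction order
  # (edge-adjacency before vertex-adjacency before border), then index
  ord <- if (direction == "sublevel") order(-g$ew, seq_along(g$ew))
         else order(g$ew, seq_along(g$ew))
  res <- uf_merge_pairs(g$node_val, g$ei[ord], g$ej[ord], g$ew[ord],
                        maximize = direction == "sublevel")
  death <- res[, "extreme"]; birth <- res[, "merge"]
  pers <- abs(death - birth)
  keep <- is.finite(death) & pers > 0
  death <- death[keep]; birth <- birth[keep]; pers <- pers[keep]
  node <- as.integer(res[keep, "node"])
  # critical square -> critical pixel (the square's extreme pixel)
  si <- (node - 1L) %% g$nsqr + 1L
  sj <- (node - 1L) %/% g$nsqr + 1L
  crit_row <- crit_col <- integer(length(node))
  if (length(node)) {
    pick <- if (direction == "sublevel") which.max else which.min
    for (k in seq_along(node)) {
      vals <- c(u[si[k], sj[k]], u[si[k] + 1L, sj[k]],
                u[si[k], sj[k] + 1L], u[si[k] + 1L, sj[k] + 1L])
      w <- pick(vals)
      crit_row[k] <- si[k] + (w == 2L || w == 4L)
      crit_col[k] <- sj[k] + (w >= 3L)
    }
  }
  pairs <- data.frame(birth = birth, death = death, persistence = pers,
                      crit_row = crit_row - offset, crit_col = crit_col - offset)
  pairs <- pairs[order(-pairs$persistence, pairs$birth, pairs$crit_row,
                       pairs$crit_col), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, direction = direction,
                 source_shape = dim(image$values),
                 pixel_size = image$pixel_size,
                 pad_border = pad_border),
            class = "persistence_diagram")
}

#' Order-1 persistence diagram of the sublevel-set filtration
#'
#' Computes all finite-persistence H1 classes of the cubical complex of an
#' image (pixels as vertices, higher cells carrying the maximum of their
#' pixels) filtered by increasing intensity. Cycles of this filtration
#' correspond to bright shapes on a darker surround: each class is born when
#' the dark surround closes a loop around the shape and dies when the shape
#' itself is flooded.
#'
#' Zero-persistence classes are discarded. Each retained pair records the
#' critical pixel at which the class dies (`crit_row`, `crit_col`), from
#' which [representative_contour()] derives a representative closed curve.
#'
#' @param image An [intensity_image()] (or a plain matrix, taken as already
#'   normalized).
#' @param pad_border If `TRUE`, the image is padded with one dark pixel on
#'   each side before filtering, so that bright structures touching the
#'   border can still close a cycle. Default `FALSE`: the complex is exactly
#'   the image rectangle.
#' @return A `persistence_diagram`: a list with a data frame `pairs`
#'   (columns `birth`, `death`, `persistence`, `crit_row`, `crit_col`,
#'   sorted by decreasing persistence), the filtration `direction`, and the
#'   image shape.
#' @seealso [superlevel_h1_diagram()], [betti1_at_threshold()]
#' @examples
#' img <- generate_toy_image("ring3")
#' sublevel_h1_diagram(img)$pairs
#' @export
sublevel_h1_diagram <- function(image, pad_border = FALSE) {
  h1_diagram(image, "sublevel", pad_border)
}

#' Order-1 persistence diagram of the superlevel-set filtration
#'
#' As [sublevel_h1_diagram()], but the complex is filtered by decreasing
#' intensity (higher cells carry the minimum of their pixels). Classes now
#' correspond to dark blobs enclosed by brighter surroundings, and the
#' persistence of a class equals the contrast of the dark blob against its
#' enclosing bright rim. Births occur at higher intensity than deaths.
#'
#' @inheritParams sublevel_h1_diagram
#' @return A `persistence_diagram`; see [sublevel_h1_diagram()].
#' @export
superlevel_h1_diagram <- function(image, pad_border = FALSE) {
  h1_diagram(image, "superlevel", pad_border)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> %s, %d pair(s), image %d x %d\n",
              x$direction, nrow(x$pairs),
              x$source_shape[1], x$source_shape[2]))
  if (nrow(x$pairs)) print(utils::head(x$pairs, 10L))
  invisible(x)
}

# Region of a persistence pair: the strict-side level-set component at the
# birth value that contains the critical pixel. For a sublevel pair this is
# the bright region {u > birth}; for a superlevel pair, the dark region
# {u < birth}. 8-connectivity matches the dual-graph adjacency used by the
# persistence computation.
pair_region_mask <- function(pair, image, direction) {
  u <- as_intensity_image(image, normalize = FALSE)$values
  mask <- if (direction == "sublevel") u > pair$birth else u < pair$birth
  if (!mask[pair$crit_row, pair$crit_col])
    stop("internal consistency error: critical pixel outside its level set")
  lab <- label_components(mask, 8L)
  lab == lab[pair$crit_row, pair$crit_col]
}

#' Representative contour of a persistence pair
#'
#' Extracts a closed curve standing for an H1 class: the external boundary
#' of the connected level-set region associated with the pair. For a
#' sublevel pair this is the 8-connected component of the strict superlevel
#' set at the birth value that contains the pair's critical pixel (a bright
#' shape); for a superlevel pair, symmetrically, the strict sublevel
#' component (a dark blob). The returned curve is closed, traced on the
#' pixel-corner lattice, and encloses the critical pixel of the pair's
#' death.
#'
#' @param pair One row of the `pairs` data frame of a diagram computed on
#'   `image` (or a list with fields `birth`, `crit_row`, `crit_col`).
#' @param image The image the diagram was computed on.
#' @param direction `"sublevel"` or `"superlevel"`; defaults to the
#'   direction stored in `pair` if present.
#' @return A [contour_curve()].
#' @export
representative_contour <- function(pair, image, direction = NULL) {
  if (is.null(direction)) direction <- pair$direction
  if (is.null(direction)) stop("'direction' must be given")
  mask <- pair_region_mask(pair, image, direction)
  contour_from_mask(mask)
}

#' Select the pairs of a diagram above a persistence threshold
#'
#' Returns the sub-diagram whose pairs have persistence strictly greater
#' than `t`; pairs are otherwise unchanged.
#'
#' @param diagram A `persistence_diagram`.
#' @param t Non-negative persistence threshold.
#' @return A `persistence_diagram` with the selected pairs.
#' @export
select_persistent <- function(diagram, t) {
  stopifnot(inherits(diagram, "persistence_diagram"), t >= 0)
  diagram$pairs <- diagram$pairs[diagram$pairs$persistence > t, , drop = FALSE]
  rownames(diagram$pairs) <- NULL
  diagram
}
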