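#' Closed contour curve with filled-interior view
#'
#' A `contour_curve` is a closed, ordered polyline traced on the
#' pixel-corner lattice of an image: vertices sit at half-integer (row,
#' col) positions, consecutive vertices are one lattice step apart, and the
#' last vertex connects back to the first. The stored `interior` mask is
#' the rasterized filled interior of the polygon (pixels whose centre lies
#' inside), which by construction includes any holes enclosed by the curve.
#'
#' @param vertices n x 2 numeric matrix of (row, col) corner coordinates.
#' @param dim Image dimensions `c(H, W)` the interior mask refers to.
#' @return A `contour_curve` with fields `vertices`, `interior`, `dim`.
#' @seealso [contour_from_mask()], [contour_fill()]
#' @export
contour_curve <- function(vertices, dim) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 4L) stop("a closed contour needs at least 4 vertices")
  structure(list(vertices = vertices,
                 interior = contour_fill(vertices, dim),
                 dim = as.integer(dim)),
            class = "contour_curve")
}

#' @export
print.contour_curve <- function(x, ...) {
  cat(sprintf("<contour_curve> %d vertices, interior %d px (image %d x %d)\n",
              nrow(x$vertices), sum(x$interior), x$dim[1], x$dim[2]))
  invisible(x)
}

# Directed crack-boundary edges of a binary mask. Each boundary side of a
# foreground pixel contributes one directed edge between pixel corners;
# corners are encoded on an integer lattice where corner (a, b) sits at
# image coordinates (a + 0.5, b + 0.5), a in 0..H, b in 0..W.
# Directions: 1 = +col, 2 = +row, 3 = -col, 4 = -row.
boundary_edges <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  up    <- core & !pad[1:H, 2:(W + 1L)]
  down  <- core & !pad[3:(H + 2L), 2:(W + 1L)]
  left  <- core & !pad[2:(H + 1L), 1:W]
  right <- core & !pad[2:(H + 1L), 3:(W + 2L)]
  edges <- function(m, da, db, dir) {
    w <- which(m, arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    cbind(a = w[, 1] + da, b = w[, 2] + db, dir = dir)
  }
  rbind(
    edges(up,    -1L, -1L, 1L),  # top side, travelling +col from (i-1, j-1)
    edges(right, -1L,  0L, 2L),  # right side, +row from (i-1, j)
    edges(down,   0L,  0L, 3L),  # bottom side, -col from (i, j)
    edges(left,   0L, -1L, 4L)   # left side, -row from (i, j-1)
  )
}

DIR_STEP <- matrix(c(0L, 1L, 1L, 0L, 0L, -1L, -1L, 0L), ncol = 2, byrow = TRUE)

#' Trace the external boundary of a connected pixel region
#'
#' Follows the crack boundary of the foreground region on the pixel-corner
#' lattice, starting from its topmost-leftmost boundary corner, and returns
#' the outer closed loop. At corners where two diagonally-touching
#' foreground pixels meet, the trace crosses over to the neighbouring
#' pixel, so an 8-connected region yields a single external boundary
#' (matching the 8-connectivity used for level-set components).
#'
#' @param mask Logical matrix; the foreground should be one 8-connected
#'   region (only the loop through the region's first boundary corner is
#'   returned).
#' @return n x 2 matrix of (row, col) corner coordinates (half-integer).
#' @export
trace_region_boundary <- function(mask) {
  if (!any(mask)) stop("empty mask has no boundary")
  be <- boundary_edges(mask)
  H <- nrow(mask); W <- ncol(mask)
  key <- be[, "a"] * (W + 1L) + be[, "b"] + 1L
  nkey <- (H + 1L) * (W + 1L)
  out1 <- integer(nkey); out2 <- integer(nkey)
  for (r in seq_len(nrow(be))) {
    k <- key[r]
    if (out1[k] == 0L) out1[k] <- be[r, "dir"] else out2[k] <- be[r, "dir"]
  }
  # start from the topmost pixel of the leftmost occupied column: the
  # background above it reaches the image border, so its top side lies on
  # the external boundary; begin travelling +col from its top-left corner
  s <- which(mask)[1]
  jj <- (s - 1L) %/% H + 1L
  ii <- min(which(mask[, jj]))
  start_a <- ii - 1L; start_b <- jj - 1L; start_dir <- 1L
  a <- start_a; b <- start_b; dir <- start_dir
  verts_a <- integer(0); verts_b <- integer(0)
  repeat {
    verts_a <- c(verts_a, a); verts_b <- c(verts_b, b)
    a2 <- a + DIR_STEP[dir, 1]; b2 <- b + DIR_STEP[dir, 2]
    k2 <- a2 * (W + 1L) + b2 + 1L
    d1 <- out1[k2]; d2 <- out2[k2]
    ndir <- if (d2 == 0L) d1 else {
      # ambiguous corner (diagonal contact): cross over to the other pixel,
      # keeping diagonally-touching foreground in one external loop
      cross <- c(4L, 1L, 2L, 3L)[dir]
      if (d1 == cross || d2 == cross) cross else d1
    }
    if (ndir == 0L) stop("boundary tracing failed (broken edge chain)")
    a <- a2; b <- b2; dir <- ndir
    if (a == start_a && b == start_b && dir == start_dir) break
  }
  cbind(row = verts_a + 0.5, col = verts_b + 0.5)
}

#' Rasterize the filled interior of a corner-lattice polygon
#'
#' A pixel belongs to the interior when its centre lies inside the closed
#' polygon (even-odd rule). Because polygon edges are unit steps on the
#' corner lattice, only vertical edges can cross the horizontal scanline
#' through a pixel centre, which makes the parity count exact.
#'
#' @param vertices n x 2 matrix of (row, col) corner coordinates.
#' @param dim `c(H, W)` output mask dimensions.
#' @return Logical H x W matrix.
#' @export
contour_fill <- function(vertices, dim) {
  H <- dim[1]; W <- dim[2]
  a <- vertices[, 1] - 0.5; b <- vertices[, 2] - 0.5
  nxt <- c(seq_len(nrow(vertices))[-1], 1L)
  vert <- a != a[nxt]
  if (!any(vert)) return(matrix(FALSE, H, W))
  m <- pmin(a[vert], a[nxt][vert])   # lower corner row index of the edge
  bb <- b[vert]
  row <- m + 1L                       # the pixel row whose centres it crosses
  keep <- row >= 1 & row <= H & bb >= 0 & bb < W
  cnt <- matrix(0L, H, W + 1L)
  if (any(keep)) {
    pos <- row[keep] + (bb[keep]) * H   # linear index into cnt (column b+1)
    tab <- table(pos)
    cnt[as.integer(names(tab))] <- as.integer(tab)
  }
  parity <- t(apply(cnt, 1, cumsum))
  (parity[, seq_len(W), drop = FALSE] %% 2L) == 1L
}

#' Contour of a pixel region
#'
#' Traces the external boundary of the (8-connected) foreground region and
#' packages it with its filled interior as a [contour_curve()].
#'
#' @param mask Logical matrix, one 8-connected foreground region.
#' @return A `contour_curve`.
#' @export
contour_from_mask <- function(mask) {
  contour_curve(trace_region_boundary(mask), dim(mask))
}

#' Directed Hausdorff distance between two vertex sets
#'
#' `max over a in A of min over b in B` of the Euclidean distance, in the
#' coordinate units of the inputs (pixels for slice contours). This is the
#' asymmetric distance used to size the dilation when splitting nested
#' cycle representatives.
#'
#' @param a,b [contour_curve()] objects or plain n x 2 coordinate matrices.
#' @return Non-negative scalar.
#' @export
directed_hausdorff <- function(a, b) {
  A <- if (inherits(a, "contour_curve")) a$vertices else as.matrix(a)
  B <- if (inherits(b, "contour_curve")) b$vertices else as.matrix(b)
  if (!nrow(A) || !nrow(B)) stop("both vertex sets must be nonempty")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(pmax(apply(d2, 1, min), 0)))
}
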