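#' Intersection-over-union of two binary masks
#'
#' The ratio of the number of pixels in the intersection and in the union
#' of the two masks; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b Logical matrices of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
iou_score <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  sum(a & b) / uni
}

#' Read a z-stack of grayscale slices
#'
#' Accepts a multi-page TIFF file, a directory of single-page TIFFs (sorted
#' by file name), or a list of numeric matrices (passed through). Colour
#' images are reduced to their first channel.
#'
#' @param input Path or list of matrices.
#' @return List of numeric matrices.
#' @export
read_stack <- function(input) {
  if (is.list(input) && all(vapply(input, is.matrix, logical(1))))
    return(input)
  if (is.list(input) && all(vapply(input, inherits, logical(1), "intensity_image")))
    return(lapply(input, `[[`, "values"))
  if (!is.character(input) || length(input) != 1L)
    stop("'input' must be a path or a list of matrices")
  if (dir.exists(input)) {
    files <- sort(list.files(input, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF files found in ", input)
    pages <- lapply(files, tiff::readTIFF)
  } else {
    if (!file.exists(input)) stop("input stack not found: ", input)
    pages <- tiff::readTIFF(input, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    as.matrix(p)
  })
}

#' Write a z-stack as a multi-page TIFF
#'
#' @param stack List of numeric matrices in \[0, 1\] or
#'   [intensity_image()] objects.
#' @param path Output file.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  mats <- lapply(stack, function(s)
    if (inherits(s, "intensity_image")) s$values else s)
  tiff::writeTIFF(mats, path, bits.per.sample = bits)
  invisible(path)
}

#' Write a labeled segmentation mask as 16-bit TIFF
#'
#' @param labels Integer matrix (0 = background, 1 = membrane interior,
#'   1 + k = cavity k).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Write persistence diagrams to CSV
#'
#' Columns `direction, birth, death, persistence, representative_id`, with
#' '.' decimal separator and LF line endings. Representative contours go to
#' a companion file via [write_contours_csv()] keyed by
#' `representative_id`.
#'
#' @param diagrams List of `persistence_diagram` objects.
#' @param path Output CSV file.
#' @param representative_ids Optional list of integer vectors (one per
#'   diagram) giving the id of each pair's contour, NA when absent.
#' @return `path`, invisibly.
#' @export
write_diagram_csv <- function(diagrams, path, representative_ids = NULL) {
  rows <- c("direction,birth,death,persistence,representative_id")
  for (d in seq_along(diagrams)) {
    dg <- diagrams[[d]]
    if (!nrow(dg$pairs)) next
    ids <- if (is.null(representative_ids)) rep(NA_integer_, nrow(dg$pairs))
           else representative_ids[[d]]
    rows <- c(rows, sprintf("%s,%s,%s,%s,%s", dg$direction,
                            fmt_num(dg$pairs$birth), fmt_num(dg$pairs$death),
                            fmt_num(dg$pairs$persistence),
                            ifelse(is.na(ids), "", as.character(ids))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Write contour curves to CSV
#'
#' Columns `representative_id, vertex_index, row, col` ('.' decimals, LF
#' endings).
#'
#' @param contours List of [contour_curve()] (names or positions give the
#'   ids).
#' @param path Output CSV file.
#' @param ids Integer ids, one per contour (default `seq_along`).
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path, ids = seq_along(contours)) {
  rows <- c("representative_id,vertex_index,row,col")
  for (k in seq_along(contours)) {
    v <- contours[[k]]$vertices
    rows <- c(rows, sprintf("%d,%d,%s,%s", ids[k], seq_len(nrow(v)),
                            fmt_num(v[, 1]), fmt_num(v[, 2])))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read back a contour CSV written by [write_contours_csv()]
#'
#' @param path CSV file.
#' @param dim Image dimensions used to rebuild the interior masks.
#' @return Named list of [contour_curve()] keyed by representative id.
#' @export
read_contours_csv <- function(path, dim) {
  df <- utils::read.csv(path)
  lapply(split(df, df$representative_id), function(g) {
    g <- g[order(g$vertex_index), ]
    contour_curve(cbind(row = g$row, col = g$col), dim)
  })
}

#' Write phantom stack, ground truth and parameters to a directory
#'
#' The stack and per-slice ground-truth masks are written as multi-page
#' TIFFs, and the generating parameters are echoed to a JSON sidecar.
#'
#' @param phantom Result of [generate_phantom_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(phantom$stack, file.path(dir, "stack.tif"))
  write_stack(lapply(phantom$truth$membrane_masks, function(m) m * 1),
              file.path(dir, "truth_membrane.tif"), bits = 8L)
  cav <- lapply(seq_along(phantom$truth$cavity_masks), function(z) {
    lab <- matrix(0, phantom$params$shape[1], phantom$params$shape[2])
    for (k in seq_along(phantom$truth$cavity_masks[[z]]))
      lab[phantom$truth$cavity_masks[[z]][[k]]] <- k / 255
    lab
  })
  write_stack(cav, file.path(dir, "truth_cavities.tif"), bits = 8L)
  par <- phantom$params
  class(par) <- NULL
  jsonlite::write_json(par, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
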