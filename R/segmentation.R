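#' Slice-segmentation configuration
#'
#' @param threshold A [threshold_config()] used for both filtration
#'   directions.
#' @param inside_tol Fraction of a candidate cavity's interior pixels that
#'   must lie inside the membrane profile for the cavity to be kept
#'   (default 0.99; a tolerance for one-pixel boundary rasterization).
#' @param hausdorff_direction Direction of the directed Hausdorff distance
#'   that sizes the dilation when splitting nested cycles:
#'   `"inner_to_outer"` (default) or `"outer_to_inner"`.
#' @param pad_border Passed to the diagram computations; see
#'   [sublevel_h1_diagram()].
#' @return A `seg_config` list.
#' @export
seg_config <- function(threshold = threshold_config(),
                       inside_tol = 0.99,
                       hausdorff_direction = c("inner_to_outer", "outer_to_inner"),
                       pad_border = FALSE) {
  structure(list(threshold = threshold,
                 inside_tol = inside_tol,
                 hausdorff_direction = match.arg(hausdorff_direction),
                 pad_border = pad_border),
            class = "seg_config")
}

no_membrane_error <- function(msg) {
  stop(structure(class = c("persiseg_no_membrane", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Segment the membrane profile of one slice
#'
#' Computes the sublevel H1 diagram of the slice, selects its most
#' persistent cycles with the automatic threshold, takes the union of the
#' selected cycles' bright regions and returns the external boundary of
#' that union. Dark holes inside the union are deliberately ignored here:
#' cavity detection is an independent routine ([detect_cavities()]). When
#' the union has several connected components, the largest is kept and the
#' others are reported with a warning (one cell profile per image is
#' assumed).
#'
#' @param image An [intensity_image()].
#' @param config A [seg_config()].
#' @return A [contour_curve()]: the membrane profile. Its interior is the
#'   filled cell region.
#' @export
segment_membrane <- function(image, config = seg_config()) {
  image <- as_intensity_image(image)
  diag <- sublevel_h1_diagram(image, pad_border = config$pad_border)
  if (!nrow(diag$pairs))
    no_membrane_error("no membrane found: sublevel diagram is empty")
  t_star <- optimal_threshold(diag$pairs$persistence, config$threshold)
  sel <- select_persistent(diag, t_star)
  if (!nrow(sel$pairs))
    no_membrane_error("no membrane found: no cycle above the persistence threshold")
  acc <- matrix(FALSE, nrow(image$values), ncol(image$values))
  for (k in seq_len(nrow(sel$pairs)))
    acc <- acc | pair_region_mask(sel$pairs[k, ], image, "sublevel")
  lab <- label_components(acc, 8L)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) > 1L)
    warning(sprintf("selected bright regions form %d components; keeping the largest",
                    length(sizes)))
  contour_from_mask(lab == which.max(sizes))
}

#' Detect internal cavities of one slice
#'
#' Computes the superlevel H1 diagram (dark blobs enclosed by brighter
#' surroundings), restricts it to the classes whose representative region
#' lies inside the membrane profile, chooses the automatic persistence
#' threshold on that subfamily alone, and returns the representatives of
#' the classes above it.
#'
#' @param image An [intensity_image()].
#' @param gamma The membrane profile from [segment_membrane()] on the same
#'   image.
#' @param config A [seg_config()].
#' @return List of [contour_curve()] cavities (possibly empty), ordered by
#'   decreasing persistence. Nested representatives may be present; pass
#'   the result through [refine_nested()].
#' @export
detect_cavities <- function(image, gamma, config = seg_config()) {
  image <- as_intensity_image(image)
  diag <- superlevel_h1_diagram(image, pad_border = config$pad_border)
  p <- diag$pairs
  if (!nrow(p)) return(list())
  g_int <- gamma$interior
  # one labelling per distinct birth level serves all pairs born there
  regions <- vector("list", nrow(p))
  inside <- logical(nrow(p))
  for (b in unique(p$birth)) {
    lab <- label_components(image$values < b, 8L)
    for (k in which(p$birth == b)) {
      reg <- lab == lab[p$crit_row[k], p$crit_col[k]]
      filled <- as.logical(EBImage::fillHull(reg))
      dim(filled) <- dim(reg)
      regions[[k]] <- reg
      inside[k] <- sum(filled & g_int) >= config$inside_tol * sum(filled)
    }
  }
  if (!any(inside)) return(list())
  sub <- which(inside)
  t_star <- optimal_threshold(p$persistence[sub], config$threshold)
  keep <- sub[p$persistence[sub] > t_star]
  lapply(keep, function(k) contour_from_mask(regions[[k]]))
}

#' Split one nested pair of cycle representatives
#'
#' Given an inner curve whose interior is contained in the outer curve's
#' interior (the configuration produced by a saddle point), carves the
#' outer representative away from the inner one: the inner filled mask is
#' dilated by a Euclidean disk whose radius is the directed Hausdorff
#' distance between the two curves (from the inner curve to the outer one
#' by default), the dilated mask is subtracted from the outer interior, and
#' the external boundary of the largest remaining component becomes the
#' outer class's new representative. By construction of the radius the
#' dilated region touches the outer curve, so the remainder does not wrap
#' around the inner curve and the two refined interiors are disjoint.
#'
#' If the subtraction empties the outer region (near-coincident curves),
#' the outer curve is returned unchanged with a warning.
#'
#' @param inner,outer [contour_curve()] objects, `inner` nested in `outer`.
#' @param config A [seg_config()] (controls the Hausdorff direction).
#' @return The new outer [contour_curve()].
#' @export
split_nested_pair <- function(inner, outer, config = seg_config()) {
  if (!all(outer$interior[inner$interior]))
    stop("'inner' is not nested inside 'outer'")
  r <- if (config$hausdorff_direction == "inner_to_outer")
    directed_hausdorff(inner, outer) else directed_hausdorff(outer, inner)
  for (radius in c(r, r + 1)) {   # +1 px retry guards against raster bridges
    dist <- EBImage::distmap(!inner$interior)
    dim(dist) <- dim(inner$interior)
    dilated <- inner$interior | (dist <= radius)
    remainder <- outer$interior & !dilated
    if (!any(remainder)) {
      warning("nested-cycle split left an empty outer region; keeping the outer curve")
      return(outer)
    }
    lab <- label_components(remainder, 8L)
    new_outer <- contour_from_mask(lab == which.max(tabulate(lab[lab > 0L])))
    if (!any(new_outer$interior & inner$interior)) return(new_outer)
  }
  warning("nested-cycle split could not separate the interiors; keeping the outer curve")
  outer
}

#' Resolve all nested cavity representatives
#'
#' Repeatedly applies [split_nested_pair()] to nested couples of curves,
#' innermost first, until no interior is contained in another. The output
#' has the same length as the input and pairwise-disjoint interiors
#' (partial overlaps that are not nestings are left untouched).
#'
#' @param cavities List of [contour_curve()].
#' @param config A [seg_config()].
#' @return List of refined [contour_curve()] objects, same length.
#' @export
refine_nested <- function(cavities, config = seg_config()) {
  n <- length(cavities)
  if (n < 2L) return(cavities)
  max_sweeps <- n * n + 1L
  for (sweep in seq_len(max_sweeps)) {
    areas <- vapply(cavities, function(c) sum(c$interior), numeric(1))
    ord <- order(areas)
    found <- FALSE
    for (a in ord) {
      for (b in ord[areas[ord] > areas[a]]) {
        ia <- cavities[[a]]$interior; ib <- cavities[[b]]$interior
        if (all(ib[ia])) {
          cavities[[b]] <- split_nested_pair(cavities[[a]], cavities[[b]], config)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) return(cavities)
  }
  stop(sprintf(paste0("nested-cycle refinement did not converge after %d sweeps ",
                      "(%d curves; areas: %s)"),
               max_sweeps, n,
               paste(vapply(cavities, function(c) sum(c$interior), numeric(1)),
                     collapse = ", ")))
}

#' Segment one slice end to end
#'
#' Membrane profile, cavity detection restricted to its interior, and
#' nested-cycle refinement, assembled into a `slice_segmentation`.
#'
#' @param image An [intensity_image()].
#' @param config A [seg_config()].
#' @param slice_index Integer index recorded in the result.
#' @return A `slice_segmentation`: list with `membrane` (a
#'   [contour_curve()]), `cavities` (list of disjoint contour curves inside
#'   the membrane), `slice_index`, `dim`, and the per-direction thresholds
#'   used (`threshold_sublevel`, `threshold_superlevel`).
#' @export
segment_slice <- function(image, config = seg_config(), slice_index = 1L) {
  image <- as_intensity_image(image)
  diag <- sublevel_h1_diagram(image, pad_border = config$pad_border)
  t_sub <- if (nrow(diag$pairs))
    optimal_threshold(diag$pairs$persistence, config$threshold) else NA_real_
  gamma <- segment_membrane(image, config)
  cavities <- detect_cavities(image, gamma, config)
  cavities <- refine_nested(cavities, config)
  structure(list(membrane = gamma, cavities = cavities,
                 slice_index = as.integer(slice_index),
                 dim = dim(image$values),
                 threshold_sublevel = t_sub),
            class = "slice_segmentation")
}

#' @export
print.slice_segmentation <- function(x, ...) {
  cat(sprintf("<slice_segmentation> slice %d: membrane %d px, %d cavit%s\n",
              x$slice_index, sum(x$membrane$interior), length(x$cavities),
              if (length(x$cavities) == 1) "y" else "ies"))
  invisible(x)
}

#' Labeled mask of a slice segmentation
#'
#' Integer matrix with 0 = background, 1 = membrane interior, and 2 + k for
#' the interior of cavity k (cavities override the membrane label).
#'
#' @param seg A `slice_segmentation`.
#' @return Integer H x W matrix.
#' @export
segmentation_label_mask <- function(seg) {
  lab <- matrix(0L, seg$dim[1], seg$dim[2])
  lab[seg$membrane$interior] <- 1L
  for (k in seq_along(seg$cavities))
    lab[seg$cavities[[k]]$interior] <- 1L + k
  lab
}
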