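#' Pipeline configuration
#'
#' @param input Path to a multi-page TIFF, a directory of TIFFs, or an
#'   in-memory list of matrices.
#' @param out_dir Output directory.
#' @param pixel_size,axial_spacing Voxel spacing in micrometres (defaults
#'   0.16 and 0.3, the spinning-disk resolution the package targets).
#' @param normalize `"slice"` (min-max per slice, default), `"stack"`
#'   (min-max over the whole volume) or `"none"`.
#' @param seg A [seg_config()].
#' @param recon A [recon_config()]; its `pixel_size`/`axial_spacing` are
#'   overridden by the values given here.
#' @param seed Integer seed (used by stochastic post-processing steps; the
#'   segmentation itself is deterministic).
#' @param verbose Print progress to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir = NULL,
                            pixel_size = 0.16, axial_spacing = 0.3,
                            normalize = c("slice", "stack", "none"),
                            seg = seg_config(), recon = recon_config(),
                            seed = 1L, verbose = TRUE) {
  normalize <- match.arg(normalize)
  if (pixel_size <= 0 || axial_spacing <= 0) stop("spacings must be positive")
  recon$pixel_size <- pixel_size
  recon$axial_spacing <- axial_spacing
  structure(list(input = input, out_dir = out_dir, pixel_size = pixel_size,
                 axial_spacing = axial_spacing, normalize = normalize,
                 seg = seg, recon = recon, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

log_msg <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Run the full segmentation and reconstruction pipeline
#'
#' Reads the stack, normalizes intensities, segments every slice (membrane
#' profile, cavities, nested-cycle refinement), reconstructs the
#' triangulated surface, smooths it with Taubin's method and optionally
#' remeshes it. Slices where no membrane is found are logged and skipped;
#' fewer than two segmentable slices is a hard error. When `out_dir` is
#' set, per-slice labeled masks (16-bit TIFF), contour and diagram CSVs,
#' the meshes (PLY and OBJ) and a JSON run log are written there.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `segmentations`, `mesh` (smoothed),
#'   `raw_mesh`, `audit`, `skipped` (slice indices), `log` (per-slice
#'   thresholds and cavity counts).
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  mats <- read_stack(config$input)
  if (config$normalize == "stack") {
    rng <- range(unlist(lapply(mats, range)))
    if (rng[2] > rng[1])
      mats <- lapply(mats, function(m) (m - rng[1]) / (rng[2] - rng[1]))
  }
  n <- length(mats)
  segmentations <- list()
  skipped <- integer(0)
  slice_log <- list()
  for (z in seq_len(n)) {
    img <- intensity_image(mats[[z]], pixel_size = config$pixel_size,
                           normalize = config$normalize == "slice")
    seg <- tryCatch(
      segment_slice(img, config$seg, slice_index = z),
      persiseg_no_membrane = function(e) e)
    if (inherits(seg, "condition")) {
      skipped <- c(skipped, z)
      log_msg(config, "slice %d: skipped (%s)", z, conditionMessage(seg))
      next
    }
    segmentations[[length(segmentations) + 1L]] <- seg
    slice_log[[length(slice_log) + 1L]] <-
      list(slice = z, threshold_sublevel = seg$threshold_sublevel,
           n_cavities = length(seg$cavities))
    log_msg(config, "slice %d: membrane %d px, %d cavities (t* = %.3f)",
            z, sum(seg$membrane$interior), length(seg$cavities),
            seg$threshold_sublevel)
  }
  if (length(skipped))
    log_msg(config, "%d slice(s) skipped with no membrane", length(skipped))
  if (length(segmentations) < 2L)
    stop("fewer than 2 segmentable slices; cannot reconstruct a surface")

  raw_mesh <- reconstruct_mesh(segmentations, config$recon)
  mesh <- taubin_smooth(raw_mesh, config$recon$taubin_lambda,
                        config$recon$taubin_mu, config$recon$taubin_iters)
  if (!is.null(config$recon$remesh_target_vertices))
    mesh <- remesh_uniform(mesh, config$recon$remesh_target_vertices)
  audit <- audit_mesh(mesh, config$recon$d_max)
  log_msg(config, "mesh: %d vertices, %d triangles, %d components; d_max %s",
          nrow(mesh$vertices), nrow(mesh$triangles), audit$components,
          if (audit$d_max_ok) "ok" else "VIOLATED")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (seg in segmentations) {
      z <- seg$slice_index
      write_label_mask(segmentation_label_mask(seg),
                       file.path(config$out_dir, sprintf("mask_%03d.tif", z)))
      cons <- c(list(seg$membrane), seg$cavities)
      write_contours_csv(cons,
                         file.path(config$out_dir, sprintf("contours_%03d.csv", z)))
    }
    write_ply(mesh, file.path(config$out_dir, "mesh.ply"))
    write_obj(mesh, file.path(config$out_dir, "mesh.obj"))
    jsonlite::write_json(
      list(slices = slice_log, skipped = skipped,
           audit = audit[c("d_max_ok", "welding_ok", "components")],
           n_vertices = nrow(mesh$vertices), n_triangles = nrow(mesh$triangles)),
      file.path(config$out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(segmentations = segmentations, mesh = mesh,
                 raw_mesh = raw_mesh, audit = audit, skipped = skipped,
                 log = slice_log))
}
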