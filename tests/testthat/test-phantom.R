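test_that("phantom generation is deterministic for a fixed seed", {
  p <- small_phantom_params(noise_sigma = 0.04, seed = 42L)
  a <- generate_phantom_stack(p)
  b <- generate_phantom_stack(p)
  expect_identical(lapply(a$stack, `[[`, "values"),
                   lapply(b$stack, `[[`, "values"))
  c <- generate_phantom_stack(small_phantom_params(noise_sigma = 0.04, seed = 43L))
  expect_false(identical(a$stack[[1]]$values, c$stack[[1]]$values))
})

test_that("an undegraded phantom is piecewise constant and matches its masks", {
  p <- small_phantom_params(blur_sigma = 0, noise_sigma = 0, quantize = 0L)
  ph <- generate_phantom_stack(p)
  for (z in c(1L, 4L)) {
    u <- ph$stack[[z]]$values
    expect_setequal(unique(as.vector(u)),
                    c(p$background_intensity, 0.10,
                      p$cytoplasm_intensity, p$membrane_intensity))
    # every non-background pixel is exactly the cell region minus the channel
    expect_identical(u != p$background_intensity, ph$truth$membrane_masks[[z]])
    for (cm in ph$truth$cavity_masks[[z]])
      expect_true(all(u[cm] == 0.10))
  }
})

test_that("slices through both cavity ellipsoids contain exactly two dark disks", {
  ph <- generate_phantom_stack()
  mid <- 8L
  expect_equal(ph$truth$cavity_count[mid], 2L)
  expect_length(ph$truth$cavity_masks[[mid]], 2L)
  expect_true(all(vapply(ph$truth$cavity_masks[[mid]], sum, integer(1)) > 20L))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(cytoplasm_intensity = 0.96), "background < cavity")
  expect_error(phantom_params(membrane_radii = c(-1, 30, 30)), "positive")
  expect_error(
    generate_phantom_stack(phantom_params(membrane_radii = c(60, 35, 40))),
    "exceeds")
})

test_that("unknown toy fixtures report the available names", {
  expect_error(generate_toy_image("nope"), "ring3")
})

test_that("segmentation quality degrades monotonically with noise", {
  mean_iou <- function(noise) {
    ph <- generate_phantom_stack(small_phantom_params(noise_sigma = noise,
                                                      seed = 3L))
    mean(vapply(seq_along(ph$stack), function(z) {
      seg <- segment_slice(intensity_image(ph$stack[[z]]$values))
      iou_score(seg$membrane$interior, ph$truth$membrane_masks[[z]])
    }, numeric(1)))
  }
  ious <- vapply(c(0, 0.05, 0.15), mean_iou, numeric(1))
  expect_true(all(diff(ious) <= 0))
  expect_gt(ious[1], 0.95)
})

test_that("phantom writer round-trips through TIFF and JSON", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom_stack(small_phantom_params())
  write_phantom(ph, dir)
  back <- read_stack(file.path(dir, "stack.tif"))
  expect_length(back, length(ph$stack))
  expect_lt(max(abs(back[[2]] - ph$stack[[2]]$values)), 1 / 65535)
  par <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(par$blur_sigma, ph$params$blur_sigma)
  truth <- read_stack(file.path(dir, "truth_membrane.tif"))
  expect_identical(truth[[1]] > 0, ph$truth$membrane_masks[[1]])
})
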