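test_that("noiseless phantom slices are recovered almost exactly", {
  ph <- generate_phantom_stack(small_phantom_params())
  for (z in c(1L, 3L, 6L)) {
    seg <- segment_slice(intensity_image(ph$stack[[z]]$values), slice_index = z)
    expect_gte(iou_score(seg$membrane$interior, ph$truth$membrane_masks[[z]]),
               0.95)
    expect_equal(length(seg$cavities), ph$truth$cavity_count[z])
    expect_lt(mean_contour_distance(seg$membrane,
                                    ph$truth$membrane_masks[[z]]), 1)
    for (cav in seg$cavities) {
      d <- min(vapply(ph$truth$cavity_masks[[z]], function(m)
        mean_contour_distance(cav, m), numeric(1)))
      expect_lt(d, 1)
    }
    # invariants: cavities inside the membrane and pairwise disjoint
    for (cav in seg$cavities)
      expect_gte(sum(cav$interior & seg$membrane$interior) / sum(cav$interior),
                 0.99)
    if (length(seg$cavities) > 1)
      for (i in 1:(length(seg$cavities) - 1))
        for (j in (i + 1):length(seg$cavities))
          expect_equal(sum(seg$cavities[[i]]$interior &
                           seg$cavities[[j]]$interior), 0L)
    # fill-consistency of every output contour
    for (cc in c(list(seg$membrane), seg$cavities))
      expect_identical(cc$interior, contour_fill(cc$vertices, cc$dim))
  }
})

test_that("noise below the persistence threshold does not change cavity counts", {
  noiseless <- generate_phantom_stack(small_phantom_params())
  noisy <- generate_phantom_stack(small_phantom_params(noise_sigma = 0.05,
                                                       seed = 5L))
  for (z in c(2L, 4L)) {
    s0 <- segment_slice(intensity_image(noiseless$stack[[z]]$values))
    s1 <- segment_slice(intensity_image(noisy$stack[[z]]$values))
    expect_equal(length(s1$cavities), length(s0$cavities))
  }
})

test_that("speckle below the threshold is excluded from the membrane profile", {
  u <- matrix(0.05, 40, 40)
  u[disk_mask(40, 40, c(20, 20), 10)] <- 0.9
  set.seed(2)
  for (k in 1:6) u[sample(5:35, 1), sample(32:38, 1)] <- 0.3
  gamma <- segment_membrane(intensity_image(u, normalize = FALSE))
  expect_true(all(gamma$vertices[, 2] < 32))   # speckle region untouched
  expect_gte(iou_score(gamma$interior, disk_mask(40, 40, c(20, 20), 10)), 0.9)
})

test_that("a constant image raises the dedicated no-membrane error", {
  expect_error(segment_membrane(generate_toy_image("const")),
               class = "persiseg_no_membrane")
  expect_error(segment_slice(generate_toy_image("const")),
               class = "persiseg_no_membrane")
})

test_that("cavities outside the membrane profile are rejected", {
  u <- matrix(0.05, 60, 60)
  u[disk_mask(60, 60, c(30, 22), 14)] <- 0.9          # the cell
  ring <- disk_mask(60, 60, c(30, 50), 7) & !disk_mask(60, 60, c(30, 50), 4)
  u[ring] <- 0.9                                      # external bright ring
  img <- intensity_image(u, normalize = FALSE)
  gamma <- suppressWarnings(segment_membrane(img))
  cavs <- detect_cavities(img, gamma)
  expect_length(cavs, 0L)                              # ring hole is outside
})

test_that("a slice with no interior minima yields no cavities", {
  u <- matrix(0.05, 30, 30)
  u[disk_mask(30, 30, c(15, 15), 9)] <- 0.9
  img <- intensity_image(u, normalize = FALSE)
  gamma <- segment_membrane(img)
  expect_length(detect_cavities(img, gamma), 0L)
})

test_that("nested pair splitting carves a disjoint outer representative", {
  inner <- contour_from_mask(disk_mask(60, 60, c(25, 25), 5))
  outer <- contour_from_mask(disk_mask(60, 60, c(32, 32), 20))
  res <- split_nested_pair(inner, outer)
  expect_equal(sum(res$interior & inner$interior), 0L)
  expect_true(all(outer$interior[res$interior]))   # stays inside the old outer
})

test_that("near-coincident nested curves trigger the degenerate fallback", {
  inner <- contour_from_mask(disk_mask(40, 40, c(20, 20), 9))
  outer <- contour_from_mask(disk_mask(40, 40, c(20, 20), 10))
  expect_warning(res <- split_nested_pair(inner, outer), "keeping the outer")
  expect_identical(res$vertices, outer$vertices)
})

test_that("split_nested_pair rejects non-nested inputs", {
  a <- contour_from_mask(disk_mask(40, 40, c(12, 12), 5))
  b <- contour_from_mask(disk_mask(40, 40, c(30, 30), 5))
  expect_error(split_nested_pair(a, b), "not nested")
})

test_that("refinement resolves nesting and is idempotent", {
  # no nesting: untouched
  a <- contour_from_mask(disk_mask(50, 50, c(15, 15), 6))
  b <- contour_from_mask(disk_mask(50, 50, c(35, 35), 6))
  expect_identical(refine_nested(list(a, b)), list(a, b))

  # one nested pair
  inner <- contour_from_mask(disk_mask(60, 60, c(25, 25), 5))
  outer <- contour_from_mask(disk_mask(60, 60, c(32, 32), 20))
  ref <- refine_nested(list(inner, outer))
  expect_length(ref, 2L)
  expect_equal(sum(ref[[1]]$interior & ref[[2]]$interior), 0L)

  # three-level chain ends pairwise disjoint, count preserved
  c1 <- contour_from_mask(disk_mask(90, 90, c(30, 45), 5))
  c2 <- contour_from_mask(disk_mask(90, 90, c(38, 45), 15))
  c3 <- contour_from_mask(disk_mask(90, 90, c(46, 45), 30))
  ref3 <- refine_nested(list(c1, c2, c3))
  expect_length(ref3, 3L)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(sum(ref3[[i]]$interior & ref3[[j]]$interior), 0L)
  ref3b <- refine_nested(ref3)
  expect_identical(lapply(ref3b, `[[`, "interior"),
                   lapply(ref3, `[[`, "interior"))
})

test_that("the nested-cavities fixture separates into disjoint curves", {
  img <- generate_toy_image("nested_cavities")
  gamma <- segment_membrane(img)
  cavs <- detect_cavities(img, gamma)
  expect_length(cavs, 2L)
  ref <- refine_nested(cavs)
  expect_length(ref, 2L)
  expect_equal(sum(ref[[1]]$interior & ref[[2]]$interior), 0L)
  # each dark disk ends up covered by exactly one refined curve
  darkest <- which(img$values == 0.1, arr.ind = TRUE)[1, ]
  second <- which(img$values == 0.2, arr.ind = TRUE)[1, ]
  inA <- vapply(ref, function(cc) cc$interior[darkest[1], darkest[2]], logical(1))
  inB <- vapply(ref, function(cc) cc$interior[second[1], second[2]], logical(1))
  expect_equal(sum(inA), 1L)
  expect_equal(sum(inB), 1L)
  expect_false(any(inA & inB))
})

test_that("segmentation label masks encode membrane and cavities", {
  ph <- generate_phantom_stack(small_phantom_params())
  seg <- segment_slice(intensity_image(ph$stack[[3]]$values), slice_index = 3)
  lab <- segmentation_label_mask(seg)
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L, 3L))
  expect_equal(sum(lab >= 2L),
               sum(vapply(seg$cavities, function(c) sum(c$interior), integer(1))))
})
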