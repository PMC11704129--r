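test_that("ring toy yields the single expected pair in both directions", {
  img <- generate_toy_image("ring3")
  d <- sublevel_h1_diagram(img)
  expect_equal(nrow(d$pairs), 1L)
  expect_equal(d$pairs$birth, 0.1)
  expect_equal(d$pairs$death, 0.9)
  expect_equal(d$pairs$persistence, 0.8)
  expect_equal(d$pairs[, c("crit_row", "crit_col")],
               data.frame(crit_row = 2L, crit_col = 2L))

  dark <- intensity_image(1 - img$values, normalize = FALSE)
  ds <- superlevel_h1_diagram(dark)
  expect_equal(nrow(ds$pairs), 1L)
  expect_equal(ds$pairs$birth, 0.9)
  expect_equal(ds$pairs$death, 0.1)
  expect_equal(ds$pairs$persistence, 0.8)
})

test_that("constant images have empty diagrams", {
  img <- generate_toy_image("const")
  expect_equal(nrow(sublevel_h1_diagram(img)$pairs), 0L)
  expect_equal(nrow(superlevel_h1_diagram(img)$pairs), 0L)
})

test_that("input validation rejects bad images", {
  expect_error(intensity_image(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
  expect_error(intensity_image(matrix(1, 1, 5)), "2x2")
  expect_error(intensity_image(matrix(2, 3, 3), normalize = FALSE), "\\[0, 1\\]")
  expect_error(betti1_at_threshold(generate_toy_image("ring3"), 1.5), "\\[0, 1\\]")
})

test_that("a saddle births a new class while the elder keeps its representative", {
  img <- generate_toy_image("saddle_dumbbell")
  d <- sublevel_h1_diagram(img)
  expect_equal(nrow(d$pairs), 2L)
  expect_equal(d$pairs$birth, c(0.05, 0.30))
  expect_equal(d$pairs$death, c(0.75, 0.57))

  elder <- representative_contour(d$pairs[1, ], img, "sublevel")
  young <- representative_contour(d$pairs[2, ], img, "sublevel")
  # elder representative covers both hills, the younger only the second
  expect_true(elder$interior[which(img$values == 0.75, arr.ind = TRUE)[1, 1],
                             which(img$values == 0.75, arr.ind = TRUE)[1, 2]])
  expect_true(elder$interior[12, 30])
  expect_true(young$interior[12, 30])
  expect_false(young$interior[12, 10])

  # removing the second hill does not change the elder's representative
  flat <- img$values
  flat[flat == 0.57] <- 0.30
  d2 <- sublevel_h1_diagram(intensity_image(flat, normalize = FALSE))
  expect_equal(nrow(d2$pairs), 1L)
  elder2 <- representative_contour(d2$pairs[1, ],
                                   intensity_image(flat, normalize = FALSE),
                                   "sublevel")
  expect_identical(elder$vertices, elder2$vertices)
})

test_that("disk representative hugs the disk boundary", {
  img <- generate_toy_image("disk")
  d <- sublevel_h1_diagram(img)
  rc <- representative_contour(d$pairs[1, ], img, "sublevel")
  radii <- sqrt((rc$vertices[, 1] - 11)^2 + (rc$vertices[, 2] - 11)^2)
  expect_lt(mean(abs(radii - 6)), 1)
})

test_that("superlevel diagram equals sublevel diagram of the inverted image", {
  set.seed(11)
  for (rep in 1:20) {
    u <- matrix(sample(0:10, 144, TRUE) / 10, 12, 12)
    img <- intensity_image(u, normalize = FALSE)
    inv <- intensity_image(1 - u, normalize = FALSE)
    a <- superlevel_h1_diagram(img)$pairs
    b <- sublevel_h1_diagram(inv)$pairs
    key <- function(bi, de) paste(sort(paste(round(bi, 9), round(de, 9))),
                                  collapse = ";")
    expect_equal(key(a$birth, a$death), key(1 - b$birth, 1 - b$death))
  }
})

test_that("alive-pair counts match the brute-force Betti oracle", {
  set.seed(5)
  for (rep in 1:20) {
    u <- matrix(sample(0:10, 144, TRUE) / 10, 12, 12)
    img <- intensity_image(u, normalize = FALSE)
    for (dir in c("sublevel", "superlevel")) {
      d <- if (dir == "sublevel") sublevel_h1_diagram(img)
           else superlevel_h1_diagram(img)
      for (t in unique(as.vector(u)))
        expect_equal(persiseg:::pairs_alive_at(d, t),
                     betti1_at_threshold(img, t, dir),
                     info = sprintf("rep %d dir %s t %.1f", rep, dir, t))
    }
  }
})

test_that("diagram transforms follow intensity transforms", {
  set.seed(21)
  for (rep in 1:10) {
    u <- matrix(sample(1:8, 100, TRUE) / 20, 10, 10)   # values in (0, 0.4]
    img <- intensity_image(u, normalize = FALSE)
    d0 <- sublevel_h1_diagram(img)$pairs

    # shift invariance of persistence; births/deaths shift by c
    sh <- sublevel_h1_diagram(intensity_image(u + 0.3, normalize = FALSE))$pairs
    expect_equal(sort(sh$persistence), sort(d0$persistence))
    expect_equal(sort(sh$birth), sort(d0$birth + 0.3))
    expect_equal(sort(sh$death), sort(d0$death + 0.3))

    # scale equivariance of persistence
    sc <- sublevel_h1_diagram(intensity_image(u * 0.5, normalize = FALSE))$pairs
    expect_equal(sort(sc$persistence), sort(d0$persistence * 0.5))

    # monotone relabeling preserves the number of pairs
    mono <- sublevel_h1_diagram(intensity_image(sqrt(u), normalize = FALSE))$pairs
    expect_equal(nrow(mono), nrow(d0))
  }
})

test_that("oracle examples match their derived values", {
  img <- generate_toy_image("ring3")
  expect_equal(betti1_at_threshold(img, 0.5, "sublevel"), 1L)
  expect_equal(betti1_at_threshold(img, 0.95, "sublevel"), 0L)
  expect_equal(betti1_at_threshold(generate_toy_image("const"), 0.3, "sublevel"), 0L)
})

test_that("border padding lets border-touching bright structures close a cycle", {
  u <- matrix(0.1, 6, 6)
  u[1:3, 2:4] <- 0.9   # bright blob touching the top border
  img <- intensity_image(u, normalize = FALSE)
  expect_equal(nrow(sublevel_h1_diagram(img)$pairs), 0L)
  padded <- sublevel_h1_diagram(img, pad_border = TRUE)
  expect_equal(nrow(padded$pairs), 1L)
  expect_equal(padded$pairs$persistence, 0.8)
})
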