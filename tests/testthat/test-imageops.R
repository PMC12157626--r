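# Operators vs brute-force oracles and their morphological invariants.

test_that("background subtraction agrees with the direct grayscale-opening oracle", {
  set.seed(7)
  for (shape in c("paraboloid", "ball")) {
    # smooth ramp + bumps, 32x32
    ramp <- outer(seq(0, 40, length.out = 32), seq(0, 20, length.out = 32), `+`)
    ramp[10, 10] <- ramp[10, 10] + 500
    ramp[20:22, 5:7] <- ramp[20:22, 5:7] + 300
    img <- as_image(ramp, NA_integer_)
    sub <- subtract_background(img, 3, shape == "paraboloid")
    ref <- ramp - oracle_opening(ramp, 3, shape)
    expect_equal(unclass(sub), ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(sub <= ramp + 1e-12))
  }
})

test_that("background subtraction: constant image, isolated peak, pointwise bound", {
  const <- as_image(matrix(50, 20, 20), 16L)
  expect_true(all(subtract_background(const, 3) == 0))

  spike <- matrix(0, 21, 21); spike[11, 11] <- 800
  out <- subtract_background(as_image(spike, NA_integer_), 3)
  # structure smaller than the element is preserved almost entirely
  expect_gt(out[11, 11], 0.95 * 800)

  set.seed(11)
  noisy <- as_image(matrix(runif(900, 0, 100), 30, 30), NA_integer_)
  out <- subtract_background(noisy, 3)
  expect_true(all(out <= unclass(noisy) + 1e-12))
  expect_error(subtract_background(noisy, 0.5), "radius")
})

test_that("ball-variant background envelope is idempotent on its own output", {
  set.seed(2)
  img <- outer(seq(0, 30, length.out = 32), seq(0, 15, length.out = 32), `+`) +
    matrix(runif(1024, 0, 40), 32, 32)
  bg <- gray_opening(img, 3, "ball")
  bg2 <- gray_opening(bg, 3, "ball")
  expect_equal(bg2, bg, tolerance = 1e-9)
})

test_that("gaussian blur matches a direct 2-D kernel convolution and preserves mass", {
  set.seed(5)
  img <- matrix(runif(289, 0, 1000), 17, 17)
  expect_equal(unclass(gaussian_blur(as_image(img, NA_integer_), 1)),
               oracle_gaussian(img, 1), tolerance = 1e-10, ignore_attr = TRUE)

  # unit impulse at the center: central value equals the kernel's central weight
  imp <- matrix(0, 17, 17); imp[9, 9] <- 1
  k <- oracle_gaussian(imp, 1)
  expect_equal(gaussian_blur(as_image(imp, NA_integer_), 1)[9, 9], k[9, 9],
               tolerance = 1e-12)

  const <- as_image(matrix(3.5, 10, 12), NA_integer_)
  expect_equal(unclass(gaussian_blur(const, 2)), matrix(3.5, 10, 12),
               tolerance = 1e-12, ignore_attr = TRUE)

  # constant-border image: reflective padding preserves the total exactly
  pad <- matrix(10, 24, 24)
  pad[8:16, 8:16] <- pad[8:16, 8:16] + matrix(runif(81, 0, 500), 9, 9)
  out <- gaussian_blur(as_image(pad, NA_integer_), 1)
  expect_lt(abs(sum(out) - sum(pad)) / sum(pad), 1e-6)
  expect_error(gaussian_blur(const, 0), "sigma")
})

test_that("erosion matches the neighbor-count sweep oracle and is anti-extensive", {
  # canonical shapes
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_false(any(erode(one, 1)))

  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  er <- erode(sq, 1)
  expect_equal(which(er), which(matrix(FALSE, 9, 9) | {
    m <- matrix(FALSE, 9, 9); m[4:6, 4:6] <- TRUE; m
  }))

  set.seed(21)
  for (i in 1:10) {
    m <- random_mask(16, 16, runif(1, 0.3, 0.8))
    e1 <- erode(m, 1)
    expect_identical(e1, oracle_erode(m))
    expect_true(all(which(e1) %in% which(m)))            # result subset of input
    expect_identical(erode(e1, 1), erode(m, 2))          # iteration composition
    expect_lte(sum(erode(m, 2)), sum(e1))                # decreasing in iterations
  }
})

test_that("component labeling and size filtering match the flood-fill oracle", {
  # connectivity distinguishes a diagonal pair
  dg <- matrix(FALSE, 4, 4); dg[2, 2] <- TRUE; dg[3, 3] <- TRUE
  expect_equal(label_and_filter(dg, min_area = 2, connectivity = 8)$n, 1L)
  expect_equal(label_and_filter(dg, min_area = 2, connectivity = 4)$n, 0L)
  expect_equal(label_and_filter(dg, min_area = 0, connectivity = 4)$n, 2L)

  expect_equal(label_and_filter(matrix(FALSE, 6, 6))$n, 0L)

  set.seed(31)
  for (i in 1:50) {
    m <- random_mask(24, 24, runif(1, 0.15, 0.5))
    conn <- sample(c(4L, 8L), 1)
    comps <- oracle_components(m, conn)
    lab <- label_and_filter(m, min_area = 0, connectivity = conn)
    expect_equal(lab$n, length(comps))
    expect_equal(sort(lab$areas), sort(vapply(comps, nrow, integer(1))))
    expect_equal(sum(lab$areas), sum(m))                 # areas partition foreground
    # labels are contiguous 1..K
    expect_setequal(setdiff(unique(as.vector(lab$labels)), 0L), seq_len(lab$n))
    # "smaller than N is removed": area >= N survives
    if (lab$n > 0) {
      amin <- min(lab$areas)
      kept <- label_and_filter(m, min_area = amin, connectivity = conn)
      expect_equal(kept$n, sum(lab$areas >= amin))
      # component count non-increasing in min_area
      expect_lte(label_and_filter(m, min_area = amin + 3, connectivity = conn)$n,
                 kept$n)
    }
  }
})

test_that("binarize uses the strictly-greater convention on both scales", {
  img <- as_image(matrix(0:255, 16, 16), 8L)
  expect_false(any(binarize(img, 255)))
  expect_true(all(binarize(img, -1)))
  h <- histogram256(img)
  t <- 100L
  expect_equal(sum(binarize(img, t, h)), sum(h$counts[(t + 2):256]))
})

test_that("histogram256 maps 16-bit and float images by min-max rescale", {
  set.seed(3)
  img <- as_image(matrix(runif(400, 500, 9000), 20, 20), 16L)
  h <- histogram256(img)
  expect_equal(sum(h$counts), 400)
  expect_true(h$counts[1] > 0 && h$counts[256] > 0)   # extremes hit the end bins
  bi <- bin_indices(img, h)
  expect_true(all(bi >= 0 & bi <= 255))
  expect_equal(tabulate(bi + 1L, 256L), h$counts)
  # degenerate: constant image
  expect_error(threshold_triangle(histogram256(as_image(matrix(5, 4, 4), 16L))),
               class = "degenerate_histogram")
})
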