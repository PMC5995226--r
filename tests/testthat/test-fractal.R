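test_that("similarity dimension evaluates the defining formula", {
  expect_equal(similarity_dimension(2, 1 / 2), 1)
  expect_equal(similarity_dimension(4, 1 / 3), log(4) / log(3))
  expect_equal(similarity_dimension(3, 1 / 2), log(3) / log(2))
  expect_equal(similarity_dimension(4, 1 / 2), 2)
  expect_error(similarity_dimension(4, 1.2), "between 0 and 1")
  expect_error(similarity_dimension(0, 0.5), "positive integer")
})

test_that("box counting recovers Euclidean controls and classic fractal dimensions", {
  sq <- box_count(generate_fixture("filled_square", size = 256))
  expect_equal(sq$dimension, 2, tolerance = 0.01)
  ln <- box_count(generate_fixture("line", size = 256))
  expect_equal(ln$dimension, 1, tolerance = 0.01)

  sp <- box_count(generate_fixture("sierpinski", depth = 7), box_sizes = 2^(0:5))
  expect_equal(sp$dimension, log(3) / log(2), tolerance = 1e-10)
  expect_gt(sp$r_squared, 0.999)

  ko <- box_count(generate_fixture("koch", depth = 6), box_sizes = 3^(0:4))
  expect_lt(abs(ko$dimension - log(4) / log(3)), 0.05)

  expect_error(box_count(matrix(0, 10, 10)), "foreground")
  expect_error(box_count(matrix(1, 4, 4), box_sizes = c(1, 2)), "3 distinct box sizes")
})

test_that("box counts are monotone in box size and under set union", {
  img <- generate_fixture("sierpinski", depth = 6)
  bc <- box_count(img, box_sizes = 2^(0:4))
  expect_true(all(diff(bc$counts$N) <= 0)) # larger boxes, never more of them
  # union with a disjoint blob can only add boxes at every size
  img2 <- img
  img2[50:60, 50:60] <- 1L
  bc2 <- box_count(img2, box_sizes = 2^(0:4))
  expect_true(all(bc2$counts$N >= bc$counts$N))
  expect_true(all(bc$dimension >= 0, bc$dimension <= 2 + 0.05))
})

test_that("estimated dimension of generated fixtures converges with depth", {
  err <- vapply(4:7, function(d) {
    bc <- box_count(generate_fixture("koch", depth = d), box_sizes = 3^(0:(d - 2)))
    abs(bc$dimension - log(4) / log(3))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[4], 0.05)
  serr <- vapply(4:7, function(d) {
    bc <- box_count(generate_fixture("sierpinski", depth = d), box_sizes = 2^(0:(d - 2)))
    abs(bc$dimension - log(3) / log(2))
  }, numeric(1))
  expect_true(all(serr < 1e-9)) # exactly self-similar under dyadic boxes
})

test_that("Holder exponents: constant images, a point mass, and scaling invariance", {
  const <- matrix(1, 32, 32)
  a_sum <- holder_alpha(const, measure = "sum")
  expect_equal(range(a_sum$alpha), c(2, 2)) # mu ~ eps^2 everywhere
  a_max <- holder_alpha(const, measure = "max")
  expect_equal(range(a_max$alpha), c(0, 0)) # mu constant in eps
  a_min <- holder_alpha(const, measure = "min")
  expect_equal(range(a_min$alpha), c(0, 0))

  point <- matrix(0, 33, 33); point[17, 17] <- 1
  ap <- holder_alpha(point, measure = "sum")
  expect_equal(ap$alpha[17, 17], 0) # window sum constant around the spike

  set.seed(8)
  tex <- generate_fixture("blob_texture", size = 64, seed = 8)
  a1 <- holder_alpha(tex, measure = "sum", quantum = 1e-6)
  a2 <- holder_alpha(tex * 7.3, measure = "sum", quantum = 7.3e-6)
  expect_equal(a1$alpha, a2$alpha, tolerance = 1e-10) # slope unchanged by scaling

  expect_error(holder_alpha(const, radii = 3), "at least 2")
  expect_error(holder_alpha(const, radii = c(2, 4)), "odd")
  expect_error(holder_alpha(matrix(-1, 4, 4)), "nonnegative")
})

test_that("the multifractal spectrum degenerates correctly and respects the alpha range", {
  ai <- holder_alpha(matrix(1, 64, 64), measure = "sum")
  sp <- multifractal_spectrum(ai, n_bins = 10)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$alpha, 2)
  expect_equal(sp$f_alpha, 2, tolerance = 0.05)

  tex <- generate_fixture("blob_texture", size = 128, seed = 4)
  at <- holder_alpha(tex, measure = "sum")
  spt <- multifractal_spectrum(at, n_bins = 12)
  expect_true(all(spt$alpha >= at$alpha_min & spt$alpha <= at$alpha_max))
  expect_true(all(spt$f_alpha <= 2 + 0.05))
  expect_error(multifractal_spectrum(at, n_bins = 1), "at least 2")
})

test_that("the spectrum peak of a binary self-similar pattern approaches the support dimension", {
  s <- generate_fixture("sierpinski", depth = 9)
  ai <- holder_alpha(s, measure = "sum")
  sp <- multifractal_spectrum(ai, n_bins = 3)
  support_dim <- box_count(s, box_sizes = 2^(0:7))$dimension
  expect_lt(abs(max(sp$f_alpha) - support_dim), 0.1)
})

test_that("fixture generators honor their construction counts", {
  s0 <- generate_fixture("sierpinski", depth = 0)
  expect_equal(dim(s0), c(1, 1)); expect_equal(s0[1, 1], 1L)
  for (d in 2:5)
    expect_equal(attr(generate_fixture("koch", depth = d), "n_segments"), 4^d)
  tree <- generate_fixture("fractal_tree", depth = 10, size = 256)
  expect_equal(attr(tree, "n_segments"), 2^11 - 1)
  expect_gt(sum(tree), 100) # the raster is a real image, not just a count
  expect_error(generate_fixture("menger"), "unknown fixture kind")
  # blob texture is deterministic under its seed
  expect_identical(generate_fixture("blob_texture", size = 32, seed = 5),
                   generate_fixture("blob_texture", size = 32, seed = 5))
})

test_that("images round-trip through PNG and TIFF", {
  img <- generate_fixture("blob_texture", size = 48, seed = 2)
  for (ext in c(".png", ".tiff")) {
    path <- withr::local_tempfile(fileext = ext)
    write_image(img, path)
    back <- read_image(path)
    expect_equal(dim(back), dim(img))
    expect_lt(max(abs(back - img)), 1 / 255) # 8/16-bit quantization only
  }
})
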