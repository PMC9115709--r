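test_that("analytic shapes reproduce hand-evaluated circularity and sphericity", {
  circle <- shape_metrics(tibble::tibble(area = pi, perimeter = 2 * pi))
  expect_equal(circle$circularity, 1)
  expect_equal(circle$sphericity_index, 1)
  expect_equal(circle$equivalent_diameter, 2)

  square <- shape_metrics(tibble::tibble(area = 1, perimeter = 4))
  expect_equal(square$circularity, pi / 4)
  expect_equal(square$sphericity_index, sqrt(pi / 4), tolerance = 1e-12)

  # dimensionless metrics are scale invariant
  s <- 7.3
  scaled <- shape_metrics(tibble::tibble(area = s^2, perimeter = 4 * s))
  expect_equal(scaled$circularity, square$circularity)
  expect_equal(scaled$sphericity_index, square$sphericity_index)
  expect_equal(scaled$equivalent_diameter, s * square$equivalent_diameter)

  expect_spq_error(shape_metrics(tibble::tibble(area = -1, perimeter = 4)), "validation")
  expect_warning(shape_metrics(tibble::tibble(area = 10, perimeter = 1)),
                 class = "spq_warning_circularity")
})

test_that("sphericity index is the square root of circularity", {
  withr::local_seed(40)
  tbl <- tibble::tibble(area = runif(20, 1, 100), perimeter = runif(20, 10, 60))
  m <- suppressWarnings(shape_metrics(tbl))
  expect_equal(m$sphericity_index, sqrt(m$circularity), tolerance = 1e-12)
})

test_that("a digitized disk measures within 2% of the analytic circle values", {
  disk <- simulate_spheroid_mask("disk", radius = 100)
  m <- shape_from_mask(disk$mask, pixel_size = 2)
  expect_equal(m$sphericity_index, 1, tolerance = 0.02)
  expect_equal(m$circularity, 1, tolerance = 0.04)
  expect_equal(m$area, pi * 100^2 * 4, tolerance = 0.02)
  expect_equal(m$perimeter, 2 * pi * 100 * 2, tolerance = 0.02)
  expect_equal(m$roundness, 1, tolerance = 0.02)
})

test_that("a 2:1 ellipse mask matches the Ramanujan-perimeter oracle within 2%", {
  ell <- simulate_spheroid_mask("ellipse", radius = 100, axis_ratio = 0.5)
  m <- shape_from_mask(ell$mask)
  expect_equal(m$sphericity_index, ell$truth$sphericity_index, tolerance = 0.02)
  expect_equal(m$area, ell$truth$area, tolerance = 0.02)
  expect_equal(m$perimeter, ell$truth$perimeter, tolerance = 0.02)
  expect_equal(m$roundness, 0.5, tolerance = 0.03)
})

test_that("mask-derived and measurement-derived paths agree on the mask's own measurements", {
  ell <- simulate_spheroid_mask("ellipse", radius = 60, axis_ratio = 0.7)
  m <- shape_from_mask(ell$mask)
  direct <- shape_metrics(tibble::tibble(area = m$area, perimeter = m$perimeter))
  expect_equal(m$circularity, direct$circularity, tolerance = 1e-12)
  expect_equal(m$sphericity_index, direct$sphericity_index, tolerance = 1e-12)
})

test_that("empty masks error and multi-component masks keep the largest object", {
  expect_spq_error(shape_from_mask(matrix(FALSE, 20, 20)), "no_object")

  disk <- simulate_spheroid_mask("disk", radius = 30)$mask
  mask <- matrix(FALSE, nrow(disk) + 10, ncol(disk) + 10)
  mask[1:nrow(disk), 1:ncol(disk)] <- disk
  mask[nrow(mask) - 2, ncol(mask) - 2] <- TRUE  # a stray speck
  expect_message(m <- shape_from_mask(mask), "2 components")
  expect_equal(m$n_components, 2)
  expect_equal(m$area, sum(disk), tolerance = 1e-12)
})

test_that("SI decreases strictly along increasingly eccentric ellipses of fixed area", {
  ratios <- c(1, 0.8, 0.6, 0.4, 0.2)
  si <- vapply(ratios, function(q) {
    # fixed area: a = r / sqrt(q), b = r * sqrt(q)
    a <- 50 / sqrt(q)
    truth <- simulate_spheroid_mask("ellipse", radius = a, axis_ratio = q)$truth
    truth$sphericity_index
  }, numeric(1))
  expect_true(all(diff(si) < 0))
  expect_true(all(si <= 1 + 1e-12))
})

test_that("masks round-trip through PNG and TIFF readers", {
  disk <- simulate_spheroid_mask("disk", radius = 20)$mask
  p1 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(disk * 1, p1)
  expect_equal(read_mask(p1), disk)
  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(disk * 1, p2)
  expect_equal(read_mask(p2), disk)
})

test_that("group summaries report mean, SE and n per metric, order-invariantly", {
  shapes <- shape_metrics(tibble::tibble(
    spheroid_id = c("a", "b"),
    area = c(0.8^2 * pi / 4, pi / 4) * 100,  # engineered SI 0.8 and 1.0
    perimeter = c(pi, pi) * 10
  ))
  expect_equal(sort(shapes$sphericity_index), c(0.8, 1.0), tolerance = 1e-12)
  s <- summarize_shapes(shapes)
  si <- s[s$metric == "sphericity_index", ]
  expect_equal(si$mean, 0.9)
  expect_equal(si$se, 0.1)
  expect_equal(si$n, 2)

  # forty identical shapes: zero standard error
  many <- shapes[rep(1, 40), ]
  s40 <- summarize_shapes(many)
  expect_true(all(s40$se == 0))
  expect_true(all(s40$n == 40))

  # permutation invariance
  s_rev <- summarize_shapes(shapes[2:1, ])
  expect_equal(as.data.frame(s_rev), as.data.frame(s))

  expect_spq_error(summarize_shapes(shapes[0, ]), "insufficient_data")
})
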