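test_that("PGM round-trip preserves pixels and sidecar spacing", {
  set.seed(42)
  px <- matrix(sample.int(4096, 64) - 1, 8, 8)
  img <- gray_image(px, 0.78125)
  path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, path)
  back <- read_image(path)
  expect_equal(back$pixels, px)
  expect_equal(back$spacing_row, 0.78125)
  expect_equal(back$spacing_col, 0.78125)
})

test_that("reading an image without any spacing is a hard error", {
  path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(matrix(1:16, 4, 4), path)   # bare matrix: no sidecar written
  expect_error(read_image(path), "spacing unavailable")
  expect_silent(img <- read_image(path, spacing = 0.5))
  expect_equal(img$spacing_row, 0.5)
})

test_that("gray_image validates its invariants", {
  expect_error(gray_image(matrix(1, 1, 5), 1), "2 x 2")
  expect_error(gray_image(matrix(c(1, NA, 3, 4), 2, 2), 1), "finite")
  expect_error(gray_image(matrix(1:4, 2, 2), 0), "spacing")
})

test_that("resampling a 512 grid over a 200 mm field hits the default spacing", {
  expect_equal(200 / 512, 0.390625)
  set.seed(7)
  img <- gray_image(matrix(rnorm(64 * 64), 64, 64), spacing_row = 200 / 512)
  out <- resample_to_spacing(img, 0.390625)
  expect_identical(out$pixels, img$pixels)  # already at target: bit-identical
  expect_equal(out$spacing_row, 0.390625)
})

test_that("upsampled ramp matches direct bilinear evaluation", {
  px <- matrix(c(0, 0, 2, 2), 2, 2)  # [[0,2],[0,2]] row-major
  img <- gray_image(px, spacing_row = 1)
  out <- resample_to_spacing(img, 0.5)
  expect_equal(dim(out$pixels), c(4L, 4L))
  for (r in 1:4) {
    for (c in 1:4) {
      yy <- (r - 0.5) * 0.5 - 0.5
      xx <- (c - 0.5) * 0.5 - 0.5
      expect_equal(out$pixels[r, c], bilinear_point(px, yy, xx))
    }
  }
})

test_that("resampling preserves physical extent and is idempotent at target", {
  set.seed(11)
  img <- gray_image(matrix(rnorm(40 * 30), 40, 30), spacing_row = 0.7,
                    spacing_col = 1.1)
  out <- resample_to_spacing(img, 0.4)
  expect_lt(abs(nrow(out$pixels) * 0.4 - 40 * 0.7), 0.4)
  expect_lt(abs(ncol(out$pixels) * 0.4 - 30 * 1.1), 0.4)
  again <- resample_to_spacing(out, 0.4)
  expect_equal(again$pixels, out$pixels, tolerance = 1e-12)
})

test_that("axis-aligned rectangle rasterizes to exactly the covered centers", {
  # rectangle strictly containing pixel centers x in 2..5, y in 3..7
  poly <- roi_polygon(rbind(c(1.5, 2.5), c(5.5, 2.5), c(5.5, 7.5),
                            c(1.5, 7.5)))
  mask <- rasterize_roi(poly, c(12, 12))
  expect_equal(sum(mask), 20)
  expect_true(all(mask[(3:7) + 1, (2:5) + 1]))
})

test_that("triangle mask equals the exhaustive point-in-polygon oracle", {
  poly <- roi_polygon(rbind(c(1.2, 0.8), c(10.7, 2.3), c(4.4, 11.6)))
  mask <- rasterize_roi(poly, c(14, 14))
  oracle <- matrix(FALSE, 14, 14)
  for (r in 1:14) {
    for (c in 1:14) {
      oracle[r, c] <- pip_point(poly$vertices, c - 1, r - 1)
    }
  }
  expect_equal(unclass(mask), oracle, ignore_attr = TRUE)
})

test_that("rasterization is invariant to vertex-list rotation", {
  set.seed(3)
  th <- sort(runif(9, 0, 2 * pi))
  v <- cbind(8 + 6 * cos(th), 8 + 6 * sin(th))
  m1 <- rasterize_roi(roi_polygon(v), c(17, 17))
  for (shift in c(2, 5)) {
    vr <- v[c(shift:9, 1:(shift - 1)), ]
    expect_equal(rasterize_roi(roi_polygon(vr), c(17, 17)), m1)
  }
})

test_that("degenerate and too-small polygons are rejected", {
  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(roi_polygon(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))),
               "self-intersecting")
  tiny <- roi_polygon(rbind(c(0.4, 0.4), c(1.6, 0.4), c(1.6, 1.6),
                            c(0.4, 1.6)))
  expect_error(rasterize_roi(tiny, c(8, 8)), "ROI too small")
})

test_that("quantization follows level(v) = clamp(1 + floor((v - lo)/(hi - lo) Ng))", {
  set.seed(5)
  vals <- rnorm(25, 100, 10)
  vals[1] <- 160  # guarantee a beyond-window value on each side
  vals[2] <- 40
  mu <- mean(vals); sg <- sd(vals)
  img <- gray_image(matrix(vals, 5, 5), 1)
  mask <- matrix(TRUE, 5, 5)
  q <- normalize_and_quantize(img, mask, bits = 6)
  lo <- mu - 3 * sg; hi <- mu + 3 * sg
  expected <- pmin(pmax(1 + floor((vals - lo) / (hi - lo) * 64), 1), 64)
  expected[vals >= hi] <- 64
  expect_equal(as.vector(q$levels), as.numeric(expected))
  expect_equal(q$window$mu, mu)
  expect_equal(q$window$sigma, sg)
})

test_that("stated window mapping: mu 100 sd 10 sends 70/100/130 to 1/33/64", {
  lo <- 70; hi <- 130
  level <- function(v) pmin(pmax(1 + floor((v - lo) / (hi - lo) * 64), 1), 64)
  expect_equal(level(70), 1)
  expect_equal(level(100), 33)
  expect_equal(min(level(130), 64), 64)
  expect_equal(level(50), 1)    # below window clips to 1
})

test_that("constant ROI quantizes to all-ones with a warning", {
  img <- gray_image(matrix(5, 6, 6), 1)
  mask <- matrix(TRUE, 6, 6)
  expect_warning(q <- normalize_and_quantize(img, mask, 6), "degenerate")
  expect_true(all(q$levels == 1))
})

test_that("quantization is monotone and affine-equivariant", {
  set.seed(21)
  for (rep in 1:5) {
    vals <- rnorm(49, 100, 25)
    img <- gray_image(matrix(vals, 7, 7), 1)
    mask <- matrix(TRUE, 7, 7)
    q <- normalize_and_quantize(img, mask, 6)
    ord <- order(vals)
    expect_true(all(diff(q$levels[ord]) >= 0))
    img2 <- gray_image(matrix(3.7 * vals + 250, 7, 7), 1)
    q2 <- normalize_and_quantize(img2, mask, 6)
    expect_equal(q2$levels, q$levels)
  }
})
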