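test_that("histogram statistics match hand computations on degenerate and two-point histograms", {
  # constant image: everything collapses to one bin
  hs <- histogram_stats(rep(0.5, 100))
  expect_lt(abs(hs$M - 0.5), 1 / 256)  # within half a bin of the true mean
  expect_identical(hs$SE, 0)
  expect_identical(hs$S, 0)
  expect_identical(hs$MU3, 0)
  expect_identical(hs$U, 1)
  expect_identical(hs$E, 0)

  # half 0 / half 1: both values are exact bin centres at 256 bins
  hs <- histogram_stats(c(rep(0, 50), rep(1, 50)), n_bins = 256L)
  expect_equal(hs$M, 0.5)
  expect_equal(hs$SE, 0.5)
  expect_equal(hs$S, 0.2)
  expect_equal(hs$MU3, 0)
  expect_equal(hs$U, 0.5)
  expect_equal(hs$E, 1)

  expect_error(histogram_stats(numeric(0)), "empty")
  expect_error(histogram_stats(c(0.2, 1.7)), "0, 1")
})

test_that("binned moments agree with a brute-force pixel loop within one bin width", {
  set.seed(41)
  for (i in 1:5) {
    v <- runif(500)
    hs <- histogram_stats(v, n_bins = 256L)
    expect_lt(abs(hs$M - mean(v)), 1 / 256)
    expect_lt(abs(hs$SE - sqrt(mean((v - mean(v))^2))), 1 / 256)
  }
})

test_that("morphology of a full square and a single pixel is enumerable by hand", {
  mo <- morphology_traits(square_mask(10, 10, 10))
  expect_identical(mo$TPA, 100L)
  expect_identical(mo$H, 10L)
  expect_identical(mo$W, 10L)
  expect_equal(mo$CBA, 100)
  expect_equal(mo$TBR, 1)
  expect_equal(mo$THR, 1)
  expect_identical(mo$P, 36L)
  expect_equal(mo$PAR, 0.36)

  mo <- morphology_traits(square_mask(5, 1, 1, 3, 3))
  expect_identical(mo$TPA, 1L)
  expect_equal(mo$CBA, 1)
  expect_equal(mo$TBR, 1)
  expect_equal(mo$THR, 1)
  expect_identical(mo$P, 1L)
  expect_equal(mo$PAR, 1)

  expect_error(morphology_traits(matrix(0L, 4, 4)), "empty")
})

test_that("box-counting dimension recovers 2 for a filled square and 1 for a line", {
  expect_equal(fractal_dimension(square_mask(64, 64, 64)), 2, tolerance = 0.1)
  ln <- matrix(0L, 8, 64); ln[4, ] <- 1L
  expect_equal(fractal_dimension(ln), 1, tolerance = 0.1)
  expect_identical(fractal_dimension(square_mask(9, 1, 1, 5, 5)), 0)
  expect_error(fractal_dimension(matrix(0L, 3, 3)), "empty")
})

test_that("colour areas follow the hue windows and saturation floor", {
  m <- square_mask(10, 10, 10)
  green <- flat_rgb(10, 10, 0, 1, 0)          # hue 120
  ct <- color_traits(green, m)
  expect_identical(ct$GPA, 100L)
  expect_identical(ct$YPA, 0L)
  expect_equal(ct$YTR, 100)

  # 50 yellow pixels (hue 45) + 50 green
  half <- hsv_image(m, 45)
  half[, 6:10, ] <- hsv_image(m, 120)[, 6:10, ]
  ct <- color_traits(half, m)
  expect_identical(ct$GPA, 50L)
  expect_identical(ct$YPA, 50L)
  expect_equal(ct$YTR, 2)

  # dark gray foreground: below the saturation floor, counts as neither
  dark <- flat_rgb(10, 10, 0.5, 0.5, 0.5)
  ct <- color_traits(dark, m)
  expect_identical(ct$GPA, 0L)
  expect_identical(ct$YPA, 0L)
  expect_equal(ct$YTR, 100)

  expect_error(color_traits(green, square_mask(9, 9, 9)), "dimensions")
  expect_error(color_traits(green, matrix(0L, 10, 10)), "empty")
})

test_that("the trait vector has 18 entries, 16 active without yellow, and is deterministic", {
  r <- render_plant(plant_params(seed = 5))
  full <- trait_schema("full")
  tv <- extract_traits(r$rgb, r$mask, full)
  expect_length(tv, 18L)
  expect_identical(names(tv), full$ordered_names)
  expect_length(trait_schema("no-yellow")$active, 16L)
  expect_identical(tv, extract_traits(r$rgb, r$mask, full))
})

test_that("exact identities and order relations hold across random plants", {
  set.seed(11)
  for (s in 1:8) {
    r <- render_plant(plant_params(seed = 1000 + s,
                                   n_branches = sample(0:8, 1),
                                   stroke_width = sample(1:3, 1)))
    tv <- extract_traits(r$rgb, r$mask)
    expect_identical(tv[["CBA"]], tv[["H"]] * tv[["W"]])
    expect_equal(tv[["TBR"]] * tv[["CBA"]], tv[["TPA"]])
    expect_gte(tv[["THR"]] + 1e-12, tv[["TBR"]])   # hull is inside the box
    expect_gte(tv[["TPA"]], tv[["GPA"]])
    expect_gte(tv[["TPA"]], tv[["YPA"]])
    expect_gt(tv[["U"]], 0); expect_lte(tv[["U"]], 1)
    expect_gte(tv[["E"]], 0)
    expect_gte(tv[["S"]], 0); expect_lt(tv[["S"]], 1)
    expect_gte(tv[["FDIC"]], 0.8); expect_lte(tv[["FDIC"]], 2.2)
  }
})

test_that("traits are invariant to translation and scale area as expected under 2x upscaling", {
  r <- render_plant(plant_params(seed = 77, canvas = 48))
  pad <- function(rgb, mask, off_r, off_c, side) {
    a <- array(0, dim = c(side, side, 3)); m <- matrix(0L, side, side)
    a[off_r + seq_len(nrow(mask)), off_c + seq_len(ncol(mask)), ] <- rgb
    m[off_r + seq_len(nrow(mask)), off_c + seq_len(ncol(mask))] <- mask
    list(rgb = a, mask = m)
  }
  a <- pad(r$rgb, r$mask, 3, 9, 72)
  b <- pad(r$rgb, r$mask, 15, 0, 72)
  expect_equal(extract_traits(a$rgb, a$mask), extract_traits(b$rgb, b$mask))

  up <- function(x) x[rep(seq_len(nrow(x)), each = 2), rep(seq_len(ncol(x)), each = 2)]
  rgb2 <- array(0, dim = c(96, 96, 3))
  for (ch in 1:3) rgb2[, , ch] <- up(r$rgb[, , ch])
  t1 <- extract_traits(r$rgb, r$mask)
  t2 <- extract_traits(rgb2, up(r$mask))
  expect_equal(t2[["TPA"]], 4 * t1[["TPA"]])
  expect_equal(t2[["TBR"]], t1[["TBR"]], tolerance = 1e-9)
})
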