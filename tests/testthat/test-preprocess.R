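test_that("centring places the bounding box at the floor offsets with content intact", {
  rgb <- array(runif(3 * 5 * 3), dim = c(3, 5, 3))
  mask <- matrix(1L, 3, 5)
  out <- center_on_canvas(rgb, mask, 7)
  expect_identical(dim(out$mask), c(7L, 7L))
  # 0-based offsets floor((7-3)/2) = 2 and floor((7-5)/2) = 1
  expect_identical(which(rowSums(out$mask) > 0), 3:5)
  expect_identical(which(colSums(out$mask) > 0), 2:6)
  expect_identical(out$rgb[3:5, 2:6, ], rgb)

  exact <- center_on_canvas(rgb, mask, 5)
  expect_identical(dim(exact$mask), c(5L, 5L))
  expect_identical(exact$rgb[2:4, 1:5, ], rgb)  # offsets (1, 0)

  # bbox exactly M x M: offsets (0, 0), content unchanged
  sq <- center_on_canvas(rgb[, 1:3, , drop = FALSE], mask[, 1:3], 3)
  expect_identical(sq$rgb, rgb[, 1:3, , drop = FALSE])

  expect_error(center_on_canvas(rgb, mask, 4), "width")
})

test_that("centring leaves the traits of the silhouette unchanged", {
  r <- render_plant(plant_params(seed = 9, canvas = 40))
  cen <- center_on_canvas(r$rgb, r$mask, 64)
  t0 <- extract_traits(r$rgb, r$mask)
  t1 <- extract_traits(cen$rgb, cen$mask)
  for (tr in c("TPA", "P", "GPA", "YPA", "H", "W", "CBA"))
    expect_identical(t1[[tr]], t0[[tr]])
})

test_that("dataset build splits deterministically and fits the normalizer on train only", {
  recs <- synth_dataset(10, seed = 21)
  man <- build_dataset(recs, target_resolution = 64, test_fraction = 0.2,
                       seed = 7)
  sp <- phenopaint:::manifest_split(man)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  man2 <- build_dataset(recs, target_resolution = 64, test_fraction = 0.2,
                        seed = 7)
  expect_identical(phenopaint:::manifest_split(man2), sp)
  man3 <- build_dataset(recs, target_resolution = 64, test_fraction = 0.2,
                        seed = 8)
  expect_false(identical(phenopaint:::manifest_split(man3)$test, sp$test))

  expect_true(all(vapply(man$records,
                         function(r) all(dim(r$mask) == c(64L, 64L)),
                         logical(1))))

  # normalized training matrix hits 0 and 1 exactly per varying trait
  tr <- phenopaint:::manifest_traits(man, sp$train)
  z <- normalize_traits(tr, man$normalizer)
  rng <- man$normalizer$max - man$normalizer$min
  expect_equal(unname(apply(z[, rng > 0], 2, min)), rep(0, sum(rng > 0)))
  expect_equal(unname(apply(z[, rng > 0], 2, max)), rep(1, sum(rng > 0)))
})

test_that("identical images give a degenerate normalizer and empty masks are rejected", {
  r <- render_plant(plant_params(seed = 4))
  recs <- lapply(1:4, function(i)
    list(image_id = paste0("dup", i), rgb = r$rgb, mask = r$mask))
  man <- build_dataset(recs, target_resolution = 64, test_fraction = 0.25)
  expect_true(all(man$normalizer$max == man$normalizer$min))
  z <- normalize_traits(man$normalizer$max, man$normalizer)
  expect_true(all(z == 0))

  bad <- recs
  bad[[2]]$mask <- matrix(0L, 64, 64)
  expect_error(build_dataset(bad, target_resolution = 64), "dup2")
})

test_that("min-max normalization clamps, inverts, and maps extremes to 0/1", {
  set.seed(5)
  m <- matrix(runif(60, 1, 100), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  st <- fit_normalizer(m)
  z <- normalize_traits(m, st)
  expect_equal(unname(apply(z, 2, min)), c(0, 0, 0))
  expect_equal(unname(apply(z, 2, max)), c(1, 1, 1))
  back <- denormalize_traits(z, st)
  expect_equal(unname(back), unname(m), tolerance = 1e-9)
  out_of_range <- normalize_traits(st$max + 10, st)
  expect_true(all(out_of_range == 1))
})

test_that("a manifest survives a write/read round trip", {
  dir <- withr::local_tempdir()
  write_manifest(tiny_manifest, dir)
  back <- read_manifest(dir)
  expect_identical(length(back$records), length(tiny_manifest$records))
  expect_identical(back$canvas_M, tiny_manifest$canvas_M)
  expect_equal(back$normalizer$min, tiny_manifest$normalizer$min)
  expect_identical(vapply(back$records, `[[`, "", "split"),
                   vapply(tiny_manifest$records, `[[`, "", "split"))
  # stored traits match the PNG-round-tripped images they describe
  i <- 1L
  expect_equal(unname(back$records[[i]]$traits),
               unname(tiny_manifest$records[[i]]$traits), tolerance = 1e-6)
  expect_identical(back$records[[i]]$mask, tiny_manifest$records[[i]]$mask)
})
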