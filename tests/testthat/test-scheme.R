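test_that("loop scheme presets have the documented point structure", {
  bil <- loop_scheme("bilateral")
  tra <- loop_scheme("trabecular")
  sha <- loop_scheme("shared")
  expect_length(bil$fixed_names, 20L)
  expect_length(tra$fixed_names, 15L)
  expect_equal(n_points(bil), 41L)   # 20 fixed + 21 semilandmarks
  expect_equal(n_points(tra), 36L)
  expect_equal(n_points(sha), 36L)
  expect_equal(sum(vapply(bil$curves, `[[`, 0L, "n_semilandmarks")), 21L)
  # shared fixed landmarks are a strict subset of the bilateral set
  expect_true(all(tra$fixed_names %in% bil$fixed_names))
  # point indices are contiguous and cover the tail of the configuration
  idx <- unlist(lapply(bil$curves, `[[`, "point_indices"))
  expect_equal(idx, 21:41)
  expect_length(point_names(bil), 41L)
  expect_false(anyDuplicated(point_names(bil)) > 0)
})

test_that("scheme construction rejects invalid definitions", {
  expect_error(landmark_scheme(c("a", "a", "b")), "unique")
  expect_error(landmark_scheme(character(0)), "non-empty")
  expect_error(curve_spec("c1", 1L), ">= 2")
  expect_error(
    landmark_scheme("a", list(curve_spec("c1", 3L, anchor_start = "missing"))),
    "anchor")
})

test_that("slider tables encode curve neighbours with anchored endpoints", {
  # 5 semilandmarks anchored both ends -> all 5 slide, anchors as neighbours
  sc <- landmark_scheme(c("A", "B"),
                        list(curve_spec("arc", 5L, "A", "B")))
  st <- build_slider_table(sc)
  expect_equal(nrow(st), 5L)
  expect_equal(st$slide, 3:7)
  expect_equal(st$before[1], 1L)  # fixed landmark A
  expect_equal(st$after[5], 2L)   # fixed landmark B
  expect_equal(st$before[2:5], 3:6)
  # each sliding point appears exactly once
  expect_false(anyDuplicated(st$slide) > 0)

  # both loop presets: all 21 semilandmarks slide
  expect_equal(nrow(build_slider_table(loop_scheme("bilateral"))), 21L)
  expect_equal(nrow(build_slider_table(loop_scheme("trabecular"))), 21L)

  # free-ended 2-point curve has no definable sliding direction
  sc2 <- landmark_scheme("A", list(curve_spec("free2", 2L)))
  expect_error(build_slider_table(sc2), "free ends")
  expect_error(build_slider_table(landmark_scheme("A")), "no curves")
})

test_that("schemes round-trip through YAML", {
  sc <- loop_scheme("bilateral")
  path <- withr::local_tempfile(fileext = ".yml")
  write_scheme(sc, path)
  sc2 <- read_scheme(path)
  expect_equal(sc2$fixed_names, sc$fixed_names)
  expect_equal(sc2$loop_type, sc$loop_type)
  expect_equal(lapply(sc2$curves, `[[`, "point_indices"),
               lapply(sc$curves, `[[`, "point_indices"))
})

test_that("shared-landmark subsetting reduces bilateral to the pooled scheme", {
  ds <- simulate_dataset(
    simulation_spec(loop_type = "bilateral", n_per_species = c(3L, 3L)),
    seed = 11L)
  expect_equal(dim(ds$coords)[1], 41L)
  red <- subset_shared_landmarks(ds)
  expect_equal(dim(red$coords)[1], 36L)  # 15 shared fixed + 21 semilandmarks
  expect_length(red$scheme$fixed_names, 15L)
  # kept coordinates are untouched
  expect_identical(red$coords["crural_base", , ], ds$coords["crural_base", , ])
  expect_identical(red$coords["crus_sl3", , ], ds$coords["crus_sl3", , ])

  # identity subset leaves the dataset unchanged
  full <- subset_shared_landmarks(ds, ds$scheme$fixed_names)
  expect_equal(unname(full$coords), unname(ds$coords))

  # commutes with specimen reordering
  ord <- c(4L, 1L, 6L, 2L, 5L, 3L)
  a <- subset_shared_landmarks(ds[ord])
  b <- subset_shared_landmarks(ds)[ord]
  expect_equal(a$coords, b$coords)
  expect_equal(a$species, b$species)

  expect_error(subset_shared_landmarks(ds, character(0)), "non-empty")
  expect_error(subset_shared_landmarks(ds, c("crural_base", "nope")), "nope")
})

test_that("dataset validation rejects malformed input", {
  ds <- tiny_dataset()
  co <- ds$coords
  co[1, 1, 2] <- NaN
  expect_error(shape_dataset(co, ds$scheme), "non-finite.*spec002")
  co2 <- ds$coords
  expect_error(shape_dataset(co2, ds$scheme, ids = rep("x", dim(co2)[3])),
               "duplicate")
  expect_error(shape_dataset(ds$coords[-1, , ], ds$scheme), "scheme defines")
})
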