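test_that("centroid size matches its definition", {
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(centroid_size(square), sqrt(2))

  cfg <- rigid_config(10)
  # brute-force oracle: explicit loop over the definition
  ctr <- colMeans(cfg)
  brute <- 0
  for (i in seq_len(nrow(cfg))) brute <- brute + sum((cfg[i, ] - ctr)^2)
  expect_equal(centroid_size(cfg), sqrt(brute), tolerance = 1e-12)

  expect_equal(centroid_size(cfg * 3), 3 * centroid_size(cfg))
  R <- random_rotation3(1)
  expect_equal(centroid_size(sweep(cfg %*% R, 2, c(5, -2, 1), `+`)),
               centroid_size(cfg), tolerance = 1e-12)
  expect_error(centroid_size(matrix(0, 1, 3)), "2 points")
})

test_that("ordinary Procrustes alignment recovers similarity transforms", {
  cfg <- rigid_config(8)
  fit0 <- opa_align(cfg, cfg)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$scale, 1, tolerance = 1e-10)
  expect_equal(fit0$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(fit0$residual_distance, 0, tolerance = 1e-8)

  target <- sweep(2.5 * cfg %*% rotation_z(pi / 2), 2, c(3, -1, 7), `+`)
  fit <- opa_align(cfg, target)
  expect_equal(fit$residual_distance, 0, tolerance = 1e-8)
  expect_equal(fit$aligned, target, tolerance = 1e-8)

  expect_error(opa_align(cfg, cfg[-1, ]), "identical dimensions")
})

test_that("OPA rotation matches an exhaustive planar grid search", {
  # planar pair so the optimal rotation is about z and a 0.1-degree 1-D
  # sweep is an exhaustive oracle
  set.seed(21)
  src <- cbind(matrix(rnorm(8), 4), 0)
  tgt <- cbind(matrix(rnorm(8), 4), 0)
  src <- scale(src, scale = FALSE); tgt <- scale(tgt, scale = FALSE)
  thetas <- seq(0, 2 * pi, by = pi / 1800)  # 0.1 degree steps
  grid_best <- min(vapply(thetas, function(th)
    sqrt(sum((src %*% rotation_z(th) - tgt)^2)), 0))
  fit <- opa_align(src, tgt, allow_scaling = FALSE)
  expect_equal(fit$residual_distance, grid_best, tolerance = 1e-3)
  expect_lte(fit$residual_distance, grid_best + 1e-9)
})

test_that("OPA agrees with an independent implementation on 3D data", {
  skip_if_not_installed("vegan")
  set.seed(5)
  src <- rigid_config(12, seed = 5)
  tgt <- rigid_config(12, seed = 6)
  fit <- opa_align(src, tgt, allow_scaling = TRUE, allow_reflection = TRUE)
  vg <- vegan::procrustes(tgt, src, scale = TRUE, symmetric = FALSE)
  expect_equal(fit$residual_distance^2, sum(stats::residuals(vg)^2),
               tolerance = 1e-8)
})

test_that("Procrustes distance is a symmetric metric on shapes", {
  cfg <- rigid_config(9)
  expect_equal(procrustes_distance(cfg, cfg), 0)
  moved <- sweep(cfg %*% random_rotation3(2), 2, c(1, 2, 3), `+`)
  expect_equal(procrustes_distance(cfg, moved), 0, tolerance = 1e-8)

  set.seed(77)
  for (rep in 1:25) {
    a <- matrix(rnorm(27), 9); b <- matrix(rnorm(27), 9); c <- matrix(rnorm(27), 9)
    a <- a / centroid_size(a); b <- b / centroid_size(b); c <- c / centroid_size(c)
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-10)
    expect_lte(procrustes_distance(a, c),
               procrustes_distance(a, b) + procrustes_distance(b, c) + 1e-10)
  }
})

test_that("GPA aligns identical shapes perfectly and respects constraints", {
  cfg <- rigid_config(12, seed = 8)
  n <- 6L
  coords <- array(0, dim = c(12, 3, n))
  set.seed(9)
  for (i in seq_len(n))
    coords[, , i] <- sweep(runif(1, 0.5, 3) * cfg %*% random_rotation3(),
                           2, rnorm(3, sd = 4), `+`)
  al <- gpa(coords)
  for (i in seq_len(n)) {
    expect_equal(colMeans(al$coords[, , i]), rep(0, 3), tolerance = 1e-8)
    expect_equal(centroid_size(al$coords[, , i]), 1, tolerance = 1e-8)
    expect_equal(procrustes_distance(al$coords[, , i], al$consensus), 0,
                 tolerance = 1e-6)
  }
  expect_equal(al$consensus, apply(al$coords, c(1, 2), mean), tolerance = 1e-12)
})

test_that("with two specimens each is equidistant from the consensus", {
  ds <- tiny_dataset(n_per = c(1L, 1L), sep = 0.05, seed = 13L)
  al <- gpa(ds)
  d1 <- procrustes_distance(al$coords[, , 1], al$consensus)
  d2 <- procrustes_distance(al$coords[, , 2], al$consensus)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("GPA output is invariant under rigid perturbation of any input", {
  ds <- tiny_dataset(seed = 17L)
  al1 <- gpa(ds)
  co <- ds$coords
  co[, , 3] <- sweep(1.7 * co[, , 3] %*% random_rotation3(4), 2,
                     c(10, -5, 2), `+`)
  al2 <- gpa(shape_dataset(co, ds$scheme, species = ds$species))
  expect_equal(al1$consensus, al2$consensus, tolerance = 1e-6)
  expect_equal(unname(al1$coords), unname(al2$coords), tolerance = 1e-6)
})

test_that("GPA consensus recovers the generating mean shape", {
  # Monte-Carlo check against the generator's ground truth: the consensus
  # should approach the species mean at the 1/sqrt(n) rate (factor 3 slack)
  n <- 24L
  noise <- 0.006
  ds <- tiny_dataset(n_per = n, sep = 0, noise = noise, seed = 31L)
  truth <- attr(ds, "ground_truth")$species_means[[1]]
  truth <- truth - matrix(colMeans(truth), nrow(truth), 3, byrow = TRUE)
  truth <- truth / sqrt(sum(truth^2))
  al <- gpa(ds)
  p <- dim(ds$coords)[1]
  expect_lt(procrustes_distance(al$consensus, truth),
            3 * noise * sqrt(3 * p) / sqrt(n))
})

test_that("Procrustes residual sum is non-increasing over GPA refits", {
  ds <- tiny_dataset(seed = 23L)
  al_loose <- gpa(ds, max_iter = 1L)
  al_tight <- gpa(ds)
  ss <- function(a) sum(vapply(seq_len(dim(a$coords)[3]), function(i)
    procrustes_distance(a$coords[, , i], a$consensus)^2, 0))
  expect_lte(ss(al_tight), ss(al_loose) + 1e-10)
})
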