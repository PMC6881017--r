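test_that("bending energy matrix is PSD with an affine null space", {
  ref <- rigid_config(10, seed = 41L)
  B <- bending_energy_matrix(ref)
  expect_equal(B, t(B), tolerance = 1e-12)
  expect_gte(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  # any affine transform of the reference costs zero bending energy
  A <- rbind(c(1, 0.4, -0.2), c(0, 1.1, 0.3), c(0.2, 0, 0.9))
  sheared <- sweep(ref %*% A, 2, c(2, -1, 0.5), `+`)
  expect_equal(bending_energy(sheared, B), 0, tolerance = 1e-9)
  # a clearly non-affine target costs positive energy
  warped <- ref
  warped[1, ] <- warped[1, ] + c(0.5, 0, 0)
  expect_gt(bending_energy(warped, B), 1e-6)
})

test_that("bending energy quadratic form matches the TPS-weights oracle", {
  # independent route: fit the interpolating TPS through (reference ->
  # heights), take energy = w' K w from its weights
  ref <- rigid_config(6, seed = 43L)
  B <- bending_energy_matrix(ref)
  K <- -as.matrix(dist(ref))
  P <- cbind(1, ref)
  set.seed(44)
  for (rep in 1:5) {
    y <- rnorm(6)
    L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
    wa <- solve(L, c(y, rep(0, 4)))
    w <- wa[1:6]
    expect_equal(drop(t(y) %*% B %*% y), drop(t(w) %*% K %*% w),
                 tolerance = 1e-9)
  }
})

test_that("coincident reference points are reported by index", {
  ref <- rigid_config(5, seed = 45L)
  ref[4, ] <- ref[2, ]
  expect_error(bending_energy_matrix(ref), "2 and 4")
})

test_that("sliding leaves a specimen identical to the consensus untouched", {
  fit <- trabecular_fit()$gpa
  st <- build_slider_table(trabecular_fit()$dataset$scheme)
  fake <- fit
  fake$coords <- array(fit$consensus, dim = c(dim(fit$consensus), 2L))
  out <- slide_semilandmarks(fake, st)
  expect_equal(out[, , 1], fit$consensus, tolerance = 1e-8)
})

test_that("a sliding pass never increases bending energy", {
  ds <- simulate_dataset(simulation_preset("trabecular"), seed = 51L)
  st <- build_slider_table(ds$scheme)
  al <- gpa(ds)  # aligned but not yet slid
  B <- bending_energy_matrix(al$consensus)
  out <- slide_semilandmarks(al, st)
  for (i in seq_len(dim(out)[3])) {
    before <- bending_energy(al$coords[, , i] - al$consensus, B)
    after <- bending_energy(out[, , i] - al$consensus, B)
    expect_lte(after, before + 1e-12)
  }
})

test_that("single-point sliding matches a scalar line-search oracle", {
  ds <- simulate_dataset(simulation_preset("trabecular"), seed = 53L)
  al <- gpa(ds)
  B <- bending_energy_matrix(al$consensus)
  full <- build_slider_table(ds$scheme)
  one <- full[8, , drop = FALSE]  # a single interior semilandmark
  class(one) <- class(full)
  Y <- al$coords[, , 3]
  out <- loopmorph:::.slide_one(Y, one, B)
  # oracle: 1-D minimization of the bending energy along the tangent
  u <- Y[one$after, ] - Y[one$before, ]
  u <- u / sqrt(sum(u^2))
  energy_at <- function(t) {
    Y2 <- Y; Y2[one$slide, ] <- Y[one$slide, ] + t * u
    bending_energy(Y2, B)
  }
  opt <- optimize(energy_at, interval = c(-0.5, 0.5), tol = 1e-10)
  got <- drop((out[one$slide, ] - Y[one$slide, ]) %*% u)
  expect_equal(got, opt$minimum, tolerance = 1e-6)
})

test_that("coincident sliding neighbours raise a named error", {
  ds <- simulate_dataset(simulation_preset("trabecular"), seed = 55L)
  st <- build_slider_table(ds$scheme)
  al <- gpa(ds)
  al$coords[st$before[1], , 1] <- al$coords[st$after[1], , 1]
  expect_error(slide_semilandmarks(al, st),
               paste("point", st$slide[1]))
})

test_that("sliding during GPA does not increase the consensus bending objective", {
  ds <- simulate_dataset(simulation_preset("trabecular"), seed = 57L)
  st <- build_slider_table(ds$scheme)
  plain <- gpa(ds)
  slid <- gpa(ds, sliders = st)
  B <- bending_energy_matrix(plain$consensus)
  total_be <- function(a) sum(vapply(seq_len(dim(a$coords)[3]), function(i)
    bending_energy(a$coords[, , i] - a$consensus, B), 0))
  expect_lte(total_be(slid), total_be(plain) + 1e-8)
  expect_true(slid$slid)
})
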