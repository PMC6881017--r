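test_that("sums of squares decompose and results are seed-stable", {
  fit <- trabecular_fit()$gpa
  an <- procrustes_anova(fit, terms = c("size", "group"), n_perm = 99L,
                         seed = 42L)
  tab <- an$table
  expect_equal(sum(tab[c("size", "group", "Residuals"), "SS"]),
               tab["Total", "SS"], tolerance = 1e-9)
  expect_true(all(tab[c("size", "group"), "p"] >= 1 / 100))
  expect_true(all(tab[c("size", "group"), "p"] <= 1))
  an2 <- procrustes_anova(fit, terms = c("size", "group"), n_perm = 99L,
                          seed = 42L)
  expect_identical(an$table, an2$table)  # bit-stable under a fixed seed
})

test_that("shape that is an exact linear function of log size fits perfectly", {
  set.seed(93)
  tpl <- make_template_loop("generic")
  p <- nrow(tpl$mean)
  n <- 14L
  slope <- matrix(rnorm(p * 3), ncol = 3); slope <- slope / sqrt(sum(slope^2)) * 0.05
  logsizes <- seq(log(5), log(20), length.out = n)
  coords <- array(0, dim = c(p, 3, n))
  for (i in seq_len(n)) {
    shp <- tpl$mean + slope * (logsizes[i] - mean(logsizes))
    shp <- shp / centroid_size(shp) * exp(logsizes[i])
    coords[, , i] <- shp  # no noise, no rigid nuisance
  }
  al <- gpa(coords)
  an <- procrustes_anova(al, terms = "size", n_perm = 49L, seed = 1L)
  expect_gt(an$table["size", "SS"] / an$table["Total", "SS"], 0.999)
  expect_equal(an$table["size", "p"], 1 / 50)
})

test_that("a strong group effect reaches the minimum attainable p-value", {
  ds <- tiny_dataset(n_per = c(8L, 8L), sep = 0.05, noise = 0.003, seed = 95L)
  al <- gpa(ds)
  an <- procrustes_anova(al, terms = "group", n_perm = 199L, seed = 2L)
  expect_equal(an$table["group", "p"], 1 / 200)
})

test_that("the SS decomposition is invariant to a global rotation", {
  fit <- trabecular_fit()$gpa
  an1 <- procrustes_anova(fit, terms = c("size", "group"), n_perm = 19L,
                          seed = 5L)
  rot <- fit
  R <- random_rotation3(97)
  for (i in seq_len(dim(rot$coords)[3]))
    rot$coords[, , i] <- rot$coords[, , i] %*% R
  rot$consensus <- rot$consensus %*% R
  an2 <- procrustes_anova(rot, terms = c("size", "group"), n_perm = 19L,
                          seed = 5L)
  expect_equal(an1$table$SS, an2$table$SS, tolerance = 1e-9)
  expect_equal(an1$table$F, an2$table$F, tolerance = 1e-9)
})

test_that("aliased designs and invalid terms are rejected", {
  fit <- trabecular_fit()$gpa
  expect_error(procrustes_anova(fit, terms = "species"), "distinct values")
  expect_error(procrustes_anova(fit, terms = "size:group"), "main effects")
  # constant size makes size aliased with the intercept
  broken <- fit
  broken$centroid_sizes[] <- 5
  expect_error(procrustes_anova(broken, terms = "size"), "aliased.*size")
})

test_that("heterogeneous allometric slopes are detected, shared ones are not", {
  # distinct random allometric vectors per species, strong magnitude
  ds_het <- simulate_dataset(
    simulation_spec(loop_type = "generic", n_per_species = c(12L, 12L),
                    mean_offset_scale = 0.02, within_sd = 0.002,
                    allometry_scale = 0.08, common_allometry = FALSE,
                    size_sdlog = 0.3),
    seed = 97L)
  al <- gpa(ds_het)
  het <- common_allometry_test(al, n_perm = 99L, seed = 7L)
  expect_equal(het$table["size:group", "p"], 1 / 100)

  # one shared vector: the interaction should look null (not tiny-p)
  ds_sh <- simulate_dataset(
    simulation_spec(loop_type = "generic", n_per_species = c(12L, 12L),
                    mean_offset_scale = 0.02, within_sd = 0.002,
                    allometry_scale = 0.08, common_allometry = TRUE,
                    size_sdlog = 0.3),
    seed = 98L)
  sh <- common_allometry_test(gpa(ds_sh), n_perm = 99L, seed = 8L)
  expect_gt(sh$table["size:group", "p"], 0.05)
  # but the common slope itself is strongly supported
  expect_equal(sh$table["size", "p"], 1 / 100)
})

test_that("groups with a degenerate size range are rejected", {
  fit <- trabecular_fit()$gpa
  broken <- fit
  broken$centroid_sizes[broken$species == "spF"] <- 7
  expect_error(common_allometry_test(broken), "constant centroid size.*spF")
})
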