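# Small in-code fixtures shared across test files. Expensive objects are
# memoised so repeated tests reuse one fit.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# generic 12-point loop dataset, two groups, clearly separated
tiny_dataset <- function(n_per = c(6L, 6L), sep = 0.03, noise = 0.005,
                         seed = 1L, ...) {
  simulate_dataset(
    simulation_spec(loop_type = "generic", n_per_species = n_per,
                    mean_offset_scale = sep, within_sd = noise, ...),
    seed = seed)
}

# an asymmetric, well-conditioned 3D configuration
rigid_config <- function(p = 10L, seed = 99L) {
  set.seed(seed)
  matrix(stats::rnorm(p * 3), ncol = 3)
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

random_rotation3 <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

bilateral_fit <- function() memo("bilateral_fit", {
  ds <- simulate_dataset(simulation_preset("bilateral"), seed = 101L)
  list(dataset = ds,
       gpa = gpa(ds, sliders = build_slider_table(ds$scheme)))
})

trabecular_fit <- function() memo("trabecular_fit", {
  ds <- simulate_dataset(simulation_preset("trabecular"), seed = 202L)
  list(dataset = ds,
       gpa = gpa(ds, sliders = build_slider_table(ds$scheme)))
})

combined_fit <- function() memo("combined_fit", {
  ds <- simulate_dataset(simulation_preset("combined"), seed = 303L)
  list(dataset = ds,
       gpa = gpa(ds, sliders = build_slider_table(ds$scheme)))
})
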