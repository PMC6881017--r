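# Quadratic Bezier arc through start -> control -> end, evaluated at
# interior parameters (the semilandmark positions of a curve).
.bezier <- function(p0, pc, p1, t) {
  outer((1 - t)^2, p0) + outer(2 * t * (1 - t), pc) + outer(t^2, p1)
}

# Fixed-landmark template positions (arbitrary consistent units; the
# template is normalized to unit centroid size). Axes: x anterior, y
# lateral (half structure, y >= 0), z ventral.
.template_fixed <- rbind(
  cardinal_process = c(0.00, 0.00, 0.20),
  hinge_tooth_socket = c(0.10, 0.90, 0.10),
  inner_hinge_plate = c(0.20, 0.45, 0.05),
  outer_hinge_plate = c(0.15, 0.75, 0.12),
  septum_base_posterior = c(0.50, 0.00, -0.10),
  septum_crest = c(1.20, 0.00, 0.10),
  septum_anterior_end = c(1.80, 0.00, -0.05),
  crural_base = c(0.30, 0.50, 0.10),
  crural_process_tip = c(0.90, 0.45, 0.55),
  descending_branch_base = c(1.00, 0.50, 0.15),
  descending_septal_attachment = c(1.50, 0.15, 0.00),
  ascending_branch_crest = c(1.90, 0.30, 0.60),
  transverse_band_lateral = c(2.00, 0.35, 0.75),
  transverse_band_medial = c(2.10, 0.00, 0.90),
  loop_anterior_extreme = c(2.30, 0.10, 0.40))

.template_bilateral_extra <- rbind(
  connecting_band_dorsal_origin = c(1.40, 0.50, 0.20),
  connecting_band_ventral_insertion = c(1.50, 0.40, 0.70),
  connecting_band_midpoint = c(1.45, 0.47, 0.45),
  ascending_branch_lateral_flare = c(1.80, 0.50, 0.50),
  descending_branch_anterior_edge = c(1.70, 0.55, 0.10))

.curve_controls <- list(
  crus = c(0.60, 0.60, 0.30),
  descending_ascending = c(1.90, 0.45, 0.05),
  transverse_band = c(2.05, 0.20, 0.95))

#' Template mean configuration for a loop type
#'
#' Builds a parametric half-loop template: the fixed landmarks of the
#' chosen scheme at junction/extremal positions, plus three 3D arcs (crus,
#' descending--ascending branch, transverse band) sampled at the scheme's
#' semilandmark counts. The bilateral template adds five connecting-band
#' region landmarks to the fifteen shared ones. The configuration is
#' centered and normalized to unit centroid size.
#'
#' @param loop_type `"bilateral"`, `"trabecular"` or `"generic"` (a small
#'   8-fixed-landmark, single-curve template useful for fast simulations).
#' @return List with `scheme` (a `landmark_scheme`) and `mean` (`p x 3`
#'   template configuration, unit centroid size).
#' @export
make_template_loop <- function(loop_type = c("bilateral", "trabecular", "generic")) {
  loop_type <- match.arg(loop_type)
  if (loop_type == "generic") {
    scheme <- landmark_scheme(
      rownames(.template_fixed)[c(1, 5, 6, 8, 9, 10, 12, 14)],
      list(curve_spec("descending_ascending", 4L, "descending_branch_base",
                      "ascending_branch_crest")),
      loop_type = "generic")
    fixed <- .template_fixed[scheme$fixed_names, , drop = FALSE]
  } else {
    scheme <- loop_scheme(loop_type)
    fixed <- rbind(.template_fixed,
                   if (loop_type == "bilateral") .template_bilateral_extra)
  }
  semis <- lapply(scheme$curves, function(cv) {
    t <- seq_len(cv$n_semilandmarks) / (cv$n_semilandmarks + 1)
    .bezier(fixed[cv$anchor_start, ], .curve_controls[[cv$name]],
            fixed[cv$anchor_end, ], t)
  })
  config <- rbind(fixed, do.call(rbind, semis))
  config <- .center(config)
  config <- config / sqrt(sum(config^2))
  rownames(config) <- point_names(scheme)
  list(scheme = scheme, mean = config)
}

#' Specify a synthetic loop-landmark simulation
#'
#' Defines a species-structured simulation: species mean shapes are the
#' template deformed by smooth (thin-plate-spline interpolated) random
#' displacements; specimens add optional per-species allometric shape
#' change tied to log centroid size and isotropic digitizing noise, and are
#' then rigidly perturbed (random rotation and translation) and scaled to
#' their centroid size so that superimposition is never trivially bypassed.
#'
#' @param loop_type Template type (see [make_template_loop()]).
#' @param n_per_species Integer vector of specimens per species (its length
#'   sets the number of species).
#' @param mean_offset_scale Standard deviation (shape units, i.e. relative
#'   to unit centroid size) of the per-species smooth mean deformations.
#' @param within_sd Isotropic per-coordinate digitizing/individual noise sd
#'   (shape units).
#' @param allometry_scale Magnitude of the per-species allometric vector
#'   (shape change per unit log size); 0 disables allometry.
#' @param common_allometry If `TRUE` all species share one allometric
#'   vector; if `FALSE` each species gets an independent random vector.
#' @param allometry_mix Optional fraction in `[0, 1]` of shared allometric
#'   structure: species vectors are built as a mixture of one common
#'   direction (weight `sqrt(allometry_mix)`) and independent directions.
#'   Overrides `common_allometry`; mimics congeners whose allometries are
#'   correlated but not identical.
#' @param genus Optional character vector (one per species) of genus
#'   labels; species within a genus share a large-scale genus deformation
#'   of sd `genus_offset_scale` and differ by `mean_offset_scale`.
#' @param genus_offset_scale Sd of the genus-level deformation (ignored
#'   without `genus`).
#' @param size_meanlog,size_sdlog Log-normal centroid-size parameters
#'   (recycled over species).
#' @param n_control Number of control points for the smooth deformations.
#' @param species Optional species names.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(loop_type = "generic",
                            n_per_species = c(10L, 10L),
                            mean_offset_scale = 0.03,
                            within_sd = 0.005,
                            allometry_scale = 0,
                            common_allometry = FALSE,
                            allometry_mix = NULL,
                            genus = NULL,
                            genus_offset_scale = 0.05,
                            size_meanlog = log(10),
                            size_sdlog = 0.15,
                            n_control = 8L,
                            species = NULL) {
  g <- length(n_per_species)
  stopifnot(g >= 1L, all(n_per_species >= 1L),
            mean_offset_scale >= 0, within_sd >= 0, allometry_scale >= 0,
            genus_offset_scale >= 0)
  if (is.null(species)) species <- paste0("sp", seq_len(g))
  if (!is.null(genus)) stopifnot(length(genus) == g)
  if (!is.null(allometry_mix))
    stopifnot(allometry_mix >= 0, allometry_mix <= 1)
  structure(list(loop_type = loop_type,
                 n_per_species = as.integer(n_per_species),
                 mean_offset_scale = mean_offset_scale,
                 within_sd = within_sd,
                 allometry_scale = allometry_scale,
                 common_allometry = common_allometry,
                 allometry_mix = allometry_mix,
                 genus = genus, genus_offset_scale = genus_offset_scale,
                 size_meanlog = rep_len(size_meanlog, g),
                 size_sdlog = rep_len(size_sdlog, g),
                 n_control = as.integer(n_control),
                 species = species),
            class = "simulation_spec")
}

# Smooth random deformation field of sd `scale`: random displacements at a
# few control points, TPS-interpolated to every template point. Smoothness
# keeps semilandmark order monotone along curves, mirroring real digitizing.
.smooth_deformation <- function(template, scale, n_control) {
  p <- nrow(template)
  ctrl_idx <- sample.int(p, min(n_control, p))
  disp <- matrix(stats::rnorm(length(ctrl_idx) * 3L, sd = scale),
                 ncol = 3L)
  .tps_interpolate(template[ctrl_idx, , drop = FALSE], disp, template)
}

# Remove the similarity components (translation, rotation, scaling of the
# template) from a p x 3 displacement field, so generated allometric
# vectors are pure shape changes that superimposition cannot absorb.
.project_to_shape_tangent <- function(v, template) {
  p <- nrow(template)
  skews <- list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
                rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)),
                rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  N <- cbind(kronecker(diag(3), rep(1, p)),
             as.vector(template),
             vapply(skews, function(S) as.vector(template %*% S), numeric(3 * p)))
  Q <- qr.Q(qr(N))
  vv <- as.vector(v)
  matrix(vv - Q %*% crossprod(Q, vv), ncol = 3L)
}

.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Simulate a species-structured loop landmark dataset
#'
#' Draws a dataset under a [simulation_spec()], with full ground truth
#' (species mean shapes, allometric vectors, sizes, the template) attached
#' as the `"ground_truth"` attribute. Bit-reproducible for a fixed seed.
#'
#' @param spec A `simulation_spec`.
#' @param seed Integer seed.
#' @return A `shape_dataset`; `attr(, "ground_truth")` carries the truth.
#' @export
simulate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  tpl <- make_template_loop(spec$loop_type)
  template <- tpl$mean
  p <- nrow(template)
  g <- length(spec$n_per_species)

  genus_means <- NULL
  if (!is.null(spec$genus)) {
    glev <- unique(spec$genus)
    genus_means <- lapply(glev, function(gl)
      template + .smooth_deformation(template, spec$genus_offset_scale,
                                     spec$n_control))
    names(genus_means) <- glev
  }
  species_means <- vector("list", g)
  for (s in seq_len(g)) {
    base <- if (is.null(genus_means)) template else genus_means[[spec$genus[s]]]
    species_means[[s]] <- base +
      .smooth_deformation(template, spec$mean_offset_scale, spec$n_control)
  }
  names(species_means) <- spec$species

  allom <- vector("list", g)
  if (spec$allometry_scale > 0) {
    make_vec <- function() {
      v <- .project_to_shape_tangent(matrix(stats::rnorm(p * 3L), ncol = 3L),
                                     template)
      v / sqrt(sum(v^2)) * spec$allometry_scale
    }
    mix <- spec$allometry_mix
    if (is.null(mix)) mix <- if (spec$common_allometry) 1 else 0
    if (mix >= 1) {
      allom <- rep(list(make_vec()), g)
    } else {
      shared <- if (mix > 0) make_vec() else matrix(0, p, 3L)
      allom <- lapply(seq_len(g), function(s) {
        v <- sqrt(mix) * shared + sqrt(1 - mix) * make_vec()
        v / sqrt(sum(v^2)) * spec$allometry_scale
      })
    }
  } else allom <- rep(list(matrix(0, p, 3L)), g)
  names(allom) <- spec$species

  n <- sum(spec$n_per_species)
  coords <- array(NA_real_, dim = c(p, 3L, n))
  species <- character(n); sizes <- numeric(n)
  i <- 0L
  for (s in seq_len(g)) {
    for (j in seq_len(spec$n_per_species[s])) {
      i <- i + 1L
      logsize <- stats::rnorm(1, spec$size_meanlog[s], spec$size_sdlog[s])
      shape <- species_means[[s]] +
        allom[[s]] * (logsize - spec$size_meanlog[s]) +
        matrix(stats::rnorm(p * 3L, sd = spec$within_sd), ncol = 3L)
      cfg <- .center(shape)
      cfg <- cfg / sqrt(sum(cfg^2)) * exp(logsize)
      cfg <- cfg %*% .random_rotation()
      cfg <- sweep(cfg, 2L, stats::rnorm(3, sd = 2 * exp(logsize)), `+`)
      coords[, , i] <- cfg
      species[i] <- spec$species[s]
      sizes[i] <- exp(logsize)
    }
  }
  genus <- if (!is.null(spec$genus))
    spec$genus[match(species, spec$species)] else NULL
  ds <- shape_dataset(coords, tpl$scheme, species = species, genus = genus)
  attr(ds, "ground_truth") <- list(
    template = template, species_means = species_means,
    allometry_vectors = allom, sizes = sizes, spec = spec, seed = seed)
  ds
}

#' Built-in simulation scenarios
#'
#' Three study-condition presets mirroring the sampling structure of the
#' North Pacific long-loop datasets, plus a pure-noise null:
#' \describe{
#'   \item{`"bilateral"`}{5 species of one genus, n = 16, 12, 9, 2, 1
#'     (total 40), well-separated means, species-specific allometry.}
#'   \item{`"trabecular"`}{3 species in 2 genera, n = 8, 5, 5 (total 18):
#'     one distant genus and two congeneric species with strongly
#'     overlapping means (a deliberately hard discrimination), no
#'     allometry.}
#'   \item{`"combined"`}{8 species in 3 genera, n = 16, 12, 9, 2, 1, 8, 5,
#'     5 (total 58), genus-level structure dominating species-level
#'     structure.}
#'   \item{`"null"`}{2 groups with identical means (pure noise), generic
#'     template.}
#' }
#'
#' @param name Scenario name.
#' @return A `simulation_spec`.
#' @export
simulation_preset <- function(name = c("bilateral", "trabecular", "combined",
                                       "null")) {
  name <- match.arg(name)
  switch(name,
    bilateral = simulation_spec(
      loop_type = "bilateral",
      n_per_species = c(16L, 12L, 9L, 2L, 1L),
      species = c("spA", "spB", "spC", "spD", "spE"),
      genus = rep("genus1", 5L),
      genus_offset_scale = 0,
      mean_offset_scale = 0.035,
      within_sd = 0.004,
      allometry_scale = 0.12,
      allometry_mix = 0.6,
      size_meanlog = log(c(14, 11, 12, 13, 12)),
      size_sdlog = 0.18),
    trabecular = simulation_spec(
      loop_type = "trabecular",
      n_per_species = c(8L, 5L, 5L),
      species = c("spF", "spG", "spH"),
      genus = c("genus2", "genus2", "genus3"),
      genus_offset_scale = 0.05,
      mean_offset_scale = 0.003,
      within_sd = 0.007,
      allometry_scale = 0,
      size_meanlog = log(c(16, 13, 12)),
      size_sdlog = 0.15),
    combined = simulation_spec(
      loop_type = "trabecular",
      n_per_species = c(16L, 12L, 9L, 2L, 1L, 8L, 5L, 5L),
      species = c("spA", "spB", "spC", "spD", "spE", "spF", "spG", "spH"),
      genus = c(rep("genus1", 5L), "genus2", "genus2", "genus3"),
      genus_offset_scale = 0.06,
      mean_offset_scale = 0.025,
      within_sd = 0.004,
      allometry_scale = 0.08,
      allometry_mix = 0.6,
      size_meanlog = log(c(14, 11, 12, 13, 12, 16, 13, 12)),
      size_sdlog = 0.15),
    null = simulation_spec(
      loop_type = "generic",
      n_per_species = c(10L, 10L),
      mean_offset_scale = 0,
      within_sd = 0.005,
      allometry_scale = 0))
}

#' Monte-Carlo null and power sweep
#'
#' For each cell of a grid of mean separations and noise levels, simulates
#' datasets, runs GPA, leave-one-out CVA classification and (optionally)
#' the Procrustes ANOVA group test, and summarizes accuracy and rejection
#' rates with binomial standard errors.
#'
#' @param separations Numeric vector of `mean_offset_scale` values.
#' @param within_sd Noise sd (single value).
#' @param n_per_species Specimens per species.
#' @param n_reps Simulated datasets per cell.
#' @param n_perm Permutations for the ANOVA test (0 skips the ANOVA).
#' @param alpha Rejection level for the ANOVA test.
#' @param seed Base seed (cell r of the grid uses `seed + r`).
#' @return Data.frame with one row per grid cell: `separation`,
#'   `mean_accuracy` (%), `accuracy_se`, `rejection_rate`, `rejection_se`.
#' @export
null_and_power_suite <- function(separations = c(0, 0.01, 0.03),
                                 within_sd = 0.005,
                                 n_per_species = c(8L, 8L),
                                 n_reps = 20L, n_perm = 99L,
                                 alpha = 0.05, seed = 1L) {
  rows <- list()
  cell <- 0L
  for (sep in separations) {
    cell <- cell + 1L
    acc <- numeric(n_reps); rej <- rep(NA, n_reps)
    for (r in seq_len(n_reps)) {
      sp <- simulation_spec(loop_type = "generic",
                            n_per_species = n_per_species,
                            mean_offset_scale = sep, within_sd = within_sd)
      ds <- simulate_dataset(sp, seed = seed + 1000L * cell + r)
      al <- gpa(ds)
      acc[r] <- loo_classification(al)$overall_accuracy
      if (n_perm > 0L) {
        an <- procrustes_anova(al, terms = "group", n_perm = n_perm,
                               seed = seed + 1000L * cell + r)
        rej[r] <- an$table["group", "p"] <= alpha
      }
    }
    rows[[cell]] <- data.frame(
      separation = sep,
      mean_accuracy = mean(acc),
      accuracy_se = stats::sd(acc) / sqrt(n_reps),
      rejection_rate = if (n_perm > 0L) mean(rej) else NA,
      rejection_se = if (n_perm > 0L)
        sqrt(mean(rej) * (1 - mean(rej)) / n_reps) else NA)
  }
  do.call(rbind, rows)
}
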