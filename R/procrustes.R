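#' Centroid size of a configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of every point from the configuration centroid.
#' Invariant to translation and rotation; scales linearly under isotropic
#' scaling.
#'
#' @param config Numeric `p x 3` (or `p x k`) coordinate matrix, `p >= 2`.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L)
    stop("centroid size undefined for fewer than 2 points", call. = FALSE)
  sqrt(sum(scale(config, scale = FALSE)^2))
}

.center <- function(m) sweep(m, 2L, colMeans(m))

# Optimal rotation of X onto C (both centered): minimizes ||X R - C||_F.
# With reflection disallowed the determinant is forced to +1 by sign-flipping
# the smallest singular axis (also resolves rank-deficient cross-covariance).
.opt_rotation <- function(X, C, allow_reflection = FALSE) {
  M <- crossprod(X, C)
  sv <- svd(M)
  R <- tcrossprod(sv$u, sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- tcrossprod(u, sv$v)
  }
  R
}

# Deterministic canonical orientation for a (centered) reference shape.
# Point-weighted second moments are used rather than the plain covariance:
# the asymmetric weights break the near-degenerate transverse axes a loop
# shape tends to have, so the rotation is stable under roundoff and
# equivariant (a rotated input yields the same canonical output).
.canonical_rotation <- function(C) {
  w <- seq_len(nrow(C))
  M <- crossprod(C * w, C)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors
  D <- C %*% ev
  for (j in 1:3) if (sum(w * D[, j]) < 0) ev[, j] <- -ev[, j]
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  ev
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Least-squares similarity superimposition of `source` onto `target`:
#' translation, rotation, optionally scaling and reflection.
#'
#' @param source,target `p x 3` coordinate matrices with equal `p`.
#' @param allow_scaling Fit an optimal scale factor (default `TRUE`).
#' @param allow_reflection Permit an improper rotation (default `FALSE`).
#' @return List of class `opa_fit`: `rotation` (3x3), `scale`, `translation`
#'   (length 3), `residual_distance` (root summed squared deviation after
#'   transform), and `aligned` (the transformed source).
#' @export
opa_align <- function(source, target, allow_scaling = TRUE,
                      allow_reflection = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target)))
    stop("source and target must have identical dimensions", call. = FALSE)
  xbar <- colMeans(source); ybar <- colMeans(target)
  Xc <- sweep(source, 2L, xbar); Yc <- sweep(target, 2L, ybar)
  if (sum(Xc^2) == 0 || sum(Yc^2) == 0)
    stop("degenerate configuration (all points coincident)", call. = FALSE)
  M <- crossprod(Xc, Yc)
  sv <- svd(M)
  d <- sv$d
  u <- sv$u
  if (!allow_reflection && det(tcrossprod(sv$u, sv$v)) < 0) {
    u[, ncol(u)] <- -u[, ncol(u)]
    d[length(d)] <- -d[length(d)]
  }
  R <- tcrossprod(u, sv$v)
  s <- if (allow_scaling) sum(d) / sum(Xc^2) else 1
  aligned <- s * (Xc %*% R)
  aligned <- sweep(aligned, 2L, ybar, `+`)
  translation <- ybar - as.vector(s * crossprod(R, xbar))[seq_along(ybar)]
  # translation as applied to row vectors: x %*% R * s + t
  translation <- ybar - as.vector(xbar %*% R) * s
  structure(list(rotation = R, scale = s, translation = translation,
                 residual_distance = sqrt(sum((aligned - target)^2)),
                 aligned = aligned),
            class = "opa_fit")
}

#' Procrustes distance between two shapes
#'
#' Root summed squared coordinate difference after centering both
#' configurations and optimally rotating `b` onto `a` (no scaling, no
#' reflection). Symmetric; zero iff the two shapes are identical up to
#' rotation and translation. On unit-centroid-size shapes this is the
#' partial Procrustes distance, a metric on the preshape sphere.
#'
#' @param a,b `p x 3` coordinate matrices with equal `p`.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("dimension mismatch", call. = FALSE)
  ac <- .center(a); bc <- .center(b)
  R <- .opt_rotation(bc, ac)
  sqrt(sum((bc %*% R - ac)^2))
}

#' Generalized Procrustes analysis with optional semilandmark sliding
#'
#' Superimposes all configurations into a common shape space: each is
#' centered and scaled to unit centroid size, then iteratively rotated onto
#' the running consensus (itself renormalized to unit size each round) until
#' the root-mean-square consensus change falls below `tol`. When a slider
#' table is supplied, sliding passes that move each curve semilandmark along
#' its tangent to minimize thin-plate-spline bending energy against the
#' consensus are alternated with re-superimposition.
#'
#' @param dataset A `shape_dataset` with at least 2 specimens, or a
#'   `p x 3 x n` array.
#' @param sliders Optional `slider_table` from [build_slider_table()].
#' @param tol Convergence tolerance on RMS consensus change (default 1e-8).
#' @param max_iter Maximum rotation iterations per superimposition pass.
#' @param slide_cycles Maximum outer slide/re-fit cycles (default 3).
#' @param slide_method Sliding criterion: `"bending"` (default) or
#'   `"procrustes"` (see [slide_semilandmarks()]).
#' @return Object of class `gpa`: list with `coords` (aligned `p x 3 x n`,
#'   each specimen centered with unit centroid size), `consensus` (`p x 3`
#'   mean of the aligned configurations), `centroid_sizes` (original-scale),
#'   `iterations`, `converged`, `slid`, plus the dataset labels and scheme.
#' @export
gpa <- function(dataset, sliders = NULL, tol = 1e-8, max_iter = 100L,
                slide_cycles = 3L, slide_method = c("bending", "procrustes")) {
  slide_method <- match.arg(slide_method)
  if (inherits(dataset, "shape_dataset")) {
    coords <- dataset$coords
    meta <- list(species = dataset$species, genus = dataset$genus,
                 ids = dataset$ids, scheme = dataset$scheme)
  } else {
    coords <- dataset
    stopifnot(length(dim(coords)) == 3L)
    meta <- list(species = NULL, genus = NULL,
                 ids = dimnames(coords)[[3]], scheme = NULL)
  }
  n <- dim(coords)[3]
  if (n < 2L) stop("GPA needs at least 2 specimens", call. = FALSE)
  p <- dim(coords)[1]
  cs <- numeric(n)
  X <- coords
  for (i in seq_len(n)) {
    m <- .center(coords[, , i])
    cs[i] <- sqrt(sum(m^2))
    if (cs[i] == 0) stop("degenerate specimen ", i, call. = FALSE)
    X[, , i] <- m / cs[i]
  }

  fit_pass <- function(X, C0 = NULL) {
    fit <- cpp_gpa_fit(X, if (is.null(C0)) matrix(0, 0, 0) else C0,
                       tol, as.integer(max_iter))
    list(X = fit$coords, C = fit$consensus, iterations = fit$iterations,
         converged = fit$converged)
  }

  fit <- fit_pass(X)
  total_iter <- fit$iterations
  slid <- FALSE
  if (!is.null(sliders)) {
    stopifnot(inherits(sliders, "slider_table"))
    for (cycle in seq_len(slide_cycles)) {
      Cprev <- fit$C
      be <- if (slide_method == "bending") bending_energy_matrix(fit$C)
      Xs <- fit$X
      for (i in seq_len(n))
        Xs[, , i] <- .slide_one(Xs[, , i], sliders, be,
                                reference = fit$C, method = slide_method)
      # sliding moves points off the preshape sphere; re-impose constraints
      for (i in seq_len(n)) {
        m <- .center(Xs[, , i])
        Xs[, , i] <- m / sqrt(sum(m^2))
      }
      fit <- fit_pass(Xs, C0 = fit$C)
      total_iter <- total_iter + fit$iterations
      slid <- TRUE
      if (sqrt(mean((fit$C - Cprev)^2)) < tol) break
    }
  }
  # canonical orientation: principal axes of the consensus with a
  # deterministic sign convention, so the shape-space frame does not depend
  # on specimen input order (GPA is otherwise defined only up to rotation)
  consensus <- apply(fit$X, c(1, 2), mean)
  ev <- .canonical_rotation(consensus)
  for (i in seq_len(n)) fit$X[, , i] <- fit$X[, , i] %*% ev
  consensus <- consensus %*% ev
  dimnames(fit$X) <- dimnames(coords)
  structure(list(coords = fit$X, consensus = consensus,
                 centroid_sizes = stats::setNames(cs, meta$ids),
                 iterations = total_iter, converged = fit$converged,
                 slid = slid, species = meta$species, genus = meta$genus,
                 ids = meta$ids, scheme = meta$scheme),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  d <- dim(x$coords)
  cat("Generalized Procrustes fit: ", d[3], " specimens x ", d[1],
      " points\n", sep = "")
  cat("  sliding semilandmarks: ", if (x$slid) "yes" else "no",
      "; iterations: ", x$iterations,
      if (!x$converged) " (not converged)" else "", "\n", sep = "")
  cat("  centroid size range: ",
      paste(signif(range(x$centroid_sizes), 4), collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  n <- dim(object$coords)[3]
  d <- vapply(seq_len(n), function(i)
    procrustes_distance(object$coords[, , i], object$consensus), 0)
  out <- list(n = n, p = dim(object$coords)[1],
              dist_to_consensus = stats::setNames(d, object$ids),
              total_ss = sum(d^2), iterations = object$iterations,
              slid = object$slid)
  class(out) <- "summary.gpa"
  out
}

#' @export
print.summary.gpa <- function(x, ...) {
  cat("GPA summary: n = ", x$n, ", p = ", x$p, "\n", sep = "")
  cat("  total Procrustes SS about consensus: ", format(x$total_ss), "\n", sep = "")
  cat("  distance to consensus:\n")
  print(summary(x$dist_to_consensus))
  invisible(x)
}

#' @export
residuals.gpa <- function(object, ...) {
  sweep(object$coords, c(1, 2), object$consensus)
}

#' @export
plot.gpa <- function(x, ...) {
  co <- x$coords
  n <- dim(co)[3]
  graphics::plot(NA, xlim = range(co[, 1, ]), ylim = range(co[, 3, ]),
                 xlab = "x (aligned)", ylab = "z (aligned)",
                 main = "Aligned configurations (x-z projection)", asp = 1, ...)
  for (i in seq_len(n))
    graphics::points(co[, 1, i], co[, 3, i], pch = 16,
                     col = grDevices::adjustcolor("grey40", 0.4), cex = 0.5)
  graphics::points(x$consensus[, 1], x$consensus[, 3], pch = 16, col = "red3")
  invisible(x)
}

#' Flatten aligned coordinates to an n x 3p matrix
#'
#' Rows are specimens; columns interleave per point as (x, y, z), matching
#' the ordering used by the ordination and ANOVA stages.
#'
#' @param x A `gpa` object or `p x 3 x n` array.
#' @return `n x 3p` numeric matrix.
#' @export
flatten_coords <- function(x) {
  co <- if (inherits(x, "gpa")) x$coords else x
  n <- dim(co)[3]
  t(vapply(seq_len(n), function(i) as.vector(t(co[, , i])),
           numeric(dim(co)[1] * 3L)))
}

#' Rebuild a p x 3 configuration from a flattened row
#' @param v Numeric vector of length 3p (x, y, z per point).
#' @return `p x 3` matrix.
#' @export
unflatten_coords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
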