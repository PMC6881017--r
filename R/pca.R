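#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the flattened aligned
#' coordinates about the consensus. Axis signs are fixed deterministically
#' by making each component's largest-magnitude loading positive, so scores
#' and plots are reproducible across runs and platforms.
#'
#' @param aligned A `gpa` object (n >= 3 specimens).
#' @return Object of class `shape_pca`: `eigenvalues` (descending),
#'   `variance_fractions` (summing to 1 over positive components), `scores`
#'   (`n x k`), `rotation` (`3p x k` component loadings), `center` (flattened
#'   consensus), `consensus` (`p x 3`), and the specimen labels.
#' @export
shape_pca <- function(aligned) {
  stopifnot(inherits(aligned, "gpa"))
  X <- flatten_coords(aligned)
  n <- nrow(X)
  if (n < 3L) stop("shape PCA needs at least 3 specimens", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  pos <- eig > max(eig[1] * 1e-12, 1e-15)
  k <- sum(pos)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rotation <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each axis made positive
  for (j in seq_len(k)) {
    if (.axis_sign(rotation[, j]) < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (k > 0L)
    dimnames(scores) <- list(aligned$ids, paste0("PC", seq_len(k)))
  eig <- eig[seq_len(k)]
  structure(list(eigenvalues = eig,
                 variance_fractions = eig / sum(eig),
                 scores = scores, rotation = rotation, center = ctr,
                 consensus = aligned$consensus,
                 species = aligned$species, genus = aligned$genus,
                 ids = aligned$ids),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("Shape PCA: ", nrow(x$scores), " specimens, ",
      length(x$eigenvalues), " positive components\n", sep = "")
  cat("  variance explained (%): ",
      paste(sprintf("PC%d=%.2f", seq_len(k), 100 * x$variance_fractions[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  tab <- rbind(eigenvalue = object$eigenvalues,
               `proportion (%)` = 100 * object$variance_fractions,
               `cumulative (%)` = 100 * cumsum(object$variance_fractions))
  colnames(tab) <- paste0("PC", seq_along(object$eigenvalues))
  class(tab) <- c("summary.shape_pca", class(tab))
  tab
}

#' @export
print.summary.shape_pca <- function(x, ...) {
  print(round(unclass(x)[, seq_len(min(8L, ncol(x))), drop = FALSE], 4))
  invisible(x)
}

#' @export
plot.shape_pca <- function(x, axes = c(1, 2), ...) {
  grp <- if (!is.null(x$species)) factor(x$species) else factor(rep(1, nrow(x$scores)))
  cols <- grDevices::hcl.colors(max(2L, nlevels(grp)), "Dark 3")[as.integer(grp)]
  lab <- sprintf("PC%d (%.1f%%)", axes, 100 * x$variance_fractions[axes])
  graphics::plot(x$scores[, axes[1]], x$scores[, axes[2]], col = cols, pch = 16,
                 xlab = lab[1], ylab = lab[2], main = "Shape PCA", ...)
  if (nlevels(grp) > 1)
    graphics::legend("topright", legend = levels(grp), pch = 16, cex = 0.7,
                     col = grDevices::hcl.colors(max(2L, nlevels(grp)), "Dark 3"))
  invisible(x)
}

#' Back-transform a PC score to a configuration
#'
#' Returns the shape lying at a given signed score along one principal
#' component: the consensus plus `score` times the component vector,
#' reshaped to `p x 3`. Used to visualize the shape changes at the extremes
#' of an axis.
#'
#' @param pca A `shape_pca`.
#' @param axis Component index (within the positive-eigenvalue range).
#' @param score Signed score along the axis (0 returns the consensus).
#' @return `p x 3` coordinate matrix.
#' @export
shape_at_score <- function(pca, axis, score) {
  stopifnot(inherits(pca, "shape_pca"))
  if (axis < 1L || axis > length(pca$eigenvalues))
    stop("axis out of range (1..", length(pca$eigenvalues), ")", call. = FALSE)
  unflatten_coords(pca$center + score * pca$rotation[, axis])
}
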