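# Sign convention for an ordination axis: the largest-magnitude loading is
# made positive; near-ties (within 1e-6 of the max) break to the smallest
# index so the convention is stable under row reordering and roundoff.
.axis_sign <- function(v) {
  cand <- which(abs(v) >= max(abs(v)) - 1e-6)
  if (v[min(cand)] < 0) -1 else 1
}

# Resolve a grouping argument against a gpa object: NULL / "species" /
# "genus" / an explicit vector.
.resolve_groups <- function(aligned, groups) {
  g <- if (is.null(groups)) aligned$species
    else if (identical(groups, "species")) aligned$species
    else if (identical(groups, "genus")) aligned$genus
    else groups
  if (is.null(g) || anyNA(g))
    stop("group labels missing for some specimens", call. = FALSE)
  factor(g, levels = unique(g))
}

# k_retained rule: smallest number of PCs reaching `target` cumulative
# variance, capped at n - g - 1 (so the pooled within-group covariance in
# the subspace is invertible) and at the number of positive components.
.choose_k <- function(eigenvalues, n, g, k_retained = "var95") {
  cap <- max(1L, min(length(eigenvalues), n - g - 1L))
  if (is.numeric(k_retained)) return(max(1L, min(as.integer(k_retained), cap)))
  if (!identical(k_retained, "var95"))
    stop("k_retained must be an integer or \"var95\"", call. = FALSE)
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  min(which(cum >= 0.95 - 1e-12)[1], cap)
}

# Group means, pooled within-group covariance and Mahalanobis distances in a
# score subspace.
.group_stats <- function(Z, grp) {
  g <- nlevels(grp)
  k <- ncol(Z)
  means <- matrix(0, g, k, dimnames = list(levels(grp), colnames(Z)))
  W <- matrix(0, k, k)
  for (lev in levels(grp)) {
    rows <- Z[grp == lev, , drop = FALSE]
    means[lev, ] <- colMeans(rows)
    W <- W + crossprod(sweep(rows, 2L, colMeans(rows)))
  }
  W <- W / (nrow(Z) - g)
  Winv <- solve(W)
  D <- matrix(0, g, g, dimnames = list(levels(grp), levels(grp)))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    d <- means[i, ] - means[j, ]
    D[i, j] <- sqrt(drop(t(d) %*% Winv %*% d))
  }
  list(means = means, W = W, Winv = Winv, mahalanobis = (D + t(D)) / 2)
}

.pc_scores <- function(X) {
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2L, ctr))
  eig <- sv$d^2 / (nrow(X) - 1)
  pos <- which(eig > max(eig, 0) * 1e-12)
  list(scores = sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], length(pos)),
       basis = sv$v[, pos, drop = FALSE], eigenvalues = eig[pos], center = ctr)
}

#' Canonical variate analysis of aligned shapes
#'
#' Discriminates a priori groups in shape space. Aligned coordinates are
#' first projected onto the leading principal components (guarding against
#' a singular within-group covariance in the full shape space); the
#' canonical axes then solve the generalized eigenproblem of between-group
#' versus pooled within-group covariance in that subspace. Mahalanobis
#' distances between group means are computed in the same subspace with the
#' pooled within-group covariance, and a leave-one-out cross-validated
#' classification (closest group mean by Mahalanobis distance, equal
#' priors) is run via [loo_classification()].
#'
#' @param aligned A `gpa` object.
#' @param groups `NULL` (use the dataset's species labels), `"species"`,
#'   `"genus"`, or an explicit label vector. Every group needs at least 2
#'   members; drop singleton groups (e.g. a species with one specimen)
#'   before calling.
#' @param k_retained Number of PCs to retain, or `"var95"` (default): the
#'   smallest number reaching 95% cumulative variance, capped at
#'   `n - g - 1`.
#' @return Object of class `shape_cva`: `canonical_scores` (`n x (g-1)`),
#'   `canonical_axes`, `mahalanobis` (`g x g`), `confusion` (leave-one-out
#'   counts, rows = true group), `overall_accuracy` and
#'   `per_group_accuracy` (percentages), `k_retained`, `groups`.
#' @export
shape_cva <- function(aligned, groups = NULL, k_retained = "var95") {
  stopifnot(inherits(aligned, "gpa"))
  grp <- .resolve_groups(aligned, groups)
  sizes <- table(grp)
  if (any(sizes < 2L))
    stop("group(s) with a single specimen: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "),
         ". Drop them before running the CVA (a leave-one-out ",
         "cross-validation cannot hold out a singleton's only specimen).",
         call. = FALSE)
  g <- nlevels(grp)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  X <- flatten_coords(aligned)
  n <- nrow(X)
  pc <- .pc_scores(X)
  k <- .choose_k(pc$eigenvalues, n, g, k_retained)
  Z <- pc$scores[, seq_len(k), drop = FALSE]
  gs <- .group_stats(Z, grp)
  # between-group covariance (group-size weighted)
  grand <- colMeans(Z)
  Bm <- matrix(0, k, k)
  for (lev in levels(grp)) {
    d <- gs$means[lev, ] - grand
    Bm <- Bm + sizes[[lev]] * tcrossprod(d)
  }
  Bm <- Bm / (g - 1)
  eW <- eigen(gs$W, symmetric = TRUE)
  Whalf_inv <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, 1e-300)), k) %*% t(eW$vectors)
  eB <- eigen(Whalf_inv %*% Bm %*% Whalf_inv, symmetric = TRUE)
  n_axes <- min(g - 1L, k)
  axes <- Whalf_inv %*% eB$vectors[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(n_axes))
    if (.axis_sign(axes[, j]) < 0) axes[, j] <- -axes[, j]
  cscores <- sweep(Z, 2L, grand) %*% axes
  dimnames(cscores) <- list(aligned$ids, paste0("CV", seq_len(n_axes)))
  loo <- loo_classification(aligned, groups = as.character(grp),
                            k_retained = k_retained)
  structure(list(canonical_scores = cscores, canonical_axes = axes,
                 canonical_eigenvalues = eB$values[seq_len(n_axes)],
                 mahalanobis = gs$mahalanobis,
                 confusion = loo$confusion,
                 overall_accuracy = loo$overall_accuracy,
                 per_group_accuracy = loo$per_group_accuracy,
                 k_retained = k, groups = grp, group_sizes = sizes,
                 pc_basis = pc$basis[, seq_len(k), drop = FALSE],
                 pc_center = pc$center, group_means = gs$means,
                 Winv = gs$Winv, consensus = aligned$consensus,
                 ids = aligned$ids),
            class = "shape_cva")
}

#' @export
print.shape_cva <- function(x, ...) {
  cat("Canonical variate analysis: ", length(x$groups), " specimens, ",
      nlevels(x$groups), " groups, ", x$k_retained, " PCs retained\n", sep = "")
  cat("  leave-one-out overall accuracy: ",
      sprintf("%.2f%%", x$overall_accuracy), "\n", sep = "")
  cat("  Mahalanobis distances between group means:\n")
  D <- round(x$mahalanobis, 3)
  D[upper.tri(D, diag = TRUE)] <- NA
  print(D[-1, -ncol(D), drop = FALSE], na.print = "")
  invisible(x)
}

#' @export
summary.shape_cva <- function(object, ...) {
  out <- list(mahalanobis = object$mahalanobis,
              confusion = object$confusion,
              overall_accuracy = object$overall_accuracy,
              per_group_accuracy = object$per_group_accuracy,
              k_retained = object$k_retained)
  class(out) <- "summary.shape_cva"
  out
}

#' @export
print.summary.shape_cva <- function(x, ...) {
  cat("CVA summary (", x$k_retained, " PCs retained)\n", sep = "")
  cat("Mahalanobis distances:\n"); print(round(x$mahalanobis, 3))
  cat("\nLeave-one-out confusion (rows = true group):\n"); print(x$confusion)
  cat("\nPer-group accuracy (%):\n")
  print(round(x$per_group_accuracy, 2))
  cat(sprintf("Overall accuracy: %.2f%%\n", x$overall_accuracy))
  invisible(x)
}

#' @export
plot.shape_cva <- function(x, axes = c(1, 2), ...) {
  cs <- x$canonical_scores
  if (ncol(cs) == 1L) cs <- cbind(cs, 0)
  grp <- x$groups
  cols <- grDevices::hcl.colors(max(2L, nlevels(grp)), "Dark 3")[as.integer(grp)]
  graphics::plot(cs[, axes[1]], cs[, axes[2]], col = cols, pch = 16,
                 xlab = paste0("CV", axes[1]), ylab = paste0("CV", axes[2]),
                 main = "Canonical variate analysis", ...)
  graphics::legend("topright", legend = levels(grp), pch = 16, cex = 0.7,
                   col = grDevices::hcl.colors(max(2L, nlevels(grp)), "Dark 3"))
  invisible(x)
}

#' Classify new configurations with a fitted CVA
#'
#' Each new configuration is centered, scaled to unit centroid size,
#' rotated onto the training consensus, projected into the retained-PC
#' subspace, and assigned to the group with the smallest Mahalanobis
#' distance (equal priors).
#'
#' @param object A `shape_cva`.
#' @param newdata `p x 3 x m` array, `p x 3` matrix, or `shape_dataset`.
#' @param ... Unused.
#' @return Character vector of predicted group labels.
#' @export
predict.shape_cva <- function(object, newdata, ...) {
  co <- if (inherits(newdata, "shape_dataset")) newdata$coords else newdata
  if (length(dim(co)) == 2L) co <- array(co, dim = c(dim(co), 1L))
  m <- dim(co)[3]
  out <- character(m)
  for (i in seq_len(m)) {
    cfg <- .center(co[, , i])
    cfg <- cfg / sqrt(sum(cfg^2))
    cfg <- cfg %*% .opt_rotation(cfg, object$consensus)
    z <- drop((as.vector(t(cfg)) - object$pc_center) %*% object$pc_basis)
    d2 <- apply(object$group_means, 1L, function(mu)
      drop(t(z - mu) %*% object$Winv %*% (z - mu)))
    out[i] <- names(d2)[which.min(d2)]
  }
  out
}

#' Leave-one-out cross-validated classification in shape space
#'
#' For each specimen in turn, the PC subspace and the group statistics are
#' refit without it (the global superimposition is kept fixed), and the
#' held-out specimen is assigned to the group whose mean is closest in
#' Mahalanobis distance (equal priors). Ties break to the first group in
#' label order.
#'
#' @inheritParams shape_cva
#' @return List with `confusion` (`g x g` counts, rows = true group),
#'   `overall_accuracy` and `per_group_accuracy` (percentages, two-decimal
#'   scale), `predicted` labels.
#' @export
loo_classification <- function(aligned, groups = NULL, k_retained = "var95") {
  stopifnot(inherits(aligned, "gpa"))
  grp <- .resolve_groups(aligned, groups)
  sizes <- table(grp)
  if (any(sizes < 2L))
    stop("group(s) with a single specimen: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "),
         ". Drop them before the leave-one-out classification.", call. = FALSE)
  g <- nlevels(grp)
  X <- flatten_coords(aligned)
  n <- nrow(X)
  predicted <- character(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    pc <- .pc_scores(Xi)
    k <- .choose_k(pc$eigenvalues, n - 1L, g, k_retained)
    Zi <- pc$scores[, seq_len(k), drop = FALSE]
    gs <- .group_stats(Zi, droplevels(grp[-i]))
    z <- drop((X[i, ] - pc$center) %*% pc$basis[, seq_len(k), drop = FALSE])
    d2 <- apply(gs$means, 1L, function(mu)
      drop(t(z - mu) %*% gs$Winv %*% (z - mu)))
    # ties break to the first group in label order
    lev_order <- match(rownames(gs$means), levels(grp))
    best <- order(d2, lev_order)[1]
    predicted[i] <- rownames(gs$means)[best]
  }
  confusion <- table(true = grp, predicted = factor(predicted, levels = levels(grp)))
  overall <- round(100 * sum(diag(confusion)) / n, 2)
  per_group <- round(100 * diag(confusion) / rowSums(confusion), 2)
  list(confusion = unclass(confusion), overall_accuracy = overall,
       per_group_accuracy = per_group, predicted = predicted)
}

#' Sensitivity of Mahalanobis distances to the number of retained PCs
#'
#' Recomputes the between-group Mahalanobis distance matrix for a sweep of
#' retained-PC counts, since published distances can depend on an unstated
#' dimension reduction.
#'
#' @inheritParams shape_cva
#' @param k_values Integer vector of subspace dimensions to evaluate.
#' @return Data.frame with columns `k`, `group1`, `group2`, `distance`.
#' @export
mahalanobis_k_sweep <- function(aligned, groups = NULL,
                                k_values = NULL) {
  grp <- .resolve_groups(aligned, groups)
  g <- nlevels(grp)
  X <- flatten_coords(aligned)
  n <- nrow(X)
  pc <- .pc_scores(X)
  cap <- max(1L, min(length(pc$eigenvalues), n - g - 1L))
  if (is.null(k_values)) k_values <- unique(pmin(seq(2L, cap, by = 2L), cap))
  out <- list()
  for (k in k_values) {
    k <- min(k, cap)
    gs <- .group_stats(pc$scores[, seq_len(k), drop = FALSE], grp)
    idx <- which(lower.tri(gs$mahalanobis), arr.ind = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      k = k,
      group1 = rownames(gs$mahalanobis)[idx[, 1]],
      group2 = colnames(gs$mahalanobis)[idx[, 2]],
      distance = gs$mahalanobis[idx])
  }
  unique(do.call(rbind, out))
}
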