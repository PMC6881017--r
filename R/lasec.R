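#' Fit between a subsampled and a full-data ordination
#'
#' Both score matrices are truncated to their common leading components,
#' centered and scaled to unit centroid size, and the subsampled scores are
#' superimposed onto the full-data scores by ordinary Procrustes alignment
#' (translation, rotation, scaling; reflection permitted, since PC axis
#' signs are arbitrary). The fit is `1 - PSS`, where PSS is the
#' post-alignment sum of squared distances; identical ordinations score 1.
#'
#' @param sub_scores,full_scores `n x k` score matrices over the same
#'   specimens in the same order.
#' @return Scalar in `[0, 1]`.
#' @export
lasec_fit <- function(sub_scores, full_scores) {
  sub_scores <- as.matrix(sub_scores); full_scores <- as.matrix(full_scores)
  if (nrow(sub_scores) != nrow(full_scores))
    stop("score matrices must cover the same specimens", call. = FALSE)
  k <- min(ncol(sub_scores), ncol(full_scores))
  X <- .center(sub_scores[, seq_len(k), drop = FALSE])
  Y <- .center(full_scores[, seq_len(k), drop = FALSE])
  X <- X / sqrt(sum(X^2))
  Y <- Y / sqrt(sum(Y^2))
  # OPA with reflection: min over s, R of ||s X R - Y||^2 = 1 - (sum sv)^2
  pss <- 1 - sum(svd(crossprod(X, Y))$d)^2
  1 - max(pss, 0)
}

#' Landmark sampling evaluation curve
#'
#' Quantifies how many landmarks an ordination needs: per iteration, three
#' random points are drawn and the subset grows one random point at a time
#' until all are included; at each size a GPA and PCA of the subset are run
#' and the subset scores are compared to the full-data scores with
#' [lasec_fit()]. The per-size median over iterations is the fit
#' trajectory; a plateau near 1 means additional landmarks add no
#' morphometric information.
#'
#' @param dataset A `shape_dataset` (no sliding is applied; all points are
#'   treated as landmarks).
#' @param n_iterations Number of random subsampling iterations
#'   (default 1000).
#' @param seed Integer seed; results are bit-stable for a fixed seed.
#' @return Object of class `lasec`: `sampled_sizes` (3..p), `fit_values`
#'   (`n_iterations x sizes`; `NA` where a subset GPA was degenerate),
#'   `median_fit`, `thresholds` (smallest size whose median fit reaches
#'   0.90 / 0.95 / 0.99), `n_iterations`, `seed`.
#' @export
lasec <- function(dataset, n_iterations = 1000L, seed = NULL) {
  stopifnot(inherits(dataset, "shape_dataset"))
  p <- dim(dataset$coords)[1]
  n <- dim(dataset$coords)[3]
  if (p < 4L) stop("LaSEC needs at least 4 points", call. = FALSE)
  if (n < 3L) stop("LaSEC needs at least 3 specimens", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  full <- gpa(dataset$coords)
  full_scores <- .pc_scores(flatten_coords(full))$scores
  sizes <- 3:p
  fits <- matrix(NA_real_, n_iterations, length(sizes))
  n_degenerate <- 0L
  for (it in seq_len(n_iterations)) {
    ord <- sample.int(p)
    for (si in seq_along(sizes)) {
      sub <- ord[seq_len(sizes[si])]
      fits[it, si] <- tryCatch({
        al <- gpa(dataset$coords[sub, , , drop = FALSE])
        lasec_fit(.pc_scores(flatten_coords(al))$scores, full_scores)
      }, error = function(e) NA_real_)
    }
  }
  n_degenerate <- sum(is.na(fits))
  if (n_degenerate > 0L)
    message("LaSEC: ", n_degenerate,
            " degenerate subset superimpositions recorded as NA")
  med <- apply(fits, 2L, stats::median, na.rm = TRUE)
  thr <- vapply(c(0.90, 0.95, 0.99), function(t) {
    hit <- which(med >= t)
    if (length(hit)) sizes[hit[1]] else NA_integer_
  }, 0L)
  names(thr) <- c("fit0.90", "fit0.95", "fit0.99")
  structure(list(sampled_sizes = sizes, fit_values = fits, median_fit = med,
                 thresholds = thr, n_iterations = as.integer(n_iterations),
                 n_degenerate = n_degenerate, seed = seed),
            class = "lasec")
}

#' @export
print.lasec <- function(x, ...) {
  cat("Landmark sampling evaluation curve: sizes ",
      min(x$sampled_sizes), "-", max(x$sampled_sizes), ", ",
      x$n_iterations, " iterations\n", sep = "")
  cat("  median fit at full sampling: ",
      format(x$median_fit[length(x$median_fit)]), "\n", sep = "")
  cat("  landmarks needed for median fit 0.90/0.95/0.99: ",
      paste(x$thresholds, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.lasec <- function(x, ...) {
  graphics::plot(NA, xlim = range(x$sampled_sizes), ylim = c(0, 1),
                 xlab = "Number of landmarks sampled", ylab = "Fit (1 - PSS)",
                 main = "Landmark sampling evaluation curve", ...)
  n_show <- min(nrow(x$fit_values), 200L)
  for (it in seq_len(n_show))
    graphics::lines(x$sampled_sizes, x$fit_values[it, ],
                    col = grDevices::adjustcolor("grey60", 0.3))
  graphics::lines(x$sampled_sizes, x$median_fit, lwd = 2)
  graphics::abline(v = x$thresholds, lty = 2)
  invisible(x)
}

#' Export a LaSEC trajectory as a long table
#' @param x A `lasec` object.
#' @return Data.frame with columns `size`, `iteration`, `fit`.
#' @export
lasec_table <- function(x) {
  stopifnot(inherits(x, "lasec"))
  data.frame(size = rep(x$sampled_sizes, each = nrow(x$fit_values)),
             iteration = rep(seq_len(nrow(x$fit_values)),
                             length(x$sampled_sizes)),
             fit = as.vector(x$fit_values))
}
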