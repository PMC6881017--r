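#' Permutation-based Procrustes ANOVA on aligned shapes
#'
#' Sequential (Type I) decomposition of the summed squared Procrustes
#' deviations of the flattened aligned coordinates over a model built from
#' `size` (log centroid size by default), `group` and their interaction.
#' Significance is assessed by residual randomization (RRPP): for each
#' term, the residuals of the reduced model containing all preceding terms
#' are row-permuted and added back to the reduced fit, the term's F ratio
#' is recomputed, and `p = (1 + #\{F* >= F\}) / (n_perm + 1)`; with the
#' default 999 permutations the smallest attainable p-value is 0.001.
#' Fully reproducible for a given `seed`.
#'
#' @param aligned A `gpa` object.
#' @param terms Ordered character vector drawn from
#'   `c("size", "group", "size:group")`.
#' @param groups Group labels (default: the dataset's species).
#' @param size Size covariate per specimen; default log centroid size from
#'   the superimposition (set `log_size = FALSE` for raw centroid size).
#' @param log_size Use log centroid size (default `TRUE`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation draws.
#' @param permutation `"rrpp"` (residual randomization, default) or
#'   `"raw"` (permute the observation rows directly).
#' @return Object of class `proc_anova`: the ANOVA `table` (data.frame with
#'   Df, SS, MS, F, p columns plus Residuals and Total rows), `n_perm`,
#'   `seed`, `terms`.
#' @export
procrustes_anova <- function(aligned, terms = c("size", "group"),
                             groups = NULL, size = NULL, log_size = TRUE,
                             n_perm = 999L, seed = NULL,
                             permutation = c("rrpp", "raw")) {
  stopifnot(inherits(aligned, "gpa"))
  permutation <- match.arg(permutation)
  terms <- as.character(terms)
  bad <- setdiff(terms, c("size", "group", "size:group"))
  if (length(bad) || !length(terms) || anyDuplicated(terms))
    stop("terms must be distinct values among size, group, size:group",
         call. = FALSE)
  if ("size:group" %in% terms && !all(c("size", "group") %in% terms))
    stop("size:group requires both main effects in the model", call. = FALSE)
  Y <- flatten_coords(aligned)
  n <- nrow(Y)
  need_grp <- any(grepl("group", terms))
  grp <- if (need_grp) .resolve_groups(aligned, groups) else NULL
  if (any(c("size", "size:group") %in% terms)) {
    if (is.null(size)) size <- aligned$centroid_sizes
    if (length(size) != n) stop("size length mismatch", call. = FALSE)
    sz <- if (log_size) log(size) else size
  } else sz <- NULL

  term_cols <- function(term) switch(term,
    size = matrix(sz, ncol = 1, dimnames = list(NULL, "size")),
    group = stats::model.matrix(~grp)[, -1, drop = FALSE],
    `size:group` = stats::model.matrix(~grp)[, -1, drop = FALSE] * sz)
  blocks <- lapply(terms, term_cols)
  # orthonormal basis built block by block so the sequential (Type I)
  # decomposition is exact regardless of pivoting
  Q <- matrix(1 / sqrt(n), n, 1L)
  r_cum <- 1L
  for (j in seq_along(blocks)) {
    B <- blocks[[j]] - Q %*% crossprod(Q, blocks[[j]])
    sv <- svd(B)
    rank <- sum(sv$d > max(sv$d[1] * 1e-8, 1e-12))
    if (rank < ncol(B))
      stop("rank-deficient model; aliased term: ", terms[j], call. = FALSE)
    Q <- cbind(Q, sv$u[, seq_len(rank), drop = FALSE])
    r_cum <- c(r_cum, ncol(Q))
  }
  nt <- length(terms)
  df_term <- diff(r_cum)
  df_res <- n - r_cum[nt + 1L]
  if (df_res < 1L) stop("no residual degrees of freedom", call. = FALSE)

  proj_ss <- function(Qcols, Y) sum(crossprod(Qcols, Y)^2)
  SS_total <- sum(Y^2) - proj_ss(Q[, 1L, drop = FALSE], Y)
  SS_term <- vapply(seq_len(nt), function(j)
    proj_ss(Q[, (r_cum[j] + 1L):r_cum[j + 1L], drop = FALSE], Y), 0)
  SS_res <- SS_total - sum(SS_term)
  MS_term <- SS_term / df_term
  MS_res <- SS_res / df_res
  Fobs <- MS_term / MS_res

  if (!is.null(seed)) set.seed(as.integer(seed))
  perms <- replicate(n_perm, sample.int(n))
  Qfull <- Q
  pvals <- numeric(nt)
  for (j in seq_len(nt)) {
    Qinc <- Q[, (r_cum[j] + 1L):r_cum[j + 1L], drop = FALSE]
    if (permutation == "rrpp") {
      Qred <- Q[, seq_len(r_cum[j]), drop = FALSE]
      Fitr <- Qred %*% crossprod(Qred, Y)
      Er <- Y - Fitr
    }
    count <- 0L
    for (b in seq_len(n_perm)) {
      Ystar <- if (permutation == "rrpp") Fitr + Er[perms[, b], , drop = FALSE]
        else Y[perms[, b], , drop = FALSE]
      ss_j <- proj_ss(Qinc, Ystar)
      ss_res <- sum(Ystar^2) - proj_ss(Qfull, Ystar)
      Fb <- (ss_j / df_term[j]) / (ss_res / df_res)
      if (Fb >= Fobs[j]) count <- count + 1L
    }
    pvals[j] <- (count + 1L) / (n_perm + 1L)
  }

  tab <- data.frame(
    Df = c(df_term, df_res, n - 1L),
    SS = c(SS_term, SS_res, SS_total),
    MS = c(MS_term, MS_res, NA),
    F = c(Fobs, NA, NA),
    p = c(pvals, NA, NA),
    row.names = c(terms, "Residuals", "Total"))
  structure(list(table = tab, n_perm = as.integer(n_perm), seed = seed,
                 terms = terms, permutation = permutation,
                 log_size = log_size),
            class = "proc_anova")
}

#' @export
print.proc_anova <- function(x, ...) {
  cat("Procrustes ANOVA (", x$permutation, " permutation, ", x$n_perm,
      " permutations", if (!is.null(x$seed)) paste0(", seed ", x$seed),
      ")\n", sep = "")
  tab <- x$table
  tab$SS <- signif(tab$SS, 5); tab$MS <- signif(tab$MS, 5)
  tab$F <- signif(tab$F, 4)
  print(tab, na.print = "")
  invisible(x)
}

#' @export
summary.proc_anova <- function(object, ...) object$table

#' Test for a common allometric component across groups
#'
#' Fits the sequential model shape ~ size + group + size:group and reports
#' the size-by-group interaction: a significant interaction means the
#' groups' allometric slopes differ, i.e. there is no common allometric
#' component (different groups change shape with size in different ways).
#'
#' @inheritParams procrustes_anova
#' @return A `proc_anova` object whose `size:group` row is the homogeneity
#'   of slopes test.
#' @export
common_allometry_test <- function(aligned, groups = NULL, n_perm = 999L,
                                  seed = NULL, log_size = TRUE) {
  grp <- .resolve_groups(aligned, groups)
  sz <- aligned$centroid_sizes
  spans <- tapply(sz, grp, function(v) diff(range(v)))
  if (any(spans <= 0))
    stop("group(s) with constant centroid size: ",
         paste(names(spans)[spans <= 0], collapse = ", "), call. = FALSE)
  procrustes_anova(aligned, terms = c("size", "group", "size:group"),
                   groups = groups, n_perm = n_perm, seed = seed,
                   log_size = log_size)
}
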