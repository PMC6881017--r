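#' Configure an end-to-end loop-morphometrics analysis
#'
#' @param dataset A `shape_dataset`, or `NULL` if `input` is given.
#' @param input Path to a landmark table (read with
#'   [read_landmark_table()]).
#' @param scheme A `landmark_scheme` or path to a YAML scheme file
#'   (required with `input`).
#' @param metadata Optional path to a metadata CSV (specimen_id, species,
#'   genus).
#' @param dialect Landmark table dialect (see [read_landmark_table()]).
#' @param slide Slide curve semilandmarks during superimposition.
#' @param slide_method Sliding criterion, `"bending"` or `"procrustes"`.
#' @param groups Grouping for CVA/ANOVA: `"species"` or `"genus"`.
#' @param k_retained PC retention rule for the CVA (see [shape_cva()]).
#' @param n_perm ANOVA permutations.
#' @param lasec_iterations LaSEC iterations (0 skips LaSEC).
#' @param seed Master seed; stage seeds are derived as fixed offsets so
#'   each stochastic stage is independently reproducible.
#' @param out_dir Output directory for CSV/JSON tables (`NULL`: no files).
#' @param drop_singletons Drop single-specimen groups before the CVA (with
#'   a message), since a leave-one-out classification cannot use them.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(dataset = NULL, input = NULL, scheme = NULL,
                            metadata = NULL, dialect = "auto", slide = TRUE,
                            slide_method = "bending",
                            groups = "species", k_retained = "var95",
                            n_perm = 999L, lasec_iterations = 0L,
                            seed = 1L, out_dir = NULL,
                            drop_singletons = TRUE) {
  if (is.null(dataset) && is.null(input))
    stop("supply a dataset or an input path", call. = FALSE)
  structure(as.list(environment()), class = "analysis_config")
}

.stage_seed <- function(seed, stage) {
  as.integer(seed) + c(gpa = 0L, anova = 101L, lasec = 202L,
                       simulate = 303L)[[stage]]
}

#' Run the full analysis pipeline
#'
#' Read (or take) a dataset, superimpose with optional semilandmark
#' sliding, then run shape PCA, CVA with leave-one-out classification,
#' Procrustes ANOVAs (shape ~ size, shape ~ group, shape ~ size + group +
#' size:group), and optionally LaSEC. When `out_dir` is set, every result
#' table is written as CSV plus a JSON summary and a manifest recording the
#' configuration, seed and package version.
#'
#' @param config An [analysis_config()].
#' @return List of class `loop_pipeline` with elements `gpa`, `pca`, `cva`,
#'   `anova_size`, `anova_group`, `anova_allometry`, `lasec` (or `NULL`),
#'   `dropped_groups`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  ds <- config$dataset
  if (is.null(ds)) {
    sc <- config$scheme
    if (is.character(sc)) sc <- read_scheme(sc)
    if (!inherits(sc, "landmark_scheme"))
      stop("stage read: a landmark_scheme is required with an input path",
           call. = FALSE)
    ds <- read_landmark_table(config$input, sc, dialect = config$dialect)
    if (!is.null(config$metadata))
      ds <- attach_metadata(ds, read_metadata(config$metadata))
  }
  sliders <- if (isTRUE(config$slide) && length(ds$scheme$curves))
    build_slider_table(ds$scheme) else NULL
  aligned <- gpa(ds, sliders = sliders, slide_method = config$slide_method)
  pca <- shape_pca(aligned)

  grp <- .resolve_groups(aligned, config$groups)
  sizes <- table(grp)
  dropped <- names(sizes)[sizes < 2L]
  keep <- !(as.character(grp) %in% dropped)
  if (length(dropped)) {
    if (!config$drop_singletons)
      stop("stage cva: single-specimen group(s) ",
           paste(dropped, collapse = ", "),
           "; drop them or set drop_singletons = TRUE", call. = FALSE)
    message("dropping single-specimen group(s) from CVA: ",
            paste(dropped, collapse = ", "))
  }
  aligned_cva <- if (all(keep)) aligned else {
    ds_k <- ds[which(keep)]
    gpa(ds_k, sliders = sliders, slide_method = config$slide_method)
  }
  cva <- shape_cva(aligned_cva, groups = config$groups,
                   k_retained = config$k_retained)

  an_seed <- .stage_seed(config$seed, "anova")
  anova_size <- procrustes_anova(aligned, terms = "size",
                                 n_perm = config$n_perm, seed = an_seed)
  anova_group <- procrustes_anova(aligned, terms = "group",
                                  groups = config$groups,
                                  n_perm = config$n_perm, seed = an_seed + 1L)
  anova_allometry <- tryCatch(
    common_allometry_test(aligned, groups = config$groups,
                          n_perm = config$n_perm, seed = an_seed + 2L),
    error = function(e) {
      message("allometry test skipped: ", conditionMessage(e)); NULL
    })
  las <- if (config$lasec_iterations > 0L)
    lasec(ds, n_iterations = config$lasec_iterations,
          seed = .stage_seed(config$seed, "lasec")) else NULL

  out <- structure(list(gpa = aligned, pca = pca, cva = cva,
                        anova_size = anova_size, anova_group = anova_group,
                        anova_allometry = anova_allometry, lasec = las,
                        dropped_groups = dropped, config = config),
                   class = "loop_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  out
}

#' @export
print.loop_pipeline <- function(x, ...) {
  cat("Loop morphometrics pipeline\n")
  cat("  specimens: ", length(x$gpa$ids), "; sliding: ",
      if (x$gpa$slid) "yes" else "no", "\n", sep = "")
  cat(sprintf("  PC1-PC3 variance: %s\n",
              paste(sprintf("%.2f%%", 100 * x$pca$variance_fractions[1:min(3, length(x$pca$variance_fractions))]),
                    collapse = ", ")))
  cat(sprintf("  CVA overall LOO accuracy: %.2f%%", x$cva$overall_accuracy))
  if (length(x$dropped_groups))
    cat(" (dropped: ", paste(x$dropped_groups, collapse = ", "), ")", sep = "")
  cat("\n")
  cat("  ANOVA p: size ", format(x$anova_size$table["size", "p"]),
      ", group ", format(x$anova_group$table["group", "p"]), sep = "")
  if (!is.null(x$anova_allometry))
    cat(", size:group ", format(x$anova_allometry$table["size:group", "p"]),
        sep = "")
  cat("\n")
  if (!is.null(x$lasec))
    cat("  LaSEC median fit at full sampling: ",
        format(x$lasec$median_fit[length(x$lasec$median_fit)]), "\n", sep = "")
  invisible(x)
}

#' Write pipeline result tables
#'
#' CSV tables (PCA variance and scores, Mahalanobis distances, confusion
#' matrix, ANOVA tables, LaSEC trajectory, centroid sizes) plus a JSON
#' summary and a manifest (configuration, seed, package version).
#'
#' @param x A `loop_pipeline`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = TRUE)
  w(data.frame(eigenvalue = x$pca$eigenvalues,
               variance_pct = round(100 * x$pca$variance_fractions, 2)),
    "pca_variance.csv")
  w(round(x$pca$scores, 8), "pca_scores.csv")
  w(round(x$cva$mahalanobis, 3), "mahalanobis.csv")
  w(x$cva$confusion, "confusion.csv")
  w(x$anova_size$table, "anova_size.csv")
  w(x$anova_group$table, "anova_group.csv")
  if (!is.null(x$anova_allometry))
    w(x$anova_allometry$table, "anova_allometry.csv")
  if (!is.null(x$lasec))
    utils::write.csv(lasec_table(x$lasec), file.path(dir, "lasec.csv"),
                     row.names = FALSE)
  w(data.frame(centroid_size = x$gpa$centroid_sizes), "centroid_sizes.csv")
  summary_obj <- list(
    n = length(x$gpa$ids),
    pc_variance_pct = round(100 * x$pca$variance_fractions, 2),
    cva_overall_accuracy_pct = x$cva$overall_accuracy,
    cva_per_group_accuracy_pct = as.list(x$cva$per_group_accuracy),
    anova_p = list(size = x$anova_size$table["size", "p"],
                   group = x$anova_group$table["group", "p"],
                   allometry = if (!is.null(x$anova_allometry))
                     x$anova_allometry$table["size:group", "p"]),
    dropped_groups = x$dropped_groups)
  jsonlite::write_json(summary_obj, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- x$config
  cfg$dataset <- if (!is.null(cfg$dataset)) "<in-memory dataset>" else NULL
  cfg$scheme <- if (inherits(cfg$scheme, "landmark_scheme"))
    "<in-memory scheme>" else cfg$scheme
  manifest <- list(config = cfg[!vapply(cfg, is.null, TRUE)],
                   seed = x$config$seed,
                   package = "loopmorph",
                   version = as.character(utils::packageVersion("loopmorph")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# Previously published values for the three North Pacific long-loop
# datasets, used only for side-by-side comparison when a user supplies
# those datasets' landmark files.
.reference_values <- data.frame(
  dataset = c("bilateral", "bilateral", "bilateral", "bilateral", "bilateral",
              "trabecular", "trabecular", "trabecular", "trabecular",
              "combined", "combined", "combined", "combined", "combined"),
  quantity = c("pc1_variance_pct", "pc2_variance_pct", "pc3_variance_pct",
               "loo_overall_accuracy_pct", "mahalanobis_closest_pair",
               "pc1_variance_pct", "loo_overall_accuracy_pct",
               "mahalanobis_congeners", "per_group_accuracy_min_pct",
               "pc1_variance_pct", "loo_overall_accuracy_pct",
               "genus_loo_overall_accuracy_pct", "mahalanobis_congeners",
               "mahalanobis_closest_pair"),
  value = c(35.93, 15.81, 11.97, 100, 7.588,
            59.12, 72.22, 3.426, 60,
            68.9, 100, 100, 15.201, 10.972))

#' Compare computed quantities with previously published values
#'
#' For whichever of the three classic long-loop datasets are supplied as
#' landmark-table + metadata file pairs, runs the default pipeline and
#' tabulates computed versus published values (PC variance fractions,
#' leave-one-out accuracies, key Mahalanobis distances), with a
#' retained-PC sensitivity sweep of the Mahalanobis distances attached as
#' the `"k_sweep"` attribute. Missing datasets are skipped with a notice;
#' with no data present an empty report is returned.
#'
#' @param bilateral,trabecular,combined Optional `list(landmarks = path,
#'   metadata = path)` for each dataset (bilateral scheme for the first,
#'   shared/trabecular scheme for the others).
#' @param k_retained PC retention rule passed to the CVA.
#' @param seed Seed for the ANOVA permutation stages.
#' @return Data.frame with columns `dataset`, `quantity`, `computed`,
#'   `reference`, `abs_dev`; class `reference_comparison`.
#' @export
compare_reference_values <- function(bilateral = NULL, trabecular = NULL,
                                     combined = NULL, k_retained = "var95",
                                     seed = 1L) {
  inputs <- list(bilateral = bilateral, trabecular = trabecular,
                 combined = combined)
  schemes <- list(bilateral = loop_scheme("bilateral"),
                  trabecular = loop_scheme("trabecular"),
                  combined = loop_scheme("shared"))
  rows <- list()
  sweeps <- list()
  for (nm in names(inputs)) {
    spec <- inputs[[nm]]
    if (is.null(spec)) next
    if (!file.exists(spec$landmarks) ||
        (!is.null(spec$metadata) && !file.exists(spec$metadata))) {
      message("skipping ", nm, ": file not found")
      next
    }
    ds <- read_landmark_table(spec$landmarks, schemes[[nm]])
    if (!is.null(spec$metadata))
      ds <- attach_metadata(ds, read_metadata(spec$metadata))
    res <- run_pipeline(analysis_config(dataset = ds, k_retained = k_retained,
                                        n_perm = 999L, seed = seed))
    D <- res$cva$mahalanobis
    off <- D[lower.tri(D)]
    computed <- c(pc1_variance_pct = 100 * res$pca$variance_fractions[1],
                  pc2_variance_pct = 100 * res$pca$variance_fractions[2],
                  pc3_variance_pct = 100 * res$pca$variance_fractions[3],
                  loo_overall_accuracy_pct = res$cva$overall_accuracy,
                  per_group_accuracy_min_pct = min(res$cva$per_group_accuracy),
                  mahalanobis_closest_pair = min(off))
    if (!is.null(ds$genus) && nm == "combined") {
      gcva <- shape_cva(res$gpa, groups = "genus", k_retained = k_retained)
      computed["genus_loo_overall_accuracy_pct"] <- gcva$overall_accuracy
    }
    ref <- .reference_values[.reference_values$dataset == nm, ]
    ref <- ref[ref$quantity %in% names(computed), ]
    rows[[nm]] <- data.frame(dataset = nm, quantity = ref$quantity,
                             computed = unname(computed[ref$quantity]),
                             reference = ref$value,
                             abs_dev = abs(unname(computed[ref$quantity]) - ref$value))
    sweeps[[nm]] <- mahalanobis_k_sweep(res$cva_aligned %||% res$gpa)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset = character(), quantity = character(),
               computed = numeric(), reference = numeric(),
               abs_dev = numeric())
  rownames(out) <- NULL
  attr(out, "k_sweep") <- sweeps
  class(out) <- c("reference_comparison", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
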