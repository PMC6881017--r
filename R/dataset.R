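#' Assemble a shape dataset
#'
#' Bundles a block of specimen configurations (all digitized under one
#' scheme) with species and optional genus labels. Coordinates are unitless
#' reals in a consistent per-dataset unit; no missing values are allowed.
#'
#' @param coords Numeric array `p x 3 x n` (points, xyz, specimens), or a
#'   list of `p x 3` matrices.
#' @param scheme The `landmark_scheme` the configurations follow.
#' @param species Character vector of species labels, length `n`.
#' @param genus Optional character vector of genus labels, length `n`.
#' @param ids Specimen identifiers; defaults to zero-padded integers in
#'   input order.
#' @return An object of class `shape_dataset`: list with elements `coords`
#'   (p x 3 x n array), `scheme`, `species`, `genus`, `ids`.
#' @export
shape_dataset <- function(coords, scheme, species = NULL, genus = NULL,
                          ids = NULL) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords), dim = c(dim(coords[[1]]), length(coords)))
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n <- dim(coords)[3]
  p <- dim(coords)[1]
  if (is.null(ids)) ids <- sprintf("spec%03d", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (length(ids) != n) stop("ids length must match specimen count", call. = FALSE)
  if (p != n_points(scheme))
    stop("configurations have ", p, " points but scheme defines ",
         n_points(scheme), call. = FALSE)
  bad <- which(apply(coords, 3, function(m) any(!is.finite(m))))
  if (length(bad))
    stop("non-finite coordinates in specimen(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  if (is.null(species)) species <- rep(NA_character_, n)
  species <- as.character(species)
  if (length(species) != n) stop("species length must match specimen count", call. = FALSE)
  if (!is.null(genus)) {
    genus <- as.character(genus)
    if (length(genus) != n) stop("genus length must match specimen count", call. = FALSE)
  }
  dimnames(coords) <- list(point_names(scheme), c("x", "y", "z"), ids)
  structure(list(coords = coords, scheme = scheme, species = species,
                 genus = genus, ids = ids),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat("Shape dataset: ", dim(x$coords)[3], " specimens x ",
      dim(x$coords)[1], " points (3D), scheme: ", x$scheme$loop_type,
      " loop\n", sep = "")
  sp <- x$species[!is.na(x$species)]
  if (length(sp)) {
    tab <- table(x$species)
    cat("  species: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of specimens / points
#' @param dataset A `shape_dataset`.
#' @return Integer count.
#' @export
n_specimens <- function(dataset) dim(dataset$coords)[3]

#' Subset specimens of a shape dataset
#' @param x A `shape_dataset`.
#' @param i Specimen indices, logical mask or ids.
#' @param ... Unused.
#' @return A `shape_dataset` with the selected specimens, order preserved.
#' @export
`[.shape_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  shape_dataset(x$coords[, , i, drop = FALSE], x$scheme,
                species = x$species[i],
                genus = if (!is.null(x$genus)) x$genus[i],
                ids = x$ids[i])
}

#' Reduce a dataset to the landmarks shared across loop types
#'
#' Keeps the named fixed landmarks (dropping the rest) and all curve
#' semilandmarks, so datasets digitized under different loop schemes can be
#' pooled over their shared points. The two built-in loop schemes share 15
#' fixed landmarks and all three curves, so a 41-point bilateral dataset
#' reduces to 36 points.
#'
#' @param dataset A `shape_dataset`.
#' @param shared_names Fixed-landmark names to keep (default: the built-in
#'   shared set).
#' @return A `shape_dataset` under a reduced scheme (loop type `"generic"`).
#' @export
subset_shared_landmarks <- function(dataset, shared_names = shared_landmark_names()) {
  stopifnot(inherits(dataset, "shape_dataset"))
  shared_names <- as.character(shared_names)
  if (!length(shared_names)) stop("shared_names must be non-empty", call. = FALSE)
  miss <- setdiff(shared_names, dataset$scheme$fixed_names)
  if (length(miss))
    stop("landmarks not in scheme: ", paste(miss, collapse = ", "), call. = FALSE)
  sc <- dataset$scheme
  keep_fixed <- which(sc$fixed_names %in% shared_names)
  # anchors must survive the reduction for the curves to stay slidable
  for (cv in sc$curves)
    for (anc in c(cv$anchor_start, cv$anchor_end))
      if (!identical(anc, "free") && !anc %in% sc$fixed_names[keep_fixed])
        stop("curve '", cv$name, "' anchor '", anc,
             "' not among shared_names", call. = FALSE)
  semi_idx <- unlist(lapply(sc$curves, `[[`, "point_indices"), use.names = FALSE)
  keep <- c(keep_fixed, semi_idx)
  new_scheme <- landmark_scheme(sc$fixed_names[keep_fixed],
                                lapply(sc$curves, function(cv)
                                  curve_spec(cv$name, cv$n_semilandmarks,
                                             cv$anchor_start, cv$anchor_end)),
                                loop_type = "generic")
  shape_dataset(dataset$coords[keep, , , drop = FALSE], new_scheme,
                species = dataset$species, genus = dataset$genus,
                ids = dataset$ids)
}

#' Names of the fixed landmarks shared between loop types
#' @return Character vector of the 15 shared fixed-landmark names.
#' @export
shared_landmark_names <- function() .shared_fixed

#' Pool two datasets over their shared landmarks
#'
#' Reduces each dataset to `shared_names` via [subset_shared_landmarks()]
#' and concatenates specimens.
#'
#' @param a,b `shape_dataset` objects whose schemes contain `shared_names`.
#' @param shared_names Fixed landmarks to pool over.
#' @return A combined `shape_dataset`.
#' @export
pool_datasets <- function(a, b, shared_names = shared_landmark_names()) {
  ra <- subset_shared_landmarks(a, shared_names)
  rb <- subset_shared_landmarks(b, shared_names)
  if (n_points(ra$scheme) != n_points(rb$scheme))
    stop("reduced schemes disagree in point count", call. = FALSE)
  shape_dataset(
    array(c(ra$coords, rb$coords),
          dim = c(dim(ra$coords)[1:2], n_specimens(ra) + n_specimens(rb))),
    ra$scheme,
    species = c(ra$species, rb$species),
    genus = c(if (is.null(ra$genus)) rep(NA_character_, n_specimens(ra)) else ra$genus,
              if (is.null(rb$genus)) rep(NA_character_, n_specimens(rb)) else rb$genus),
    ids = c(ra$ids, rb$ids))
}
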