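#' Define a semilandmark curve
#'
#' A curve is an ordered run of sliding semilandmarks digitized along an
#' anatomical arc (e.g. the crus or the transverse band of a brachidium).
#' Curve order defines sliding neighbours; endpoints may be anchored to fixed
#' landmarks, in which case the semilandmarks adjacent to an anchor slide
#' against that fixed point.
#'
#' @param name Curve label.
#' @param n_semilandmarks Number of sliding semilandmarks on the curve
#'   (at least 2).
#' @param anchor_start,anchor_end Fixed-landmark names the curve runs between,
#'   or `"free"` for an unanchored end.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(name, n_semilandmarks, anchor_start = "free",
                       anchor_end = "free") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_semilandmarks <- as.integer(n_semilandmarks)
  if (is.na(n_semilandmarks) || n_semilandmarks < 2L)
    stop("curve '", name, "': n_semilandmarks must be >= 2", call. = FALSE)
  structure(
    list(name = name, n_semilandmarks = n_semilandmarks,
         anchor_start = anchor_start, anchor_end = anchor_end,
         point_indices = integer(0)),
    class = "curve_spec")
}

#' Define a landmark scheme
#'
#' A scheme fixes the identity and order of all points in a configuration:
#' the fixed landmarks first, then each curve's semilandmarks in curve order.
#' All coordinates handled by the package are 3D.
#'
#' @param fixed_names Character vector of unique fixed-landmark labels.
#' @param curves List of [curve_spec()] objects (may be empty).
#' @param loop_type One of `"bilateral"`, `"trabecular"`, `"generic"`.
#' @return An object of class `landmark_scheme` with the per-curve
#'   `point_indices` resolved (1-based, after the fixed block).
#' @seealso [loop_scheme()] for the built-in loop presets,
#'   [build_slider_table()] for the sliding-neighbour table.
#' @export
landmark_scheme <- function(fixed_names, curves = list(),
                            loop_type = c("generic", "bilateral", "trabecular")) {
  loop_type <- match.arg(loop_type)
  fixed_names <- as.character(fixed_names)
  if (length(fixed_names) == 0L || anyNA(fixed_names) || any(!nzchar(fixed_names)))
    stop("fixed_names must be non-empty labels", call. = FALSE)
  if (anyDuplicated(fixed_names))
    stop("fixed_names must be unique", call. = FALSE)
  if (!is.list(curves) || (length(curves) && !all(vapply(curves, inherits, TRUE, "curve_spec"))))
    stop("curves must be a list of curve_spec objects", call. = FALSE)
  cnames <- vapply(curves, `[[`, "", "name")
  if (anyDuplicated(cnames)) stop("curve names must be unique", call. = FALSE)
  offset <- length(fixed_names)
  for (i in seq_along(curves)) {
    for (a in c("anchor_start", "anchor_end")) {
      anc <- curves[[i]][[a]]
      if (!identical(anc, "free") && !anc %in% fixed_names)
        stop("curve '", curves[[i]]$name, "': anchor '", anc,
             "' is not a fixed landmark", call. = FALSE)
    }
    m <- curves[[i]]$n_semilandmarks
    curves[[i]]$point_indices <- offset + seq_len(m)
    offset <- offset + m
  }
  structure(
    list(fixed_names = fixed_names, curves = curves,
         loop_type = loop_type, dimension = 3L),
    class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme (", x$loop_type, " loop)\n", sep = "")
  cat("  fixed landmarks: ", length(x$fixed_names), "\n", sep = "")
  for (cv in x$curves)
    cat("  curve '", cv$name, "': ", cv$n_semilandmarks, " semilandmarks (",
        cv$anchor_start, " -> ", cv$anchor_end, ")\n", sep = "")
  cat("  total points: ", n_points(x), "\n", sep = "")
  invisible(x)
}

#' Total number of points in a scheme
#' @param scheme A `landmark_scheme`.
#' @return Integer: fixed landmarks plus all semilandmarks.
#' @export
n_points <- function(scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  length(scheme$fixed_names) +
    sum(vapply(scheme$curves, `[[`, 0L, "n_semilandmarks"))
}

#' Point labels in configuration order
#' @param scheme A `landmark_scheme`.
#' @return Character vector of length [n_points()]: fixed-landmark names
#'   followed by `<curve>_sl<k>` semilandmark labels.
#' @export
point_names <- function(scheme) {
  c(scheme$fixed_names,
    unlist(lapply(scheme$curves, function(cv)
      paste0(cv$name, "_sl", seq_len(cv$n_semilandmarks))), use.names = FALSE))
}

# Shared fixed landmarks present in both loop types (Type I junction points
# and Type II geometric extremes on the loop, cardinalia and septum).
.shared_fixed <- c(
  "cardinal_process", "hinge_tooth_socket", "inner_hinge_plate",
  "outer_hinge_plate", "septum_base_posterior", "septum_crest",
  "septum_anterior_end", "crural_base", "crural_process_tip",
  "descending_branch_base", "descending_septal_attachment",
  "ascending_branch_crest", "transverse_band_lateral",
  "transverse_band_medial", "loop_anterior_extreme")

# Extra fixed landmarks only present on bilateral loops (connecting-band
# region between descending and ascending branches).
.bilateral_extra <- c(
  "connecting_band_dorsal_origin", "connecting_band_ventral_insertion",
  "connecting_band_midpoint", "ascending_branch_lateral_flare",
  "descending_branch_anterior_edge")

.loop_curves <- function() list(
  curve_spec("crus", 7L, "crural_base", "crural_process_tip"),
  curve_spec("descending_ascending", 8L, "descending_branch_base",
             "ascending_branch_crest"),
  curve_spec("transverse_band", 6L, "transverse_band_lateral",
             "transverse_band_medial"))

#' Built-in loop landmark schemes
#'
#' Presets for the two long-loop types digitized on one (symmetric) half of
#' the structure: the bilateral loop carries 20 fixed landmarks, the
#' trabecular loop the 15 landmarks shared between both types; both carry
#' three curves (crus, descending--ascending branch, transverse band) with
#' 7 + 8 + 6 = 21 sliding semilandmarks. `"shared"` is the trabecular-sized
#' scheme used when pooling both loop types over their shared landmarks.
#'
#' @param type `"bilateral"`, `"trabecular"` or `"shared"`.
#' @return A `landmark_scheme` (41, 36 and 36 points respectively).
#' @export
loop_scheme <- function(type = c("bilateral", "trabecular", "shared")) {
  type <- match.arg(type)
  if (type == "bilateral")
    landmark_scheme(c(.shared_fixed, .bilateral_extra), .loop_curves(),
                    loop_type = "bilateral")
  else
    landmark_scheme(.shared_fixed, .loop_curves(),
                    loop_type = if (type == "trabecular") "trabecular" else "generic")
}

#' Build the sliding-neighbour table for a scheme
#'
#' One row per sliding semilandmark, giving the point indices (`before`,
#' `slide`, `after`) that define its tangent direction during
#' bending-energy sliding. Semilandmarks adjacent to an anchored curve end
#' use that fixed landmark as neighbour; on a free end the two nearest
#' semilandmarks are used (so a free-ended curve needs length >= 3).
#'
#' @param scheme A `landmark_scheme` with at least one curve.
#' @return A data.frame with integer columns `before`, `slide`, `after`;
#'   class `slider_table`. Indices are 1-based configuration indices.
#' @export
build_slider_table <- function(scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  if (!length(scheme$curves))
    stop("scheme has no curves: nothing slides", call. = FALSE)
  rows <- list()
  fixed_idx <- function(name) match(name, scheme$fixed_names)
  for (cv in scheme$curves) {
    idx <- cv$point_indices
    m <- length(idx)
    free_start <- identical(cv$anchor_start, "free")
    free_end <- identical(cv$anchor_end, "free")
    if ((free_start || free_end) && m < 3L)
      stop("curve '", cv$name, "' too short for free ends: ",
           "no sliding direction definable", call. = FALSE)
    for (j in seq_len(m)) {
      slide <- idx[j]
      before <- if (j > 1L) idx[j - 1L]
        else if (!free_start) fixed_idx(cv$anchor_start) else NA_integer_
      after <- if (j < m) idx[j + 1L]
        else if (!free_end) fixed_idx(cv$anchor_end) else NA_integer_
      # free endpoint: slide along the chord of the two nearest curve points
      if (is.na(before)) { before <- idx[j + 1L]; after <- idx[j + 2L] }
      if (is.na(after)) { after <- idx[j - 1L]; before <- idx[j - 2L] }
      rows[[length(rows) + 1L]] <- c(before, slide, after)
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("before", "slide", "after")
  if (anyDuplicated(tab$slide))
    stop("a point is claimed as sliding by more than one curve", call. = FALSE)
  class(tab) <- c("slider_table", "data.frame")
  tab
}

#' Write / read a landmark scheme as a YAML file
#'
#' Human-editable serialization of a scheme (fixed landmark names, curves
#' with anchors and semilandmark counts, loop type).
#'
#' @param scheme A `landmark_scheme`.
#' @param path File path.
#' @return `write_scheme` returns `path` invisibly; `read_scheme` returns the
#'   `landmark_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  obj <- list(
    loop_type = scheme$loop_type,
    fixed_names = scheme$fixed_names,
    curves = lapply(scheme$curves, function(cv)
      list(name = cv$name, n_semilandmarks = cv$n_semilandmarks,
           anchor_start = cv$anchor_start, anchor_end = cv$anchor_end)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  curves <- lapply(obj$curves, function(cv)
    curve_spec(cv$name, cv$n_semilandmarks, cv$anchor_start, cv$anchor_end))
  landmark_scheme(obj$fixed_names, curves, loop_type = obj$loop_type)
}
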