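#' Thin-plate-spline bending energy matrix of a reference configuration
#'
#' Builds the bending energy matrix of the 3D thin-plate spline anchored on
#' `reference`, using the 3D kernel U(r) = -r. The quadratic form
#' `t(y) %*% B %*% y` (applied per coordinate axis) measures the non-affine
#' deformation needed to map the reference onto a target; affine
#' transformations of the reference incur zero energy.
#'
#' @param reference `p x 3` coordinate matrix without coincident points.
#' @return Symmetric positive semi-definite `p x p` matrix.
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as.matrix(reference)
  p <- nrow(reference)
  D <- as.matrix(stats::dist(reference))
  coincident <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(coincident))
    stop("coincident reference points ", coincident[1, 1], " and ",
         coincident[1, 2], call. = FALSE)
  K <- -D
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  Linv <- solve(L)
  B <- Linv[seq_len(p), seq_len(p), drop = FALSE]
  (B + t(B)) / 2
}

#' Bending energy of a target configuration relative to a reference
#'
#' Sum over coordinate axes of the quadratic form of the reference's
#' bending energy matrix.
#'
#' @param config `p x 3` target configuration.
#' @param be Bending energy matrix from [bending_energy_matrix()].
#' @return Non-negative scalar (up to numerical noise).
#' @export
bending_energy <- function(config, be) {
  config <- as.matrix(config)
  sum(vapply(1:3, function(d) drop(crossprod(config[, d], be %*% config[, d])), 0))
}

# Slide the semilandmarks of one configuration along current-neighbour
# tangents. method "bending": displacements jointly minimize the TPS
# bending energy relative to the reference carrying `be` (restricted
# quadratic minimum in closed form). method "procrustes": each point moves
# to the tangent projection closest to the reference (minimized Procrustes
# distance), which decouples point-wise.
.slide_one <- function(Y, sliders, be, reference = NULL,
                       method = c("bending", "procrustes")) {
  method <- match.arg(method)
  s <- sliders$slide
  U <- Y[sliders$after, , drop = FALSE] - Y[sliders$before, , drop = FALSE]
  len <- sqrt(rowSums(U^2))
  if (any(len == 0))
    stop("zero-length tangent at point ", s[which(len == 0)[1]], call. = FALSE)
  U <- U / len
  if (method == "bending") {
    A <- be[s, s, drop = FALSE] * tcrossprod(U)
    b <- rowSums((be %*% Y)[s, , drop = FALSE] * U)
    t_hat <- tryCatch(solve(A, -b), error = function(e) -qr.coef(qr(A), b))
    t_hat[is.na(t_hat)] <- 0
  } else {
    t_hat <- rowSums((reference[s, , drop = FALSE] - Y[s, , drop = FALSE]) * U)
  }
  Y[s, ] <- Y[s, ] + U * t_hat
  Y
}

#' Slide semilandmarks of every specimen against the consensus
#'
#' One bending-energy sliding pass: each sliding semilandmark of each
#' aligned specimen moves along its tangent direction (the unit vector from
#' its `before` to its `after` neighbour, recomputed from current
#' positions); the displacement magnitudes jointly minimize the
#' thin-plate-spline bending energy of the specimen relative to the
#' consensus, restricted to those directions. Fixed landmarks never move.
#' A pass can only decrease (or hold) each specimen's bending energy.
#'
#' @param aligned A `gpa` object (or list with `coords` and `consensus`).
#' @param sliders A `slider_table`.
#' @param method `"bending"` (thin-plate-spline bending energy, default) or
#'   `"procrustes"` (each semilandmark moves to the tangent position
#'   closest to the consensus).
#' @return `p x 3 x n` array of updated coordinates. Note the updated
#'   specimens are no longer exactly centered/unit-size; [gpa()] re-imposes
#'   those constraints when it drives the sliding internally.
#' @export
slide_semilandmarks <- function(aligned, sliders,
                                method = c("bending", "procrustes")) {
  method <- match.arg(method)
  stopifnot(inherits(sliders, "slider_table"))
  co <- aligned$coords
  be <- if (method == "bending") bending_energy_matrix(aligned$consensus)
  out <- co
  for (i in seq_len(dim(co)[3]))
    out[, , i] <- .slide_one(co[, , i], sliders, be,
                             reference = aligned$consensus, method = method)
  out
}

# 3D thin-plate-spline interpolation: values observed at ctrl points,
# evaluated at target points (used by the synthetic generator to build
# smooth species-mean deformations).
.tps_interpolate <- function(ctrl, values, targets) {
  ctrl <- as.matrix(ctrl); values <- as.matrix(values); targets <- as.matrix(targets)
  m <- nrow(ctrl)
  K <- -as.matrix(stats::dist(ctrl))
  P <- cbind(1, ctrl)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(values, matrix(0, 4L, ncol(values)))
  wa <- solve(L, rhs)
  w <- wa[seq_len(m), , drop = FALSE]
  a <- wa[m + 1:4, , drop = FALSE]
  d2 <- pmax(outer(rowSums(targets^2), rowSums(ctrl^2), `+`) -
               2 * tcrossprod(targets, ctrl), 0)
  Dt <- -sqrt(d2)
  Dt %*% w + cbind(1, targets) %*% a
}
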