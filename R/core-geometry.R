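# Fundamental types shared by every stage: point clouds, SE(3) transforms,
# sparse correspondences and displacement fields. Units are millimetres,
# coordinates (x, y, z), right-handed.

#' Construct a point cloud
#'
#' The universal currency of the pipeline: an N x 3 matrix of coordinates in
#' millimetres, with optional per-point structure labels and optional
#' provenance indices into an originating cloud (used by the simulator to
#' record which variant vertex each partial-view point came from).
#'
#' @param points numeric N x 3 matrix (or coercible), columns x, y, z in mm.
#' @param labels optional per-point structure identifier, length N.
#' @param source_index optional integer vector, length N, of 1-based indices
#'   into the cloud this one was sampled from.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, labels = NULL, source_index = NULL) {
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3L) {
    err("points must be an N x 3 matrix", "invalid_cloud_error")
  }
  storage.mode(points) <- "double"
  if (nrow(points) < 1L) err("a point cloud needs at least one point", "invalid_cloud_error")
  if (!all(is.finite(points))) err("all coordinates must be finite", "invalid_cloud_error")
  if (!is.null(labels) && length(labels) != nrow(points)) {
    err("labels must have one entry per point", "invalid_cloud_error")
  }
  if (!is.null(source_index)) {
    source_index <- as.integer(source_index)
    if (length(source_index) != nrow(points) || anyNA(source_index) || any(source_index < 1L)) {
      err("source_index must be positive integers, one per point", "invalid_cloud_error")
    }
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, labels = labels, source_index = source_index),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s%s>\n", nrow(x$points),
              if (!is.null(x$labels)) sprintf(", %d structures", length(unique(x$labels))) else "",
              if (!is.null(x$source_index)) ", with provenance" else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param p a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(p) nrow(p$points)

as_cloud_matrix <- function(p) {
  if (inherits(p, "point_cloud")) p$points else as.matrix(p)
}

#' Construct a rigid transform
#'
#' An element of SE(3): a proper rotation plus a translation in mm. The
#' rotation is validated to be orthonormal with determinant +1 (within 1e-9).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    err("rotation must be 3x3 and translation length 3", "invalid_transform_error")
  }
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    err("transform entries must be finite", "invalid_transform_error")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    err("rotation is not orthonormal within 1e-9", "invalid_transform_error")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    err("rotation determinant is not +1 within 1e-9", "invalid_transform_error")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return a `rigid_transform` with identity rotation and zero translation.
#' @export
rigid_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: rotation angle %.3f deg, |t| = %.4f mm>\n",
              rotation_angle(x), sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Rotation angle of a rigid transform
#' @param t a `rigid_transform`.
#' @return rotation magnitude in degrees.
#' @export
rotation_angle <- function(t) {
  ct <- (sum(diag(t$rotation)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Rotation matrix about an axis
#' @param axis length-3 axis (normalized internally).
#' @param degrees rotation angle in degrees.
#' @return 3 x 3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, degrees) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) err("axis must be nonzero", "config_error")
  a <- axis / n
  th <- degrees * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Construct a correspondence set
#'
#' Sparse (u, v) index pairs linking a source cloud (index u) to a target
#' cloud (index v), 1-based. Duplicated pairs are rejected.
#'
#' @param pairs K x 2 integer matrix, columns u (source) and v (target).
#' @return an object of class `correspondence_set`.
#' @export
correspondence_set <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || nrow(pairs) < 1L) {
    err("pairs must be a K x 2 matrix", "invalid_correspondence_error")
  }
  storage.mode(pairs) <- "integer"
  if (anyNA(pairs) || any(pairs < 1L)) {
    err("correspondence indices must be positive integers", "invalid_correspondence_error")
  }
  if (anyDuplicated(pairs) > 0L) {
    err("duplicate (u, v) pairs are not allowed", "invalid_correspondence_error")
  }
  dimnames(pairs) <- list(NULL, c("u", "v"))
  structure(list(pairs = pairs), class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("<correspondence_set: %d pairs>\n", nrow(x$pairs)))
  invisible(x)
}

check_correspondences <- function(sigma, n_source, n_target) {
  if (!inherits(sigma, "correspondence_set")) {
    err("sigma must be a correspondence_set", "invalid_correspondence_error")
  }
  if (any(sigma$pairs[, 1] > n_source) || any(sigma$pairs[, 2] > n_target)) {
    err("correspondence indices exceed cloud sizes", "invalid_correspondence_error")
  }
  invisible(sigma)
}

#' Construct a displacement field
#'
#' Per-point 3-D motion vectors in mm, aligned index-for-index with a source
#' point cloud.
#'
#' @param vectors numeric N x 3 matrix of motion vectors.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L) err("vectors must be N x 3", "invalid_field_error")
  storage.mode(vectors) <- "double"
  if (!all(is.finite(vectors))) err("all components must be finite", "invalid_field_error")
  dimnames(vectors) <- list(NULL, c("dx", "dy", "dz"))
  structure(list(vectors = vectors), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  nrm <- sqrt(rowSums(x$vectors^2))
  cat(sprintf("<displacement_field: %d vectors, mean |v| = %.4f mm>\n",
              nrow(x$vectors), mean(nrm)))
  invisible(x)
}

#' Apply a rigid transform to a point cloud
#'
#' Each output point is `rotation %*% point + translation`; labels and
#' provenance indices are carried through unchanged.
#'
#' @param t a `rigid_transform`.
#' @param p a `point_cloud` (or bare N x 3 matrix, returned as a matrix).
#' @return transformed cloud of the same type as `p`.
#' @export
apply_rigid <- function(t, p) {
  if (!inherits(t, "rigid_transform")) {
    t <- tryCatch(rigid_transform(t$rotation, t$translation),
                  error = function(e) err("invalid rigid transform", "invalid_transform_error"))
  }
  m <- as_cloud_matrix(p)
  out <- m %*% t(t$rotation)
  out <- sweep(out, 2, t$translation, "+")
  if (inherits(p, "point_cloud")) {
    point_cloud(out, labels = p$labels, source_index = p$source_index)
  } else {
    out
  }
}

#' Compose two rigid transforms
#'
#' `apply_rigid(compose_rigid(a, b), p)` equals `apply_rigid(a, apply_rigid(b, p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return their composition as a `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  if (!inherits(a, "rigid_transform") || !inherits(b, "rigid_transform")) {
    err("both arguments must be rigid_transform objects", "invalid_transform_error")
  }
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse transform.
#' @export
invert_rigid <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Least-squares rigid fit between matched points
#'
#' Closed-form orthogonal-Procrustes (Kabsch) solution minimizing the sum of
#' squared distances between matched points, with the reflection case
#' corrected so the result is a proper rotation.
#'
#' @param src,dst `point_cloud` objects (or N x 3 matrices).
#' @param pairs a `correspondence_set`; `NULL` pairs points index-for-index
#'   (requires equal sizes).
#' @return the optimal `rigid_transform` mapping `src` onto `dst`.
#' @export
fit_rigid <- function(src, dst, pairs = NULL) {
  S <- as_cloud_matrix(src)
  D <- as_cloud_matrix(dst)
  if (is.null(pairs)) {
    if (nrow(S) != nrow(D)) err("src and dst sizes differ; supply pairs", "degenerate_fit_error")
    A <- S
    B <- D
  } else {
    check_correspondences(pairs, nrow(S), nrow(D))
    A <- S[pairs$pairs[, 1], , drop = FALSE]
    B <- D[pairs$pairs[, 2], , drop = FALSE]
  }
  if (nrow(A) < 3L) err("need at least 3 correspondence pairs", "degenerate_fit_error")
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  # collinear (or coincident) source configurations leave the rotation
  # under-determined about the line
  sv_src <- svd(Ac, nu = 0, nv = 0)$d
  if (sv_src[2] <= max(sv_src[1], 1) * 1e-9) {
    err("correspondences are collinear or coincident", "degenerate_fit_error")
  }
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cb - as.numeric(R %*% ca))
}
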