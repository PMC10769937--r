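# Evaluation metrics: Chamfer distance, mean displacement error, structure-
# restricted landmark error, and the visible-points ratio.

#' Chamfer distance between two point clouds
#'
#' Symmetric mean nearest-neighbour distance with non-squared Euclidean
#' norms, in mm:
#' `CD(A,B) = mean_x min_y |x - y| + mean_y min_x |x - y|`.
#'
#' @param a,b `point_cloud` objects or N x 3 matrices (both non-empty).
#' @return scalar distance (mm).
#' @export
chamfer_distance <- function(a, b) {
  A <- as_cloud_matrix(a)
  B <- as_cloud_matrix(b)
  if (nrow(A) < 1L || nrow(B) < 1L) err("clouds must be non-empty", "precondition_error")
  mean(cpp_nn(A, B)$dist) + mean(cpp_nn(B, A)$dist)
}

#' Mean displacement error
#'
#' Mean Euclidean norm of the difference between an estimated and a
#' ground-truth displacement field, in mm. Dataset-level summaries are the
#' mean of per-sample values.
#'
#' @param est,gt `displacement_field` objects (or N x 3 matrices) of equal
#'   length.
#' @return scalar error (mm).
#' @export
mde <- function(est, gt) {
  E <- if (inherits(est, "displacement_field")) est$vectors else as.matrix(est)
  G <- if (inherits(gt, "displacement_field")) gt$vectors else as.matrix(gt)
  if (nrow(E) != nrow(G)) err("displacement fields differ in length", "precondition_error")
  mean(sqrt(rowSums((E - G)^2)))
}

#' Structure-restricted landmark error
#'
#' For every landmark of the (deformed) ex vivo set, the distance to the
#' nearest in vivo landmark *of the same structure*; the result is the mean
#' over all ex vivo landmarks. Structures present on only one side are
#' skipped and reported in the `skipped` attribute.
#'
#' @param l_exv,l_inv named lists of L x 3 landmark matrices keyed by
#'   structure id.
#' @return scalar error (mm) with attribute `skipped` (character).
#' @export
landmark_error <- function(l_exv, l_inv) {
  shared <- intersect(names(l_exv), names(l_inv))
  if (length(shared) == 0L) err("no shared structures between landmark sets", "precondition_error")
  skipped <- setdiff(union(names(l_exv), names(l_inv)), shared)
  dists <- unlist(lapply(shared, function(k) {
    E <- as.matrix(l_exv[[k]])
    V <- as.matrix(l_inv[[k]])
    cpp_nn(E, V)$dist
  }))
  structure(mean(dists), skipped = skipped)
}

#' Visible-points ratio
#'
#' Fraction of a shape variant's points present in the partial target cloud,
#' `|target| / |variant|`.
#'
#' @param target partial `point_cloud`.
#' @param variant complete variant `point_cloud`.
#' @return scalar in (0, 1] for valid samples.
#' @export
visible_ratio <- function(target, variant) {
  nv <- n_points(variant)
  if (nv < 1L) err("variant cloud is empty", "precondition_error")
  n_points(target) / nv
}

# displace landmark positions by the field of the nearest template vertex
deform_landmarks <- function(landmarks, template_cloud, field) {
  tm <- as_cloud_matrix(template_cloud)
  lapply(landmarks, function(L) {
    L <- as.matrix(L)
    nn <- cpp_nn(L, tm)$idx
    L + field$vectors[nn, , drop = FALSE]
  })
}

#' Evaluate a registration result against a synthetic sample
#'
#' Computes the full metric report: mean displacement error against the
#' ground-truth field, Chamfer distance between the deformed full template
#' and the target (unmasked), landmark error with template landmarks carried
#' along the estimated field (nearest-vertex displacement), and the sample's
#' visible-points ratio.
#'
#' @param result a `registration_result` (field in the original template
#'   frame) or a bare `displacement_field`.
#' @param sample an `ear_sample`.
#' @param sample_id identifier recorded in the report.
#' @return a one-row data.frame of class `metric_report` with columns
#'   `sample_id`, `mde`, `chamfer`, `landmark_error`, `visible_ratio`.
#' @export
evaluate_sample <- function(result, sample, sample_id = "sample") {
  field <- if (inherits(result, "registration_result")) result$field else result
  if (!inherits(field, "displacement_field")) {
    err("result must carry a displacement_field", "precondition_error")
  }
  if (nrow(field$vectors) != n_points(sample$template)) {
    err("result is not aligned with the sample's template", "precondition_error")
  }
  deformed <- sample$template$points + field$vectors
  rep_ <- data.frame(
    sample_id = sample_id,
    mde = mde(field, sample$gt_displacement),
    chamfer = chamfer_distance(deformed, sample$target),
    landmark_error = as.numeric(landmark_error(
      deform_landmarks(sample$landmarks_template, sample$template, field),
      sample$landmarks_target)),
    visible_ratio = sample$visible_ratio,
    stringsAsFactors = FALSE
  )
  class(rep_) <- c("metric_report", "data.frame")
  rep_
}
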