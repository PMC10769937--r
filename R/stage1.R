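# Stage 1 of the pipeline: estimate an initial rigid alignment and a sparse
# correspondence set between the complete template and the partial target,
# through pluggable backends. The "descriptor" backend is a classical
# geometric matcher (voxel downsampling, normal-histogram descriptors,
# mutual matching, RANSAC); the "oracle" backend exploits the simulator's
# provenance indices and isolates stage-2 testing from stage-1 quality.

#' Stage-one result
#'
#' @param transform estimated `rigid_transform` aligning source to target.
#' @param correspondences sparse `correspondence_set` (source u, target v).
#' @param inlier_rmse root-mean-square residual (mm) of the correspondences
#'   under the transform.
#' @param backend_name backend that produced the result.
#' @return an object of class `stage_one_result`.
#' @export
stage_one_result <- function(transform, correspondences, inlier_rmse, backend_name) {
  if (!inherits(transform, "rigid_transform")) err("invalid transform", "invalid_transform_error")
  if (!inherits(correspondences, "correspondence_set")) {
    err("correspondences missing", "registration_failure_error")
  }
  if (!is.finite(inlier_rmse) || inlier_rmse < 0) {
    err("inlier_rmse must be a nonnegative number", "registration_failure_error")
  }
  structure(list(transform = transform, correspondences = correspondences,
                 inlier_rmse = inlier_rmse, backend_name = backend_name),
            class = "stage_one_result")
}

#' @export
print.stage_one_result <- function(x, ...) {
  cat(sprintf("<stage_one_result [%s]: %d correspondences, inlier RMSE %.4f mm, rotation %.2f deg>\n",
              x$backend_name, nrow(x$correspondences$pairs), x$inlier_rmse,
              rotation_angle(x$transform)))
  invisible(x)
}

rmse_under <- function(transform, source, target, sigma) {
  S <- apply_rigid(transform, as_cloud_matrix(source))
  D <- as_cloud_matrix(target)
  res <- S[sigma$pairs[, 1], , drop = FALSE] - D[sigma$pairs[, 2], , drop = FALSE]
  sqrt(mean(rowSums(res^2)))
}

#' Estimate initial rigid alignment and sparse correspondences
#'
#' Dispatches to a named backend. Every returned correspondence pair is
#' consistent with the returned transform up to the backend's inlier
#' threshold.
#'
#' @param source complete template `point_cloud` (N >= 3).
#' @param target partial target `point_cloud` (M >= 3).
#' @param backend `"descriptor"` (default) or `"oracle"`.
#' @param params named list of backend parameters, see [backend_descriptor()].
#' @return a `stage_one_result`.
#' @export
stage1_estimate <- function(source, target, backend = "descriptor", params = list()) {
  if (n_points(source) < 3L || n_points(target) < 3L) {
    err("source and target need at least 3 points", "degenerate_input_error")
  }
  switch(backend,
         oracle = backend_oracle(source, target),
         descriptor = do.call(backend_descriptor, c(list(source, target), params)),
         err(sprintf("unknown stage-1 backend '%s'", backend), "config_error"))
}

#' Oracle stage-one backend
#'
#' Uses the simulator's provenance: every target point carries the index of
#' the variant vertex it was sampled from, and the variant's vertex order
#' matches the template. The correspondence set is exact by construction and
#' the transform is the least-squares rigid fit over it.
#'
#' @param source template `point_cloud`.
#' @param target partial `point_cloud` with `source_index` provenance.
#' @return a `stage_one_result`.
#' @export
backend_oracle <- function(source, target) {
  if (is.null(target$source_index)) {
    err("oracle backend needs target source_index provenance", "precondition_error")
  }
  if (max(target$source_index) > n_points(source)) {
    err("target provenance exceeds source size", "precondition_error")
  }
  sigma <- correspondence_set(cbind(target$source_index, seq_len(n_points(target))))
  tau <- fit_rigid(source, target, sigma)
  stage_one_result(tau, sigma, rmse_under(tau, source, target, sigma), "oracle")
}

# --- descriptor backend ------------------------------------------------------

# voxel-grid downsampling; returns indices of representative points (the
# point closest to its voxel centroid), preserving original index space
voxel_downsample <- function(pts, voxel) {
  key <- floor(sweep(pts, 2, apply(pts, 2, min)) / voxel)
  id <- paste(key[, 1], key[, 2], key[, 3])
  split_idx <- split(seq_len(nrow(pts)), id)
  vapply(split_idx, function(ix) {
    if (length(ix) == 1L) return(ix)
    ctr <- colMeans(pts[ix, , drop = FALSE])
    ix[which.min(rowSums(sweep(pts[ix, , drop = FALSE], 2, ctr)^2))]
  }, integer(1), USE.NAMES = FALSE)
}

# local surface normals by PCA over k nearest neighbours, oriented outward
# from the cloud centroid
estimate_normals <- function(pts, k = 12L) {
  k <- min(k, nrow(pts))
  nn <- cpp_knn(pts, pts, k)$idx
  ctr <- colMeans(pts)
  t(vapply(seq_len(nrow(pts)), function(i) {
    nb <- pts[nn[i, ], , drop = FALSE]
    ev <- eigen(stats::cov(nb), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    if (sum(nrm * (pts[i, ] - ctr)) < 0) nrm <- -nrm
    nrm
  }, numeric(3)))
}

# Fast-point-feature-histogram-family descriptor: per node, angular Darboux
# features (alpha, phi, theta) against each neighbour are histogrammed
# (simplified histogram, SPFH), then blended with distance-weighted
# neighbour histograms.
fpfh_descriptors <- function(pts, normals, radius, n_bins = 11L) {
  n <- nrow(pts)
  kmax <- min(30L, n)
  knn <- cpp_knn(pts, pts, kmax)
  spfh <- matrix(0, n, 3L * n_bins)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- knn$idx[i, knn$dist[i, ] <= radius & knn$idx[i, ] != i]
    nbrs[[i]] <- sel
    if (length(sel) == 0L) next
    p <- pts[i, ]; np <- normals[i, ]
    hist3 <- numeric(3L * n_bins)
    for (j in sel) {
      dvec <- pts[j, ] - p
      d <- sqrt(sum(dvec^2))
      if (d == 0) next
      dvec <- dvec / d
      u <- np
      v <- pracma_cross(dvec, u)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) next
      v <- v / nv
      w <- pracma_cross(u, v)
      nq <- normals[j, ]
      alpha <- sum(v * nq)                      # [-1, 1]
      phi <- sum(u * dvec)                      # [-1, 1]
      theta <- atan2(sum(w * nq), sum(u * nq))  # [-pi, pi]
      b1 <- min(n_bins, 1L + floor((alpha + 1) / 2 * n_bins))
      b2 <- min(n_bins, 1L + floor((phi + 1) / 2 * n_bins))
      b3 <- min(n_bins, 1L + floor((theta + pi) / (2 * pi) * n_bins))
      hist3[b1] <- hist3[b1] + 1
      hist3[n_bins + b2] <- hist3[n_bins + b2] + 1
      hist3[2L * n_bins + b3] <- hist3[2L * n_bins + b3] + 1
    }
    if (sum(hist3) > 0) spfh[i, ] <- hist3 / sum(hist3)
  }
  fpfh <- spfh
  for (i in seq_len(n)) {
    sel <- nbrs[[i]]
    if (length(sel) == 0L) next
    wts <- 1 / pmax(sqrt(rowSums(sweep(pts[sel, , drop = FALSE], 2, pts[i, ])^2)), 1e-9)
    fpfh[i, ] <- spfh[i, ] + colSums(spfh[sel, , drop = FALSE] * wts) / sum(wts)
  }
  fpfh
}

#' Descriptor stage-one backend
#'
#' Classical global registration: voxel downsampling, rotation-invariant
#' normal-histogram descriptors at the downsampled nodes, mutual
#' nearest-neighbour matching in descriptor space, and robust rigid
#' estimation by RANSAC with a fixed seed, refined by a least-squares fit
#' over the inliers. Correspondences are reported in the original index
#' space of both clouds.
#'
#' @param source,target `point_cloud` objects.
#' @param voxel downsampling voxel size (mm).
#' @param feature_radius descriptor neighbourhood radius (mm).
#' @param ransac_iters RANSAC iterations.
#' @param inlier_threshold inlier residual threshold (mm).
#' @param seed RANSAC seed.
#' @return a `stage_one_result`.
#' @export
backend_descriptor <- function(source, target, voxel = 0.25, feature_radius = 0.9,
                               ransac_iters = 50000L, inlier_threshold = 0.5,
                               seed = 7L) {
  S <- as_cloud_matrix(source)
  D <- as_cloud_matrix(target)
  si <- voxel_downsample(S, voxel)
  ti <- voxel_downsample(D, voxel)
  if (length(si) < 10L || length(ti) < 10L) {
    err("too few downsampled nodes (< 10) for descriptor matching", "degenerate_input_error")
  }
  Sp <- S[si, , drop = FALSE]
  Tp <- D[ti, , drop = FALSE]
  fs <- fpfh_descriptors(Sp, estimate_normals(Sp), feature_radius)
  ft <- fpfh_descriptors(Tp, estimate_normals(Tp), feature_radius)
  ab <- cpp_nn(fs, ft)$idx
  ba <- cpp_nn(ft, fs)$idx
  mutual <- which(ba[ab] == seq_along(ab))
  if (length(mutual) < 3L) err("no mutual descriptor matches found", "registration_failure_error")
  ms <- Sp[mutual, , drop = FALSE]
  mt <- Tp[ab[mutual], , drop = FALSE]
  rr <- with_seed(seed, cpp_ransac_rigid(ms, mt, as.integer(ransac_iters), inlier_threshold))
  if (rr$n_inliers < 3L) err("RANSAC found no inlier set", "registration_failure_error")
  inl <- which(rr$inliers)
  tau <- fit_rigid(ms, mt, correspondence_set(cbind(inl, inl)))
  # trimmed ICP polish on the downsampled nodes; the target is the partial
  # cloud, so associations run target -> source (every target node has a
  # true source correspondent, not vice versa)
  for (icp_it in seq_len(30L)) {
    Sp_t <- apply_rigid(tau, Sp)
    nn <- cpp_nn(Tp, Sp_t)
    cut <- max(3 * stats::median(nn$dist), inlier_threshold)
    keep <- which(nn$dist <= cut)
    if (length(keep) < 3L) break
    tau_new <- tryCatch(
      fit_rigid(Sp, Tp, correspondence_set(unique(cbind(nn$idx[keep], keep)))),
      error = function(e) NULL)
    if (is.null(tau_new)) break
    delta <- max(abs(tau_new$rotation - tau$rotation),
                 abs(tau_new$translation - tau$translation))
    tau <- tau_new
    if (delta < 1e-8) break
  }
  # refit can change the inlier set once; recompute against the refined tau
  res <- sqrt(rowSums((apply_rigid(tau, ms) - mt)^2))
  inl <- which(res <= inlier_threshold)
  if (length(inl) >= 3L) {
    tau2 <- tryCatch(fit_rigid(ms, mt, correspondence_set(cbind(inl, inl))),
                     error = function(e) tau)
    res2 <- sqrt(rowSums((apply_rigid(tau2, ms) - mt)^2))
    if (sum(res2 <= inlier_threshold) >= length(inl)) {
      tau <- tau2
      res <- res2
      inl <- which(res <= inlier_threshold)
    }
  } else {
    inl <- which(rr$inliers)
  }
  if (length(inl) == 0L) err("no inliers under refined transform", "registration_failure_error")
  sigma <- correspondence_set(cbind(si[mutual[inl]], ti[ab[mutual[inl]]]))
  stage_one_result(tau, sigma, sqrt(mean(res[inl]^2)), "descriptor")
}
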