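# Stage 2: hierarchical non-rigid registration. The global motion is
# decomposed into per-level sub-motions: at level k the current points are
# mapped to sinusoidal encodings of frequency 2^(k + k0), a small multilayer
# regressor maps encodings to per-point 3-D increments, and the regressor is
# optimized per instance (Adam) against the correspondence-masked Chamfer
# loss plus a displacement regularizer. Low frequencies at shallow levels
# yield near-rigid sub-motions; deeper levels refine non-rigid detail.

#' Deformation-pyramid configuration
#'
#' @param n_levels number of pyramid levels.
#' @param max_iters_per_level optimization iteration cap per level.
#' @param k0 initial frequency offset; coordinates are normalized to a unit
#'   bounding box before encoding, so level-k frequency is `2^(k + k0)` per
#'   unit extent.
#' @param regressor_width hidden-layer width of the per-level regressor.
#' @param regressor_depth number of hidden layers.
#' @param step_size Adam learning rate.
#' @param stop_tol relative-improvement early-stop threshold.
#' @param patience consecutive low-improvement iterations before stopping.
#' @param reg_weight displacement-regularizer weight at level 1 (halved at
#'   each deeper level so high-frequency levels may express finer motion).
#' @param seed seed for regressor initialization.
#' @return an object of class `pyramid_config`.
#' @export
pyramid_config <- function(n_levels = 9L, max_iters_per_level = 60L, k0 = -6,
                           regressor_width = 64L, regressor_depth = 3L,
                           step_size = 0.02, stop_tol = 1e-4, patience = 10L,
                           reg_weight = 0.5, seed = 1L) {
  cfg <- list(n_levels = as.integer(n_levels),
              max_iters_per_level = as.integer(max_iters_per_level),
              k0 = k0, regressor_width = as.integer(regressor_width),
              regressor_depth = as.integer(regressor_depth),
              step_size = step_size, stop_tol = stop_tol,
              patience = as.integer(patience), reg_weight = reg_weight,
              seed = as.integer(seed))
  if (cfg$n_levels < 1L || cfg$max_iters_per_level < 1L || cfg$regressor_depth < 1L) {
    err("n_levels, max_iters_per_level and regressor_depth must be >= 1", "config_error")
  }
  if (cfg$stop_tol <= 0 || cfg$step_size <= 0) {
    err("stop_tol and step_size must be positive", "config_error")
  }
  if (cfg$reg_weight < 0) err("reg_weight must be >= 0", "config_error")
  structure(cfg, class = "pyramid_config")
}

#' Sinusoidal positional encoding
#'
#' Maps each point to the 6-vector
#' `(sin(2^(k+k0) p), cos(2^(k+k0) p))`, applied component-wise to the
#' coordinates. Shallow levels (low k) see near-constant encodings and hence
#' express near-rigid motion; deeper levels resolve finer spatial detail.
#'
#' @param points `point_cloud` or N x 3 matrix.
#' @param k level number (>= 0).
#' @param k0 frequency offset.
#' @return N x 6 encoding matrix.
#' @export
sinusoidal_encode <- function(points, k, k0 = 0) {
  if (k < 0) err("k must be >= 0", "config_error")
  P <- as_cloud_matrix(points)
  w <- 2^(k + k0)
  cbind(sin(w * P), cos(w * P))
}

#' Correspondence-masked Chamfer loss
#'
#' Restricts the deformed source to the points that have a correspondence
#' (the masked set) and returns its Chamfer distance to the full target.
#'
#' @param deformed_source `point_cloud` or matrix (already deformed).
#' @param target `point_cloud` or matrix.
#' @param sigma a `correspondence_set`; only its source indices are used.
#' @return scalar loss (mm).
#' @export
correspondence_loss <- function(deformed_source, target, sigma) {
  S <- as_cloud_matrix(deformed_source)
  D <- as_cloud_matrix(target)
  if (!inherits(sigma, "correspondence_set") || nrow(sigma$pairs) == 0L) {
    err("sigma must be a non-empty correspondence_set", "precondition_error")
  }
  check_correspondences(sigma, nrow(S), nrow(D))
  mask <- sort(unique(sigma$pairs[, 1]))
  chamfer_distance(S[mask, , drop = FALSE], D)
}

# --- tiny MLP with analytic backprop ----------------------------------------

mlp_init <- function(n_in, width, depth, n_out, seed) {
  with_seed(seed, {
    sizes <- c(n_in, rep(width, depth), n_out)
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      fan_in <- sizes[l]
      W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                       fan_in, sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    # zero-init the output layer: every level starts as the identity motion
    W[[length(W)]][] <- 0
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_len(L)) {
    Z <- sweep(H %*% par$W[[l]], 2, par$b[[l]], "+")
    H <- if (l < L) pmax(Z, 0) else Z
    acts[[l + 1L]] <- H
  }
  list(out = H, acts = acts)
}

mlp_backward <- function(par, acts, d_out) {
  L <- length(par$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- d_out
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_state <- function(par) {
  zeros <- function(x) lapply(x, function(v) { v[] <- 0; v })
  list(mW = zeros(par$W), vW = zeros(par$W), mb = zeros(par$b), vb = zeros(par$b), t = 0L)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (l in seq_along(par$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grad$W[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    par$W[[l]] <- par$W[[l]] - lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grad$b[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    par$b[[l]] <- par$b[[l]] - lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(par = par, st = st)
}

# masked Chamfer loss and its gradient with respect to the deformed points
# (only masked rows receive gradient); exact nearest neighbours each call
chamfer_loss_grad <- function(Q, mask, target) {
  A <- Q[mask, , drop = FALSE]
  nA <- nrow(A); nB <- nrow(target)
  ab <- cpp_nn(A, target)
  ba <- cpp_nn(target, A)
  loss <- mean(ab$dist) + mean(ba$dist)
  gA <- matrix(0, nA, 3)
  ok <- ab$dist > 1e-12
  diffs <- A - target[ab$idx, , drop = FALSE]
  gA[ok, ] <- diffs[ok, , drop = FALSE] / ab$dist[ok] / nA
  ok2 <- ba$dist > 1e-12
  diffs2 <- A[ba$idx, , drop = FALSE] - target
  contrib <- matrix(0, nB, 3)
  contrib[ok2, ] <- diffs2[ok2, , drop = FALSE] / ba$dist[ok2] / nB
  g2 <- rowsum(contrib, group = ba$idx)
  gA[as.integer(rownames(g2)), ] <- gA[as.integer(rownames(g2)), ] + g2
  G <- matrix(0, nrow(Q), 3)
  G[mask, ] <- gA
  list(loss = loss, grad = G)
}

#' Hierarchical pyramid non-rigid registration
#'
#' Registers a rigidly pre-aligned source cloud onto a (possibly partial)
#' target. At each level the current points are sinusoidally encoded, a
#' freshly initialized regressor predicts per-point increments, and the
#' regressor weights are optimized by Adam on the masked Chamfer loss plus a
#' decaying mean-squared-increment regularizer, with early stopping on
#' stalled improvement. The level's output points feed the next level; the
#' returned field is the composition of all sub-motions. Coordinates are
#' normalized to a unit bounding box internally and the field is returned in
#' mm. Deterministic for a fixed `cfg$seed`.
#'
#' @param source pre-aligned `point_cloud` (the caller applies the stage-one
#'   transform first).
#' @param target `point_cloud`.
#' @param sigma non-empty `correspondence_set` masking the loss.
#' @param cfg a `pyramid_config`.
#' @return list with `field` (a `displacement_field` over `source`) and
#'   `diagnostics` (per level: iterations, loss trajectories, mean increment
#'   norm in mm).
#' @export
ndp_register <- function(source, target, sigma, cfg = pyramid_config()) {
  S <- as_cloud_matrix(source)
  D <- as_cloud_matrix(target)
  check_correspondences(sigma, nrow(S), nrow(D))
  mask <- sort(unique(sigma$pairs[, 1]))
  lo <- pmin(apply(S, 2, min), apply(D, 2, min))
  hi <- pmax(apply(S, 2, max), apply(D, 2, max))
  scale <- max(hi - lo)
  if (scale <= 0) err("degenerate (zero-extent) input clouds", "degenerate_input_error")
  ctr <- (lo + hi) / 2
  Sn <- sweep(S, 2, ctr) / scale
  Dn <- sweep(D, 2, ctr) / scale
  P <- Sn
  diagnostics <- vector("list", cfg$n_levels)
  rowcross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  for (k in seq_len(cfg$n_levels)) {
    enc <- sinusoidal_encode(P, k, cfg$k0)
    # the regressor predicts a per-point rigid sub-motion (linearized
    # rotation w and translation v): d = w x p + v. A near-constant output
    # over a structure moves it rigidly, which suits articulated anatomy.
    par <- mlp_init(6L, cfg$regressor_width, cfg$regressor_depth, 6L,
                    seed = cfg$seed + 1000L * k)
    st <- adam_state(par)
    gamma <- cfg$reg_weight * 0.5^(k - 1)
    best_loss <- Inf
    best_par <- par
    stalled <- 0L
    traj_cd <- numeric(0); traj_reg <- numeric(0); traj_tot <- numeric(0)
    for (it in seq_len(cfg$max_iters_per_level)) {
      fwd <- mlp_forward(par, enc)
      w <- fwd$out[, 1:3, drop = FALSE]
      v <- fwd$out[, 4:6, drop = FALSE]
      d <- rowcross(w, P) + v
      Q <- P + d
      cg <- chamfer_loss_grad(Q, mask, Dn)
      reg <- gamma * mean(rowSums(d^2))
      total <- cg$loss + reg
      if (!is.finite(total)) {
        err(sprintf("non-finite loss at level %d, iteration %d", k, it),
            "numerical_failure_error")
      }
      traj_cd <- c(traj_cd, cg$loss); traj_reg <- c(traj_reg, reg); traj_tot <- c(traj_tot, total)
      if (total < best_loss) {
        impr <- (best_loss - total) / max(best_loss, 1e-12)
        best_loss <- total
        best_par <- par
        stalled <- if (is.finite(impr) && impr < cfg$stop_tol) stalled + 1L else 0L
      } else {
        stalled <- stalled + 1L
      }
      # the first Adam steps climb out of the zero-increment initialization;
      # give the optimizer a warmup before the stall counter can stop it
      if (stalled >= cfg$patience && it > 2L * cfg$patience) break
      g_d <- cg$grad + (2 * gamma / nrow(d)) * d
      # back through d = w x p + v:  dL/dv = g, dL/dw = p x g
      grad <- mlp_backward(par, fwd$acts, cbind(rowcross(P, g_d), g_d))
      upd <- adam_step(par, grad, st, cfg$step_size)
      par <- upd$par
      st <- upd$st
    }
    out_best <- mlp_forward(best_par, enc)$out
    d_best <- rowcross(out_best[, 1:3, drop = FALSE], P) + out_best[, 4:6, drop = FALSE]
    diagnostics[[k]] <- list(level = k, iterations = length(traj_tot),
                             loss_cd = traj_cd, loss_reg = traj_reg,
                             loss_total = traj_tot,
                             increment_mean_norm = mean(sqrt(rowSums(d_best^2))) * scale)
    P <- P + d_best
  }
  field <- displacement_field((P - Sn) * scale)
  list(field = field, diagnostics = diagnostics)
}

#' Full two-stage complete-to-partial registration
#'
#' Runs stage one (rigid alignment + sparse correspondences), applies the
#' rigid transform to the source, then refines with the deformation pyramid.
#' The returned displacement field is expressed in the original source
#' frame, i.e. `phi(x) = tau(x) + phi_ndp(tau(x)) - x`.
#'
#' @param source complete template `point_cloud`.
#' @param target partial target `point_cloud`.
#' @param backend stage-one backend name (`"descriptor"` or `"oracle"`).
#' @param stage1_params named list of stage-one backend parameters.
#' @param cfg a `pyramid_config`.
#' @param fallback_identity if `TRUE`, a stage-one failure falls back to the
#'   identity transform with nearest-neighbour correspondences (recorded in
#'   the result); if `FALSE` (default) the failure propagates.
#' @return an object of class `registration_result`: fields `transform`,
#'   `correspondences`, `field` (original frame), `deformed` (point_cloud),
#'   `diagnostics`, `backend_name`.
#' @export
register_c2p <- function(source, target, backend = "descriptor",
                         stage1_params = list(), cfg = pyramid_config(),
                         fallback_identity = FALSE) {
  s1 <- tryCatch(
    stage1_estimate(source, target, backend, stage1_params),
    error = function(e) {
      if (!fallback_identity) stop(e)
      nn <- cpp_nn(as_cloud_matrix(target), as_cloud_matrix(source))$idx
      sigma <- correspondence_set(unique(cbind(nn, seq_len(n_points(target)))))
      res <- stage_one_result(rigid_identity(), sigma,
                              rmse_under(rigid_identity(), source, target, sigma),
                              paste0(backend, ":identity-fallback"))
      res
    })
  aligned <- apply_rigid(s1$transform, source)
  ndp <- ndp_register(aligned, target, s1$correspondences, cfg)
  total_field <- displacement_field(aligned$points + ndp$field$vectors -
                                    as_cloud_matrix(source))
  structure(list(transform = s1$transform,
                 correspondences = s1$correspondences,
                 inlier_rmse = s1$inlier_rmse,
                 backend_name = s1$backend_name,
                 field = total_field,
                 deformed = point_cloud(as_cloud_matrix(source) + total_field$vectors,
                                        labels = source$labels),
                 diagnostics = ndp$diagnostics),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result [%s]: %d correspondences, mean |phi| = %.3f mm>\n",
              x$backend_name, nrow(x$correspondences$pairs),
              mean(sqrt(rowSums(x$field$vectors^2)))))
  invisible(x)
}
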