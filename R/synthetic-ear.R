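# Procedural simulator of segmented middle-ear anatomy. It replaces the
# ex vivo micro-CT template with a parametric stand-in (curved canal-wall
# tube, conical membrane disc, three articulated prolate ossicle bodies),
# then produces shape variants via free-form lattice deformation and an
# articulated kinematic chain, and extracts noisy partial "in vivo" views
# with exact ground-truth displacement fields.

EAR_STRUCTURES <- c("canal_wall", "tympanic_membrane", "malleus", "incus", "stapes")

#' Construct a segmented ear model
#'
#' A template (or deformed variant) of the middle ear: an ordered
#' anterior-to-posterior map of structures to point clouds, joint positions
#' between adjacent structures, a per-structure support anchor (visibility
#' reference for partial sampling) and per-structure landmarks.
#'
#' @param structures named ordered list of `point_cloud` objects.
#' @param articulation_points list of 3-vectors (mm), one per adjacent pair.
#' @param support_points named list of 3-vectors (mm), one per structure.
#' @param landmarks named list of L x 3 matrices, one per structure.
#' @return an object of class `ear_model`.
#' @export
ear_model <- function(structures, articulation_points, support_points, landmarks) {
  if (length(structures) < 2L) err("an ear model needs at least 2 structures", "model_error")
  nm <- names(structures)
  if (is.null(nm) || anyDuplicated(nm) > 0L || any(nm == "")) {
    err("structures must have unique names", "model_error")
  }
  for (s in structures) {
    if (!inherits(s, "point_cloud")) err("every structure must be a point_cloud", "model_error")
  }
  if (length(articulation_points) != length(structures) - 1L) {
    err("articulation point count must equal structure count - 1", "model_error")
  }
  if (!identical(sort(names(support_points)), sort(nm)) ||
      !identical(sort(names(landmarks)), sort(nm))) {
    err("support_points and landmarks must cover every structure", "model_error")
  }
  structure(list(structures = structures,
                 articulation_points = articulation_points,
                 support_points = support_points,
                 landmarks = landmarks),
            class = "ear_model")
}

#' @export
print.ear_model <- function(x, ...) {
  cat(sprintf("<ear_model: %d structures (%s), %d points>\n",
              length(x$structures), paste(names(x$structures), collapse = ", "),
              sum(vapply(x$structures, n_points, 1L))))
  invisible(x)
}

#' Flatten an ear model into one labelled point cloud
#'
#' Concatenates the structures in their anterior-to-posterior order; labels
#' record the structure each point belongs to. Row order is stable, so
#' flattened template and variant clouds align index-for-index.
#'
#' @param model an `ear_model`.
#' @return a `point_cloud` with structure labels.
#' @export
model_cloud <- function(model) {
  pts <- do.call(rbind, lapply(model$structures, function(s) s$points))
  labs <- rep(names(model$structures), vapply(model$structures, n_points, 1L))
  point_cloud(pts, labels = labs)
}

#' Simulation configuration
#'
#' Parameters of the shape-variant and partial-view simulation. Deformation
#' bounds may be single `list(translation =, rotation =)` pairs applied
#' everywhere, or lists with a `default` entry plus per-structure (or
#' per-joint) overrides keyed by structure name.
#'
#' Defaults are calibrated so that the mean ground-truth target displacement
#' over many samples is around 1.5 mm, the magnitude of anatomical variation
#' the registration stages are expected to absorb.
#'
#' @param n_points points sampled per structure in the template.
#' @param nonrigid_bounds per control-group lattice bounds: max translation
#'   (mm) and max rotation (deg).
#' @param rigid_bounds per joint bounds of the articulated chain: max
#'   rotation (deg) and max translation (mm).
#' @param lattice_resolution control nodes per axis of the deformation
#'   lattice (length 3, each >= 2).
#' @param visibility_lambda exponential decay scale (mm) of the keep-score
#'   with distance from a structure's support point; `Inf` removes the
#'   distance term.
#' @param visibility_noise_sd standard deviation of the Gaussian noise added
#'   to the keep-score.
#' @param base_visible_frac base fraction of each structure's points budgeted
#'   for the partial view before depth occlusion.
#' @param occlusion_range `c(a, b)` multiplicative retention factor drawn
#'   uniformly per structure; setting `c(1, 1)` disables the depth-occlusion
#'   model entirely.
#' @param occlusion_floor lower clamp of the depth-retention function.
#' @param posterior_structures names of the structures subject to depth
#'   occlusion (shadowed by anterior anatomy); structures absent from the
#'   model are ignored.
#' @param jitter_delta per-axis uniform jitter bound (mm) on surviving points.
#' @param template_seed seed for the shared template geometry (the same
#'   template serves every sample, as one micro-CT model serves all patients).
#' @param seed default seed for operations not given one explicitly.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_points = c(canal_wall = 400, tympanic_membrane = 300,
                                           malleus = 160, incus = 140, stapes = 100),
                              nonrigid_bounds = list(translation = 0.2, rotation = 3),
                              rigid_bounds = list(
                                default = list(rotation = 5, translation = 0.25),
                                canal_membrane = list(rotation = 23, translation = 1.4)),
                              lattice_resolution = c(3, 3, 3),
                              visibility_lambda = 2.5,
                              visibility_noise_sd = 0.15,
                              base_visible_frac = 0.9,
                              occlusion_range = c(0.6, 1),
                              occlusion_floor = 0.15,
                              posterior_structures = c("malleus", "incus", "stapes"),
                              jitter_delta = 0.05,
                              template_seed = 20,
                              seed = 1) {
  cfg <- list(n_points = n_points, nonrigid_bounds = nonrigid_bounds,
              rigid_bounds = rigid_bounds, lattice_resolution = lattice_resolution,
              visibility_lambda = visibility_lambda,
              visibility_noise_sd = visibility_noise_sd,
              base_visible_frac = base_visible_frac,
              occlusion_range = occlusion_range,
              occlusion_floor = occlusion_floor,
              posterior_structures = posterior_structures,
              jitter_delta = jitter_delta,
              template_seed = template_seed, seed = seed)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  bchk <- function(b, what) {
    flat <- if (!is.null(b$translation) || !is.null(b$rotation)) list(b) else b
    for (e in flat) {
      if (is.null(e$translation) || is.null(e$rotation) ||
          e$translation < 0 || e$rotation < 0) {
        err(sprintf("%s must give nonnegative translation and rotation bounds", what),
            "config_error")
      }
    }
  }
  bchk(cfg$nonrigid_bounds, "nonrigid_bounds")
  bchk(cfg$rigid_bounds, "rigid_bounds")
  if (length(cfg$lattice_resolution) != 3L || any(cfg$lattice_resolution < 2)) {
    err("lattice_resolution must be three values >= 2", "config_error")
  }
  if (cfg$visibility_lambda <= 0) err("visibility_lambda must be positive", "config_error")
  if (cfg$visibility_noise_sd < 0) err("visibility_noise_sd must be >= 0", "config_error")
  if (cfg$base_visible_frac <= 0 || cfg$base_visible_frac > 1) {
    err("base_visible_frac must be in (0, 1]", "config_error")
  }
  a <- cfg$occlusion_range[1]; b <- cfg$occlusion_range[2]
  if (length(cfg$occlusion_range) != 2L || a < 0 || a > b || b > 1) {
    err("occlusion_range must satisfy 0 <= a <= b <= 1", "config_error")
  }
  if (cfg$jitter_delta < 0) err("jitter_delta must be >= 0", "config_error")
  invisible(cfg)
}

bounds_for <- function(bounds, name) {
  if (!is.null(bounds$translation) || !is.null(bounds$rotation)) return(bounds)
  if (!is.null(bounds[[name]])) return(bounds[[name]])
  if (!is.null(bounds$default)) return(bounds$default)
  err(sprintf("no deformation bounds for '%s'", name), "config_error")
}

# --- template construction ---------------------------------------------------

unit_vec <- function(v) v / sqrt(sum(v^2))

# rotation mapping +z onto direction d
frame_to_dir <- function(d) {
  d <- unit_vec(d)
  up <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit_vec(pracma_cross(up, d))
  e2 <- pracma_cross(d, e1)
  cbind(e1, e2, d)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# geometry parameters of the parametric template (mm); anterior at z = 0,
# depth increases posteriorly
ear_geometry <- function() {
  mal_dir <- unit_vec(c(0, 0.55, 0.84))
  inc_dir <- unit_vec(c(0, 0.12, 0.99))
  sta_dir <- unit_vec(c(0, -0.25, 0.97))
  list(
    canal = list(length = 4, radius = 2.2, bend = 0.4),
    membrane = list(center = c(0, 0, 4.3), radius = 2.2, depth = 0.5),
    malleus = list(center = c(0, 0.6, 5.1), dir = mal_dir, semi = c(0.35, 0.35, 1.15)),
    incus = list(center = c(0, 1.15, 6.35), dir = inc_dir, semi = c(0.38, 0.38, 0.95)),
    stapes = list(center = c(0, 0.95, 7.45), dir = sta_dir, semi = c(0.28, 0.28, 0.5))
  )
}

sample_ellipsoid <- function(n, center, dir, semi) {
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  g <- sweep(g, 2, semi, "*")
  B <- frame_to_dir(dir)
  sweep(g %*% t(B), 2, center, "+")
}

#' Build the procedural middle-ear template
#'
#' Constructs a deterministic segmented template: a curved canal-wall tube, a
#' conical membrane disc and three elongated ossicle bodies chained
#' end-to-end at articulation points, ordered anterior to posterior along the
#' depth axis (+z). Landmarks sit at analytically known extremal points
#' (structure tips and centers); the first canal-wall landmark marks the
#' external ear opening and serves as the depth-occlusion reference. Support
#' points default to structure centroids.
#'
#' @param n_points named integer vector of per-structure point counts (at
#'   least 50 each); defaults to the counts in [simulation_config()].
#' @param seed RNG seed; the same seed reproduces the template bitwise.
#' @return an `ear_model`.
#' @export
build_template <- function(n_points = simulation_config()$n_points, seed = 20) {
  need <- EAR_STRUCTURES
  if (!all(need %in% names(n_points))) {
    err(sprintf("n_points must name all structures: %s", paste(need, collapse = ", ")),
        "config_error")
  }
  n_points <- n_points[need]
  if (any(n_points < 50)) err("each structure needs at least 50 points", "config_error")
  geo <- ear_geometry()
  with_seed(seed, {
    structures <- list()
    landmarks <- list()

    # canal wall: tube along z with a gentle sinusoidal bend of the axis
    cn <- n_points[["canal_wall"]]
    zc <- runif(cn, 0, geo$canal$length)
    th <- runif(cn, 0, 2 * pi)
    bend <- function(z) geo$canal$bend * sin(pi * z / (2 * geo$canal$length))
    structures$canal_wall <- point_cloud(cbind(bend(zc) + geo$canal$radius * cos(th),
                                               geo$canal$radius * sin(th), zc))
    landmarks$canal_wall <- rbind(c(bend(0), 0, 0),
                                  c(bend(geo$canal$length), 0, geo$canal$length),
                                  c(bend(geo$canal$length / 2), geo$canal$radius,
                                    geo$canal$length / 2))

    # tympanic membrane: cone-shaped disc, apex (umbo) pulled posteriorly
    mn <- n_points[["tympanic_membrane"]]
    rr <- sqrt(runif(mn))
    ph <- runif(mn, 0, 2 * pi)
    mc <- geo$membrane$center
    structures$tympanic_membrane <- point_cloud(cbind(
      mc[1] + geo$membrane$radius * rr * cos(ph),
      mc[2] + geo$membrane$radius * rr * sin(ph),
      mc[3] + geo$membrane$depth * (1 - rr)))
    umbo <- mc + c(0, 0, geo$membrane$depth)
    landmarks$tympanic_membrane <- rbind(umbo,
                                         mc + c(geo$membrane$radius, 0, 0),
                                         mc + c(0, geo$membrane$radius, 0))

    for (nm in c("malleus", "incus", "stapes")) {
      g <- geo[[nm]]
      structures[[nm]] <- point_cloud(sample_ellipsoid(n_points[[nm]], g$center, g$dir, g$semi))
      landmarks[[nm]] <- rbind(g$center - g$semi[3] * g$dir,
                               g$center + g$semi[3] * g$dir,
                               g$center)
    }

    tip <- function(nm, sgn) geo[[nm]]$center + sgn * geo[[nm]]$semi[3] * geo[[nm]]$dir
    articulation_points <- list(
      canal_membrane = mc + c(0, geo$membrane$radius, 0),
      membrane_malleus = tip("malleus", -1),
      malleus_incus = (tip("malleus", +1) + tip("incus", -1)) / 2,
      incus_stapes = (tip("incus", +1) + tip("stapes", -1)) / 2
    )
    support_points <- lapply(structures, function(s) colMeans(s$points))
    ear_model(structures, articulation_points, support_points, landmarks)
  })
}

# --- non-rigid lattice simulation -------------------------------------------

# Piecewise-trilinear free-form deformation evaluated at lattice coordinates
# s in [0,1]^3 (clamped), given per-node displacement array disp[node, 3]
# and per-axis resolutions r. Node order follows expand.grid(i, j, k).
ffd_interpolate <- function(s, disp, r) {
  s <- pmin(pmax(s, 0), 1)
  out <- matrix(0, nrow(s), 3)
  u <- sweep(s, 2, r - 1, "*")
  i0 <- pmin(floor(u), matrix(rep(r - 2, each = nrow(s)), ncol = 3))
  f <- u - i0
  node_id <- function(i, j, k) 1 + i + r[1] * (j + r[2] * k)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di == 1) f[, 1] else 1 - f[, 1]) *
         (if (dj == 1) f[, 2] else 1 - f[, 2]) *
         (if (dk == 1) f[, 3] else 1 - f[, 3])
    idx <- node_id(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)
    out <- out + w * disp[idx, , drop = FALSE]
  }
  out
}

#' Simulate a non-rigid shape variant
#'
#' Per structure, fits a free-form-deformation control lattice to the
#' structure's principal-axis bounding box, partitions control nodes into
#' slab groups along the length, thickness and width axes, gives each group a
#' random rigid motion drawn uniformly within the configured bounds, and
#' moves vertices (and the structure's landmarks and support point) by
#' piecewise-trilinear interpolation of the node displacements. Topology is
#' unchanged; zero bounds reproduce the input exactly.
#'
#' @param model template `ear_model`.
#' @param cfg a `simulation_config`.
#' @param seed RNG seed.
#' @return the deformed `ear_model`.
#' @export
simulate_nonrigid <- function(model, cfg, seed = cfg$seed) {
  validate_simulation_config(cfg)
  r <- as.integer(cfg$lattice_resolution)
  nodes_unit <- as.matrix(expand.grid(seq(0, 1, length.out = r[1]),
                                      seq(0, 1, length.out = r[2]),
                                      seq(0, 1, length.out = r[3])))
  with_seed(seed, {
    out <- model
    snames <- names(model$structures)
    for (si in seq_along(snames)) {
      nm <- snames[si]
      b <- bounds_for(cfg$nonrigid_bounds, nm)
      pts <- model$structures[[nm]]$points
      ctr <- colMeans(pts)
      B <- prcomp(sweep(pts, 2, ctr))$rotation
      if (det(B) < 0) B[, 3] <- -B[, 3]
      local <- sweep(pts, 2, ctr) %*% B
      lo <- apply(local, 2, min) - 1e-6
      hi <- apply(local, 2, max) + 1e-6
      span <- hi - lo
      nodes <- sweep(sweep(nodes_unit, 2, span, "*"), 2, lo, "+")
      disp <- matrix(0, nrow(nodes), 3)
      # slab groups along each principal axis: length, thickness, width
      for (axis in 1:3) {
        slab <- round(nodes_unit[, axis] * (r[axis] - 1)) + 1
        for (g in seq_len(r[axis])) {
          members <- which(slab == g)
          tvec <- runif(3, -1, 1) * b$translation
          ax <- rnorm(3)
          ang <- runif(1, -1, 1) * b$rotation
          if (ang == 0 && all(tvec == 0)) next  # exact identity at zero bounds
          c0 <- colMeans(nodes[members, , drop = FALSE])
          R <- rotation_about_axis(ax, ang)
          moved <- sweep(sweep(nodes[members, , drop = FALSE], 2, c0) %*% t(R), 2, c0 + tvec, "+")
          disp[members, ] <- disp[members, ] + (moved - nodes[members, , drop = FALSE])
        }
      }
      to_lattice <- function(world) {
        sweep(sweep(sweep(world, 2, ctr) %*% B, 2, lo), 2, span, "/")
      }
      move <- function(world) {
        d_local <- ffd_interpolate(to_lattice(world), disp, r)
        world + d_local %*% t(B)
      }
      out$structures[[nm]] <- point_cloud(move(pts),
                                          labels = model$structures[[nm]]$labels)
      out$landmarks[[nm]] <- move(model$landmarks[[nm]])
      out$support_points[[nm]] <- as.numeric(move(matrix(model$support_points[[nm]], 1)))
      # the joint driving this structure stays attached to it
      if (si >= 2) {
        out$articulation_points[[si - 1]] <-
          as.numeric(move(matrix(model$articulation_points[[si - 1]], 1)))
      }
    }
    out
  })
}

# --- articulated rigid simulation -------------------------------------------

#' Simulate an articulated rigid pose variant
#'
#' Treats the structures as a kinematic chain connected end-to-end at the
#' articulation points. A root rigid motion (drawn within the per-joint
#' bounds, about the first articulation) moves every structure; each ossicle
#' joint then adds a rotation about its (already moved) articulation point
#' plus a small translation, propagating to all downstream structures by
#' forward kinematics. The canal wall and tympanic membrane carry only the
#' root motion. Within-structure distances are preserved exactly.
#'
#' @param model (typically non-rigidly deformed) `ear_model`.
#' @param cfg a `simulation_config`.
#' @param seed RNG seed.
#' @return the posed `ear_model`.
#' @export
simulate_rigid <- function(model, cfg, seed = cfg$seed) {
  validate_simulation_config(cfg)
  ns <- length(model$structures)
  if (length(model$articulation_points) != ns - 1L) {
    err("model is missing articulation points", "model_error")
  }
  joints <- model$articulation_points
  with_seed(seed, {
    draw_local <- function(b, pivot) {
      ax <- rnorm(3)
      ang <- runif(1, -1, 1) * b$rotation
      tvec <- runif(3, -1, 1) * b$translation
      R <- rotation_about_axis(ax, ang)
      rigid_transform(R, as.numeric(pivot - R %*% pivot) + tvec)
    }
    jname <- function(k) {
      nms <- names(joints)
      if (!is.null(nms) && nms[k] != "") nms[k] else as.character(k)
    }
    root <- draw_local(bounds_for(cfg$rigid_bounds, jname(1)), joints[[1]])
    # cumulative transform per structure: 1..2 root only, then chain joints
    G <- vector("list", ns)
    G[[1]] <- root
    if (ns >= 2) G[[2]] <- root
    if (ns >= 3) {
      for (k in 2:(ns - 1)) {
        b <- bounds_for(cfg$rigid_bounds, jname(k))
        L <- draw_local(b, joints[[k]])
        G[[k + 1]] <- compose_rigid(G[[k]], L)
      }
    }
    out <- model
    nm <- names(model$structures)
    for (si in seq_len(ns)) {
      g <- G[[si]]
      out$structures[[si]] <- apply_rigid(g, model$structures[[si]])
      out$landmarks[[nm[si]]] <- apply_rigid(g, model$landmarks[[nm[si]]])
      out$support_points[[nm[si]]] <-
        as.numeric(apply_rigid(g, matrix(model$support_points[[nm[si]]], 1)))
      if (si <= ns - 1L) {
        out$articulation_points[[si]] <-
          as.numeric(apply_rigid(G[[si]], matrix(joints[[si]], 1)))
      }
    }
    out
  })
}

#' Ground-truth displacement field between template and variant
#'
#' Vertex-for-vertex difference between a deformed variant and its template
#' (both flattened in structure order).
#'
#' @param template,variant `ear_model` objects with identical structure
#'   names, ordering and per-structure point counts.
#' @return a `displacement_field` aligned with `model_cloud(template)`.
#' @export
ground_truth_field <- function(template, variant) {
  if (!identical(names(template$structures), names(variant$structures))) {
    err("template and variant structures differ", "model_error")
  }
  tc <- model_cloud(template)
  vc <- model_cloud(variant)
  if (n_points(tc) != n_points(vc)) {
    err("template and variant vertex counts differ", "model_error")
  }
  displacement_field(vc$points - tc$points)
}

# depth-retention function: linearly decreasing with distance to the
# external-ear reference, clamped below at `floor`
depth_retention <- function(depths, floor_) {
  dmax <- max(depths)
  if (dmax <= 0) return(rep(1, length(depths)))
  pmin(pmax(1 - depths / dmax, floor_), 1)
}

#' Extract a noisy partial view of a shape variant
#'
#' Emulates what an endoscopic OCT scan sees of the variant: per structure, a
#' keep-score `exp(-d / lambda) + noise` (d = distance to the structure's
#' support point) ranks vertices, and the top-scoring vertices are retained
#' up to a budget. The budget shrinks for posterior structures via a
#' decreasing function of the structure centroid's distance to the
#' external-ear reference (the first canal-wall landmark) times a uniform
#' random occlusion factor. Surviving points receive per-axis uniform jitter.
#' Output points carry `source_index` provenance into the flattened variant.
#'
#' @param variant an `ear_model` shape variant.
#' @param cfg a `simulation_config`.
#' @param seed RNG seed.
#' @return a `point_cloud` with labels and `source_index`.
#' @export
sample_partial <- function(variant, cfg, seed = cfg$seed) {
  validate_simulation_config(cfg)
  a <- cfg$occlusion_range[1]; b <- cfg$occlusion_range[2]
  occlusion_on <- !(a == 1 && b == 1)
  ref <- as.numeric(variant$landmarks[[1]][1, ])
  cents <- t(vapply(variant$structures, function(s) colMeans(s$points), numeric(3)))
  depths <- sqrt(rowSums(sweep(cents, 2, ref)^2))
  retain <- if (occlusion_on) depth_retention(depths, cfg$occlusion_floor) else rep(1, nrow(cents))
  # anterior structures are not shadowed; only posterior ones lose budget
  anterior <- !(names(variant$structures) %in% cfg$posterior_structures)
  retain[anterior] <- 1
  offsets <- c(0, cumsum(vapply(variant$structures, n_points, 1L)))
  with_seed(seed, {
    kept_pts <- list(); kept_idx <- list(); kept_lab <- list()
    for (si in seq_along(variant$structures)) {
      nm <- names(variant$structures)[si]
      pts <- variant$structures[[si]]$points
      n <- nrow(pts)
      occ <- if (occlusion_on) runif(1, a, b) else 1
      if (anterior[si]) occ <- 1
      budget <- min(n, round(n * cfg$base_visible_frac * retain[si] * occ))
      d <- sqrt(rowSums(sweep(pts, 2, variant$support_points[[nm]])^2))
      s <- exp(-d / cfg$visibility_lambda) + rnorm(n, 0, cfg$visibility_noise_sd)
      if (budget > 0) {
        keep <- sort(order(s, decreasing = TRUE)[seq_len(budget)])
        jit <- matrix(runif(3 * budget, -cfg$jitter_delta, cfg$jitter_delta), ncol = 3)
        kept_pts[[nm]] <- pts[keep, , drop = FALSE] + jit
        kept_idx[[nm]] <- offsets[si] + keep
        kept_lab[[nm]] <- rep(nm, budget)
      } else {
        # keep the RNG stream aligned whether or not points survive
        runif(0)
      }
    }
    if (length(kept_pts) == 0L) err("partial sampling retained no points", "empty_output_error")
    point_cloud(do.call(rbind, kept_pts),
                labels = unlist(kept_lab, use.names = FALSE),
                source_index = unlist(kept_idx, use.names = FALSE))
  })
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 1000003) %% 2147483647)
}

#' Generate one synthetic registration sample
#'
#' Full simulation chain: build (or reuse) the template, apply the non-rigid
#' lattice deformation and the articulated rigid pose, record the exact
#' ground-truth displacement field, and extract the noisy partial target.
#'
#' @param cfg a `simulation_config`.
#' @param seed sample RNG seed; per-stage seeds are derived from it.
#' @param template optional pre-built template `ear_model` to reuse across
#'   samples (built from `cfg$template_seed` when `NULL`).
#' @return an object of class `ear_sample` with fields `template`, `target`,
#'   `gt_displacement`, `variant`, `landmarks_template`, `landmarks_target`,
#'   `visible_ratio`, plus the underlying `ear_model` objects.
#' @export
generate_sample <- function(cfg = simulation_config(), seed = cfg$seed, template = NULL) {
  validate_simulation_config(cfg)
  if (is.null(template)) template <- build_template(cfg$n_points, cfg$template_seed)
  t_nr <- simulate_nonrigid(template, cfg, derive_seed(seed, 1))
  variant <- simulate_rigid(t_nr, cfg, derive_seed(seed, 2))
  gt <- ground_truth_field(template, variant)
  target <- sample_partial(variant, cfg, derive_seed(seed, 3))
  vcloud <- model_cloud(variant)
  structure(list(template = model_cloud(template),
                 template_model = template,
                 variant = vcloud,
                 variant_model = variant,
                 target = target,
                 gt_displacement = gt,
                 landmarks_template = template$landmarks,
                 landmarks_target = variant$landmarks,
                 visible_ratio = n_points(target) / n_points(vcloud),
                 seed = seed,
                 config = cfg),
            class = "ear_sample")
}

#' @export
print.ear_sample <- function(x, ...) {
  cat(sprintf("<ear_sample: template %d pts, target %d pts, visible ratio %.3f, mean |gt| %.3f mm>\n",
              n_points(x$template), n_points(x$target), x$visible_ratio,
              mean(sqrt(rowSums(x$gt_displacement$vectors^2)))))
  invisible(x)
}

#' Generate a dataset of synthetic samples on disk
#'
#' Writes `n` samples (per-sample seeds `seed + i`), the shared template and
#' a manifest. Clouds are stored as ascii PLY, displacement fields as
#' 3-column CSV aligned with template rows, landmarks and metadata as JSON.
#'
#' @param n number of samples (>= 1).
#' @param cfg a `simulation_config`.
#' @param seed base seed.
#' @param out_dir output directory (created if needed).
#' @return the manifest as a data.frame (one row per sample: directory, seed,
#'   visible ratio, mean ground-truth displacement norm).
#' @export
generate_dataset <- function(n, cfg = simulation_config(), seed = cfg$seed, out_dir) {
  if (n < 1) err("n must be >= 1", "config_error")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    err(sprintf("cannot create output directory '%s'", out_dir), "io_error")
  }
  template <- build_template(cfg$n_points, cfg$template_seed)
  write_point_cloud(model_cloud(template), file.path(out_dir, "template.ply"))
  write_landmarks(template$landmarks, file.path(out_dir, "template_landmarks.json"))
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- generate_sample(cfg, seed + i, template = template)
    sdir <- file.path(out_dir, sprintf("sample_%04d", i))
    dir.create(sdir, showWarnings = FALSE)
    write_point_cloud(smp$target, file.path(sdir, "target.ply"))
    write_point_cloud(smp$variant, file.path(sdir, "variant.ply"))
    write_field(smp$gt_displacement, file.path(sdir, "gt_displacement.csv"))
    write_landmarks(smp$landmarks_target, file.path(sdir, "landmarks_target.json"))
    mean_gt <- mean(sqrt(rowSums(smp$gt_displacement$vectors^2)))
    jsonlite::write_json(list(seed = smp$seed, visible_ratio = smp$visible_ratio,
                              mean_gt_displacement = mean_gt),
                         file.path(sdir, "meta.json"), auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(sample = basename(sdir), seed = seed + i,
                            visible_ratio = smp$visible_ratio,
                            mean_gt_displacement = mean_gt,
                            files = I(list(c("target.ply", "variant.ply",
                                             "gt_displacement.csv",
                                             "landmarks_target.json", "meta.json"))))
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
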