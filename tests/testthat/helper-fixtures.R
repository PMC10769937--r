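# Shared fixtures, generated in code. The cache avoids rebuilding the same
# template/sample across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small template (250 points) for fast unit tests
small_counts <- c(canal_wall = 60L, tympanic_membrane = 55L, malleus = 50L,
                  incus = 50L, stapes = 50L)

small_template <- function() cached("small_template", build_template(small_counts, seed = 20))

small_config <- function(...) {
  simulation_config(n_points = small_counts, ...)
}

# configuration that keeps every variant vertex, un-jittered; overrides win
keepall_config <- function(n_points = small_counts, ...) {
  args <- list(n_points = n_points, visibility_lambda = Inf,
               visibility_noise_sd = 0, base_visible_frac = 1,
               occlusion_range = c(1, 1), jitter_delta = 0)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# fast pyramid settings for unit tests (full defaults are exercised in the
# acceptance suite)
tiny_pyramid <- function(...) {
  pyramid_config(n_levels = 4L, max_iters_per_level = 25L, patience = 6L, ...)
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

random_cloud <- function(n, seed = 1, scale = 5) {
  local_seed(seed, point_cloud(matrix(runif(3 * n, -scale, scale), ncol = 3)))
}

random_rigid <- function(seed = 1, max_deg = 30, max_t = 2) {
  local_seed(seed,
             rigid_transform(rotation_about_axis(rnorm(3), runif(1, -max_deg, max_deg)),
                             runif(3, -max_t, max_t)))
}

# exhaustive double-loop Chamfer distance (independent oracle)
brute_chamfer <- function(A, B) {
  A <- if (inherits(A, "point_cloud")) A$points else A
  B <- if (inherits(B, "point_cloud")) B$points else B
  mins_ab <- vapply(seq_len(nrow(A)), function(i) {
    min(vapply(seq_len(nrow(B)), function(j) sqrt(sum((A[i, ] - B[j, ])^2)), 0))
  }, 0)
  mins_ba <- vapply(seq_len(nrow(B)), function(j) {
    min(vapply(seq_len(nrow(A)), function(i) sqrt(sum((A[i, ] - B[j, ])^2)), 0))
  }, 0)
  mean(mins_ab) + mean(mins_ba)
}

temp_dir <- function() {
  d <- tempfile("earalign-test-")
  dir.create(d, recursive = TRUE)
  d
}
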