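test_that("rigid application matches analytic cases and carries metadata", {
  pc <- point_cloud(rbind(c(1, 0, 0), c(0, 2, 0)), labels = c("a", "b"),
                    source_index = c(3L, 7L))
  out <- apply_rigid(rigid_identity(), pc)
  expect_equal(out$points, pc$points)
  expect_identical(out$labels, pc$labels)
  expect_identical(out$source_index, pc$source_index)

  rz90 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90))
  expect_equal(apply_rigid(rz90, matrix(c(1, 0, 0), 1))[1, ], c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("rigid application preserves pairwise distances on random clouds", {
  for (s in 1:5) {
    pc <- random_cloud(40, seed = s)
    t <- random_rigid(seed = s + 100)
    d0 <- dist(pc$points)
    d1 <- dist(apply_rigid(t, pc)$points)
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("composition equals sequential application and group laws hold", {
  a <- random_rigid(seed = 1)
  b <- random_rigid(seed = 2)
  cc <- random_rigid(seed = 3)
  pts <- random_cloud(100, seed = 4)$points
  expect_equal(apply_rigid(compose_rigid(a, b), pts),
               apply_rigid(a, apply_rigid(b, pts)), tolerance = 1e-9)
  # identity laws
  t <- random_rigid(seed = 5)
  expect_equal(compose_rigid(rigid_identity(), t)$rotation, t$rotation, tolerance = 1e-12)
  ti <- compose_rigid(t, invert_rigid(t))
  expect_lt(max(abs(ti$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ti$translation)), 1e-9)
  # associativity
  lhs <- compose_rigid(compose_rigid(a, b), cc)
  rhs <- compose_rigid(a, compose_rigid(b, cc))
  expect_equal(lhs$rotation, rhs$rotation, tolerance = 1e-9)
  expect_equal(lhs$translation, rhs$translation, tolerance = 1e-9)
})

test_that("invalid transforms are rejected", {
  expect_error(rigid_transform(matrix(1:9, 3, 3)), class = "invalid_transform_error")
  refl <- diag(c(1, 1, -1))  # orthonormal but improper
  expect_error(rigid_transform(refl), class = "invalid_transform_error")
})

test_that("fit_rigid recovers a constructed transform exactly", {
  src <- random_cloud(25, seed = 9)
  t <- random_rigid(seed = 10)
  dst <- apply_rigid(t, src)
  fit <- fit_rigid(src, dst)
  expect_lt(max(abs(fit$rotation - t$rotation)), 1e-9)
  expect_lt(max(abs(fit$translation - t$translation)), 1e-9)
  # src = dst with identity pairs gives the identity
  fit0 <- fit_rigid(src, src)
  expect_lt(max(abs(fit0$rotation - diag(3))), 1e-9)
})

test_that("fit_rigid residual beats 1,000 random perturbed transforms", {
  src <- random_cloud(30, seed = 11)
  t <- random_rigid(seed = 12)
  set.seed(13)
  dst <- point_cloud(apply_rigid(t, src)$points + matrix(rnorm(90, sd = 0.01), ncol = 3))
  fit <- fit_rigid(src, dst)
  sse <- function(tr) sum((apply_rigid(tr, src)$points - dst$points)^2)
  best <- sse(fit)
  set.seed(14)
  for (i in 1:1000) {
    pert <- rigid_transform(
      fit$rotation %*% rotation_about_axis(rnorm(3), runif(1, -2, 2)),
      fit$translation + runif(3, -0.05, 0.05))
    expect_gte(sse(pert), best - 1e-12)
  }
})

test_that("fit_rigid is invariant to a common rigid motion of both clouds", {
  src <- random_cloud(20, seed = 15)
  t <- random_rigid(seed = 16)
  dst <- apply_rigid(t, src)
  g <- random_rigid(seed = 17)
  fit0 <- fit_rigid(src, dst)
  fitg <- fit_rigid(apply_rigid(g, src), apply_rigid(g, dst))
  # relative transform in the moved frame is g fit0 g^-1
  expected <- compose_rigid(g, compose_rigid(fit0, invert_rigid(g)))
  expect_lt(max(abs(fitg$rotation - expected$rotation)), 1e-9)
  expect_lt(max(abs(fitg$translation - expected$translation)), 1e-9)
})

test_that("degenerate correspondence configurations are rejected", {
  line <- point_cloud(cbind(1:5, 0, 0))
  expect_error(fit_rigid(line, line), class = "degenerate_fit_error")
  two <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(fit_rigid(two, two), class = "degenerate_fit_error")
})

test_that("correspondence sets validate indices and duplicates", {
  expect_error(correspondence_set(rbind(c(1, 1), c(1, 1))),
               class = "invalid_correspondence_error")
  expect_error(correspondence_set(rbind(c(0, 1))), class = "invalid_correspondence_error")
  sigma <- correspondence_set(rbind(c(1, 2), c(2, 1)))
  expect_error(earalign:::check_correspondences(sigma, 1, 5),
               class = "invalid_correspondence_error")
})
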