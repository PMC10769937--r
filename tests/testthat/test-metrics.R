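test_that("Chamfer distance matches analytic cases and is symmetric", {
  a <- point_cloud(rbind(c(0, 0, 0)))
  b <- point_cloud(rbind(c(1, 0, 0)))
  expect_equal(chamfer_distance(a, a), 0)
  expect_equal(chamfer_distance(a, b), 2.0)
  c2 <- point_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(chamfer_distance(c2, b), 2.0)  # (1+1)/2 + 1
  for (s in 1:5) {
    A <- random_cloud(sample(5:50, 1), seed = s)
    B <- random_cloud(sample(5:50, 1), seed = s + 50)
    expect_equal(chamfer_distance(A, B), chamfer_distance(B, A), tolerance = 1e-12)
    expect_gte(chamfer_distance(A, B), 0)
    expect_equal(chamfer_distance(A, A), 0)
  }
})

test_that("mean displacement error matches analytic and brute-force values", {
  est <- displacement_field(matrix(0, 6, 3))
  expect_equal(mde(est, est), 0)
  gt <- displacement_field(matrix(rep(c(-3, -4, 0), each = 6), 6, 3))
  expect_equal(mde(est, gt), 5.0)
  E <- local_seed(71, matrix(rnorm(30), 10, 3))
  G <- local_seed(72, matrix(rnorm(30), 10, 3))
  brute <- mean(vapply(1:10, function(i) sqrt(sum((E[i, ] - G[i, ])^2)), 0))
  expect_equal(mde(E, G), brute, tolerance = 1e-12)
  expect_error(mde(E, G[1:5, ]), class = "precondition_error")
})

test_that("mde satisfies the triangle inequality on random triples", {
  for (s in 1:10) {
    a <- local_seed(s, matrix(rnorm(24), 8, 3))
    b <- local_seed(s + 20, matrix(rnorm(24), 8, 3))
    cc <- local_seed(s + 40, matrix(rnorm(24), 8, 3))
    expect_lte(mde(a, cc), mde(a, b) + mde(b, cc) + 1e-12)
  }
})

test_that("landmark error is structure-restricted and permutation-invariant", {
  exv <- list(A = rbind(c(0, 0, 0)))
  inv <- list(A = rbind(c(1, 0, 0), c(0, 2, 0)))
  expect_equal(as.numeric(landmark_error(exv, inv)), 1.0)
  expect_equal(as.numeric(landmark_error(exv, exv)), 0)
  # a nearer landmark in a different structure must be ignored
  inv2 <- list(A = rbind(c(2, 0, 0)), B = rbind(c(0.5, 0, 0)))
  expect_equal(as.numeric(landmark_error(exv, inv2)), 2.0)
  # permuting landmarks within a structure changes nothing
  inv_perm <- list(A = inv$A[2:1, , drop = FALSE])
  expect_equal(as.numeric(landmark_error(exv, inv_perm)),
               as.numeric(landmark_error(exv, inv)))
  # structures on one side only are skipped and reported
  le <- landmark_error(c(exv, list(C = rbind(c(9, 9, 9)))), inv)
  expect_identical(attr(le, "skipped"), "C")
  expect_error(landmark_error(list(X = rbind(c(0, 0, 0))), inv),
               class = "precondition_error")
})

test_that("visible ratio is the exact count quotient", {
  tgt <- random_cloud(500, seed = 1)
  var <- random_cloud(1000, seed = 2)
  expect_equal(visible_ratio(tgt, var), 0.5)
  expect_equal(visible_ratio(var, var), 1.0)
  smp <- generate_sample(keepall_config(), seed = 4)
  expect_equal(visible_ratio(smp$target, smp$variant), 1.0)
})

test_that("sample evaluation is exact for perfect and identity results", {
  cfg0 <- keepall_config(nonrigid_bounds = list(translation = 0, rotation = 0),
                         rigid_bounds = list(rotation = 0, translation = 0))
  smp0 <- generate_sample(cfg0, seed = 6)
  perfect0 <- evaluate_sample(smp0$gt_displacement, smp0, "undeformed")
  expect_equal(perfect0$mde, 0)
  expect_equal(perfect0$landmark_error, 0)
  expect_equal(perfect0$chamfer, 0)

  cfg <- keepall_config()
  smp <- generate_sample(cfg, seed = 6)
  perfect <- evaluate_sample(smp$gt_displacement, smp, "perfect")
  expect_equal(perfect$mde, 0)
  # landmarks ride the nearest vertex, so a deformed sample leaves only the
  # small interpolation residual
  expect_lt(perfect$landmark_error, 0.2)
  identity_res <- evaluate_sample(displacement_field(matrix(0, n_points(smp$template), 3)),
                                  smp, "identity")
  expect_equal(identity_res$mde,
               mean(sqrt(rowSums(smp$gt_displacement$vectors^2))), tolerance = 1e-12)
})

test_that("metric reports survive a serialization round-trip", {
  cfg <- keepall_config()
  smp <- generate_sample(cfg, seed = 7)
  rep1 <- evaluate_sample(smp$gt_displacement, smp, "s1")
  path <- file.path(temp_dir(), "report.csv")
  write_report(rep1, path)
  rep2 <- read_report(path)
  for (col in c("mde", "chamfer", "landmark_error", "visible_ratio")) {
    expect_equal(rep2[[col]], rep1[[col]], tolerance = 1e-12)
  }
})
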