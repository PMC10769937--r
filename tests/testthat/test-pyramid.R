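test_that("sinusoidal encodings match analytic values and are periodic", {
  e0 <- sinusoidal_encode(matrix(0, 1, 3), k = 3, k0 = -2)
  expect_equal(as.numeric(e0), c(0, 0, 0, 1, 1, 1))
  e1 <- sinusoidal_encode(matrix(c(pi / 2, 0, 0), 1), k = 0, k0 = 0)
  expect_equal(as.numeric(e1), c(1, 0, 0, 0, 1, 1), tolerance = 1e-12)
  p <- matrix(runif(30), 10, 3)
  for (k in c(0, 2, 5)) {
    shift <- 2 * pi / 2^(k - 3)
    expect_equal(sinusoidal_encode(p, k, -3),
                 sinusoidal_encode(p + shift, k, -3), tolerance = 1e-9)
  }
  expect_error(sinusoidal_encode(p, k = -1), class = "config_error")
})

test_that("masked correspondence loss matches analytic and brute-force values", {
  # coincident masked set
  src <- point_cloud(rbind(c(0, 0, 0), c(9, 9, 9)))
  tgt <- point_cloud(rbind(c(0, 0, 0)))
  sigma <- correspondence_set(rbind(c(1, 1)))
  expect_equal(correspondence_loss(src, tgt, sigma), 0)
  # singleton pair at distance 1: both Chamfer terms equal 1
  tgt2 <- point_cloud(rbind(c(1, 0, 0)))
  expect_equal(correspondence_loss(src, tgt2, sigma), 2.0)
  # random case vs exhaustive double loop, masking half the source
  A <- random_cloud(10, seed = 61)
  B <- random_cloud(8, seed = 62)
  sig <- correspondence_set(cbind(c(1, 3, 5, 7, 9), c(1, 2, 3, 4, 5)))
  expect_equal(correspondence_loss(A, B, sig),
               brute_chamfer(A$points[c(1, 3, 5, 7, 9), ], B$points),
               tolerance = 1e-12)
  expect_error(correspondence_loss(A, B, list()), class = "precondition_error")
})

test_that("registering a cloud onto itself predicts almost no motion", {
  src <- model_cloud(small_template())
  sigma <- correspondence_set(cbind(seq_len(n_points(src)), seq_len(n_points(src))))
  res <- ndp_register(src, src, sigma, tiny_pyramid())
  bbox_diag <- sqrt(sum((apply(src$points, 2, max) - apply(src$points, 2, min))^2))
  expect_lt(mean(sqrt(rowSums(res$field$vectors^2))), 0.01 * bbox_diag)
})

test_that("a smooth low-frequency bend is recovered to within a quarter of its size", {
  tmpl <- model_cloud(build_template(c(canal_wall = 500, tympanic_membrane = 400,
                                       malleus = 250, incus = 200, stapes = 150),
                                     seed = 20))
  # gentle global bend: displacement grows smoothly with depth
  z <- tmpl$points[, 3]
  gt <- cbind(0.25 * sin(z / 3), 0.2 * (z / 8)^2, 0.15 * cos(z / 4))
  target <- point_cloud(tmpl$points + gt, source_index = seq_len(nrow(gt)))
  mdes <- vapply(1:3, function(s) {
    res <- register_c2p(tmpl, target, backend = "oracle",
                        cfg = pyramid_config(seed = s))
    mde(res$field, displacement_field(gt))
  }, 0)
  expect_lt(median(mdes), 0.25 * mean(sqrt(rowSums(gt^2))))
})

test_that("per-level total loss of the applied increments never exceeds the initial loss", {
  cfg <- keepall_config()
  smp <- generate_sample(cfg, seed = 5)
  s1 <- stage1_estimate(smp$template, smp$target, "oracle")
  aligned <- apply_rigid(s1$transform, smp$template)
  res <- ndp_register(aligned, smp$target, s1$correspondences, tiny_pyramid())
  for (d in res$diagnostics) {
    expect_true(all(is.finite(d$loss_total)))
    expect_lte(length(d$loss_total), tiny_pyramid()$max_iters_per_level)
    expect_lte(min(d$loss_total), d$loss_total[1] + 1e-12)
    # best-so-far sequence (accepted iterations) is non-increasing
    expect_true(all(diff(cummin(d$loss_total)) <= 0))
  }
})

test_that("level-1 increments are spatially smooth when the motion is a shift", {
  src <- model_cloud(small_template())
  target <- point_cloud(sweep(src$points, 2, c(0.8, -0.3, 0.5), "+"),
                        source_index = seq_len(n_points(src)))
  sigma <- correspondence_set(cbind(seq_len(n_points(src)), seq_len(n_points(src))))
  res <- ndp_register(src, target, sigma,
                      pyramid_config(n_levels = 1, max_iters_per_level = 120,
                                     k0 = -8, patience = 20))
  f <- res$field$vectors
  mean_norm <- mean(sqrt(rowSums(f^2)))
  ext <- max(apply(src$points, 2, max) - apply(src$points, 2, min))
  nn <- earalign:::cpp_knn(src$points, src$points, 2)
  close_pairs <- which(nn$dist[, 2] < ext / 10)
  diffs <- sqrt(rowSums((f[close_pairs, , drop = FALSE] -
                           f[nn$idx[close_pairs, 2], , drop = FALSE])^2))
  expect_lt(max(diffs), 0.1 * mean_norm)
})

test_that("full pipeline output is deterministic and expressed in the source frame", {
  cfg <- keepall_config()
  smp <- generate_sample(cfg, seed = 9)
  r1 <- register_c2p(smp$template, smp$target, backend = "oracle", cfg = tiny_pyramid())
  r2 <- register_c2p(smp$template, smp$target, backend = "oracle", cfg = tiny_pyramid())
  expect_lt(abs(mde(r1$field, smp$gt_displacement) -
                  mde(r2$field, smp$gt_displacement)), 1e-6)
  # deformed = source + field by construction
  expect_equal(r1$deformed$points, smp$template$points + r1$field$vectors,
               tolerance = 1e-12)
})

test_that("non-finite inputs and empty correspondence sets are rejected", {
  src <- random_cloud(20, seed = 3)
  expect_error(ndp_register(src, src, correspondence_set(rbind(c(25, 1))),
                            tiny_pyramid()),
               class = "invalid_correspondence_error")
  expect_error(pyramid_config(n_levels = 0), class = "config_error")
  expect_error(pyramid_config(stop_tol = 0), class = "config_error")
})
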