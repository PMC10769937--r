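test_that("template construction is deterministic and anatomically ordered", {
  m1 <- build_template(small_counts, seed = 20)
  m2 <- build_template(small_counts, seed = 20)
  expect_identical(m1, m2)
  counts <- vapply(m1$structures, n_points, 1L)
  expect_identical(unname(counts), unname(small_counts[names(counts)]))
  depths <- vapply(m1$structures, function(s) mean(s$points[, 3]), 0)
  expect_true(all(diff(depths) > 0))  # anterior -> posterior along z
  expect_error(build_template(c(canal_wall = 10, tympanic_membrane = 50,
                                malleus = 50, incus = 50, stapes = 50)),
               class = "config_error")
})

test_that("zero deformation bounds reproduce the template identically end-to-end", {
  cfg <- keepall_config(nonrigid_bounds = list(translation = 0, rotation = 0),
                        rigid_bounds = list(rotation = 0, translation = 0))
  tmpl <- small_template()
  nr <- simulate_nonrigid(tmpl, cfg, seed = 4)
  expect_identical(nr$structures, tmpl$structures)
  rg <- simulate_rigid(nr, cfg, seed = 5)
  expect_identical(rg$structures, tmpl$structures)
  smp <- generate_sample(cfg, seed = 6)
  expect_equal(smp$visible_ratio, 1.0)
  expect_true(all(smp$gt_displacement$vectors == 0))
  expect_identical(smp$target$points, smp$variant$points)
})

test_that("simulation stages are deterministic under a fixed seed", {
  cfg <- small_config()
  s1 <- generate_sample(cfg, seed = 33)
  s2 <- generate_sample(cfg, seed = 33)
  expect_identical(s1$target, s2$target)
  expect_identical(s1$gt_displacement, s2$gt_displacement)
  s3 <- generate_sample(cfg, seed = 34)
  expect_false(identical(s1$target$points, s3$target$points))
})

test_that("lattice deformation respects the control-point displacement bound", {
  cfg <- small_config(nonrigid_bounds = list(translation = 0.4, rotation = 6))
  tmpl <- small_template()
  nr <- simulate_nonrigid(tmpl, cfg, seed = 9)
  # trilinear weights are convex: no vertex can move farther than the most
  # displaced control node; bound each group motion by rotation sweep +
  # translation, accumulated over the three axis partitions
  for (nm in names(tmpl$structures)) {
    v_disp <- sqrt(rowSums((nr$structures[[nm]]$points - tmpl$structures[[nm]]$points)^2))
    ext <- max(dist(tmpl$structures[[nm]]$points))
    per_group_cap <- 0.4 + 2 * sin(pi * 6 / 360) * ext
    expect_lte(max(v_disp), 3 * per_group_cap + 1e-9)
  }
})

test_that("articulated pose simulation moves only downstream structures rigidly", {
  cfg <- small_config(rigid_bounds = list(
    default = list(rotation = 0, translation = 0),
    membrane_malleus = list(rotation = 10, translation = 0)))
  tmpl <- small_template()
  rg <- simulate_rigid(tmpl, cfg, seed = 11)
  disp <- vapply(names(tmpl$structures), function(nm) {
    mean(sqrt(rowSums((rg$structures[[nm]]$points - tmpl$structures[[nm]]$points)^2)))
  }, 0)
  expect_equal(unname(disp[c("canal_wall", "tympanic_membrane")]), c(0, 0))
  expect_true(all(disp[c("malleus", "incus", "stapes")] > 1e-3))
  # rigidity: within-structure distances preserved
  for (nm in names(tmpl$structures)) {
    d0 <- dist(tmpl$structures[[nm]]$points)
    d1 <- dist(rg$structures[[nm]]$points)
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("ground-truth fields difference the variant against the template", {
  tmpl <- small_template()
  expect_true(all(ground_truth_field(tmpl, tmpl)$vectors == 0))
  shifted <- tmpl
  for (nm in names(shifted$structures)) {
    shifted$structures[[nm]] <- point_cloud(sweep(tmpl$structures[[nm]]$points, 2,
                                                  c(1, 0, 0), "+"))
  }
  f <- ground_truth_field(tmpl, shifted)
  expect_equal(unname(colMeans(f$vectors)), c(1, 0, 0), tolerance = 1e-12)
  # brute-force mean norm on a 3-point toy model
  toy_a <- ear_model(list(a = point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
                          b = point_cloud(rbind(c(5, 5, 5)))),
                     list(c(0, 0, 0)),
                     list(a = c(0, 0, 0), b = c(5, 5, 5)),
                     list(a = matrix(0, 1, 3), b = matrix(5, 1, 3)))
  toy_b <- toy_a
  toy_b$structures$a <- point_cloud(rbind(c(0, 0, 1), c(1, 2, 0), c(0, 1, 0)))
  expected <- mean(c(1, 2, 0, 0))  # per-vertex norms incl. untouched structure b
  f2 <- ground_truth_field(toy_a, toy_b)
  expect_equal(mean(sqrt(rowSums(f2$vectors^2))), expected, tolerance = 1e-12)
})

test_that("keep-all sampling returns the variant exactly; jitter is bounded", {
  cfg <- keepall_config()
  smp <- generate_sample(cfg, seed = 3)
  expect_identical(smp$target$points, smp$variant$points)
  expect_equal(smp$visible_ratio, 1.0)

  cfgj <- keepall_config(jitter_delta = 0.05)
  smpj <- generate_sample(cfgj, seed = 3)
  offs <- abs(smpj$target$points - smpj$variant$points[smpj$target$source_index, ])
  expect_lte(max(offs), 0.05)
  expect_gt(max(offs), 0)
})

test_that("partial sampling is a provenance-true subset with valid ratio", {
  cfg <- small_config(jitter_delta = 0)
  smp <- generate_sample(cfg, seed = 8)
  expect_true(all(smp$target$source_index >= 1 &
                  smp$target$source_index <= n_points(smp$variant)))
  expect_identical(smp$target$points,
                   smp$variant$points[smp$target$source_index, , drop = FALSE])
  expect_true(smp$visible_ratio > 0 && smp$visible_ratio <= 1)
  expect_equal(smp$visible_ratio, n_points(smp$target) / n_points(smp$variant))
})

test_that("deeper structures retain fewer points (Monte-Carlo occlusion)", {
  pts <- local_seed(77, matrix(runif(300, -0.5, 0.5), ncol = 3))
  shallow <- point_cloud(sweep(pts, 2, c(0, 0, 1), "+"))
  deep <- point_cloud(sweep(pts, 2, c(0, 0, 6), "+"))
  model <- ear_model(list(near = shallow, far = deep),
                     list(c(0, 0, 2)),
                     list(near = c(0, 0, 1), far = c(0, 0, 6)),
                     list(near = matrix(c(0, 0, 0), 1), far = matrix(c(0, 0, 6), 1)))
  cfg <- simulation_config(posterior_structures = c("near", "far"))
  counts <- t(vapply(1:200, function(i) {
    pc <- sample_partial(model, cfg, seed = i)
    c(sum(pc$labels == "near"), sum(pc$labels == "far"))
  }, numeric(2)))
  expect_gt(mean(counts[, 1]), mean(counts[, 2]))
})

test_that("datasets round-trip through the manifest", {
  out <- temp_dir()
  cfg <- small_config()
  man <- generate_dataset(3, cfg, seed = 50, out_dir = out)
  expect_equal(nrow(man), 3)
  expect_true(file.exists(file.path(out, "template.ply")))
  # manifest statistics equal recomputation from the stored artifacts
  for (i in seq_len(3)) {
    sdir <- file.path(out, man$sample[i])
    gt <- read_field(file.path(sdir, "gt_displacement.csv"))
    expect_equal(man$mean_gt_displacement[i], mean(sqrt(rowSums(gt$vectors^2))),
                 tolerance = 1e-12)
    tgt <- read_point_cloud(file.path(sdir, "target.ply"))
    var <- read_point_cloud(file.path(sdir, "variant.ply"))
    expect_equal(man$visible_ratio[i], n_points(tgt) / n_points(var))
  }
  # regeneration under the same seed is bitwise identical
  out2 <- temp_dir()
  generate_dataset(3, cfg, seed = 50, out_dir = out2)
  f1 <- file.path(out, "sample_0002", "target.ply")
  f2 <- file.path(out2, "sample_0002", "target.ply")
  expect_identical(readLines(f1), readLines(f2))
})
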