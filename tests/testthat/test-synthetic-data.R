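test_that("atlas phantom hosts every region exactly once and reproducibly", {
  regions <- region_table()
  at <- make_atlas_phantom(c(30, 30, 24), 0.2, regions, seed = 1)
  labs <- as.vector(at$labels)
  expect_identical(sort(unique(labs[labs > 0])), 1:42)
  expect_true(any(labs == 0L))  # background present
  # contiguity: every region is a single rectangular block
  for (r in c(1L, 8L, 42L)) {
    idx <- which(at$labels == r, arr.ind = TRUE)
    expect_equal(nrow(idx),
                 prod(apply(idx, 2, function(v) diff(range(v)) + 1L)))
  }
  at2 <- make_atlas_phantom(c(30, 30, 24), 0.2, regions, seed = 1)
  expect_identical(at$labels, at2$labels)
  at3 <- make_atlas_phantom(c(30, 30, 24), 0.2, regions, seed = 7)
  at4 <- make_atlas_phantom(c(30, 30, 24), 0.2, regions, seed = 7)
  expect_identical(at3$labels, at4$labels)
})

test_that("one-region atlas and sizing errors behave as specified", {
  one <- data.frame(id = 1L, name = "only", sensorimotor = TRUE)
  at <- make_atlas_phantom(c(6, 6, 6), 0.2, one, seed = 2)
  expect_identical(sort(unique(as.vector(at$labels))), c(0L, 1L))
  expect_error(make_atlas_phantom(c(4, 4, 4), 0.2, region_table(), seed = 1),
               "too small")
})

test_that("bundle tensors have the designed eigensystem", {
  ph <- straight_tube_phantom(ad = 1.7e-3, rd = 0.3e-3)
  mid_vox <- c(ph$pad + 13L, 3L, 3L)  # 1-based, inside the tube
  D <- tensor6_mat <- ph$tensors$D[mid_vox[1], mid_vox[2], mid_vox[3], ]
  M <- matrix(c(D[1], D[4], D[5], D[4], D[2], D[6], D[5], D[6], D[3]), 3, 3)
  e <- eigen(M, symmetric = TRUE)
  expect_equal(e$values, c(1.7e-3, 0.3e-3, 0.3e-3), tolerance = 1e-12)
  expect_equal(abs(e$vectors[, 1]), c(1, 0, 0), tolerance = 1e-12)
  # background voxel is isotropic
  Db <- ph$tensors$D[1, 1, 1, ]
  expect_equal(Db, c(rep(0.3e-3, 3), rep(0, 3)), tolerance = 1e-15)
})

test_that("a phantom without bundles is everywhere isotropic with FA 0", {
  atlas <- atlas_volume(array(1L, dim = c(6, 6, 6)), 0.2)
  tf <- make_bundle_tensor_field(atlas, list(), 0.3e-3)
  fa <- fa_map(eigen_decompose(tf))
  expect_true(all(fa$data == 0))
})

test_that("quarter-circle bundle tangents track the analytic tangent", {
  # quarter circle of radius 2 mm in the xy plane, from angle 0 to 90 deg
  theta <- seq(0, pi / 2, length.out = 60)
  center <- c(1, 1, 1)
  cl <- cbind(center[1] + 2 * cos(theta), center[2] + 2 * sin(theta),
              center[3])
  atlas <- atlas_volume(array(1L, dim = c(24, 24, 10)), 0.2)
  b <- bundle_spec(1, 1, cl, radius = 0.15, axial_diffusivity = 1.7e-3,
                   radial_diffusivity = 0.3e-3)
  tf <- make_bundle_tensor_field(atlas, list(b), 0.3e-3)
  eig <- eigen_decompose(tf)
  fa <- fa_map(eig)
  vox <- which(fa$data > 0.5, arr.ind = TRUE)
  expect_gt(nrow(vox), 20)
  max_err <- 0
  for (k in seq_len(nrow(vox))) {
    p <- (vox[k, ] - 0.5) * 0.2
    ang <- atan2(p[2] - center[2], p[1] - center[1])
    tang <- c(-sin(ang), cos(ang), 0)  # analytic tangent at that angle
    v <- eig$vectors[vox[k, 1], vox[k, 2], vox[k, 3], , 1]
    err <- acos(min(1, abs(sum(v * tang)))) * 180 / pi
    max_err <- max(max_err, err)
  }
  expect_lt(max_err, 5)
})

test_that("overlapping bundles warn and the last writer wins", {
  atlas <- atlas_volume(array(1L, dim = c(20, 6, 6)), 0.2)
  b1 <- bundle_spec(1, 1, rbind(c(0.3, 0.5, 0.5), c(3.5, 0.5, 0.5)),
                    radius = 0.15, axial_diffusivity = 1.0e-3,
                    radial_diffusivity = 0.2e-3)
  b2 <- bundle_spec(1, 1, rbind(c(0.3, 0.5, 0.5), c(3.5, 0.5, 0.5)),
                    radius = 0.15, axial_diffusivity = 1.6e-3,
                    radial_diffusivity = 0.2e-3)
  expect_warning(tf <- make_bundle_tensor_field(atlas, list(b1, b2), 0.3e-3),
                 "last writer")
  expect_equal(max(tf$D[, , , 1]), 1.6e-3, tolerance = 1e-12)
})

test_that("simulated DWI follows the tensor forward model exactly", {
  # isotropic tensor: signal s0 * exp(-b d) for every direction
  d <- 0.8e-3
  D <- array(0, dim = c(2, 2, 2, 6))
  D[, , , 1:3] <- d
  tv <- tensor_volume(D, 0.2)
  sch <- default_gradient_scheme(n_directions = 12, b = 2871.50, n_b0 = 2)
  dwi <- simulate_dwi(tv, sch, s0 = 100, noise_sd = 0)
  dw <- which(sch$bvals > 0)
  expect_equal(as.vector(dwi$data[, , , dw]),
               rep(100 * exp(-2871.50 * d), 8 * length(dw)),
               tolerance = 1e-12)
  # b = 0 volumes give s0 regardless of tensor
  expect_equal(as.vector(dwi$data[, , , -dw]), rep(100, 8 * 2))
  # anisotropic scalar check: diag(1.7, .3, .3)e-3, g = x
  D2 <- array(0, dim = c(1, 1, 1, 6))
  D2[1, 1, 1, ] <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  sch2 <- gradient_scheme(c(0, 2871.50, 2871.50, 2871.50, 2871.50,
                            2871.50, 2871.50, 2871.50),
                          rbind(c(0, 0, 0), diag(3),
                                cbind(sqrt(0.5), sqrt(0.5), 0),
                                cbind(sqrt(0.5), 0, sqrt(0.5)),
                                cbind(0, sqrt(0.5), sqrt(0.5)),
                                sqrt(c(1, 1, 1) / 3)))
  sig <- simulate_dwi(tensor_volume(D2, 0.2), sch2, s0 = 1)$data[1, 1, 1, 2]
  expect_equal(sig, exp(-4.88155), tolerance = 1e-6)
  # seeded noise is reproducible
  n1 <- simulate_dwi(tv, sch, s0 = 1, noise_sd = 0.01, seed = 5)
  n2 <- simulate_dwi(tv, sch, s0 = 1, noise_sd = 0.01, seed = 5)
  expect_identical(n1$data, n2$data)
  expect_error(simulate_dwi(tv, sch, s0 = 0), "positive")
})

test_that("network cohorts have the emulated study design shape", {
  spec <- cohort_spec(seed = 11)
  coh <- make_network_cohort(spec)
  expect_length(coh, 18)
  expect_identical(vapply(coh, `[[`, character(1), "group"),
                   rep(c("control", "stroke"), c(10, 8)))
  for (sub in coh) {
    W <- sub$network
    expect_identical(dim(W), c(42L, 42L))
    expect_true(all(diag(W) == 0))
    expect_lt(max(abs(W - t(W))), 1e-12)
    expect_true(all(W >= 0))
  }
  # determinism
  coh2 <- make_network_cohort(spec)
  expect_identical(unclass(coh[[3]]$network), unclass(coh2[[3]]$network))
})

test_that("the effect multiplier scales exactly the designated edge", {
  # degenerate noise-free construction: complete graph, deterministic weights
  spec <- cohort_spec(n_control = 4, n_stroke = 4,
                      effect_edges = list(c("S1 upper lip region",
                                            "S1 jaw region")),
                      effect_multiplier = 2,
                      base_weight_sdlog = 0, weight_decay = 0,
                      p_base = 1, edge_probability_decay = 0, seed = 3)
  coh <- make_network_cohort(spec)
  regions <- region_table()
  i <- match("S1 upper lip region", regions$name)
  j <- match("S1 jaw region", regions$name)
  wc <- sapply(coh[1:4], function(s) s$network[i, j])
  ws <- sapply(coh[5:8], function(s) s$network[i, j])
  expect_equal(mean(ws), 2 * mean(wc))
  # all other edges identical across groups (same deterministic base)
  other <- sapply(coh, function(s) s$network[1, 2])
  expect_equal(length(unique(other)), 1L)
})

test_that("a unit multiplier leaves no systematic group difference", {
  diffs <- vapply(1:40, function(s) {
    spec <- cohort_spec(n_control = 3, n_stroke = 3, effect_multiplier = 1,
                        seed = s)
    coh <- make_network_cohort(spec)
    mw <- vapply(coh, function(x) mean(x$network), numeric(1))
    mean(mw[4:6]) - mean(mw[1:3])
  }, numeric(1))
  expect_lt(abs(mean(diffs)) / (stats::sd(diffs) / sqrt(length(diffs))), 3)
})

test_that("deficit scores obey the link, the clip and the control zero", {
  regions <- region_table()
  spec <- cohort_spec(seed = 21,
                      behavior_link = list(metric = "mean_eccentricity",
                                           scope = "sensorimotor",
                                           intercept = 5, slope = 0,
                                           noise_sd = 0))
  coh <- make_network_cohort(spec)
  rec <- make_deficit_scores(coh, spec, regions)
  expect_true(all(rec$deficit_score[rec$group == "stroke"] == 5))
  expect_true(all(rec$deficit_score[rec$group == "control"] == 0))
  expect_true(all(rec$lesion_volume[rec$group == "control"] == 0))
  expect_true(all(rec$lesion_volume[rec$group == "stroke"] > 0))
  # ceiling: a link yielding raw value 25 is clipped to 20
  spec2 <- cohort_spec(seed = 21,
                       behavior_link = list(metric = "mean_eccentricity",
                                            scope = "sensorimotor",
                                            intercept = 25, slope = 0,
                                            noise_sd = 0))
  rec2 <- make_deficit_scores(coh, spec2, regions)
  expect_true(all(rec2$deficit_score[rec2$group == "stroke"] == 20))
  expect_error(
    make_deficit_scores(coh, cohort_spec(
      seed = 1, behavior_link = list(metric = "no_such_metric",
                                     scope = "sensorimotor", intercept = 0,
                                     slope = 1, noise_sd = 0)), regions),
    "unknown backbone metric")
})

test_that("scores stay on the 0-20 scale and track the metric", {
  regions <- region_table()
  metrics <- c(); scores <- c()
  for (s in 1:7) {
    spec <- cohort_spec(n_control = 1, n_stroke = 8, seed = s,
                        behavior_link = list(metric = "mean_eccentricity",
                                             scope = "sensorimotor",
                                             intercept = -4, slope = 2,
                                             noise_sd = 0.2))
    coh <- make_network_cohort(spec)
    rec <- make_deficit_scores(coh, spec, regions)
    st <- rec[rec$group == "stroke", ]
    metrics <- c(metrics, st$metric_value)
    scores <- c(scores, st$deficit_score)
  }
  expect_true(all(scores >= 0 & scores <= 20))
  expect_gt(stats::cor(metrics, scores), 0.9)
})

test_that("null cohorts give uniform group-comparison p-values", {
  pvals <- vapply(1:200, function(s) {
    spec <- cohort_spec(n_control = 4, n_stroke = 4, effect_multiplier = 1,
                        seed = s + 9000)
    coh <- make_network_cohort(spec)
    dens <- vapply(coh, function(x) mean(x$network[x$network > 0]),
                   numeric(1))
    group_compare(dens[1:4], dens[5:8])$p
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
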