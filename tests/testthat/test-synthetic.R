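test_that("phantom generation is deterministic and internally consistent", {
  spec <- phantom_spec(shape = c(48, 64, 48), n_mito = 3, n_vesicles = 5,
                       seed = 1)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume, b$volume)
  expect_identical(a$vesicles, b$vesicles)
  # masks are mutually disjoint, so priority fusion preserves them exactly
  sc <- fuse_priority(a$cell, a$nucleus, a$mito, a$vesicles)
  expect_identical(sc == 3L, array(a$nucleus, dim(a$nucleus)))
  expect_identical(sc == 2L, array(a$mito, dim(a$mito)))
  expect_identical(sc == 4L, a$vesicles > 0L)
  expect_true(all(a$volume >= 0))
  expect_equal(n_instances(a$vesicles), 5L)
  expect_equal(sum(a$placement$type == "vesicle"), 5L)
})

test_that("phantom with no vesicles is valid", {
  ph <- generate_phantom(phantom_spec(shape = c(40, 48, 40), n_mito = 2,
                                      n_vesicles = 0, seed = 2))
  expect_equal(n_instances(ph$vesicles), 0L)
  expect_true(all(is.finite(ph$volume)))
  expect_gt(sum(ph$cell), 0)
})

test_that("infeasible vesicle packing errors after bounded retries", {
  expect_error(
    generate_phantom(phantom_spec(shape = c(32, 32, 32), n_mito = 0,
                                  n_vesicles = 400,
                                  vesicle_radius_range = c(4, 5), seed = 3)),
    "packing")
})

test_that("uniform placement is contained, separated, and unbiased", {
  ph <- tiny_phantom()
  region <- ph$cell & !ph$nucleus
  expect_equal(nrow(place_centers_uniform(0, region)), 0L)
  one <- place_centers_uniform(1, region, seed = 4)
  expect_true(region[one])
  sep <- place_centers_uniform(25, region, min_sep = 5, seed = 5)
  dmat <- as.matrix(dist(sep))
  expect_true(all(dmat[upper.tri(dmat)] >= 5))
  # per-shell frequencies of many draws match shell volume fractions
  df <- distance_fields(ph$cell, ph$nucleus)
  sh <- shell_partition(df$d_nuc, df$d_pm)
  n <- 10000
  ctr <- place_centers_uniform(n, sh$shell_index > 0, seed = 6)
  counts <- tabulate(sh$shell_index[ctr], nbins = 8)
  p <- sh$shell_volumes / sh$cytosol_volume
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= 3 * se))
})

test_that("degrade_views injects the requested error rates", {
  ph <- tiny_phantom()
  gt <- array(ph$nucleus, dim(ph$nucleus))
  clean <- degrade_views(gt, list(fn_rate = 0, fp_rate = 0,
                                  boundary_jitter = 0), seed = 7)
  expect_identical(clean$x, gt)
  expect_identical(clean$y, gt)
  expect_identical(clean$z, gt)
  # fn_rate recovery across seeds
  removed <- c()
  for (s in 1:8) {
    vs <- degrade_views(gt, list(fn_rate = 0.1, fp_rate = 0,
                                 boundary_jitter = 0), seed = s)
    removed <- c(removed, vapply(vs, function(m) sum(gt & !m) / sum(gt),
                                 numeric(1)))
  }
  se <- sqrt(0.1 * 0.9 / (sum(gt) * length(removed)))
  expect_lt(abs(mean(removed) - 0.1), 3 * se)
})

test_that("voting fusion of degraded views beats the single views", {
  ph <- tiny_phantom()
  gt <- array(ph$nucleus, dim(ph$nucleus))
  err <- list(fn_rate = 0.1, fp_rate = 0.002, boundary_jitter = 0.2)
  wins <- 0L
  for (s in 1:10) {
    vs <- degrade_views(gt, err, seed = 100 + s)
    fused <- fuse_multiview(vs$x, vs$y, vs$z)
    d_single <- vapply(vs, function(m) dice(m, gt), numeric(1))
    if (dice(fused, gt) >= max(d_single)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("threshold segmentation recovers the phantom", {
  ph <- generate_phantom(phantom_spec(shape = c(64, 96, 72), n_mito = 5,
                                      n_vesicles = 8, noise_sd = 0,
                                      seed = 21))
  seg <- threshold_segment(ph$volume, default_thresholds(ph$spec))
  # noise-free: vesicle instance count equals the requested count
  expect_equal(n_instances(seg$vesicles), 8L)
  expect_gt(dice(seg$cell, ph$cell), 0.97)
  # noisy phantom: cell Dice stays >= 0.95
  phn <- tiny_phantom()
  segn <- threshold_segment(phn$volume, default_thresholds(phn$spec))
  expect_gte(dice(segn$cell, phn$cell), 0.95)
  # thresholds above the volume maximum -> error
  expect_error(threshold_segment(phn$volume, list(cell = 10, nucleus_hi = 11,
                                                  mito_lo = 12, mito_hi = 13,
                                                  vesicle = 14)),
               "cell threshold")
})

test_that("full pipeline closure at zero injected error", {
  ph <- generate_phantom(phantom_spec(shape = c(56, 80, 64), n_mito = 4,
                                      n_vesicles = 8, seed = 31))
  # semantic: degrade with zero error, fuse, compare
  for (organ in list(ph$cell, ph$nucleus, ph$mito)) {
    gt <- array(organ, dim(organ))
    vs <- degrade_views(gt, list(fn_rate = 0, fp_rate = 0,
                                 boundary_jitter = 0), seed = 1)
    fused <- fuse_multiview(vs$x, vs$y, vs$z)
    expect_gt(dice(fused, gt), 0.9)
  }
  # instances: slice the vesicle truth along X, relink, evaluate
  slices <- slice_volume(array(as.integer(ph$vesicles), dim(ph$vesicles)),
                         "x")
  linked <- link_instances(slices)
  expect_equal(dice(linked > 0L, ph$vesicles > 0L), 1)
  rec_pred <- extract_instances(linked)
  rec_gt <- extract_instances(ph$vesicles)
  expect_equal(instance_recall(rec_pred, rec_gt)$recall, 1)
})
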