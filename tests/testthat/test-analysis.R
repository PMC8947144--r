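test_that("distance fields match a brute-force nearest-neighbor scan", {
  withr::local_seed(31)
  d <- c(12, 11, 10)
  nucleus <- array(FALSE, d); nucleus[5:7, 5:6, 4:6] <- TRUE
  cell <- array(FALSE, d); cell[2:11, 2:10, 2:9] <- TRUE
  df <- distance_fields(cell, nucleus)
  expect_equal(df$d_nuc, bf_distance_to(nucleus))
  expect_equal(df$d_pm, bf_distance_to(!cell))
  # voxel face-adjacent to the nucleus
  expect_equal(df$d_nuc[8, 5, 5], 1)
  expect_error(distance_fields(cell, array(FALSE, d)), "empty")
})

test_that("nucleus voxels outside the cell trigger intersection warning", {
  d <- c(8, 8, 8)
  cell <- array(FALSE, d); cell[2:7, 2:7, 2:7] <- TRUE
  nucleus <- array(FALSE, d); nucleus[1:4, 4:5, 4:5] <- TRUE  # spills out
  expect_warning(df <- distance_fields(cell, nucleus), "outside")
  expect_equal(df$d_nuc[2, 4, 4], 0)     # intersected part kept
  expect_gt(df$d_nuc[1, 4, 4], 0)        # spilled part dropped
})

test_that("shell partition bins normalized depth and partitions cytosol", {
  d <- c(10, 10, 10)
  d_nuc <- array(0, d)
  d_pm <- array(0, d)
  # synthetic fields: lambda rises linearly along x
  for (i in 1:10) {
    d_nuc[i, , ] <- i - 1
    d_pm[i, , ] <- 10 - i
  }
  d_nuc[1, , ] <- 0   # nucleus plane
  d_pm[10, , ] <- 0   # membrane plane
  sh <- shell_partition(d_nuc, d_pm, n_shells = 8)
  # cytosol excludes the two zero planes
  expect_equal(sh$cytosol_volume, 8 * 100L)
  expect_equal(sum(sh$shell_volumes), sh$cytosol_volume)
  lam <- (2:9 - 1) / 9
  expect_equal(unique(as.integer(sh$shell_index[2:9, 1, 1])),
               unique(pmin(8L, floor(lam * 8) + 1L)))
  # lambda ~ 0 -> shell 1; lambda near 1 -> shell 8
  expect_equal(sh$shell_index[2, 1, 1], 1L)
  expect_equal(sh$shell_index[9, 1, 1], 8L)
})

test_that("shells on concentric spheres are spherical annuli of equal
          relative thickness", {
  d <- c(41, 41, 41)
  ctr <- c(21, 21, 21)
  nucleus <- make_sphere(d, ctr, 6)
  cell <- make_sphere(d, ctr, 18)
  df <- distance_fields(cell, nucleus)
  sh <- shell_partition(df$d_nuc, df$d_pm, 4)
  idx <- which(sh$shell_index > 0, arr.ind = TRUE)
  r <- sqrt(rowSums((idx - matrix(ctr, nrow(idx), 3, byrow = TRUE))^2))
  k <- sh$shell_index[sh$shell_index > 0]
  # radius bands (6..18 in 4 shells of 3): mean radius must be ordered
  mr <- tapply(r, k, mean)
  expect_true(all(diff(mr) > 0))
  # each shell's radii concentrate in its own band (allow 1-voxel blur)
  bands <- seq(6, 18, length.out = 5)
  for (s in 1:4)
    expect_gt(mean(r[k == s] >= bands[s] - 1 & r[k == s] <= bands[s + 1] + 1),
              0.97)
})

test_that("rdf_points follows the definition and conserves counts", {
  # hand-built partition with equal shell volumes
  d <- c(16, 8, 4)
  shell <- array(0L, d)
  for (s in 1:8) shell[(2 * s - 1):(2 * s), , ] <- s
  sh <- structure(list(shell_index = shell, n_shells = 8L,
                       shell_volumes = rep(64L, 8),
                       cytosol_volume = 512L), class = "sxt_shells")
  centers <- cbind(runif(20, 5, 6), runif(20, 1, 8), runif(20, 1, 4))
  r <- rdf_points(centers, sh)   # all in shell 3
  expect_equal(r$g, c(0, 0, 8, 0, 0, 0, 0, 0))
  expect_equal(sum(r$count), 20)
  one <- rdf_points(cbind(1, 1, 1), sh)
  expect_equal(sum(one$count), 1)
  expect_error(rdf_points(matrix(0, 0, 3), sh), "no centers")
})

test_that("rdf normalization: volume-weighted mean g is 1", {
  ph <- tiny_phantom()
  df <- distance_fields(ph$cell, ph$nucleus)
  sh <- shell_partition(df$d_nuc, df$d_pm)
  wmean <- function(r) sum(r$g * r$shell_volume) / sum(r$shell_volume)
  ctr <- place_centers_uniform(300, sh$shell_index > 0, seed = 1)
  expect_equal(wmean(rdf_points(ctr, sh)), 1)
  expect_equal(wmean(rdf_voxels(ph$mito & (sh$shell_index > 0), sh)), 1)
})

test_that("uniform placement gives g within 3 standard errors of 1", {
  ph <- tiny_phantom()
  df <- distance_fields(ph$cell, ph$nucleus)
  sh <- shell_partition(df$d_nuc, df$d_pm)
  n <- 800
  ctr <- place_centers_uniform(n, sh$shell_index > 0, seed = 5)
  r <- rdf_points(ctr, sh)
  p <- sh$shell_volumes / sh$cytosol_volume
  se_g <- sqrt((1 - p) / (n * p))
  expect_true(all(abs(r$g - 1) <= 3 * se_g))
})

test_that("rdf_voxels saturates at 1 and localizes to occupied shells", {
  ph <- tiny_phantom()
  df <- distance_fields(ph$cell, ph$nucleus)
  sh <- shell_partition(df$d_nuc, df$d_pm)
  whole <- sh$shell_index > 0
  expect_equal(rdf_voxels(whole, sh)$g, rep(1, 8))
  only8 <- sh$shell_index == 8L
  r8 <- rdf_voxels(only8, sh)
  expect_true(all(r8$g[1:7] == 0) && r8$g[8] > 0)
  # brute-force tally oracle on random blobs
  withr::local_seed(32)
  blob <- whole & array(runif(length(whole)) < 0.1, dim(whole))
  r <- rdf_voxels(blob, sh)
  manual <- vapply(1:8, function(s) sum(blob & sh$shell_index == s),
                   numeric(1))
  expect_equal(r$count, as.integer(manual))
})

test_that("contact detection matches the all-pairs distance oracle", {
  withr::local_seed(33)
  for (rep in 1:3) {
    d <- c(12, 12, 12)
    ves <- array(ifelse(runif(prod(d)) < 0.08, 1L, 0L), d)
    mito <- array(runif(prod(d)) < 0.08, d)
    cts <- detect_contacts(ves, mito, cutoff = 1.5)
    # oracle: vesicle voxels within < 1.5 of any mitochondria voxel
    dm <- bf_distance_to(mito)
    expect_identical(cts$contacts > 0L, ves > 0L & dm < 1.5)
  }
})

test_that("contacts obey the cutoff and are monotone in it", {
  d <- c(9, 5, 5)
  mito <- array(FALSE, d); mito[1, 3, 3] <- TRUE
  ves <- array(0L, d)
  ves[2, 3, 3] <- 1L   # distance 1 -> contact at cutoff 1.5
  ves[3, 3, 3] <- 1L   # distance 2 -> not a contact at 1.5
  cts <- detect_contacts(ves, mito, 1.5)
  expect_true(cts$contacts[2, 3, 3] > 0L)
  expect_false(cts$contacts[3, 3, 3] > 0L)
  withr::local_seed(34)
  ves2 <- array(ifelse(runif(12^3) < 0.1, 1L, 0L), c(12, 12, 12))
  mito2 <- array(runif(12^3) < 0.1, c(12, 12, 12))
  c1 <- detect_contacts(ves2, mito2, 1.2)$contacts > 0L
  c2 <- detect_contacts(ves2, mito2, 2.4)$contacts > 0L
  expect_true(all(c2[c1]))   # smaller cutoff is a subset
  # empty input -> empty contact set, not an error
  none <- detect_contacts(array(0L, d), mito, 1.5)
  expect_equal(none$n_contacts, 0L)
  r <- rdf_contacts(none, structure(list(
    shell_index = array(1L, d), n_shells = 2L, shell_volumes = c(225L, 0L),
    cytosol_volume = 225L), class = "sxt_shells"))
  expect_equal(sum(r$count), 0)
  expect_true(all(is.na(r$g)))
})

test_that("lac_radial_profile bins by boundary distance", {
  d <- c(9, 9, 9)
  vol <- array(0.2, d)
  inst <- array(FALSE, d); inst[5, 5, 5] <- TRUE
  p <- lac_radial_profile(vol, inst)      # single voxel -> single bin
  expect_equal(nrow(p), 1L)
  expect_equal(p$mean_lac, 0.2)
  expect_equal(attr(p, "center_voxel"), c(5L, 5L, 5L))
  # uniform sphere -> every bin equal
  sph <- make_sphere(d, c(5, 5, 5), 3.2)
  pu <- lac_radial_profile(vol, sph)
  expect_equal(pu$mean_lac, rep(0.2, nrow(pu)))
  expect_equal(sum(pu$n_voxels), sum(sph))
  expect_error(lac_radial_profile(vol, array(FALSE, d)), "empty")
})

test_that("dense-core vesicles give non-decreasing LAC toward the center", {
  quiet <- generate_phantom(phantom_spec(shape = c(64, 96, 72), n_mito = 4,
                                         n_vesicles = 10, noise_sd = 0.005,
                                         seed = 77))
  prof <- lac_profiles(quiet$volume, quiet$vesicles)
  for (l in unique(prof$label)) {
    p <- prof[prof$label == l, ]
    if (nrow(p) < 2) next
    expect_true(all(diff(p$mean_lac) > -0.002),
                label = paste("monotone LAC, vesicle", l))
  }
  ph <- tiny_phantom()
  # the max-LAC center sits near the geometric center by construction
  v1 <- lac_radial_profile(ph$volume, ph$vesicles == 1L)
  ctr <- attr(v1, "center_voxel")
  rec <- extract_instances(ph$vesicles)[1, ]
  expect_lt(sqrt(sum((ctr - c(rec$cx, rec$cy, rec$cz))^2)),
            rec$equiv_radius)
})

test_that("functional regions map shells to secretory-pathway spaces", {
  expect_equal(functional_regions(1), "perinuclear")
  expect_equal(functional_regions(2), "maturation")
  expect_equal(functional_regions(5), "transportation")
  expect_equal(functional_regions(8), "secretion")
  expect_equal(functional_regions(c(3, 4, 7)),
               c("maturation", "transportation", "secretion"))
  expect_error(functional_regions(0), "1..8")
  expect_error(functional_regions(9), "1..8")
})
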