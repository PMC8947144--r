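test_that("dice reproduces hand counts and the IoU identity", {
  a <- array(FALSE, c(5, 1, 1)); a[1:3, 1, 1] <- TRUE   # |A| = 3
  b <- array(FALSE, c(5, 1, 1)); b[2:3, 1, 1] <- TRUE   # |B| = 2, overlap 2
  expect_equal(dice(a, b), 4 / 5)
  expect_equal(dice(b, a), 4 / 5)                        # symmetric
  expect_equal(dice(a, a), 1)
  disj <- array(FALSE, c(5, 1, 1)); disj[5, 1, 1] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_error(dice(a & FALSE, b & FALSE), "undefined")
  # dice = 2 IoU / (1 + IoU) on random mask pairs
  withr::local_seed(21)
  for (rep in 1:5) {
    x <- array(runif(8^3) < 0.4, c(8, 8, 8))
    y <- array(runif(8^3) < 0.4, c(8, 8, 8))
    i <- iou(x, y)
    expect_equal(dice(x, y), 2 * i / (1 + i))
  }
})

test_that("match_distance normalizes center distance by summed radii", {
  a <- list(cx = 0, cy = 0, cz = 0, equiv_radius = 2)
  expect_equal(match_distance(a, a), 0)
  b <- list(cx = 3, cy = 0, cz = 0, equiv_radius = 2)
  expect_equal(match_distance(a, b), 0.75)    # d_u = 3, radii 2 + 2
  c3 <- list(cx = 0, cy = 5, cz = 0, equiv_radius = 2)
  expect_equal(match_distance(a, c3), 1.25)   # d_u = 5 -> no match
})

test_that("instance recall is 1 on identity and 0 when nothing matches", {
  ph <- tiny_phantom()
  rec <- extract_instances(ph$vesicles)
  m <- instance_recall(rec, rec)
  expect_equal(m$recall, 1)
  expect_equal(m$fn, 0L)
  expect_true(all(tidy(m)$d == 0))
  far <- dplyr::mutate(rec, cx = cx + 1000)
  expect_equal(instance_recall(far, rec)$recall, 0)
  expect_error(instance_recall(rec, rec[0, ]), "no instances")
})

test_that("greedy recall equals exhaustive optimal assignment when pairs
          are well separated", {
  withr::local_seed(22)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    gt <- tibble::tibble(
      label = seq_len(n),
      cx = runif(n, 0, 100), cy = runif(n, 0, 100), cz = runif(n, 0, 100),
      equiv_radius = runif(n, 1, 3))
    pred <- dplyr::mutate(gt,
      cx = cx + rnorm(n, 0, 1), cy = cy + rnorm(n, 0, 1),
      cz = cz + rnorm(n, 0, 1))
    expect_equal(instance_recall(pred, gt)$recall, bf_best_recall(pred, gt))
  }
})

test_that("recall is invariant to label permutation and rigid translation", {
  withr::local_seed(23)
  n <- 6
  gt <- tibble::tibble(label = 1:n, cx = runif(n, 0, 50),
                       cy = runif(n, 0, 50), cz = runif(n, 0, 50),
                       equiv_radius = runif(n, 1, 2))
  pred <- dplyr::mutate(gt, cx = cx + 0.5)
  r0 <- instance_recall(pred, gt)$recall
  perm <- sample(n)
  r1 <- instance_recall(pred[perm, ], gt)$recall
  shift <- function(df) dplyr::mutate(df, cx = cx + 7, cy = cy - 3, cz = cz + 1)
  r2 <- instance_recall(shift(pred), shift(gt))$recall
  expect_equal(r1, r0)
  expect_equal(r2, r0)
})

test_that("AP50 handles perfect, vacuous and partial predictions", {
  ph <- tiny_phantom()
  expect_equal(average_precision_50(ph$vesicles, ph$vesicles)$ap50, 1)
  # all predictions displaced beyond IoU 0.5 -> AP 0
  d <- dim(ph$vesicles)
  empty_like <- array(0L, d)
  empty_like[1, 1, 1] <- 1L
  expect_equal(average_precision_50(empty_like, ph$vesicles)$ap50, 0)
})

test_that("AP50 equals the hand-computed PR curve for 2-of-3 matches", {
  d <- c(20, 6, 2)
  gt <- array(0L, d)
  gt[1:4, 1:4, ] <- 1L; gt[7:10, 1:4, ] <- 2L; gt[13:16, 1:4, ] <- 3L
  pred <- array(0L, d)
  pred[1:4, 1:4, ] <- 1L        # perfect match of gt 1
  pred[7:10, 1:4, ] <- 2L       # perfect match of gt 2
  pred[17:20, 1:4, ] <- 3L      # misses everything
  ap <- average_precision_50(pred, gt, scores = c(0.9, 0.8, 0.7))
  # ranks: TP, TP, FP -> precision (1, 1, 2/3), recall (1/3, 2/3, 2/3)
  expect_equal(ap$ap50, 2 / 3)
  expect_equal(ap$curve$tp, c(TRUE, TRUE, FALSE))
  # deleting a true positive cannot increase AP
  pred2 <- pred; pred2[pred2 == 1L] <- 0L
  ap2 <- average_precision_50(pred2, gt, scores = c(0.8, 0.7))
  expect_lte(ap2$ap50, ap$ap50)
})

test_that("normalized_intensity scales each slice to max 1", {
  sl <- matrix(c(2, 4, 1, 0), 2)
  ni <- normalized_intensity(sl)
  expect_equal(ni[1, 1], 0.5)
  expect_equal(max(ni), 1)
  expect_true(all(normalized_intensity(matrix(3, 4, 4)) == 1))
  expect_error(normalized_intensity(matrix(0, 2, 2)), "positive")
  withr::local_seed(24)
  sl2 <- matrix(runif(30, 0.1, 1), 5)
  expect_equal(normalized_intensity(sl2), sl2 / max(sl2))
})

test_that("contrast_ratio recovers constructed intensity ratios", {
  d <- c(3, 20, 20)
  vol <- array(1.0, d)
  org <- array(FALSE, d); org[2, 8:12, 8:12] <- TRUE
  ctx <- array(TRUE, d)
  # equal intensities -> ratio 1
  expect_equal(contrast_ratio(vol, org, ctx & !org), 1)
  # organelle at 1.2x uniform surroundings
  vol[org] <- 1.2
  expect_equal(contrast_ratio(vol, org, ctx & !org), 1.2)
  expect_error(contrast_ratio(vol, array(FALSE, d), ctx), "empty")
})

test_that("phantom mitochondria recover the generated contrast ratio", {
  ph <- generate_phantom(phantom_spec(shape = c(80, 120, 90), n_mito = 8,
                                      n_vesicles = 12, seed = 99))
  cyto <- ph$cell & !ph$nucleus & !ph$mito & !(ph$vesicles > 0)
  cr <- contrast_ratio(ph$volume, ph$mito, cyto)
  target <- ph$spec$lac_levels$mitochondria[1] / ph$spec$lac_levels$cytoplasm[1]
  expect_lt(abs(cr - target), 0.02)
})

test_that("evaluate_segmentation reports all-ones on identical scenes", {
  ph <- tiny_phantom()
  sc <- fuse_priority(ph$cell, ph$nucleus, ph$mito, ph$vesicles)
  ev <- evaluate_segmentation(sc, sc, ph$vesicles, ph$vesicles)
  expect_true(all(ev$dice_per_class == 1, na.rm = TRUE))
  expect_equal(ev$recall, 1)
  expect_equal(ev$ap50, 1)
  g <- glance(ev)
  expect_equal(g$n_instances_pred, g$n_instances_gt)
  expect_equal(nrow(tidy(ev)), 6)
})
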