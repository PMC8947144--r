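#' Dice coefficient of two binary masks
#'
#' `2 |P intersect G| / (|P| + |G|)`; symmetric, 1 for identical masks,
#' 0 for disjoint masks. Related to IoU by `dice = 2 IoU / (1 + IoU)`.
#'
#' @param pred,gt Same-shape logical arrays; not both empty.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  if (is.numeric(pred)) pred <- pred > 0
  if (is.numeric(gt)) gt <- gt > 0
  if (!identical(dim(pred), dim(gt)))
    stop("masks differ in shape", call. = FALSE)
  denom <- sum(pred) + sum(gt)
  if (denom == 0L) stop("Dice of two empty masks is undefined", call. = FALSE)
  2 * sum(pred & gt) / denom
}

#' Normalized center distance between two instances
#'
#' The matching criterion for instance recall: the Euclidean distance
#' between the two centroids divided by the sum of the equivalent-sphere
#' radii, `d = d_u / (r_pred + r_gt)`. A pair with `d < 1` (centers
#' closer than the touching distance of the two equivalent spheres)
#' counts as a true positive.
#'
#' @param pred,gt Single instance records: one-row data frames (or lists)
#'   with `cx`, `cy`, `cz` and `equiv_radius`, as produced by
#'   [extract_instances()].
#' @return The normalized distance `d >= 0`.
#' @examples
#' a <- list(cx = 0, cy = 0, cz = 0, equiv_radius = 2)
#' b <- list(cx = 3, cy = 0, cz = 0, equiv_radius = 2)
#' match_distance(a, b)   # 0.75 -> a match
#' @export
match_distance <- function(pred, gt) {
  du <- sqrt((pred$cx - gt$cx)^2 + (pred$cy - gt$cy)^2 + (pred$cz - gt$cz)^2)
  rsum <- pred$equiv_radius + gt$equiv_radius
  if (any(rsum <= 0)) stop("radii must be positive", call. = FALSE)
  du / rsum
}

# full matrix of normalized distances, rows = pred, cols = gt
match_distance_matrix <- function(pred, gt) {
  du <- outer(pred$cx, gt$cx, "-")^2 + outer(pred$cy, gt$cy, "-")^2 +
    outer(pred$cz, gt$cz, "-")^2
  sqrt(du) / outer(pred$equiv_radius, gt$equiv_radius, "+")
}

#' Instance recall with normalized center-distance matching
#'
#' Matches predicted to ground-truth instances greedily: all (pred, gt)
#' pairs are sorted by ascending normalized distance [match_distance()],
#' each instance is used at most once, and matched pairs with `d < 1`
#' are true positives. Recall is `T_p / (T_p + F_n)` over ground-truth
#' instances.
#'
#' @param pred,gt Instance record tibbles from [extract_instances()];
#'   `gt` must be nonempty.
#' @return An object of class `sxt_match`: list with `recall`, `tp`,
#'   `fn`, `fp` and a `pairs` tibble (`pred_label`, `gt_label`, `d`).
#' @export
instance_recall <- function(pred, gt) {
  if (!nrow(gt)) stop("ground truth has no instances", call. = FALSE)
  pairs <- tibble::tibble(pred_label = integer(), gt_label = integer(),
                          d = double())
  if (nrow(pred)) {
    dm <- match_distance_matrix(pred, gt)
    ord <- order(dm)                      # ascending d, stable
    used_p <- logical(nrow(pred))
    used_g <- logical(nrow(gt))
    pi <- ((ord - 1L) %% nrow(pred)) + 1L
    gi <- ((ord - 1L) %/% nrow(pred)) + 1L
    keep_p <- integer(0); keep_g <- integer(0); keep_d <- double(0)
    for (r in seq_along(ord)) {
      if (used_p[pi[r]] || used_g[gi[r]]) next
      used_p[pi[r]] <- TRUE
      used_g[gi[r]] <- TRUE
      keep_p <- c(keep_p, pi[r]); keep_g <- c(keep_g, gi[r])
      keep_d <- c(keep_d, dm[ord[r]])
      if (all(used_p) || all(used_g)) break
    }
    pairs <- tibble::tibble(pred_label = pred$label[keep_p],
                            gt_label = gt$label[keep_g], d = keep_d)
  }
  tp <- sum(pairs$d < 1)
  structure(list(recall = tp / nrow(gt), tp = tp, fn = nrow(gt) - tp,
                 fp = nrow(pred) - tp, pairs = pairs),
            class = "sxt_match")
}

#' @export
print.sxt_match <- function(x, ...) {
  cat(sprintf("<sxt_match> recall %.3f (TP %d, FN %d, FP %d)\n",
              x$recall, x$tp, x$fn, x$fp))
  invisible(x)
}

#' @export
tidy.sxt_match <- function(x, ...) x$pairs

#' @export
glance.sxt_match <- function(x, ...) {
  tibble::tibble(recall = x$recall, tp = x$tp, fn = x$fn, fp = x$fp)
}

#' Average precision at mask IoU 0.5 (AP50)
#'
#' Single-class average precision for 3D instance segmentation.
#' Predictions are processed in descending confidence (uniform scores
#' allowed; ties broken by ascending label) and each prediction matches
#' the unmatched ground-truth instance of highest 3D mask IoU, provided
#' that IoU is at least 0.5. AP is the all-point-interpolated area under
#' the precision-recall curve.
#'
#' @param pred,gt Instance maps of the same shape.
#' @param scores Optional numeric vector of per-instance confidences for
#'   `pred` (by label); default uniform.
#' @return A list of class `sxt_ap`: `ap50`, and the per-prediction
#'   `curve` tibble (`label`, `score`, `tp`, `precision`, `recall`).
#' @export
average_precision_50 <- function(pred, gt, scores = NULL) {
  pred <- instance_map(pred)
  gt <- instance_map(gt)
  check_same_shape(pred, gt)
  n_gt <- n_instances(gt)
  if (n_gt == 0L) stop("ground truth has no instances", call. = FALSE)
  n_pred <- n_instances(pred)
  if (is.null(scores)) scores <- rep(1, n_pred)
  if (length(scores) != n_pred)
    stop("need one score per predicted instance", call. = FALSE)
  if (n_pred == 0L)
    return(structure(list(ap50 = 0, curve = tibble::tibble(
      label = integer(), score = double(), tp = logical(),
      precision = double(), recall = double())), class = "sxt_ap"))

  ov <- label_overlap_iou(pred, gt)
  ord <- order(-scores, seq_len(n_pred))
  used_g <- logical(n_gt)
  tp_flags <- logical(n_pred)
  for (idx in seq_along(ord)) {
    p <- ord[idx]
    cand <- ov[ov$a == p & ov$iou >= 0.5, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$iou, cand$b), , drop = FALSE]
    g <- cand$b[which(!used_g[cand$b])[1]]
    if (is.na(g)) next
    used_g[g] <- TRUE
    tp_flags[idx] <- TRUE
  }
  tp_cum <- cumsum(tp_flags)
  prec <- tp_cum / seq_len(n_pred)
  rec <- tp_cum / n_gt
  # all-point interpolation: envelope of precision from the right
  prec_env <- rev(cummax(rev(prec)))
  drec <- diff(c(0, rec))
  ap <- sum(drec * prec_env)
  structure(list(
    ap50 = ap,
    curve = tibble::tibble(label = ord, score = scores[ord], tp = tp_flags,
                           precision = prec, recall = rec)),
    class = "sxt_ap")
}

#' @export
print.sxt_ap <- function(x, ...) {
  cat(sprintf("<sxt_ap> AP50 = %.4f over %d predictions\n",
              x$ap50, nrow(x$curve)))
  invisible(x)
}

#' @export
tidy.sxt_ap <- function(x, ...) x$curve

#' Normalize a 2D slice by its maximum intensity
#'
#' Pixel intensity divided by the maximum intensity of the slice, the
#' normalization used for orthoslice intensity comparisons.
#'
#' @param slice 2D matrix with positive maximum.
#' @return Matrix of the same shape with values in `[0, 1]` and maximum 1.
#' @export
normalized_intensity <- function(slice) {
  m <- max(slice)
  if (!is.finite(m) || m <= 0)
    stop("slice maximum must be positive", call. = FALSE)
  slice / m
}

#' Contrast ratio of an organelle against its cytoplasmic surroundings
#'
#' The mean normalized intensity over organelle voxels divided by the
#' mean over a surrounding shell, computed slice-wise along X (each slice
#' normalized by its own maximum) and averaged over the slices containing
#' both organelle and shell voxels. The shell is the set of voxels within
#' `shell_width` of the organelle, inside `context` (typically the
#' cytoplasm mask with other organelles excluded) and outside the
#' organelle itself.
#'
#' @param vol LAC volume.
#' @param organelle Logical mask of the organelle (nonempty).
#' @param context Logical mask of admissible surrounding voxels.
#' @param shell_width Shell thickness in voxels (default 2).
#' @return The mean slice-wise contrast ratio (about 1.1 for mitochondria
#'   in typical tomograms, 1.2 for insulin vesicles).
#' @export
contrast_ratio <- function(vol, organelle, context, shell_width = 2) {
  organelle <- as_mask_array(organelle, "organelle")
  context <- as_mask_array(context, "context")
  check_same_shape(vol, organelle, context)
  if (!any(organelle)) stop("organelle mask is empty", call. = FALSE)
  dorg <- edt3d_cpp(organelle, dim(organelle))
  shell <- (dorg > 0) & (dorg <= shell_width) & context & !organelle
  if (!any(shell))
    stop("surrounding shell is empty: organelle touches no admissible ",
         "context within shell_width", call. = FALSE)
  xs <- which(apply(organelle, 1, any))
  ratios <- c()
  for (i in xs) {
    o2 <- organelle[i, , ]
    s2 <- shell[i, , ]
    if (!any(s2)) next
    ni <- normalized_intensity(vol[i, , ])
    ratios <- c(ratios, mean(ni[o2]) / mean(ni[s2]))
  }
  if (!length(ratios))
    stop("no slice contains both organelle and shell voxels", call. = FALSE)
  mean(ratios)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Computes the per-class Dice coefficients for the semantic classes of a
#' fused cell scene, plus instance recall and AP50 for the vesicle
#' instance maps when provided.
#'
#' @param pred_scene,gt_scene [cell_scene()]s of the same shape.
#' @param pred_vesicles,gt_vesicles Optional instance maps for vesicles;
#'   when omitted, instance metrics use the scene's vesicle voxels as a
#'   single semantic class and are skipped.
#' @param scores Optional per-instance confidences for `pred_vesicles`.
#' @return An object of class `sxt_eval` with elements `dice_per_class`,
#'   `recall`, `ap50`, `n_instances_pred`, `n_instances_gt`.
#' @export
evaluate_segmentation <- function(pred_scene, gt_scene,
                                  pred_vesicles = NULL, gt_vesicles = NULL,
                                  scores = NULL) {
  check_same_shape(pred_scene, gt_scene)
  classes <- c(cell = 1L, mitochondria = 2L, nucleus = 3L, vesicle = 4L)
  dice_per_class <- vapply(names(classes), function(cl) {
    code <- classes[[cl]]
    p <- if (cl == "cell") pred_scene >= 1L else pred_scene == code
    g <- if (cl == "cell") gt_scene >= 1L else gt_scene == code
    if (sum(p) + sum(g) == 0L) NA_real_ else dice(p, g)
  }, numeric(1))
  recall <- ap50 <- NA_real_
  n_pred <- n_gt <- NA_integer_
  match <- NULL
  if (!is.null(pred_vesicles) && !is.null(gt_vesicles)) {
    pred_vesicles <- instance_map(pred_vesicles)
    gt_vesicles <- instance_map(gt_vesicles)
    n_pred <- n_instances(pred_vesicles)
    n_gt <- n_instances(gt_vesicles)
    if (n_gt > 0L) {
      match <- instance_recall(extract_instances(pred_vesicles),
                               extract_instances(gt_vesicles))
      recall <- match$recall
      ap50 <- average_precision_50(pred_vesicles, gt_vesicles, scores)$ap50
    }
  }
  structure(list(dice_per_class = dice_per_class, recall = recall,
                 ap50 = ap50, n_instances_pred = n_pred,
                 n_instances_gt = n_gt, match = match),
            class = "sxt_eval")
}

#' @export
print.sxt_eval <- function(x, ...) {
  cat("<sxt_eval>\n  Dice:",
      paste(sprintf("%s %.3f", names(x$dice_per_class), x$dice_per_class),
            collapse = ", "), "\n")
  if (!is.na(x$recall))
    cat(sprintf("  Recall %.3f, AP50 %.3f, instances pred/gt %d/%d\n",
                x$recall, x$ap50, x$n_instances_pred, x$n_instances_gt))
  invisible(x)
}

#' @export
tidy.sxt_eval <- function(x, ...) {
  tibble::tibble(metric = c(paste0("dice_", names(x$dice_per_class)),
                            "recall", "ap50"),
                 value = c(unname(x$dice_per_class), x$recall, x$ap50))
}

#' @export
glance.sxt_eval <- function(x, ...) {
  tibble::tibble(dice_cell = x$dice_per_class[["cell"]],
                 dice_nucleus = x$dice_per_class[["nucleus"]],
                 dice_mitochondria = x$dice_per_class[["mitochondria"]],
                 dice_vesicle = x$dice_per_class[["vesicle"]],
                 recall = x$recall, ap50 = x$ap50,
                 n_instances_pred = x$n_instances_pred,
                 n_instances_gt = x$n_instances_gt)
}
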