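#' Multi-view majority-vote fusion of semantic masks
#'
#' Combines three per-axis reconstructions of the same semantic class
#' (one 3D mask assembled from 2D predictions along each of X, Y and Z)
#' into a single mask by per-voxel majority vote: a voxel is foreground
#' when at least two of the three views agree.
#'
#' @param mask_x,mask_y,mask_z Same-shape logical 3D arrays.
#' @return A logical array of the common shape.
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
#' d <- array(c(TRUE, FALSE, FALSE, FALSE), c(2, 2, 1))
#' fuse_multiview(a, b, d)[1, 1, 1]   # 3 votes -> TRUE
#' @export
fuse_multiview <- function(mask_x, mask_y, mask_z) {
  mask_x <- as_mask_array(mask_x, "mask_x")
  mask_y <- as_mask_array(mask_y, "mask_y")
  mask_z <- as_mask_array(mask_z, "mask_z")
  d <- check_same_shape(mask_x, mask_y, mask_z)
  array(mask_x + mask_y + mask_z >= 2L, d)
}

#' Intersection over union of two binary regions
#'
#' @param mask_a,mask_b Same-shape logical arrays (2D or 3D).
#' @return `|A intersect B| / |A union B|` in `[0, 1]`. Two empty masks
#'   have no defined IoU and raise an error.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
#' iou(a > 0, b > 0)   # 1/3
#' @export
iou <- function(mask_a, mask_b) {
  if (is.numeric(mask_a)) mask_a <- mask_a > 0
  if (is.numeric(mask_b)) mask_b <- mask_b > 0
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks differ in shape", call. = FALSE)
  un <- sum(mask_a | mask_b)
  if (un == 0L) stop("IoU of two empty masks is undefined", call. = FALSE)
  sum(mask_a & mask_b) / un
}

# IoU table between the labels of two integer label vectors (same length).
# Returns a data.frame(a, b, iou) over co-occurring positive label pairs.
label_overlap_iou <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  area_a <- tabulate(a[a > 0L])
  area_b <- tabulate(b[b > 0L])
  both <- a > 0L & b > 0L
  if (!any(both))
    return(data.frame(a = integer(), b = integer(), iou = double()))
  ka <- a[both]; kb <- b[both]
  code <- (ka - 1L) * length(area_b) + kb
  tab <- tabulate(code)
  nz <- which(tab > 0L)
  ai <- (nz - 1L) %/% length(area_b) + 1L
  bi <- (nz - 1L) %% length(area_b) + 1L
  ov <- tab[nz]
  data.frame(a = ai, b = bi,
             iou = ov / (area_a[ai] + area_b[bi] - ov))
}

#' Link per-slice 2D instances into 3D instances
#'
#' Walks an ordered stack of 2D instance maps (adjacent slices along one
#' axis) and joins 2D instances on neighboring slices into one 3D
#' instance when the IoU of their 2D footprints is strictly greater than
#' `threshold` (default 0.5). Chains propagate transitively along the
#' stack. Linking is one-to-one: each instance joins at most one instance
#' of the previous slice, chosen by highest IoU (ties go to the lower
#' label); all unlinked instances start fresh 3D instances. Empty
#' intermediate slices break chains (no gap bridging).
#'
#' @param slices List of integer matrices (0 = background, arbitrary
#'   positive per-slice labels), or a 3D instance-labeled array to be
#'   read slice-by-slice.
#' @param threshold IoU link threshold; equality does not link.
#' @param axis Axis along which the slices are ordered when `slices` is
#'   a 3D array (default `"x"`, the axis used for vesicle prediction).
#' @return An [instance_map()] of the stacked shape with contiguous 3D
#'   labels.
#' @export
link_instances <- function(slices, threshold = 0.5, axis = "x") {
  if (!is.list(slices)) {
    check_dim3(slices, "slices")
    slices <- slice_volume(array(as.integer(slices), dim(slices)), axis)
  }
  axis <- attr(slices, "axis") %||% axis
  plain <- unclass(slices)
  attributes(plain) <- NULL
  if (!length(plain)) stop("empty slice list", call. = FALSE)
  d2 <- dim(plain[[1]])
  out <- vector("list", length(plain))
  next_label <- 0L
  prev_assign <- NULL   # per-slice map: 2D label -> 3D label
  for (s in seq_along(plain)) {
    cur <- plain[[s]]
    if (!identical(dim(cur), d2))
      stop("inconsistent slice shapes at slice ", s, call. = FALSE)
    cur <- matrix(as.integer(cur), d2[1], d2[2])
    labs <- sort(unique(cur[cur > 0L]))
    assign <- integer(if (length(labs)) max(labs) else 0L)
    if (length(labs) && s > 1L) {
      ov <- label_overlap_iou(plain[[s - 1L]], cur)
      ov <- ov[ov$iou > threshold, , drop = FALSE]
      if (nrow(ov)) {
        ov <- ov[order(-ov$iou, ov$a, ov$b), , drop = FALSE]
        used_prev <- logical(max(ov$a))
        used_cur <- logical(max(ov$b))
        for (r in seq_len(nrow(ov))) {
          pa <- ov$a[r]; cb <- ov$b[r]
          if (used_prev[pa] || used_cur[cb]) next
          if (pa > length(prev_assign) || prev_assign[pa] == 0L) next
          assign[cb] <- prev_assign[pa]
          used_prev[pa] <- TRUE
          used_cur[cb] <- TRUE
        }
      }
    }
    for (l in labs) {
      if (assign[l] == 0L) {
        next_label <- next_label + 1L
        assign[l] <- next_label
      }
    }
    relab <- cur
    pos <- cur > 0L
    relab[pos] <- assign[cur[pos]]
    out[[s]] <- relab
    prev_assign <- assign
  }
  vol <- stack_slices(structure(out, axis = axis, class = "sxt_slices"))
  instance_map(vol)
}

#' Merge organelle masks into one cell scene by priority
#'
#' Combines the semantic masks and the vesicle instance map into a single
#' categorical grid under the priority order insulin vesicle > nucleus >
#' mitochondria > cell: where masks overlap, the higher-priority class
#' claims the voxel. Voxels claimed only by the cell mask become
#' cytoplasm; voxels claimed by nothing are outside. Organelle voxels
#' lying outside the cell mask keep their organelle code (the priority
#' rule applied literally); [scene_qc()] reports them.
#'
#' @param cell,nucleus,mito Logical 3D masks.
#' @param vesicles Instance map (or logical mask) of insulin vesicles.
#' @return A [cell_scene()] with codes 0 outside, 1 cytoplasm,
#'   2 mitochondria, 3 nucleus, 4 vesicle.
#' @export
fuse_priority <- function(cell, nucleus, mito, vesicles) {
  cell <- as_mask_array(cell, "cell")
  nucleus <- as_mask_array(nucleus, "nucleus")
  mito <- as_mask_array(mito, "mito")
  ves <- if (is.logical(vesicles)) vesicles else vesicles > 0
  d <- check_same_shape(cell, nucleus, mito, ves)
  scene <- array(0L, d)
  scene[cell] <- 1L        # ascending priority: later assignments win
  scene[mito] <- 2L
  scene[nucleus] <- 3L
  scene[ves] <- 4L
  cell_scene(scene)
}

#' Quality-control counts for a fused cell scene
#'
#' @param scene A [cell_scene()].
#' @param cell The cell mask used during fusion.
#' @return A tibble of per-class voxel counts plus the number of organelle
#'   voxels (codes 2-4) lying outside the cell mask.
#' @export
scene_qc <- function(scene, cell) {
  cell <- as_mask_array(cell, "cell")
  check_same_shape(scene, cell)
  cts <- tabulate(as.integer(scene) + 1L, nbins = 5L)
  tibble::tibble(
    class = names(scene_codes()),
    code = unname(scene_codes()),
    voxels = cts,
    outside_cell = c(NA_integer_, NA_integer_,
                     sum(scene == 2L & !cell),
                     sum(scene == 3L & !cell),
                     sum(scene == 4L & !cell))
  )
}
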