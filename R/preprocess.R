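#' Crop a volume to an index box
#'
#' @param vol 3D array.
#' @param box Integer matrix or list of three inclusive 1-based ranges,
#'   e.g. `list(x = c(2, 3), y = c(1, 4), z = c(1, 4))` or a 3x2 matrix
#'   (rows = axes, columns = lo/hi).
#' @return The cropped volume; values are copied unchanged.
#' @examples
#' v <- array(seq_len(64), c(4, 4, 4))
#' crop_volume(v, list(c(2, 3), c(2, 3), c(2, 3)))
#' @export
crop_volume <- function(vol, box) {
  d <- check_dim3(vol, "volume")
  if (is.list(box)) box <- do.call(rbind, box)
  box <- matrix(as.integer(box), nrow = 3)
  if (ncol(box) != 2L) stop("box must give lo/hi per axis", call. = FALSE)
  if (any(box[, 1] > box[, 2]))
    stop("empty crop box (lo > hi)", call. = FALSE)
  if (any(box[, 1] < 1L) || any(box[, 2] > d))
    stop("crop box out of bounds for ", paste(d, collapse = "x"),
         " volume", call. = FALSE)
  out <- vol[box[1, 1]:box[1, 2], box[2, 1]:box[2, 2], box[3, 1]:box[3, 2],
             drop = FALSE]
  if (inherits(vol, "sxt_volume")) out <- sxt_volume(out, attr(vol, "voxel_size"))
  out
}

#' Resample a volume to the canonical analysis shape
#'
#' Intensity volumes are resampled with trilinear interpolation; label
#' volumes (masks, instance maps, scenes) use nearest-neighbor so that no
#' new label values are introduced. The default target is the canonical
#' tomogram shape of width 280, height 480 and depth 320 voxels.
#'
#' @param vol 3D array.
#' @param target Integer 3-vector of output extents.
#' @param kind `"intensity"` (trilinear) or `"label"` (nearest-neighbor).
#' @return Array of shape `target`.
#' @export
resize_volume <- function(vol, target = c(280, 480, 320),
                          kind = c("intensity", "label")) {
  d <- check_dim3(vol, "volume")
  kind <- match.arg(kind)
  target <- as.integer(target)
  if (length(target) != 3L || any(target < 1L))
    stop("target extents must be three positive integers", call. = FALSE)
  was_logical <- is.logical(vol)
  out <- resize3d_cpp(array(as.numeric(vol), d), d, target,
                      nearest = (kind == "label"))
  if (kind == "label") {
    if (was_logical) out <- array(out > 0, target)
    else out <- array(as.integer(out), target)
  }
  out
}

#' Slice a volume into 2D images along one axis, and back
#'
#' `slice_volume()` decomposes a volume into an ordered stack of 2D
#' slices along X, Y or Z; `stack_slices()` is its exact inverse.
#'
#' @param vol 3D array.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param stack A slice stack produced by `slice_volume()`, or a plain
#'   list of equal-shape matrices with `axis` supplied.
#' @return `slice_volume()` returns a list of matrices with attributes
#'   `axis` and `vol_dim`; `stack_slices()` returns the 3D array.
#' @examples
#' v <- array(rnorm(24), c(2, 3, 4))
#' identical(stack_slices(slice_volume(v, "y")), v)
#' @export
slice_volume <- function(vol, axis = c("x", "y", "z")) {
  d <- check_dim3(vol, "volume")
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  n <- d[ax]
  slices <- vector("list", n)
  for (i in seq_len(n)) {
    slices[[i]] <- switch(axis,
                          x = array(vol[i, , ], d[c(2, 3)]),
                          y = array(vol[, i, ], d[c(1, 3)]),
                          z = array(vol[, , i], d[c(1, 2)]))
  }
  structure(slices, axis = axis, vol_dim = d, class = "sxt_slices")
}

#' @rdname slice_volume
#' @export
stack_slices <- function(stack, axis = attr(stack, "axis")) {
  if (is.null(axis)) stop("axis not given and not stored on stack",
                          call. = FALSE)
  axis <- match.arg(axis, c("x", "y", "z"))
  slices <- unclass(stack)
  attributes(slices) <- NULL
  if (!length(slices)) stop("empty slice stack", call. = FALSE)
  d2 <- dim(slices[[1]])
  for (s in slices)
    if (!identical(dim(s), d2)) stop("inconsistent slice shapes", call. = FALSE)
  n <- length(slices)
  d <- switch(axis, x = c(n, d2), y = c(d2[1], n, d2[2]), z = c(d2, n))
  mode <- if (is.logical(slices[[1]])) FALSE else 0
  vol <- array(mode, d)
  for (i in seq_len(n)) {
    switch(axis,
           x = {vol[i, , ] <- slices[[i]]},
           y = {vol[, i, ] <- slices[[i]]},
           z = {vol[, , i] <- slices[[i]]})
  }
  vol
}

#' Split a 2D image into overlapping patches
#'
#' Tiles the image with a regular grid of patches (default 150 x 50
#' pixels, the size used for vesicle detection on 280 x 480 slices) whose
#' stride guarantees at least the requested overlap fraction between
#' consecutive patches; the last patch along each dimension is snapped to
#' the image border. Patches never extend beyond the image (no padding).
#'
#' @param img 2D matrix.
#' @param patch_shape Integer 2-vector, patch extent per dimension.
#' @param min_overlap Minimum fractional overlap in `[0, 1)` between
#'   consecutive patches along each tiled dimension.
#' @return A tibble with one row per patch: `patch`, `x0`, `y0` (1-based
#'   origin), and list-column `data`. Attribute `source_shape` records
#'   `dim(img)`.
#' @export
split_patches <- function(img, patch_shape = c(150, 50), min_overlap = 0.30) {
  if (length(dim(img)) != 2L) stop("img must be a matrix", call. = FALSE)
  patch_shape <- as.integer(patch_shape)
  if (length(patch_shape) != 2L || any(patch_shape < 1L))
    stop("patch_shape must be two positive integers", call. = FALSE)
  if (!is.numeric(min_overlap) || min_overlap < 0 || min_overlap >= 1)
    stop("min_overlap must lie in [0, 1)", call. = FALSE)
  d <- dim(img)
  patch_shape <- pmin(patch_shape, d)   # clip at borders
  origins <- function(extent, p) {
    stride <- max(1L, as.integer(floor(p * (1 - min_overlap))))
    o <- seq.int(1L, max(1L, extent - p + 1L), by = stride)
    if (o[length(o)] + p - 1L < extent) o <- c(o, extent - p + 1L)
    o
  }
  ox <- origins(d[1], patch_shape[1])
  oy <- origins(d[2], patch_shape[2])
  grid <- expand.grid(x0 = ox, y0 = oy, KEEP.OUT.ATTRS = FALSE)
  out <- tibble::tibble(
    patch = seq_len(nrow(grid)),
    x0 = grid$x0, y0 = grid$y0,
    data = lapply(seq_len(nrow(grid)), function(i) {
      img[grid$x0[i]:(grid$x0[i] + patch_shape[1] - 1L),
          grid$y0[i]:(grid$y0[i] + patch_shape[2] - 1L), drop = FALSE]
    })
  )
  attr(out, "source_shape") <- d
  attr(out, "patch_shape") <- patch_shape
  out
}

#' Merge scored prediction patches back into a full image
#'
#' Restores a full-size prediction from overlapping patches: where
#' patches overlap, the prediction with the higher score wins at each
#' pixel. Score ties are broken in favor of the lower patch index, so the
#' result is deterministic.
#'
#' @param patches A tibble as from [split_patches()] with list-columns
#'   `data` (predicted labels) and `scores` (same-shape confidence grids).
#' @param source_shape Output extents; defaults to the `source_shape`
#'   attribute.
#' @return A list with `labels` and `scores` matrices of `source_shape`;
#'   pixels covered by no patch get label 0 and score `-Inf`.
#' @export
merge_patches <- function(patches, source_shape = attr(patches, "source_shape")) {
  if (is.null(source_shape)) stop("source_shape not given", call. = FALSE)
  if (!"scores" %in% names(patches))
    stop("patches must carry a 'scores' list-column", call. = FALSE)
  labels <- matrix(0, source_shape[1], source_shape[2])
  scores <- matrix(-Inf, source_shape[1], source_shape[2])
  for (i in seq_len(nrow(patches))) {
    pd <- patches$data[[i]]
    ps <- patches$scores[[i]]
    if (is.null(ps) || !identical(dim(ps), dim(pd)))
      stop("patch ", i, " has missing or mismatched scores", call. = FALSE)
    xi <- patches$x0[i]:(patches$x0[i] + nrow(pd) - 1L)
    yi <- patches$y0[i]:(patches$y0[i] + ncol(pd) - 1L)
    if (max(xi) > source_shape[1] || max(yi) > source_shape[2])
      stop("patch ", i, " exceeds source_shape", call. = FALSE)
    cur_s <- scores[xi, yi, drop = FALSE]
    win <- ps > cur_s          # strict: earlier patch keeps ties
    if (any(win)) {
      cur_l <- labels[xi, yi, drop = FALSE]
      cur_l[win] <- pd[win]
      cur_s[win] <- ps[win]
      labels[xi, yi] <- cur_l
      scores[xi, yi] <- cur_s
    }
  }
  uncovered <- sum(is.infinite(scores))
  if (uncovered > 0)
    stop(uncovered, " pixels of the source are covered by no patch",
         call. = FALSE)
  list(labels = labels, scores = scores)
}
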