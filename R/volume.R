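#' Core 3D containers
#'
#' Lightweight S3 wrappers over base R arrays. A *volume* holds linear
#' absorption coefficient (LAC) values, a *mask* is one semantic class
#' (cell, nucleus, mitochondria), an *instance map* labels individual
#' objects (insulin vesicles, contacts) with contiguous positive integers,
#' and a *cell scene* is the single categorical grid produced by
#' priority fusion of all organelle masks.
#'
#' All containers are ordinary arrays in (X, Y, Z) axis order and can be
#' manipulated with base R; the constructors only validate and tag.
#'
#' @param data A 3D numeric (volume), logical (mask) or integer (instance
#'   map / scene) array.
#' @param voxel_size Voxel edge length in µm/voxel (default 1, i.e.
#'   uncalibrated).
#' @param class_name Optional semantic class for a mask: one of `"cell"`,
#'   `"nucleus"`, `"mitochondria"`.
#' @return The validated array, classed as `sxt_volume`, `sxt_mask`,
#'   `sxt_instances` or `sxt_scene`.
#' @examples
#' v <- sxt_volume(array(runif(8), c(2, 2, 2)))
#' m <- binary_mask(array(TRUE, c(2, 2, 2)), "cell")
#' @name containers
NULL

check_dim3 <- function(data, what = "data") {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop(what, " must be a 3D array, got dimensions: ",
         paste(d %||% length(data), collapse = "x"), call. = FALSE)
  if (any(d < 1L)) stop(what, " has a zero extent", call. = FALSE)
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname containers
#' @export
sxt_volume <- function(data, voxel_size = 1) {
  check_dim3(data, "volume")
  if (!is.numeric(data)) stop("volume values must be numeric", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume contains NA/NaN/Inf values", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a positive scalar", call. = FALSE)
  structure(data, voxel_size = voxel_size,
            class = c("sxt_volume", class(array(0))))
}

#' @rdname containers
#' @export
binary_mask <- function(data, class_name = NULL) {
  check_dim3(data, "mask")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("numeric mask data must be 0/1", call. = FALSE)
    data <- array(data > 0, dim(data))
  }
  if (!is.logical(data)) stop("mask must be logical or 0/1", call. = FALSE)
  if (anyNA(data)) stop("mask contains NA", call. = FALSE)
  if (!is.null(class_name)) {
    class_name <- match.arg(class_name, c("cell", "nucleus", "mitochondria"))
  }
  structure(data, class_name = class_name,
            class = c("sxt_mask", class(array(TRUE))))
}

#' @rdname containers
#' @export
instance_map <- function(data) {
  check_dim3(data, "instance map")
  if (anyNA(data)) stop("instance map contains NA", call. = FALSE)
  if (any(data < 0)) stop("instance labels must be >= 0", call. = FALSE)
  if (any(data != round(data)))
    stop("instance labels must be integers", call. = FALSE)
  d <- dim(data)
  x <- as.integer(data)
  labs <- sort(unique(x[x > 0L]))
  # relabel to a contiguous 1..k alphabet so instance identities are stable
  if (length(labs) && !identical(labs, seq_along(labs))) {
    lut <- integer(max(labs))
    lut[labs] <- seq_along(labs)
    pos <- x > 0L
    x[pos] <- lut[x[pos]]
  }
  structure(array(x, d), n_instances = length(labs),
            class = c("sxt_instances", class(array(0L))))
}

#' @rdname containers
#' @export
cell_scene <- function(data) {
  check_dim3(data, "scene")
  if (anyNA(data) || any(!(data %in% 0:4)))
    stop("scene codes must be integers in 0..4", call. = FALSE)
  structure(array(as.integer(data), dim(data)),
            class = c("sxt_scene", class(array(0L))))
}

#' @rdname containers
#' @export
scene_codes <- function() {
  c(outside = 0L, cytoplasm = 1L, mitochondria = 2L, nucleus = 3L,
    vesicle = 4L)
}

n_instances <- function(imap) {
  attr(imap, "n_instances") %||% length(setdiff(unique(as.integer(imap)), 0L))
}

as_mask_array <- function(x, what = "mask") {
  if (is.numeric(x)) x <- array(x > 0, dim(x))
  check_dim3(x, what)
  if (!is.logical(x)) stop(what, " must be logical", call. = FALSE)
  x
}

check_same_shape <- function(...) {
  dims <- lapply(list(...), dim)
  ref <- dims[[1]]
  for (d in dims[-1])
    if (!identical(ref, d))
      stop("shape mismatch: ", paste(ref, collapse = "x"), " vs ",
           paste(d, collapse = "x"), call. = FALSE)
  invisible(ref)
}

#' @export
print.sxt_volume <- function(x, ...) {
  cat(sprintf("<sxt_volume> %s voxels, voxel_size %g, LAC range [%.4g, %.4g]\n",
              paste(dim(x), collapse = "x"), attr(x, "voxel_size") %||% 1,
              min(x), max(x)))
  invisible(x)
}

#' @export
print.sxt_mask <- function(x, ...) {
  cat(sprintf("<sxt_mask%s> %s voxels, %d foreground\n",
              if (is.null(attr(x, "class_name"))) ""
              else paste0(": ", attr(x, "class_name")),
              paste(dim(x), collapse = "x"), sum(x)))
  invisible(x)
}

#' @export
print.sxt_instances <- function(x, ...) {
  cat(sprintf("<sxt_instances> %s voxels, %d instances\n",
              paste(dim(x), collapse = "x"), n_instances(x)))
  invisible(x)
}

#' @export
print.sxt_scene <- function(x, ...) {
  cts <- tabulate(as.integer(x) + 1L, nbins = 5L)
  cat(sprintf("<sxt_scene> %s voxels\n", paste(dim(x), collapse = "x")))
  cat(sprintf("  %s: %d\n", names(scene_codes()), cts))
  invisible(x)
}

#' Summarize labeled instances as a table of records
#'
#' One row per instance: voxel count, centroid (1-based voxel coordinates),
#' equivalent-sphere radius `(3 n / 4 pi)^(1/3)` in voxels, and, when a
#' volume is supplied, the mean LAC over the instance voxels.
#'
#' @param imap An instance map (integer 3D array, 0 = background).
#' @param vol Optional companion LAC volume of the same shape.
#' @return A tibble with columns `label`, `voxel_count`, `cx`, `cy`, `cz`,
#'   `equiv_radius` and (if `vol` given) `mean_lac`. Empty map gives an
#'   empty tibble.
#' @examples
#' im <- instance_map(array(c(1L, 0L, 0L, 2L, 0L, 0L, 0L, 2L), c(2, 2, 2)))
#' extract_instances(im)
#' @export
extract_instances <- function(imap, vol = NULL) {
  imap <- instance_map(imap)
  k <- n_instances(imap)
  if (k == 0L) {
    out <- tibble::tibble(label = integer(), voxel_count = integer(),
                          cx = double(), cy = double(), cz = double(),
                          equiv_radius = double())
    if (!is.null(vol)) out$mean_lac <- double()
    return(out)
  }
  lab <- as.integer(imap)
  pos <- which(lab > 0L)
  labp <- lab[pos]
  d <- dim(imap)
  i <- ((pos - 1L) %% d[1]) + 1L
  j <- (((pos - 1L) %/% d[1]) %% d[2]) + 1L
  kk <- ((pos - 1L) %/% (d[1] * d[2])) + 1L
  cnt <- tabulate(labp, nbins = k)
  out <- tibble::tibble(
    label = seq_len(k),
    voxel_count = cnt,
    cx = as.numeric(rowsum(as.numeric(i), labp)) / cnt,
    cy = as.numeric(rowsum(as.numeric(j), labp)) / cnt,
    cz = as.numeric(rowsum(as.numeric(kk), labp)) / cnt,
    equiv_radius = (3 * cnt / (4 * pi))^(1 / 3)
  )
  if (!is.null(vol)) {
    check_same_shape(imap, vol)
    out$mean_lac <- as.numeric(rowsum(as.numeric(vol)[pos], labp)) / cnt
  }
  out
}
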