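#' Specification of a synthetic beta-cell phantom
#'
#' Defines the geometry and LAC statistics of a phantom emulating an
#' insulin-secreting (INS-1E-like) cell in a soft X-ray tomogram: one
#' ellipsoidal cell body, one off-center ellipsoidal nucleus, dispersed
#' tubular mitochondria at low contrast over the cytosol (ratio ~1.1),
#' and spherical dense-core insulin vesicles whose LAC rises from ~0.35
#' at the rim to ~0.55 at the core, inside the typical vesicle LAC range
#' of 0.3-0.6. Defaults use half the canonical tomogram resolution so a
#' phantom builds in seconds.
#'
#' @param shape Volume extents (X, Y, Z).
#' @param nucleus_radius_frac Nucleus semi-axes as a fraction of the cell
#'   semi-axes.
#' @param n_mito,n_vesicles Numbers of mitochondria and vesicles.
#' @param vesicle_radius_range Vesicle radius range in voxels.
#' @param lac_levels Named list, region -> c(mean, sd): `background`,
#'   `cytoplasm`, `nucleus`, `mitochondria`, `vesicle_rim`,
#'   `vesicle_core`. Means are in LAC units (1/µm).
#' @param noise_sd Standard deviation of the global Gaussian voxel noise.
#' @param seed Optional integer seed making the phantom deterministic.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(140, 240, 160),
                         nucleus_radius_frac = 0.60,
                         n_mito = 12, n_vesicles = 40,
                         vesicle_radius_range = c(3, 6),
                         lac_levels = list(
                           background = c(0.10, 0),
                           cytoplasm = c(0.30, 0),
                           nucleus = c(0.22, 0),
                           mitochondria = c(0.3335, 0),
                           vesicle_rim = c(0.35, 0),
                           vesicle_core = c(0.55, 0)),
                         noise_sd = 0.02, seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 16L),
            nucleus_radius_frac > 0, nucleus_radius_frac < 1,
            n_mito >= 0, n_vesicles >= 0,
            length(vesicle_radius_range) == 2L,
            vesicle_radius_range[1] > 0,
            diff(vesicle_radius_range) >= 0,
            noise_sd >= 0)
  needed <- c("background", "cytoplasm", "nucleus", "mitochondria",
              "vesicle_rim", "vesicle_core")
  if (!all(needed %in% names(lac_levels)))
    stop("lac_levels must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  structure(list(shape = shape, nucleus_radius_frac = nucleus_radius_frac,
                 n_mito = as.integer(n_mito),
                 n_vesicles = as.integer(n_vesicles),
                 vesicle_radius_range = vesicle_radius_range,
                 lac_levels = lac_levels, noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

# squared normalized ellipsoid coordinate field
ellipsoid_mask <- function(shape, center, semi) {
  ax <- ((seq_len(shape[1]) - center[1]) / semi[1])^2
  ay <- ((seq_len(shape[2]) - center[2]) / semi[2])^2
  az <- ((seq_len(shape[3]) - center[3]) / semi[3])^2
  r2 <- outer(outer(ax, ay, "+"), az, "+")
  r2 <= 1
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# rasterize a capsule (segment p0-p1 with radius r) clipped to `allowed`
capsule_voxels <- function(shape, p0, p1, r, allowed) {
  lo <- pmax(1L, floor(pmin(p0, p1) - r))
  hi <- pmin(shape, ceiling(pmax(p0, p1) + r))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  v <- p1 - p0
  len2 <- sum(v^2)
  w <- cbind(g$x - p0[1], g$y - p0[2], g$z - p0[3])
  t <- if (len2 > 0) pmin(1, pmax(0, (w %*% v) / len2)) else rep(0, nrow(w))
  dx <- w - t %*% t(v)
  inside <- rowSums(dx^2) <= r^2
  idx <- cbind(g$x, g$y, g$z)[inside, , drop = FALSE]
  keep <- allowed[idx]
  idx[keep, , drop = FALSE]
}

#' Draw points uniformly over a region with minimum separation
#'
#' Samples `n` voxel positions uniformly at random over the TRUE voxels
#' of `region`. With `min_sep > 0`, candidates closer than `min_sep` to
#' an accepted point are rejected and redrawn (bounded retries), giving a
#' simple hard-core point process; with `min_sep = 0` the draws are
#' independent, the null model against which RDF enrichment is read.
#'
#' @param n Number of points.
#' @param region Logical 3D mask (nonempty).
#' @param min_sep Minimum pairwise Euclidean separation in voxels.
#' @param seed Optional seed.
#' @param max_tries Total candidate budget before giving up.
#' @return An `n` x 3 matrix of 1-based voxel coordinates.
#' @export
place_centers_uniform <- function(n, region, min_sep = 0, seed = NULL,
                                  max_tries = 200L * max(n, 1L)) {
  region <- as_mask_array(region, "region")
  if (!any(region)) stop("region is empty", call. = FALSE)
  if (n == 0L) return(matrix(0, 0, 3))
  if (!is.null(seed)) withr::local_seed(seed)
  cand_pool <- which(region)
  d <- dim(region)
  if (min_sep <= 0) {
    pick <- cand_pool[sample.int(length(cand_pool), n, replace = TRUE)]
    return(matrix(as.numeric(arrayInd(pick, d)), n, 3))
  }
  acc <- matrix(0, 0, 3)
  tries <- 0L
  while (nrow(acc) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible packing: placed ", nrow(acc), " of ", n,
           " centers at min_sep ", min_sep, call. = FALSE)
    p <- as.numeric(arrayInd(cand_pool[sample.int(length(cand_pool), 1L)], d))
    if (nrow(acc) &&
        min(sqrt(colSums((t(acc) - p)^2))) < min_sep) next
    acc <- rbind(acc, p)
  }
  unname(acc)
}

#' Generate a synthetic beta-cell phantom
#'
#' Builds the LAC volume and mutually consistent ground-truth masks
#' described by a [phantom_spec()]: the masks are disjoint (vesicles and
#' mitochondria never overlap each other or the nucleus), so they
#' survive priority fusion unchanged. Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return Object of class `sxt_phantom`: `volume` ([sxt_volume()]),
#'   logical masks `cell`, `nucleus`, `mito`, instance map `vesicles`,
#'   and `placement` (tibble logging every placed object), plus `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec()")
  if (!is.null(seed)) withr::local_seed(seed)
  shape <- spec$shape
  lv <- function(region) spec$lac_levels[[region]][1]
  lsd <- function(region) {
    v <- spec$lac_levels[[region]]
    if (length(v) > 1) v[2] else 0
  }

  cell_center <- shape / 2 + runif(3, -0.02, 0.02) * shape
  cell_semi <- 0.40 * shape * runif(3, 0.95, 1.05)
  cell <- ellipsoid_mask(shape, cell_center, cell_semi)

  dir <- random_unit_vector()
  nuc_semi <- spec$nucleus_radius_frac * cell_semi * runif(3, 0.95, 1.05)
  nuc_center <- cell_center + 0.22 * dir * cell_semi
  nucleus <- ellipsoid_mask(shape, nuc_center, nuc_semi) & cell
  cytosol <- cell & !nucleus

  placement <- list()

  # tubular mitochondria: random capsules clipped to the cytosol
  mito <- array(FALSE, shape)
  if (spec$n_mito > 0) {
    seeds <- place_centers_uniform(spec$n_mito, cytosol, min_sep = 6)
    for (m in seq_len(spec$n_mito)) {
      u <- random_unit_vector()
      half_len <- runif(1, 6, 12)
      r <- runif(1, 2, 3.2)
      p0 <- seeds[m, ] - half_len * u
      p1 <- seeds[m, ] + half_len * u
      vox <- capsule_voxels(shape, p0, p1, r, cytosol & !mito)
      if (nrow(vox)) mito[vox] <- TRUE
      placement[[length(placement) + 1L]] <- tibble::tibble(
        type = "mitochondria", label = m, cx = seeds[m, 1], cy = seeds[m, 2],
        cz = seeds[m, 3], radius = r, half_length = half_len)
    }
  }

  # dense-core vesicles: spheres fully inside the free cytosol
  vesicles <- array(0L, shape)
  ves_rel <- array(0, shape)   # relative radius 0 (core) .. 1 (rim)
  if (spec$n_vesicles > 0) {
    radii <- sort(runif(spec$n_vesicles, spec$vesicle_radius_range[1],
                        spec$vesicle_radius_range[2]), decreasing = TRUE)
    allowed <- cytosol & !mito
    d_free <- edt3d_cpp(!allowed, shape)   # clearance inside free cytosol
    centers <- matrix(0, 0, 4)             # cx, cy, cz, radius
    tries <- 0L
    lab <- 0L
    for (r in radii) {
      pool <- which(d_free > r + 0.5)
      repeat {
        tries <- tries + 1L
        if (tries > 300L * spec$n_vesicles || !length(pool))
          stop("infeasible vesicle packing: placed ", lab, " of ",
               spec$n_vesicles, call. = FALSE)
        p <- as.numeric(arrayInd(pool[sample.int(length(pool), 1L)], shape))
        if (nrow(centers)) {
          sep <- sqrt(colSums((t(centers[, 1:3, drop = FALSE]) - p)^2))
          if (any(sep < r + centers[, 4] + 1)) next
        }
        break
      }
      lab <- lab + 1L
      centers <- rbind(centers, c(p, r))
      lo <- pmax(1L, floor(p - r)); hi <- pmin(shape, ceiling(p + r))
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      gx <- ((xs - p[1]))^2
      gy <- ((ys - p[2]))^2
      gz <- ((zs - p[3]))^2
      r2 <- outer(outer(gx, gy, "+"), gz, "+")
      inside <- r2 <= r^2
      sub <- vesicles[xs, ys, zs]
      sub[inside] <- lab
      vesicles[xs, ys, zs] <- sub
      relsub <- ves_rel[xs, ys, zs]
      relsub[inside] <- sqrt(r2[inside]) / r
      ves_rel[xs, ys, zs] <- relsub
      placement[[length(placement) + 1L]] <- tibble::tibble(
        type = "vesicle", label = lab, cx = p[1], cy = p[2], cz = p[3],
        radius = r, half_length = NA_real_)
    }
  }

  vol <- array(lv("background"), shape)
  vol[cytosol] <- lv("cytoplasm")
  vol[nucleus] <- lv("nucleus")
  vol[mito] <- lv("mitochondria")
  vpos <- vesicles > 0L
  vol[vpos] <- lv("vesicle_core") +
    (lv("vesicle_rim") - lv("vesicle_core")) * ves_rel[vpos]
  for (region in c("background", "cytoplasm", "nucleus", "mitochondria")) {
    s <- lsd(region)
    if (s > 0) {
      m <- switch(region, background = !cell, cytoplasm = cytosol & !mito &
                    !vpos, nucleus = nucleus, mitochondria = mito)
      vol[m] <- vol[m] + rnorm(sum(m), 0, s)
    }
  }
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), shape)
  vol <- pmax(vol, 0)

  structure(list(
    volume = sxt_volume(array(vol, shape)),
    cell = binary_mask(cell, "cell"),
    nucleus = binary_mask(nucleus, "nucleus"),
    mito = binary_mask(mito, "mitochondria"),
    vesicles = instance_map(vesicles),
    placement = if (length(placement)) dplyr::bind_rows(placement)
                else tibble::tibble(type = character(), label = integer(),
                                    cx = double(), cy = double(),
                                    cz = double(), radius = double(),
                                    half_length = double()),
    spec = spec), class = "sxt_phantom")
}

#' @export
print.sxt_phantom <- function(x, ...) {
  cat(sprintf(
    "<sxt_phantom> %s voxels; cell %d, nucleus %d, mito %d voxels; %d vesicles\n",
    paste(dim(x$volume), collapse = "x"), sum(x$cell), sum(x$nucleus),
    sum(x$mito), n_instances(x$vesicles)))
  invisible(x)
}

#' Corrupt a ground-truth mask into three noisy single-view predictions
#'
#' Emulates the errors of per-axis 2D predictions so the multi-view
#' voting fusion can be exercised: per view, boundary voxels are flipped
#' with probability `boundary_jitter` (local dilation/erosion jitter),
#' foreground voxels are dropped with probability `fn_rate`, and
#' background voxels are speckled on with probability `fp_rate`. The
#' three views are corrupted independently.
#'
#' @param gt Logical ground-truth mask.
#' @param error Either one list `list(fn_rate=, fp_rate=, boundary_jitter=)`
#'   applied to all three views, or a list of three such lists.
#' @param seed Optional seed.
#' @return List of three masks named `x`, `y`, `z`.
#' @export
degrade_views <- function(gt, error = list(fn_rate = 0.05, fp_rate = 0.001,
                                           boundary_jitter = 0),
                          seed = NULL) {
  gt <- as_mask_array(gt, "gt")
  if (!is.null(seed)) withr::local_seed(seed)
  if (!is.null(error$fn_rate)) error <- list(error, error, error)
  if (length(error) != 3L) stop("error must give one or three rate sets",
                                call. = FALSE)
  d <- dim(gt)
  views <- lapply(error, function(e) {
    fn <- e$fn_rate %||% 0
    fp <- e$fp_rate %||% 0
    bj <- e$boundary_jitter %||% 0
    stopifnot(fn >= 0, fn < 1, fp >= 0, fp < 1, bj >= 0, bj < 1)
    m <- gt
    if (bj > 0) {
      dist_bg <- edt3d_cpp(!gt, d)
      dist_fg <- edt3d_cpp(gt, d)
      boundary <- (gt & dist_bg <= 1) | (!gt & dist_fg <= 1)
      flip <- boundary & array(runif(length(gt)) < bj, d)
      m[flip] <- !m[flip]
    }
    if (fn > 0) {
      drop_at <- which(m & gt)
      m[drop_at[runif(length(drop_at)) < fn]] <- FALSE
    }
    if (fp > 0) {
      add_at <- which(!m)
      m[add_at[runif(length(add_at)) < fp]] <- TRUE
    }
    m
  })
  names(views) <- c("x", "y", "z")
  views
}

#' Default LAC thresholds for a phantom specification
#'
#' Midpoints between the region LAC means of a [phantom_spec()], suitable
#' for [threshold_segment()].
#'
#' @param spec A [phantom_spec()].
#' @return List with `cell`, `nucleus_hi`, `mito_lo`, `mito_hi`,
#'   `vesicle`.
#' @export
default_thresholds <- function(spec = phantom_spec()) {
  m <- function(region) spec$lac_levels[[region]][1]
  list(cell = (m("background") + m("nucleus")) / 2,
       nucleus_hi = (m("nucleus") + m("cytoplasm")) / 2,
       mito_lo = (m("cytoplasm") + m("mitochondria")) / 2,
       mito_hi = (m("mitochondria") + m("vesicle_rim")) / 2,
       vesicle = (m("vesicle_rim") + m("vesicle_core")) / 2)
}

#' Threshold-based reference segmentation of a phantom volume
#'
#' A deliberately simple segmentation backend for end-to-end runs of the
#' post-processing and analysis pipeline: the volume is smoothed with a
#' small box filter, then classes are obtained by LAC banding plus
#' connected components - cell above `cell`, nucleus as the largest
#' low-LAC component inside the cell, mitochondria as the
#' `[mito_lo, mito_hi]` band away from vesicles (small components
#' discarded), vesicles as connected components above `vesicle`.
#'
#' @param vol LAC volume.
#' @param thresholds List as from [default_thresholds()].
#' @param smooth Box filter radius in voxels (0 disables smoothing).
#' @param min_mito_voxels Minimum mitochondria component size kept.
#' @return List with logical masks `cell`, `nucleus`, `mito` and the
#'   vesicle [instance_map()] `vesicles`.
#' @export
threshold_segment <- function(vol, thresholds = default_thresholds(),
                              smooth = 1L, min_mito_voxels = 30L) {
  d <- check_dim3(vol, "volume")
  sm <- if (smooth > 0) boxblur3d_cpp(array(as.numeric(vol), d), d,
                                      as.integer(smooth))
        else array(as.numeric(vol), d)
  if (!any(sm > thresholds$cell))
    stop("no voxels above the cell threshold ", thresholds$cell,
         call. = FALSE)
  largest_cc <- function(mask) {
    lab <- label3d_cpp(mask, d, 26L)
    if (max(lab) == 0L) return(array(FALSE, d))
    counts <- tabulate(lab[lab > 0L])
    lab == which.max(counts)
  }
  cell <- largest_cc(sm > thresholds$cell)
  nucleus <- largest_cc(cell & sm < thresholds$nucleus_hi)
  ves_mask <- sm > thresholds$vesicle
  ves_lab <- label3d_cpp(ves_mask, d, 26L)
  keep <- which(tabulate(ves_lab[ves_lab > 0L]) >= 2L)
  ves_lab[!(ves_lab %in% keep)] <- 0L
  vesicles <- instance_map(ves_lab)
  d_ves <- if (any(ves_mask)) edt3d_cpp(vesicles > 0L, d)
           else array(Inf, d)
  mito_band <- sm > thresholds$mito_lo & sm < thresholds$mito_hi &
    cell & !nucleus & d_ves > 2
  mlab <- label3d_cpp(mito_band, d, 26L)
  keep_m <- which(tabulate(mlab[mlab > 0L]) >= min_mito_voxels)
  mito <- array(mlab %in% keep_m & mlab > 0L, d)
  list(cell = binary_mask(cell, "cell"),
       nucleus = binary_mask(nucleus, "nucleus"),
       mito = binary_mask(mito, "mitochondria"),
       vesicles = vesicles)
}
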