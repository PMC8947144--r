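#' Distance fields from the nucleus membrane and the plasma membrane
#'
#' For every voxel, the exact Euclidean distance (voxels) to the nearest
#' nucleus voxel (`d_nuc`) and to the nearest voxel outside the cell
#' (`d_pm`). Cytosol voxels have both distances positive; together they
#' define each voxel's relative depth between the two membranes.
#'
#' @param cell,nucleus Nonempty logical masks; the nucleus is expected to
#'   lie inside the cell (if not, a warning is raised and the
#'   intersection is used).
#' @return List with 3D numeric arrays `d_nuc` and `d_pm`.
#' @export
distance_fields <- function(cell, nucleus) {
  cell <- as_mask_array(cell, "cell")
  nucleus <- as_mask_array(nucleus, "nucleus")
  d <- check_same_shape(cell, nucleus)
  if (!any(cell)) stop("cell mask is empty", call. = FALSE)
  if (!any(nucleus)) stop("nucleus mask is empty", call. = FALSE)
  outside <- sum(nucleus & !cell)
  if (outside > 0) {
    warning(outside, " nucleus voxels lie outside the cell mask; ",
            "using the intersection")
    nucleus <- nucleus & cell
    if (!any(nucleus))
      stop("nucleus does not intersect the cell mask", call. = FALSE)
  }
  list(d_nuc = edt3d_cpp(nucleus, d), d_pm = edt3d_cpp(!cell, d))
}

#' Partition the cytosol into concentric shells of relative depth
#'
#' The cytosol (inside the cell, outside the nucleus) is divided into
#' `n_shells` regions by the normalized depth
#' `lambda = d_nuc / (d_nuc + d_pm)`: shell 1 hugs the nucleus membrane,
#' shell `n_shells` the plasma membrane, and every radial line from the
#' nucleus to the membrane is divided into equal relative parts. This
#' normalizes the space in all directions, so irregular cell shapes do
#' not bias shell membership. Shell k collects voxels with
#' `lambda in [(k-1)/n, k/n)`.
#'
#' @param d_nuc,d_pm Distance fields from [distance_fields()].
#' @param n_shells Number of shells (default 8).
#' @return Object of class `sxt_shells`: list with `shell_index`
#'   (integer 3D array, 0 = not cytosol), `n_shells`, `shell_volumes`
#'   (voxel counts) and `cytosol_volume`.
#' @export
shell_partition <- function(d_nuc, d_pm, n_shells = 8) {
  check_same_shape(d_nuc, d_pm)
  n_shells <- as.integer(n_shells)
  if (n_shells < 1L) stop("n_shells must be >= 1", call. = FALSE)
  cytosol <- d_nuc > 0 & d_pm > 0
  if (!any(cytosol)) stop("cytosol is empty", call. = FALSE)
  tot <- d_nuc + d_pm
  if (any(tot[cytosol] <= 0))
    stop("degenerate voxel with d_nuc + d_pm = 0 in cytosol", call. = FALSE)
  shell <- array(0L, dim(d_nuc))
  lam <- d_nuc[cytosol] / tot[cytosol]
  shell[cytosol] <- pmin(n_shells, floor(lam * n_shells) + 1L)
  vols <- tabulate(shell[cytosol], nbins = n_shells)
  structure(list(shell_index = shell, n_shells = n_shells,
                 shell_volumes = vols, cytosol_volume = sum(vols)),
            class = "sxt_shells")
}

#' @export
print.sxt_shells <- function(x, ...) {
  cat(sprintf("<sxt_shells> %d shells over %d cytosol voxels\n",
              x$n_shells, x$cytosol_volume))
  invisible(x)
}

#' @export
tidy.sxt_shells <- function(x, ...) {
  tibble::tibble(shell = seq_len(x$n_shells), volume = x$shell_volumes,
                 volume_fraction = x$shell_volumes / x$cytosol_volume)
}

new_rdf <- function(counts, shells, population) {
  n_total <- sum(counts)
  g <- if (n_total > 0) {
    (counts / shells$shell_volumes) / (n_total / shells$cytosol_volume)
  } else rep(NA_real_, shells$n_shells)
  out <- tibble::tibble(shell = seq_len(shells$n_shells), count = counts,
                        shell_volume = shells$shell_volumes, g = g)
  class(out) <- c("sxt_rdf", class(out))
  attr(out, "population") <- population
  attr(out, "n_total") <- n_total
  out
}

shell_at_points <- function(centers, shells) {
  centers <- as.matrix(centers)
  if (!ncol(centers) == 3L) stop("centers must be n x 3", call. = FALSE)
  d <- dim(shells$shell_index)
  ijk <- round(centers)
  ijk <- pmin(pmax(ijk, 1), matrix(d, nrow(centers), 3, byrow = TRUE))
  shells$shell_index[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
}

#' Radial distribution functions over the cytosol shell partition
#'
#' The RDF of a population is the per-shell density relative to the mean
#' density over the whole cytosol:
#' `g_k = (count_k / shell_volume_k) / (N / cytosol_volume)`.
#' `g = 1` everywhere means the population is placed as by uniform
#' chance; `g > 1` marks enrichment of that shell. The shell-volume
#' normalization plays the role of the spherical `4 pi r^2` factor and is
#' exact for arbitrary cell shapes. The volume-weighted mean of `g`
#' equals 1 by construction.
#'
#' Three population types mirror the standard organelle analyses:
#' `rdf_points()` for instance centers (insulin vesicles),
#' `rdf_voxels()` for voxel distributions (mitochondria), and
#' `rdf_contacts()` for vesicle-mitochondria contact centers.
#'
#' @param centers n x 3 matrix (or data frame) of voxel coordinates.
#'   Centers falling outside the cytosol (e.g. inside the nucleus) are
#'   discarded with a warning.
#' @param shells A [shell_partition()].
#' @param population Population tag stored on the result.
#' @return An `sxt_rdf` tibble: `shell`, `count`, `shell_volume`, `g`.
#' @export
rdf_points <- function(centers, shells, population = "vesicle_number") {
  centers <- as.matrix(centers)
  if (!nrow(centers)) stop("no centers given", call. = FALSE)
  sh <- shell_at_points(centers, shells)
  drop <- sum(sh == 0L)
  if (drop > 0)
    warning(drop, " of ", length(sh),
            " centers lie outside the cytosol and were discarded")
  new_rdf(tabulate(sh[sh > 0L], nbins = shells$n_shells), shells, population)
}

#' @rdname rdf_points
#' @param mask Logical 3D mask (e.g. mitochondria voxels); voxels outside
#'   the cytosol are ignored with a warning.
#' @export
rdf_voxels <- function(mask, shells, population = "mitochondria_voxel") {
  mask <- as_mask_array(mask, "mask")
  check_same_shape(mask, shells$shell_index)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sh <- shells$shell_index[mask]
  drop <- sum(sh == 0L)
  if (drop > 0)
    warning(drop, " of ", length(sh),
            " mask voxels lie outside the cytosol and were ignored")
  new_rdf(tabulate(sh[sh > 0L], nbins = shells$n_shells), shells, population)
}

#' @rdname rdf_points
#' @param contacts An `sxt_contacts` object from [detect_contacts()].
#' @export
rdf_contacts <- function(contacts, shells, population = "contact") {
  if (!inherits(contacts, "sxt_contacts"))
    stop("contacts must come from detect_contacts()", call. = FALSE)
  if (!nrow(contacts$centers))
    return(new_rdf(rep(0L, shells$n_shells), shells, population))
  rdf_points(contacts$centers, shells, population)
}

#' Detect insulin vesicle-mitochondria contact sites
#'
#' A contact is a connected region (26-connectivity) of insulin vesicle
#' voxels lying within `cutoff` voxels (Euclidean) of the mitochondria
#' surface; the default cutoff is 1.5 voxels.
#'
#' @param vesicles Instance map or logical mask of vesicle voxels.
#' @param mito Logical mitochondria mask, same shape.
#' @param cutoff Distance cutoff in voxels; a vesicle voxel is in contact
#'   when its distance to the nearest mitochondria voxel is `< cutoff`.
#' @return Object of class `sxt_contacts`: `contacts` (instance map of
#'   contact regions), `centers` (n x 3 centroid matrix), `n_contacts`.
#'   No contacts gives an empty set, not an error.
#' @export
detect_contacts <- function(vesicles, mito, cutoff = 1.5) {
  ves <- if (is.logical(vesicles)) vesicles else vesicles > 0
  mito <- as_mask_array(mito, "mito")
  d <- check_same_shape(ves, mito)
  if (!any(mito) || !any(ves)) {
    return(structure(list(contacts = instance_map(array(0L, d)),
                          centers = matrix(0, 0, 3), n_contacts = 0L),
                     class = "sxt_contacts"))
  }
  dmito <- edt3d_cpp(mito, d)
  cvox <- ves & (dmito < cutoff)
  lab <- label3d_cpp(cvox, d, connectivity = 26L)
  imap <- instance_map(lab)
  rec <- extract_instances(imap)
  structure(list(contacts = imap,
                 centers = as.matrix(rec[, c("cx", "cy", "cz")]),
                 n_contacts = nrow(rec)),
            class = "sxt_contacts")
}

#' @export
print.sxt_contacts <- function(x, ...) {
  cat(sprintf("<sxt_contacts> %d contact regions\n", x$n_contacts))
  invisible(x)
}

#' Radial LAC profile of a single instance
#'
#' Bins the voxels of one instance by their interior Euclidean distance
#' to the instance boundary (1-voxel-wide bins) and reports the mean LAC
#' per bin. For dense-core insulin vesicles the profile increases from
#' the boundary bin to the center. The voxel with the highest LAC value
#' is reported as the vesicle center (ties go to the first voxel in
#' column-major scan order).
#'
#' @param vol LAC volume.
#' @param instance Logical mask of one instance (nonempty), same shape.
#' @return An `sxt_lacprofile` tibble (`bin`, `n_voxels`, `mean_lac`)
#'   with attribute `center_voxel` (1-based coordinates of the max-LAC
#'   voxel). Bin `b` holds voxels at boundary distance `[b, b + 1)`.
#' @export
lac_radial_profile <- function(vol, instance) {
  instance <- as_mask_array(instance, "instance")
  d <- check_same_shape(vol, instance)
  if (!any(instance)) stop("instance mask is empty", call. = FALSE)
  dist_in <- edt3d_cpp(!instance, d)
  pos <- which(instance)
  bins <- pmax(1L, as.integer(floor(dist_in[pos])))
  lac <- as.numeric(vol)[pos]
  nb <- max(bins)
  cnt <- tabulate(bins, nbins = nb)
  mean_lac <- as.numeric(rowsum(lac, bins)) / cnt[cnt > 0]
  keep <- which(cnt > 0)
  center <- pos[which.max(lac)]
  out <- tibble::tibble(bin = keep, n_voxels = cnt[keep], mean_lac = mean_lac)
  class(out) <- c("sxt_lacprofile", class(out))
  attr(out, "center_voxel") <- as.integer(arrayInd(center, d))
  out
}

#' Radial LAC profiles for every instance in a map
#'
#' @param vol LAC volume.
#' @param imap Instance map.
#' @return A tibble with columns `label`, `bin`, `n_voxels`, `mean_lac`.
#' @export
lac_profiles <- function(vol, imap) {
  imap <- instance_map(imap)
  labs <- seq_len(n_instances(imap))
  dplyr::bind_rows(lapply(labs, function(l) {
    p <- lac_radial_profile(vol, imap == l)
    tibble::tibble(label = l, bin = p$bin, n_voxels = p$n_voxels,
                   mean_lac = p$mean_lac)
  }))
}

#' Functional region of a cytosol shell
#'
#' Maps shell indices of the 8-shell partition to the functional spaces
#' of the insulin secretory pathway: shell 1 is perinuclear, shells 2-3
#' host new vesicle maturation, shells 4-6 transportation, and shells
#' 7-8 (nearest the plasma membrane, where the readily releasable pool
#' docks) secretion.
#'
#' @param shell_id Integer vector with values in 1..8.
#' @return Character vector of region names.
#' @examples
#' functional_regions(1:8)
#' @export
functional_regions <- function(shell_id) {
  shell_id <- as.integer(shell_id)
  if (anyNA(shell_id) || any(shell_id < 1L | shell_id > 8L))
    stop("shell_id must lie in 1..8", call. = FALSE)
  c("perinuclear", "maturation", "maturation", "transportation",
    "transportation", "transportation", "secretion", "secretion")[shell_id]
}
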