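# Brute-force reference implementations used as independent oracles.
# All are deliberately naive (all-pairs scans, per-voxel loops) and only
# run on tiny grids.

# distance from every voxel to the nearest TRUE voxel, all-pairs scan
bf_distance_to <- function(feature) {
  d <- dim(feature)
  idx_f <- which(feature, arr.ind = TRUE)
  out <- array(Inf, d)
  if (!nrow(idx_f)) return(out)
  all_idx <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(nrow(all_idx))) {
    dv <- sqrt((idx_f[, 1] - all_idx[v, 1])^2 +
               (idx_f[, 2] - all_idx[v, 2])^2 +
               (idx_f[, 3] - all_idx[v, 3])^2)
    out[v] <- min(dv)
  }
  out
}

bf_vote <- function(a, b, c) {
  out <- array(FALSE, dim(a))
  for (v in seq_along(a)) out[v] <- (a[v] + b[v] + c[v]) >= 2
  out
}

bf_iou <- function(a, b) sum(a & b) / sum(a | b)

# per-pixel argmax-over-covering-patches merge oracle
bf_merge <- function(patches, source_shape) {
  labels <- matrix(0, source_shape[1], source_shape[2])
  scores <- matrix(-Inf, source_shape[1], source_shape[2])
  for (x in seq_len(source_shape[1])) {
    for (y in seq_len(source_shape[2])) {
      for (i in seq_len(nrow(patches))) {
        pd <- patches$data[[i]]
        ps <- patches$scores[[i]]
        xi <- x - patches$x0[i] + 1L
        yi <- y - patches$y0[i] + 1L
        if (xi >= 1 && xi <= nrow(pd) && yi >= 1 && yi <= ncol(pd) &&
            ps[xi, yi] > scores[x, y]) {
          scores[x, y] <- ps[xi, yi]
          labels[x, y] <- pd[xi, yi]
        }
      }
    }
  }
  list(labels = labels, scores = scores)
}

# brute-force per-voxel priority evaluation (vesicle > nucleus > mito > cell)
bf_priority <- function(cell, nucleus, mito, ves) {
  out <- array(0L, dim(cell))
  for (v in seq_along(cell)) {
    out[v] <- if (ves[v]) 4L else if (nucleus[v]) 3L else if (mito[v]) 2L
              else if (cell[v]) 1L else 0L
  }
  out
}

# exhaustive optimal one-to-one assignment maximizing matches with d < 1
bf_best_recall <- function(pred, gt) {
  dm <- sxtcell::match_distance(
    list(cx = rep(pred$cx, each = nrow(gt)),
         cy = rep(pred$cy, each = nrow(gt)),
         cz = rep(pred$cz, each = nrow(gt)),
         equiv_radius = rep(pred$equiv_radius, each = nrow(gt))),
    list(cx = rep(gt$cx, nrow(pred)), cy = rep(gt$cy, nrow(pred)),
         cz = rep(gt$cz, nrow(pred)),
         equiv_radius = rep(gt$equiv_radius, nrow(pred))))
  dm <- matrix(dm, nrow(gt), nrow(pred))   # gt rows, pred cols
  best <- 0L
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  np <- nrow(pred)
  for (p in perms(seq_len(np))) {
    k <- min(np, nrow(gt))
    matches <- sum(dm[cbind(seq_len(k), p[seq_len(k)])] < 1)
    best <- max(best, matches)
  }
  best / nrow(gt)
}

# rasterized sphere mask; strict=TRUE excludes the boundary shell
make_sphere <- function(shape, center, r, strict = FALSE) {
  ax <- (seq_len(shape[1]) - center[1])^2
  ay <- (seq_len(shape[2]) - center[2])^2
  az <- (seq_len(shape[3]) - center[3])^2
  r2 <- outer(outer(ax, ay, "+"), az, "+")
  if (strict) r2 < r^2 else r2 <= r^2
}

# Stack of 2D discs forming solids whose adjacent cross-sections are
# guaranteed (by construction check) to exceed the linking IoU threshold.
# Returns list(slices = list of 2D label matrices, n_solids).
make_linkable_stack <- function(n_slices, d2, solids, threshold = 0.5) {
  disc <- function(center, r) {
    ax <- (seq_len(d2[1]) - center[1])^2
    ay <- (seq_len(d2[2]) - center[2])^2
    outer(ax, ay, "+") <= r^2
  }
  slices <- lapply(seq_len(n_slices), function(s) matrix(0L, d2[1], d2[2]))
  for (k in seq_along(solids)) {
    so <- solids[[k]]
    prev <- NULL
    for (s in so$slices) {
      m <- disc(so$center, so$radius)
      if (!is.null(prev))
        stopifnot(bf_iou(m, prev) > threshold)
      prev <- m
      sl <- slices[[s]]
      stopifnot(!any(sl[m] > 0))   # solids must not collide
      sl[m] <- k
      slices[[s]] <- sl
    }
  }
  list(slices = slices, n_solids = length(solids))
}

# small phantom shared across tests (built once per test run)
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_spec(
        shape = c(64, 96, 72), n_mito = 5, n_vesicles = 10, seed = 42))
    cache
  }
})
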