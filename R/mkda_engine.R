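# Multikernel density analysis (MKDA).  Each study contrast contributes a
# binary indicator map (10-mm spheres around its reported peaks, unioned),
# contrasts are aggregated into a weighted proportion-of-contrasts-active
# map with sqrt(sample size) weights, and significance is assessed against
# a Monte Carlo null that redraws each contrast's foci uniformly over the
# gray-matter mask: a voxel-level density threshold from the pooled null
# densities and a cluster-extent threshold from the per-iteration maximum
# suprathreshold cluster sizes (family-wise error control by the
# maximum-statistic principle).

# ---- Talairach <-> MNI (Brett's piecewise linear transform) ----

.brett_up <- matrix(c(0.9900, 0,      0,
                      0,      0.9688, 0.0460,
                      0,     -0.0485, 0.9189), 3, 3, byrow = TRUE)
.brett_dn <- matrix(c(0.9900, 0,      0,
                      0,      0.9688, 0.0420,
                      0,     -0.0485, 0.8390), 3, 3, byrow = TRUE)

#' Convert between MNI and Talairach coordinates
#'
#' Brett's piecewise linear approximation: points with MNI z >= 0 are
#' mapped by one linear transform (`x' = 0.9900 x`, `y' = 0.9688 y +
#' 0.0460 z`, `z' = -0.0485 y + 0.9189 z`) and points with z < 0 by a
#' second (`y' = 0.9688 y + 0.0420 z`, `z' = -0.0485 y + 0.8390 z`).
#' `tal_to_mni()` applies the branch-consistent inverse: the z >= 0 inverse
#' is used when it lands in the z >= 0 half-space, otherwise the z < 0
#' inverse.
#'
#' @param point Numeric length-3 mm coordinate, or an n x 3 matrix.
#' @return Transformed coordinate(s), same shape as the input.
#' @examples
#' mni_to_tal(c(10, -20, 30))
#' tal_to_mni(mni_to_tal(c(10, -20, 30)))
#' @export
mni_to_tal <- function(point) {
  p <- rbind(point)
  if (ncol(p) != 3 || any(!is.finite(p)))
    stop("coordinates must be finite mm triples", call. = FALSE)
  up <- p[, 3] >= 0
  out <- p
  if (any(up)) out[up, ] <- p[up, , drop = FALSE] %*% t(.brett_up)
  if (any(!up)) out[!up, ] <- p[!up, , drop = FALSE] %*% t(.brett_dn)
  if (is.null(dim(point))) drop(out) else out
}

#' @rdname mni_to_tal
#' @export
tal_to_mni <- function(point) {
  p <- rbind(point)
  if (ncol(p) != 3 || any(!is.finite(p)))
    stop("coordinates must be finite mm triples", call. = FALSE)
  inv_up <- solve(.brett_up)
  inv_dn <- solve(.brett_dn)
  cand <- p %*% t(inv_up)
  lo <- cand[, 3] < 0
  if (any(lo)) cand[lo, ] <- p[lo, , drop = FALSE] %*% t(inv_dn)
  if (is.null(dim(point))) drop(cand) else cand
}

# ---- foci tables ----

#' Read a foci table
#'
#' Reads a tab-separated table of peak-activation coordinates with columns
#' `study_id`, `contrast_id`, `n` (sample size), `space` (`MNI` or `TAL`)
#' and `x`, `y`, `z` in mm.  Rows in Talairach space are converted to MNI
#' with [tal_to_mni()]; the returned table is all-MNI and carries a
#' conversion audit (attribute `"converted"` listing the converted rows).
#' Malformed rows are reported with their line numbers.
#'
#' @param path TSV file path, or a `data.frame` with the same columns.
#' @return A `data.frame` of class `foci_table` (columns `study_id`,
#'   `contrast_id`, `n`, `space` (all `"MNI"`), `x`, `y`, `z`).
#' @export
read_foci <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "contrast_id", "n", "space", "x", "y", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("foci table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(tab$x) | !is.finite(tab$y) | !is.finite(tab$z) |
                 !is.finite(tab$n) | tab$n < 1)
  if (length(bad))
    stop("malformed foci row(s) at line ", paste(bad + 1, collapse = ", "),
         " (need finite x/y/z and n >= 1)", call. = FALSE)
  space <- toupper(tab$space)
  unknown <- which(!space %in% c("MNI", "TAL"))
  if (length(unknown))
    stop("unknown space label at line ", paste(unknown + 1, collapse = ", "),
         " (expected MNI or TAL)", call. = FALSE)
  converted <- which(space == "TAL")
  if (length(converted)) {
    xyz <- tal_to_mni(as.matrix(tab[converted, c("x", "y", "z")]))
    tab[converted, c("x", "y", "z")] <- xyz
    tab$space <- "MNI"
  }
  tab$space <- "MNI"
  attr(tab, "converted") <- converted
  class(tab) <- c("foci_table", "data.frame")
  tab
}

#' Write a foci table
#'
#' Tab-separated, lossless round trip with [read_foci()] for MNI-space
#' tables.
#'
#' @param foci A foci `data.frame`.
#' @param path Output TSV path.
#' @export
write_foci <- function(foci, path) {
  utils::write.table(foci[, c("study_id", "contrast_id", "n", "space",
                              "x", "y", "z")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- indicator and density maps ----

# integer voxel offsets (m x 3) that can possibly fall within `radius` mm
# of a point lying anywhere inside the central voxel
.sphere_offsets <- function(radius, voxel_size) {
  r_vox <- ceiling(radius / voxel_size + 0.5 * sqrt(3))
  g <- -r_vox:r_vox
  off <- as.matrix(expand.grid(di = g, dj = g, dk = g))
  keep <- sqrt(rowSums(off^2)) * voxel_size <=
    radius + 0.5 * sqrt(3) * voxel_size + 1e-9
  off[keep, , drop = FALSE]
}

# linear voxel indices (masked) within `radius` mm of each focus (n x 3 mm
# matrix); union over foci.  Foci whose nearest voxel is outside the grid
# bounding box are skipped with a warning.
.contrast_indices <- function(xyz, grid, radius, offsets = NULL) {
  if (is.null(offsets)) offsets <- .sphere_offsets(radius, grid$voxel_size)
  d <- grid$dim
  vox <- .world_to_vox(rbind(xyz), grid)
  near <- round(vox)
  inside <- near[, 1] >= 1 & near[, 1] <= d[1] &
            near[, 2] >= 1 & near[, 2] <= d[2] &
            near[, 3] >= 1 & near[, 3] <= d[3]
  n_skipped <- sum(!inside)
  if (n_skipped)
    warning(n_skipped, " focus/foci outside the grid bounding box skipped",
            call. = FALSE)
  idx_all <- integer(0)
  for (f in which(inside)) {
    cand <- sweep(offsets, 2, near[f, ], "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    ctr <- .vox_to_world(cand, grid)
    dist2 <- (ctr[, 1] - xyz[f, 1])^2 + (ctr[, 2] - xyz[f, 2])^2 +
             (ctr[, 3] - xyz[f, 3])^2
    cand <- cand[dist2 <= radius^2 + 1e-9, , drop = FALSE]
    idx_all <- c(idx_all,
                 cand[, 1] + (cand[, 2] - 1L) * d[1] +
                   (cand[, 3] - 1L) * d[1] * d[2])
  }
  idx_all <- unique(idx_all)
  idx_all[grid$mask[idx_all]]
}

# fast path for null simulation: foci are given as linear indices of voxel
# centers, so sphere membership depends only on the offset pattern
.contrast_indices_at_centers <- function(center_idx, grid, center_offsets) {
  d <- grid$dim
  ijk <- arrayInd(center_idx, d)
  idx_all <- integer(0)
  for (f in seq_along(center_idx)) {
    cand <- sweep(center_offsets, 2, ijk[f, ], "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    idx_all <- c(idx_all,
                 cand[, 1] + (cand[, 2] - 1L) * d[1] +
                   (cand[, 3] - 1L) * d[1] * d[2])
  }
  idx_all <- unique(idx_all)
  idx_all[grid$mask[idx_all]]
}

# exact voxel-center sphere offsets (centers within radius of a center)
.center_offsets <- function(radius, voxel_size) {
  r_vox <- floor(radius / voxel_size)
  g <- -r_vox:r_vox
  off <- as.matrix(expand.grid(di = g, dj = g, dk = g))
  off[rowSums(off^2) * voxel_size^2 <= radius^2 + 1e-9, , drop = FALSE]
}

#' Build one contrast's binary indicator map
#'
#' Sets to 1 every in-mask voxel whose center lies within `radius` mm
#' (Euclidean) of any of the contrast's peak coordinates; the maps of
#' multiple foci are unioned, never added, so a contrast contributes at
#' most 1 to any voxel regardless of how many nearby peaks it reports.
#'
#' @param foci n x 3 matrix (or data.frame with `x`, `y`, `z`) of MNI mm
#'   coordinates for one contrast.
#' @param grid A `volume_grid`.
#' @param radius Sphere radius in mm (default 10).
#' @return Logical array of dimension `grid$dim`.
#' @export
build_indicator_map <- function(foci, grid, radius = 10) {
  stopifnot(inherits(grid, "volume_grid"), radius >= 0)
  xyz <- if (is.data.frame(foci)) as.matrix(foci[, c("x", "y", "z")]) else
    rbind(foci)
  idx <- .contrast_indices(xyz, grid, radius)
  out <- array(FALSE, grid$dim)
  out[idx] <- TRUE
  out
}

#' Weighted activation-density map
#'
#' Aggregates per-contrast indicator maps into the MKDA density map: each
#' voxel's value is the sqrt(sample size)-weighted proportion of contrasts
#' whose indicator covers it,
#' `value(v) = sum_c sqrt(N_c) I_c(v) / sum_c sqrt(N_c)`, a point estimate
#' of the probability that a (weighted) contrast activates the voxel.
#'
#' @param indicators List of logical arrays (one per contrast) on the same
#'   grid, as returned by [build_indicator_map()].
#' @param sample_ns Per-contrast participant counts (> 0).
#' @param grid The shared `volume_grid`.
#' @return An object of class `density_map`: list with `grid`, `value`
#'   (array in \[0, 1\], zero outside the mask) and `weights_total`.
#' @export
density_map <- function(indicators, sample_ns, grid) {
  if (length(indicators) == 0) stop("empty contrast set", call. = FALSE)
  stopifnot(length(indicators) == length(sample_ns), all(sample_ns > 0))
  w <- sqrt(sample_ns)
  val <- array(0, grid$dim)
  for (i in seq_along(indicators)) {
    ind <- indicators[[i]]
    if (!all(dim(ind) == grid$dim)) stop("grid mismatch", call. = FALSE)
    val <- val + w[i] * (ind & grid$mask)
  }
  val <- val / sum(w)
  structure(list(grid = grid, value = val, weights_total = sum(w)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d x %d, max %.4f, weights_total %.2f\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              max(x$value), x$weights_total))
  invisible(x)
}

#' MKDA density map from a foci table
#'
#' Convenience wrapper: groups a foci table by `contrast_id`, builds one
#' indicator map per contrast and aggregates with sqrt(N) weights.
#'
#' @param foci A `foci_table` (MNI space).
#' @param grid A `volume_grid`.
#' @param radius Sphere radius in mm.
#' @return A `density_map`.
#' @export
mkda_density <- function(foci, grid, radius = 10) {
  cs <- .split_contrasts(foci, grid, radius)
  val <- .accumulate_density(cs$indices, cs$weights, grid)
  structure(list(grid = grid, value = val, weights_total = sum(cs$weights)),
            class = "density_map")
}

# per-contrast index lists + sqrt(N) weights from a foci table
.split_contrasts <- function(foci, grid, radius) {
  stopifnot(nrow(foci) > 0)
  offsets <- .sphere_offsets(radius, grid$voxel_size)
  key <- interaction(foci$study_id, foci$contrast_id, drop = TRUE)
  grp <- split(seq_len(nrow(foci)), key)
  indices <- vector("list", length(grp))
  weights <- numeric(length(grp))
  n_foci <- integer(length(grp))
  for (i in seq_along(grp)) {
    rows <- grp[[i]]
    indices[[i]] <- .contrast_indices(
      as.matrix(foci[rows, c("x", "y", "z")]), grid, radius, offsets)
    weights[i] <- sqrt(foci$n[rows[1]])
    n_foci[i] <- length(rows)
  }
  list(indices = indices, weights = weights, n_foci = n_foci,
       id = names(grp))
}

.accumulate_density <- function(indices, weights, grid) {
  val <- array(0, grid$dim)
  for (i in seq_along(indices))
    val[indices[[i]]] <- val[indices[[i]]] + weights[i]
  val / sum(weights)
}

# ---- thresholds and clusters ----

# smallest distinct sample value t with mean(samples >= t) <= p; Inf (with
# a warning) when no value in the sample achieves it (degenerate null)
.density_threshold <- function(samples, p) {
  stopifnot(p > 0, p < 1)
  n <- length(samples)
  s <- sort(samples)
  c_max <- floor(n * p)
  if (c_max < 1 || s[1] == s[n]) {
    if (s[1] == s[n])
      warning("degenerate null distribution (all values equal); ",
              "threshold set to Inf", call. = FALSE)
    else if (c_max < 1)
      warning("too few null samples for requested tail probability; ",
              "threshold set to Inf", call. = FALSE)
    return(Inf)
  }
  j0 <- n - c_max + 1
  if (s[j0] > s[j0 - 1]) return(s[j0])
  above <- which(s > s[j0])
  if (!length(above)) {
    warning("degenerate upper tail (ties at the maximum); threshold Inf",
            call. = FALSE)
    return(Inf)
  }
  s[above[1]]
}

# smallest integer k with mean(max_sizes >= k) <= fwer
.extent_threshold <- function(max_sizes, fwer) {
  stopifnot(fwer > 0, fwer < 1)
  n <- length(max_sizes)
  s <- sort(max_sizes)
  c_max <- floor(n * fwer)
  if (c_max < 1) return(max(s) + 1L)
  k <- s[n - c_max] + 1L           # count strictly greater than s[n - c_max]
  # tighten: any smaller k with count(ms >= k) <= c_max?
  while (k > 1L && (n - findInterval(k - 1L - 1e-9, s)) <= c_max) k <- k - 1L
  k
}

# union-find component labeling of a set of voxel linear indices
.label_components <- function(idx, dim, connectivity = 26) {
  n <- length(idx)
  if (n == 0) return(integer(0))
  ijk <- arrayInd(idx, dim)
  offs <- switch(as.character(connectivity),
    "6"  = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    "18" = {
      o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      o <- o[rowSums(abs(o)) %in% 1:2, , drop = FALSE]
      o[apply(o, 1, function(r) r[match(TRUE, r != 0)] > 0), , drop = FALSE]
    },
    "26" = {
      o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
      o[apply(o, 1, function(r) r[match(TRUE, r != 0)] > 0), , drop = FALSE]
    },
    stop("connectivity must be 6, 18 or 26", call. = FALSE))
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  d1 <- dim[1]; d12 <- dim[1] * dim[2]
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- ijk[, 1] + o[1] >= 1 & ijk[, 1] + o[1] <= dim[1] &
          ijk[, 2] + o[2] >= 1 & ijk[, 2] + o[2] <= dim[2] &
          ijk[, 3] + o[3] >= 1 & ijk[, 3] + o[3] <= dim[3]
    nb <- idx[ok] + o[1] + o[2] * d1 + o[3] * d12
    m <- match(nb, idx)
    src <- which(ok)[!is.na(m)]
    dst <- m[!is.na(m)]
    for (q in seq_along(src)) {
      ra <- find(src[q]); rb <- find(dst[q])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

.max_cluster_size <- function(idx, dim, connectivity = 26) {
  if (!length(idx)) return(0L)
  lab <- .label_components(idx, dim, connectivity)
  max(tabulate(lab))
}

#' Extract suprathreshold clusters from a density map
#'
#' Thresholds the map at `voxel_threshold` (voxels with density >=
#' threshold, within the mask), labels connected components
#' (26-neighborhood by default) and reports every component of size >=
#' `cluster_extent_k` with its voxel count, maximum density and peak world
#' coordinate.  Clusters are ordered by size (descending), ties broken by
#' lexicographic peak coordinate; within a cluster, a density tie at the
#' peak is broken the same way.  Additional local density maxima inside
#' each cluster are reported in the `subpeaks` list column.
#'
#' @param map A `density_map` (or a numeric array plus `grid`).
#' @param voxel_threshold Density threshold (from [derive_thresholds()] or
#'   user-supplied).
#' @param cluster_extent_k Minimum surviving cluster size in voxels.
#' @param connectivity 6, 18 or 26 (default).
#' @param grid Required when `map` is a bare array.
#' @return A `data.frame` of class `cluster_table` with columns
#'   `cluster_id`, `size`, `maximum`, `peak_x`, `peak_y`, `peak_z` and a
#'   `subpeaks` list column; zero rows when nothing survives.
#' @export
extract_clusters <- function(map, voxel_threshold, cluster_extent_k = 1,
                             connectivity = 26, grid = NULL) {
  if (inherits(map, "density_map")) {
    grid <- map$grid; val <- map$value
  } else val <- map
  stopifnot(inherits(grid, "volume_grid"))
  empty <- data.frame(cluster_id = integer(0), size = integer(0),
                      maximum = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0))
  empty$subpeaks <- list()
  class(empty) <- c("cluster_table", "data.frame")
  if (!is.finite(voxel_threshold)) return(empty)
  idx <- which(val >= voxel_threshold & grid$mask)
  if (!length(idx)) return(empty)
  lab <- .label_components(idx, grid$dim, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= cluster_extent_k)
  if (!length(keep)) return(empty)
  rows <- lapply(keep, function(l) {
    vox <- idx[lab == l]
    dv <- val[vox]
    ijk <- arrayInd(vox, grid$dim)
    world <- .vox_to_world(ijk, grid)
    best <- which(dv == max(dv))
    best <- best[order(world[best, 1], world[best, 2], world[best, 3])][1]
    sp <- .local_maxima(vox, dv, grid, connectivity)
    sp <- sp[sp$idx != vox[best], , drop = FALSE]
    list(size = length(vox), maximum = max(dv), peak = world[best, ],
         subpeaks = if (nrow(sp))
           data.frame(size = NA_integer_, x = sp$x, y = sp$y, z = sp$z,
                      value = sp$value)
         else data.frame(size = integer(0), x = numeric(0), y = numeric(0),
                         z = numeric(0), value = numeric(0)))
  })
  tab <- data.frame(
    cluster_id = NA_integer_,
    size = vapply(rows, `[[`, integer(1), "size"),
    maximum = vapply(rows, `[[`, numeric(1), "maximum"),
    peak_x = vapply(rows, function(r) r$peak[1], numeric(1)),
    peak_y = vapply(rows, function(r) r$peak[2], numeric(1)),
    peak_z = vapply(rows, function(r) r$peak[3], numeric(1)))
  ord <- order(-tab$size, tab$peak_x, tab$peak_y, tab$peak_z)
  tab <- tab[ord, ]
  tab$cluster_id <- seq_len(nrow(tab))
  tab$subpeaks <- lapply(rows, `[[`, "subpeaks")[ord]
  rownames(tab) <- NULL
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

# local maxima (value >= every in-cluster neighbor) within one component
.local_maxima <- function(vox, dv, grid, connectivity) {
  ijk <- arrayInd(vox, grid$dim)
  d1 <- grid$dim[1]; d12 <- grid$dim[1] * grid$dim[2]
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  if (connectivity == 6) o <- o[rowSums(abs(o)) == 1, , drop = FALSE]
  is_max <- rep(TRUE, length(vox))
  for (r in seq_len(nrow(o))) {
    nb <- vox + o[r, 1] + o[r, 2] * d1 + o[r, 3] * d12
    m <- match(nb, vox)
    has <- !is.na(m)
    is_max[has] <- is_max[has] & dv[has] >= dv[m[has]]
  }
  w <- which(is_max)
  world <- .vox_to_world(ijk[w, , drop = FALSE], grid)
  out <- data.frame(idx = vox[w], x = world[, 1], y = world[, 2],
                    z = world[, 3], value = dv[w])
  out[order(-out$value, out$x, out$y, out$z), , drop = FALSE]
}

# ---- Monte Carlo null ----

#' Simulate the MKDA Monte Carlo null distribution
#'
#' Preserves the observed structure — the number of contrasts, the number
#' of coordinates within each contrast and the sqrt(N) weights — but
#' redraws every focus uniformly over the mask's voxel centers
#' (independently, with replacement).  Each iteration rebuilds the
#' indicator and density maps, pools masked voxel densities into the
#' voxel-level null, and records the maximum suprathreshold cluster size at
#' the voxel threshold implied by `voxel_p`.  Fully reproducible from
#' `seed`.
#'
#' @param structure `data.frame` with one row per contrast: columns
#'   `n_foci` (>= 1) and `sample_n` (>= 1).  Obtainable from a foci table
#'   via [mkda_structure()].
#' @param grid A `volume_grid` with the gray-matter mask.
#' @param n_iterations Monte Carlo iterations (>= 100; the reference
#'   analysis style uses 5,000).
#' @param seed Integer seed.
#' @param radius Sphere radius in mm.
#' @param voxel_p Voxel-level tail probability defining the suprathreshold
#'   set for the cluster-extent null (default 0.01).
#' @param connectivity Cluster connectivity (default 26).
#' @param max_voxel_null Cap on pooled voxel-null samples kept; when
#'   `n_iterations * n_mask` exceeds it, a per-iteration random subsample
#'   of masked voxels is pooled instead (unbiased for the pooled
#'   distribution).
#' @return An object of class `null_distribution`: `n_iterations`, `seed`,
#'   `voxel_null` (pooled masked densities), `max_cluster_sizes`,
#'   `voxel_threshold`, `voxel_p`, `radius`, `connectivity`.
#' @export
simulate_null <- function(structure, grid, n_iterations = 5000, seed = 1,
                          radius = 10, voxel_p = 0.01, connectivity = 26,
                          max_voxel_null = 2e6) {
  stopifnot(inherits(grid, "volume_grid"))
  if (nrow(structure) == 0) stop("empty contrast structure", call. = FALSE)
  if (any(structure$n_foci < 1)) stop("zero-focus contrast", call. = FALSE)
  if (n_iterations < 100)
    stop("n_iterations must be >= 100 for stable thresholds", call. = FALSE)
  weights <- sqrt(structure$sample_n)
  n_foci <- as.integer(structure$n_foci)
  mask_idx <- which(grid$mask)
  n_mask <- length(mask_idx)
  center_offsets <- .center_offsets(radius, grid$voxel_size)

  set.seed(as.integer(seed))
  it_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)
  per_iter_keep <- min(n_mask, ceiling(max_voxel_null / n_iterations))

  # pass 1: pooled voxel-level null
  pool <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(it_seeds[it])
    val <- .null_density(n_foci, weights, mask_idx, grid, center_offsets)
    keep <- if (per_iter_keep < n_mask)
      sample.int(n_mask, per_iter_keep) else seq_len(n_mask)
    pool[[it]] <- val[mask_idx[keep]]
  }
  voxel_null <- unlist(pool, use.names = FALSE)
  voxel_threshold <- .density_threshold(voxel_null, voxel_p)

  # pass 2: per-iteration maximum suprathreshold cluster size (same foci,
  # regenerated from the per-iteration seeds)
  max_sizes <- integer(n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(it_seeds[it])
    val <- .null_density(n_foci, weights, mask_idx, grid, center_offsets)
    supra <- which(val >= voxel_threshold & grid$mask)
    max_sizes[it] <- .max_cluster_size(supra, grid$dim, connectivity)
  }
  base::structure(list(n_iterations = n_iterations, seed = seed,
                       voxel_null = voxel_null, max_cluster_sizes = max_sizes,
                       voxel_threshold = voxel_threshold, voxel_p = voxel_p,
                       radius = radius, connectivity = connectivity),
                  class = "null_distribution")
}

.null_density <- function(n_foci, weights, mask_idx, grid, center_offsets) {
  val <- array(0, grid$dim)
  for (cc in seq_along(n_foci)) {
    centers <- mask_idx[sample.int(length(mask_idx), n_foci[cc],
                                   replace = TRUE)]
    idx <- .contrast_indices_at_centers(centers, grid, center_offsets)
    val[idx] <- val[idx] + weights[cc]
  }
  val / sum(weights)
}

#' Contrast structure of a foci table
#'
#' One row per contrast with its focus count and sample size — the
#' structure preserved by the Monte Carlo null.
#'
#' @param foci A `foci_table`.
#' @return `data.frame` with columns `study_id`, `contrast_id`, `n_foci`,
#'   `sample_n`.
#' @export
mkda_structure <- function(foci) {
  key <- interaction(foci$study_id, foci$contrast_id, drop = TRUE)
  grp <- split(seq_len(nrow(foci)), key)
  data.frame(
    study_id = vapply(grp, function(r) as.character(foci$study_id[r[1]]), ""),
    contrast_id = vapply(grp, function(r) as.character(foci$contrast_id[r[1]]), ""),
    n_foci = lengths(grp),
    sample_n = vapply(grp, function(r) as.numeric(foci$n[r[1]]), 0),
    row.names = NULL)
}

#' Derive voxel and cluster-extent thresholds from a simulated null
#'
#' The voxel threshold is the smallest null density value exceeded by at
#' most `voxel_p` of the pooled null samples (the (1 - voxel_p) empirical
#' quantile); the cluster extent `k` is the smallest size such that the
#' fraction of null iterations whose maximum suprathreshold cluster reaches
#' `k` is at most `fwer` — i.e. family-wise error control by the
#' maximum-statistic distribution.
#'
#' @param null A `null_distribution` from [simulate_null()].
#' @param voxel_p Voxel-level tail probability (must match the one used in
#'   the simulation for the cluster extent to be coherent; if it differs,
#'   re-run [simulate_null()]).
#' @param fwer Target family-wise error rate for clusters.
#' @return List with `voxel_threshold` and `cluster_extent_k`.
#' @export
derive_thresholds <- function(null, voxel_p = 0.01, fwer = 0.05) {
  stopifnot(inherits(null, "null_distribution"))
  if (voxel_p <= 0 || voxel_p >= 1 || fwer <= 0 || fwer >= 1)
    stop("voxel_p and fwer must lie in (0, 1)", call. = FALSE)
  vt <- .density_threshold(null$voxel_null, voxel_p)
  if (!isTRUE(all.equal(voxel_p, null$voxel_p)))
    warning("voxel_p differs from the simulated one; cluster_extent_k ",
            "still reflects voxel_p = ", null$voxel_p, call. = FALSE)
  list(voxel_threshold = vt,
       cluster_extent_k = .extent_threshold(null$max_cluster_sizes, fwer))
}

# ---- difference maps ----

#' MKDA difference map with permutation inference
#'
#' Computes the difference of two conditions' density maps,
#' `diff(v) = density_A(v) - density_B(v)`, and assesses which regions are
#' more frequently engaged in one condition than the other by permuting the
#' condition labels over contrasts (each contrast keeps its foci and
#' sqrt(N) weight).  Voxel thresholds come from the pooled permutation
#' null of voxel differences, separately for the positive (A > B) and
#' negative (B > A) tail; cluster extents from the per-permutation maximum
#' suprathreshold cluster sizes of each tail.
#'
#' @param foci_A,foci_B Foci tables (MNI) for the two conditions.
#' @param grid A `volume_grid`.
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Integer seed.
#' @param radius Sphere radius mm.
#' @param voxel_p,fwer Thresholding parameters as in [simulate_null()].
#' @param connectivity Cluster connectivity.
#' @param max_voxel_null Cap on pooled permutation voxel samples.
#' @return List with `map` (the observed difference as a `density_map`
#'   whose values lie in \[-1, 1\]), `clusters_A_gt_B`, `clusters_B_gt_A`
#'   (cluster tables), `thresholds` (per tail) and `n_permutations`.
#' @export
difference_map <- function(foci_A, foci_B, grid, n_permutations = 5000,
                           seed = 1, radius = 10, voxel_p = 0.01,
                           fwer = 0.05, connectivity = 26,
                           max_voxel_null = 2e6) {
  stopifnot(inherits(grid, "volume_grid"))
  if (nrow(foci_A) == 0 || nrow(foci_B) == 0)
    stop("both conditions need at least one contrast", call. = FALSE)
  if (n_permutations < 100)
    stop("n_permutations must be >= 100", call. = FALSE)
  ca <- .split_contrasts(foci_A, grid, radius)
  cb <- .split_contrasts(foci_B, grid, radius)
  indices <- c(ca$indices, cb$indices)
  weights <- c(ca$weights, cb$weights)
  nA <- length(ca$indices); nC <- length(indices)

  diff_for <- function(a_set) {
    b_set <- setdiff(seq_len(nC), a_set)
    .accumulate_density(indices[a_set], weights[a_set], grid) -
      .accumulate_density(indices[b_set], weights[b_set], grid)
  }
  obs <- diff_for(seq_len(nA))

  mask_idx <- which(grid$mask)
  n_mask <- length(mask_idx)
  set.seed(as.integer(seed))
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_permutations)
  per_iter_keep <- min(n_mask, ceiling(max_voxel_null / n_permutations))

  pool <- vector("list", n_permutations)
  for (it in seq_len(n_permutations)) {
    set.seed(perm_seeds[it])
    a_set <- sample.int(nC, nA)
    dmap <- diff_for(a_set)
    keep <- if (per_iter_keep < n_mask)
      sample.int(n_mask, per_iter_keep) else seq_len(n_mask)
    pool[[it]] <- dmap[mask_idx[keep]]
  }
  pooled <- unlist(pool, use.names = FALSE)
  thr_pos <- suppressWarnings(.density_threshold(pooled, voxel_p))
  thr_neg <- suppressWarnings(.density_threshold(-pooled, voxel_p))

  max_pos <- max_neg <- integer(n_permutations)
  for (it in seq_len(n_permutations)) {
    set.seed(perm_seeds[it])
    a_set <- sample.int(nC, nA)
    dmap <- diff_for(a_set)
    sp <- if (is.finite(thr_pos))
      which(dmap >= thr_pos & grid$mask) else integer(0)
    sn <- if (is.finite(thr_neg))
      which(-dmap >= thr_neg & grid$mask) else integer(0)
    max_pos[it] <- .max_cluster_size(sp, grid$dim, connectivity)
    max_neg[it] <- .max_cluster_size(sn, grid$dim, connectivity)
  }
  k_pos <- .extent_threshold(max_pos, fwer)
  k_neg <- .extent_threshold(max_neg, fwer)

  map <- structure(list(grid = grid, value = obs,
                        weights_total = sum(weights)),
                   class = "density_map")
  cl_pos <- extract_clusters(obs, thr_pos, k_pos, connectivity, grid = grid)
  cl_neg <- extract_clusters(-obs, thr_neg, k_neg, connectivity, grid = grid)
  list(map = map,
       clusters_A_gt_B = cl_pos, clusters_B_gt_A = cl_neg,
       thresholds = list(
         A_gt_B = list(voxel_threshold = thr_pos, cluster_extent_k = k_pos),
         B_gt_A = list(voxel_threshold = thr_neg, cluster_extent_k = k_neg)),
       n_permutations = n_permutations, seed = seed)
}
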