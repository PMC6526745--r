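test_that("Brett transform: fixed point, derived point, round trip", {
  expect_equal(mni_to_tal(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(tal_to_mni(c(0, 0, 0)), c(0, 0, 0))
  # z >= 0 branch by matrix arithmetic
  expect_equal(mni_to_tal(c(10, -20, 30)), c(9.900, -17.996, 28.537),
               tolerance = 1e-6)
  set.seed(99)
  pts <- cbind(runif(1000, -70, 70), runif(1000, -100, 70),
               runif(1000, -45, 80))
  back <- tal_to_mni(mni_to_tal(pts))
  expect_lt(max(abs(back - pts)), 1e-6)
  expect_error(mni_to_tal(c(1, 2, NA)), "finite")
})

test_that("indicator maps follow exact sphere membership and union semantics", {
  grid <- volume_grid(c(15, 15, 15), 2, origin = c(-14, -14, -14))
  focus <- c(0, 0, 0)  # at a voxel center
  # radius 0: exactly that voxel
  m0 <- build_indicator_map(focus, grid, radius = 0)
  expect_equal(sum(m0), 1)
  expect_true(m0[8, 8, 8])
  # radius 10 on a 2 mm grid: count equals brute-force enumeration
  m10 <- build_indicator_map(focus, grid, radius = 10)
  expect_equal(sum(m10), sphere_voxel_count(focus, grid, 10))
  # off-center focus too
  f2 <- c(1.3, -0.7, 2.1)
  expect_equal(sum(build_indicator_map(f2, grid, radius = 7)),
               sphere_voxel_count(f2, grid, 7))
  # two nearby foci: union of the single-focus maps, never additive
  two <- build_indicator_map(rbind(c(0, 0, 0), c(4, 0, 0)), grid, radius = 10)
  ua <- build_indicator_map(c(0, 0, 0), grid, radius = 10)
  ub <- build_indicator_map(c(4, 0, 0), grid, radius = 10)
  expect_identical(two, ua | ub)
  expect_lte(max(two), 1)
  # focus outside the bounding box: warn and skip
  expect_warning(out <- build_indicator_map(c(500, 0, 0), grid, radius = 10),
                 "outside")
  expect_equal(sum(out), 0)
})

test_that("density weighting follows the sqrt(N) rule", {
  grid <- volume_grid(c(9, 9, 9), 2, origin = c(-8, -8, -8))
  ind <- build_indicator_map(c(0, 0, 0), grid, radius = 4)
  blank <- array(FALSE, grid$dim)
  # single contrast: density equals its indicator
  d1 <- density_map(list(ind), 25, grid)
  expect_equal(d1$value, ind * 1)
  # equal N, active in one of two: 0.5
  d2 <- density_map(list(ind, blank), c(30, 30), grid)
  expect_equal(max(d2$value), 0.5)
  # N = 20 vs 80, active only in the larger: sqrt(80)/(sqrt(20)+sqrt(80))
  d3 <- density_map(list(blank, ind), c(20, 80), grid)
  expect_equal(max(d3$value), sqrt(80) / (sqrt(20) + sqrt(80)),
               tolerance = 1e-12)
  expect_equal(max(d3$value), 2 / 3, tolerance = 1e-12)
  expect_error(density_map(list(), numeric(0), grid), "empty")
  small <- volume_grid(c(3, 3, 3), 2)
  expect_error(density_map(list(array(FALSE, c(3, 3, 3))), 10, grid),
               "mismatch")
})

test_that("cluster extraction matches a flood-fill oracle and orders deterministically", {
  grid <- volume_grid(c(8, 8, 8), 2, origin = c(0, 0, 0))
  val <- array(0, grid$dim)
  # two voxels touching only diagonally in 3D
  val[2, 2, 2] <- 0.9
  val[3, 3, 3] <- 0.8
  t26 <- extract_clusters(val, 0.5, 1, connectivity = 26, grid = grid)
  t6 <- extract_clusters(val, 0.5, 1, connectivity = 6, grid = grid)
  expect_equal(nrow(t26), 1)
  expect_equal(t26$size, 2)
  expect_equal(nrow(t6), 2)
  expect_equal(sort(flood_fill_sizes(val > 0.5, 26)), sort(t26$size))
  expect_equal(sort(flood_fill_sizes(val > 0.5, 6)), sort(t6$size))
  # peak is the maximum-density voxel in world mm
  expect_equal(c(t26$peak_x, t26$peak_y, t26$peak_z), c(2, 2, 2))
  # a larger random pattern agrees with the oracle under both connectivities
  set.seed(4)
  val2 <- array(0, grid$dim)
  val2[sample(length(val2), 40)] <- runif(40, 0.6, 1)
  for (conn in c(6, 26)) {
    tab <- extract_clusters(val2, 0.5, 1, connectivity = conn, grid = grid)
    expect_equal(sort(tab$size), sort(flood_fill_sizes(val2 >= 0.5, conn)))
  }
  # extent filter and empty input
  expect_true(all(extract_clusters(val2, 0.5, 3, grid = grid)$size >= 3))
  expect_equal(nrow(extract_clusters(array(0, grid$dim), 0.5, 1,
                                     grid = grid)), 0)
})

test_that("null simulation is reproducible and matches a brute-force mean", {
  grid <- gen_mask(shape = c(16, 16, 16), voxel_size = 4,
                   semi_axes = c(26, 26, 26))
  struct <- data.frame(n_foci = c(3, 5), sample_n = c(20, 45))
  n1 <- simulate_null(struct, grid, n_iterations = 150, seed = 7, radius = 8)
  n2 <- simulate_null(struct, grid, n_iterations = 150, seed = 7, radius = 8)
  expect_identical(n1$voxel_null, n2$voxel_null)
  expect_identical(n1$max_cluster_sizes, n2$max_cluster_sizes)
  expect_equal(length(n1$max_cluster_sizes), 150)

  # mean pooled null density equals the analytic expectation
  # sum_c w_c P(voxel covered by contrast c) / sum_c w_c, with the coverage
  # probability estimated by an independent brute-force placement simulation
  mask_idx <- which(grid$mask)
  set.seed(123)
  cover_prob <- function(n_foci, reps = 4000) {
    # P(a random masked voxel is within radius of >= 1 of n_foci uniform foci)
    hits <- replicate(reps, {
      foci <- mask_idx[sample.int(length(mask_idx), n_foci, TRUE)]
      probe <- mask_idx[sample.int(length(mask_idx), 1)]
      fijk <- arrayInd(foci, grid$dim)
      pijk <- arrayInd(probe, grid$dim)
      d2 <- rowSums((sweep(fijk, 2, pijk))^2) * grid$voxel_size^2
      any(d2 <= 8^2 + 1e-9)
    })
    mean(hits)
  }
  w <- sqrt(struct$sample_n)
  expected <- sum(w * c(cover_prob(3), cover_prob(5))) / sum(w)
  expect_equal(mean(n1$voxel_null), expected, tolerance = 0.15)

  expect_error(simulate_null(struct[0, ], grid, 150, 1), "empty")
  expect_error(simulate_null(data.frame(n_foci = 0, sample_n = 10),
                             grid, 150, 1), "zero-focus")
  expect_error(simulate_null(struct, grid, 50, 1), "100")
})

test_that("thresholds match sort-based quantile oracles and are monotone", {
  set.seed(10)
  samples <- c(rep(0, 5000), rexp(5000, 4))
  null <- structure(list(n_iterations = 500, seed = 1,
                         voxel_null = samples,
                         max_cluster_sizes = rpois(500, 3),
                         voxel_threshold = NA, voxel_p = 0.01,
                         radius = 10, connectivity = 26),
                    class = "null_distribution")
  thr01 <- derive_thresholds(null, voxel_p = 0.01)
  expect_lte(mean(samples >= thr01$voxel_threshold), 0.01)
  # smallest such distinct value: the next-smaller distinct sample fails
  below <- max(samples[samples < thr01$voxel_threshold])
  expect_gt(mean(samples >= below), 0.01)
  thr05 <- suppressWarnings(derive_thresholds(null, voxel_p = 0.05))
  expect_gte(thr01$voxel_threshold, thr05$voxel_threshold)
  # cluster extent: smallest k with exceedance fraction <= fwer
  ms <- null$max_cluster_sizes
  k <- thr01$cluster_extent_k
  expect_lte(mean(ms >= k), 0.05)
  if (k > 1) expect_gt(mean(ms >= k - 1), 0.05)
  # degenerate all-zero null is flagged
  null0 <- null
  null0$voxel_null <- rep(0, 1000)
  expect_warning(derive_thresholds(null0, voxel_p = 0.01), "degenerate")
  expect_error(derive_thresholds(null, voxel_p = 1.2), "0, 1")
})

test_that("difference map vanishes for identical conditions and errors on misuse", {
  grid <- gen_mask(shape = c(14, 14, 14), voxel_size = 4,
                   semi_axes = c(22, 22, 22))
  tr <- foci_truth(planted_clusters = list(), n_contrasts = 6,
                   background_rate = 5)
  foci <- gen_foci_dataset(tr, grid, seed = 5)$foci
  res <- suppressWarnings(
    difference_map(foci, foci, grid, n_permutations = 120, seed = 2,
                   radius = 8))
  expect_equal(max(abs(res$map$value)), 0)
  expect_equal(nrow(res$clusters_A_gt_B), 0)
  expect_equal(nrow(res$clusters_B_gt_A), 0)
  expect_error(difference_map(foci[0, ], foci, grid, 120, 1), "at least one")
})

test_that("foci tables round-trip and flag conversions and malformed rows", {
  tab <- data.frame(study_id = c("s1", "s1", "s2"),
                    contrast_id = c("c1", "c1", "c2"),
                    n = c(20, 20, 35), space = "MNI",
                    x = c(10.5, -12, 0), y = c(-20, 30.25, 5),
                    z = c(30, -8, 12.5))
  f <- tempfile(fileext = ".tsv")
  write_foci(tab, f)
  back <- read_foci(f)
  expect_equal(back$x, tab$x)
  expect_equal(back$z, tab$z)
  expect_equal(attr(back, "converted"), integer(0))
  # TAL rows are converted and audited
  tab2 <- tab
  tab2$space <- c("MNI", "TAL", "MNI")
  conv <- read_foci(tab2)
  expect_equal(attr(conv, "converted"), 2L)
  expect_equal(unlist(conv[2, c("x", "y", "z")], use.names = FALSE),
               as.vector(tal_to_mni(unlist(tab2[2, c("x", "y", "z")]))))
  expect_true(all(conv$space == "MNI"))
  # malformed rows named with line numbers
  tab3 <- tab; tab3$z[2] <- NA
  expect_error(read_foci(tab3), "line 3")
  tab4 <- tab; tab4$space <- c("MNI", "LPS", "MNI")
  expect_error(read_foci(tab4), "space")
})
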