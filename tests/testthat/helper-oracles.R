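# Independent oracles used across test files.  These deliberately avoid the
# package's own computational paths: dense matrix algebra instead of the
# blockwise profile, brute-force enumeration instead of offset tables.

# Restricted log-likelihood of the two-level meta-model, dense formulation:
# V = diag(v) + sigma2 * [same-study indicator], straight determinant and
# solve calls.
reml_loglik_dense <- function(sigma2, y, v, xmat, study) {
  k <- length(y)
  p <- ncol(xmat)
  X <- xmat
  Z <- outer(study, study, "==") * 1
  V <- diag(v) + sigma2 * Z
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((k - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(A, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# grid-search REML estimate of sigma2 (dense oracle)
reml_grid_oracle <- function(y, v, xmat, study, upper = 2, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, reml_loglik_dense, numeric(1), y = y, v = v,
               xmat = xmat, study = study)
  grid[which.max(ll)]
}

# brute-force count of voxel centers within `radius` mm of a point
sphere_voxel_count <- function(focus, grid, radius) {
  ijk <- as.matrix(expand.grid(i = seq_len(grid$dim[1]),
                               j = seq_len(grid$dim[2]),
                               k = seq_len(grid$dim[3])))
  ctr <- sweep((ijk - 1) * grid$voxel_size, 2, grid$origin, "+")
  d2 <- (ctr[, 1] - focus[1])^2 + (ctr[, 2] - focus[2])^2 +
    (ctr[, 3] - focus[3])^2
  inmask <- grid$mask[as.matrix(ijk)]
  sum(d2 <= radius^2 + 1e-9 & inmask)
}

# recursive flood fill over a logical 3D array (component sizes)
flood_fill_sizes <- function(arr, connectivity = 26) {
  dim3 <- dim(arr)
  seen <- array(FALSE, dim3)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  sizes <- integer(0)
  todo <- which(arr, arr.ind = TRUE)
  for (s in seq_len(nrow(todo))) {
    if (seen[todo[s, , drop = FALSE]]) next
    stack <- todo[s, , drop = FALSE]
    seen[stack] <- TRUE
    size <- 0L
    while (nrow(stack)) {
      cur <- stack[1, ]; stack <- stack[-1, , drop = FALSE]
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > dim3)) next
        nbm <- matrix(nb, 1)
        if (arr[nbm] && !seen[nbm]) {
          seen[nbm] <- TRUE
          stack <- rbind(stack, nb)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# tiny behavioral corpus with one effect per study and common variance
tiny_corpus <- function(k = 12, mu = 0.2, sigma2 = 0.05, v = 0.1,
                        seed = 42) {
  set.seed(seed)
  data.frame(study_id = paste0("s", seq_len(k)),
             d = rnorm(k, mu, sqrt(sigma2 + v)), v = v)
}
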