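# Synthetic-data generators with known ground truth.  These emulate the
# statistical structure the analyses assume -- nested effect sizes with
# between-study heterogeneity, moderator effects and optional
# SE-correlated selection; foci tables with planted activation clusters
# over a brain-like ellipsoid mask -- so recovery, calibration and FWER
# properties can be tested without any real corpus.  Every generator is a
# pure function of (parameters, seed).

#' Ground truth for a synthetic behavioral corpus
#'
#' @param mu Grand mean effect (Hedges' g units).
#' @param sigma2_study Between-study variance (>= 0).
#' @param beta_mod Named numeric vector of moderator coefficients; names
#'   among `valence_positive`, `task_relevance_distractor`,
#'   `population_clinical`, `mean_age` (per-year slope).
#' @param v_range Length-2 range of per-effect sampling variances.
#' @param bias_model Optional selection model: `list(pi0 = )`, the
#'   publication probability of effects with two-sided p >= .05
#'   (significant effects always publish).  `NULL` disables selection.
#' @return A `behavioral_truth` list.
#' @export
behavioral_truth <- function(mu = 0.2, sigma2_study = 0.04,
                             beta_mod = c(valence_positive = 0.14),
                             v_range = c(0.02, 0.2), bias_model = NULL) {
  stopifnot(sigma2_study >= 0, length(v_range) == 2, all(v_range > 0),
            v_range[1] <= v_range[2])
  known <- c("valence_positive", "task_relevance_distractor",
             "population_clinical", "mean_age")
  if (length(beta_mod) && !all(names(beta_mod) %in% known))
    stop("unknown moderator name(s) in beta_mod; use: ",
         paste(known, collapse = ", "), call. = FALSE)
  if (!is.null(bias_model) && (bias_model$pi0 < 0 || bias_model$pi0 > 1))
    stop("bias_model$pi0 must lie in [0, 1]", call. = FALSE)
  structure(list(mu = mu, sigma2_study = sigma2_study, beta_mod = beta_mod,
                 v_range = v_range, bias_model = bias_model),
            class = "behavioral_truth")
}

#' Generate a synthetic behavioral meta-analytic corpus
#'
#' Draws study intercepts `u_j ~ N(0, sigma2_study)`, builds per-effect
#' true effects `mu + x' beta + u_j` with randomly assigned categorical
#' moderators (valence, task relevance, population) and mean age, then
#' observes `d ~ N(true, v)` with `v` uniform over `v_range`.  Alongside
#' the precomputed records it emits a study-summary table of per-condition
#' means/SDs reverse-engineered so that [read_study_table()] /
#' [compute_smd()] reproduce each record's g exactly (neutral mean/SD
#' fixed, affective mean solved from the uncorrected d; group size solved
#' from the target variance).  If `truth$bias_model` is set, nonsignificant
#' effects are censored with probability `1 - pi0` after observation.
#'
#' @param truth A [behavioral_truth()] object.
#' @param k_studies Number of studies (>= 1).
#' @param effects_per_study Effects nested in each study.
#' @param seed Integer seed.
#' @return List with `summaries` (study-summary `data.frame`), `effects`
#'   (effect-size records with moderators and a `design` matrix attribute)
#'   and `truth` (echo, including the seed).
#' @export
gen_behavioral_dataset <- function(truth = behavioral_truth(),
                                   k_studies = 50, effects_per_study = 2,
                                   seed = 1) {
  stopifnot(inherits(truth, "behavioral_truth"), k_studies >= 1,
            effects_per_study >= 1)
  set.seed(as.integer(seed))
  k <- k_studies * effects_per_study
  study <- rep(seq_len(k_studies), each = effects_per_study)
  u <- stats::rnorm(k_studies, 0, sqrt(truth$sigma2_study))

  valence <- sample(c("negative", "positive"), k, replace = TRUE)
  task_relevance <- sample(c("target", "distractor"), k, replace = TRUE)
  population <- sample(c("healthy", "clinical"), k, replace = TRUE,
                       prob = c(0.8, 0.2))
  mean_age <- round(stats::runif(k, 18, 70), 1)

  bm <- truth$beta_mod
  lin <- truth$mu + u[study]
  if ("valence_positive" %in% names(bm))
    lin <- lin + bm[["valence_positive"]] * (valence == "positive")
  if ("task_relevance_distractor" %in% names(bm))
    lin <- lin + bm[["task_relevance_distractor"]] *
      (task_relevance == "distractor")
  if ("population_clinical" %in% names(bm))
    lin <- lin + bm[["population_clinical"]] * (population == "clinical")
  if ("mean_age" %in% names(bm))
    lin <- lin + bm[["mean_age"]] * (mean_age - mean(mean_age))

  v_target <- stats::runif(k, truth$v_range[1], truth$v_range[2])
  d_obs <- stats::rnorm(k, lin, sqrt(v_target))

  # reverse-engineer two-group condition summaries reproducing d_obs:
  # v ~ 2/n for small g, so n per group from the target variance
  n_grp <- pmax(2L, round(2 / v_target))
  df <- 2L * n_grp - 2L
  j <- 1 - 3 / (4 * df - 1)
  d_raw <- d_obs / j
  sd0 <- 0.1
  mean_neut <- 0.5
  mean_aff <- mean_neut + d_raw * sd0

  effects <- data.frame(
    study_id = sprintf("study%03d", study),
    es_id = sprintf("es%04d", seq_len(k)),
    outcome = "accuracy",
    d = d_obs,
    v = smd_variance(n_grp, n_grp, g = d_obs),
    valence = valence, task_relevance = task_relevance,
    population = population, mean_age = mean_age,
    stringsAsFactors = FALSE)

  summaries <- data.frame(
    study_id = effects$study_id, es_id = effects$es_id,
    outcome = "accuracy",
    n_aff = n_grp, mean_aff = mean_aff, sd_aff = sd0,
    n_neut = n_grp, mean_neut = mean_neut, sd_neut = sd0,
    design = "independent",
    valence = valence, task_relevance = task_relevance,
    population = population, mean_age = mean_age,
    stringsAsFactors = FALSE)

  if (!is.null(truth$bias_model)) {
    # direction-consistent selection: an effect publishes for sure when it
    # is significant in the hypothesized (positive) direction, otherwise
    # with probability pi0 -- the one-parameter censoring rule that
    # produces classic funnel asymmetry
    z <- effects$d / sqrt(effects$v)
    keep <- z > stats::qnorm(0.975) | stats::runif(k) < truth$bias_model$pi0
    effects <- effects[keep, , drop = FALSE]
    summaries <- summaries[keep, , drop = FALSE]
  }
  rownames(effects) <- rownames(summaries) <- NULL
  echo <- unclass(truth)
  echo$seed <- seed
  echo$k_studies <- k_studies
  echo$effects_per_study <- effects_per_study
  list(summaries = summaries, effects = effects, truth = echo)
}

#' Moderator design matrix for synthetic (or real) effect records
#'
#' Builds an intercept + treatment-dummy design from the moderator columns
#' present: `valence_positive`, `task_relevance_distractor`,
#' `population_clinical`, and centered `mean_age` when requested.
#'
#' @param effects Effect-record `data.frame`.
#' @param moderators Character subset of
#'   `c("valence", "task_relevance", "population", "mean_age")`.
#' @return Numeric design matrix with named columns, first `intercept`.
#' @export
moderator_design <- function(effects, moderators = character(0)) {
  X <- matrix(1, nrow(effects), 1, dimnames = list(NULL, "intercept"))
  for (m in moderators) {
    col <- switch(m,
      valence = cbind(valence_positive =
                        as.numeric(effects$valence == "positive")),
      task_relevance = cbind(task_relevance_distractor =
                        as.numeric(effects$task_relevance == "distractor")),
      population = cbind(population_clinical =
                        as.numeric(effects$population == "clinical")),
      mean_age = cbind(mean_age = effects$mean_age - mean(effects$mean_age)),
      stop("unknown moderator: ", m, call. = FALSE))
    X <- cbind(X, col)
  }
  X
}

#' Ground truth for a synthetic foci dataset
#'
#' @param planted_clusters List of `list(center = c(x, y, z) mm,
#'   dispersion = mm, prob = activation probability)`.
#' @param n_contrasts Number of contrasts.
#' @param background_rate Expected uniform background foci per contrast
#'   (Poisson).
#' @param N_range Length-2 range of per-contrast sample sizes.
#' @return A `foci_truth` list.
#' @export
foci_truth <- function(planted_clusters = list(), n_contrasts = 20,
                       background_rate = 8, N_range = c(10, 40)) {
  for (pc in planted_clusters)
    stopifnot(length(pc$center) == 3, pc$dispersion >= 0,
              pc$prob >= 0, pc$prob <= 1)
  stopifnot(n_contrasts >= 1, background_rate >= 0,
            length(N_range) == 2, all(N_range >= 1))
  structure(list(planted_clusters = planted_clusters,
                 n_contrasts = n_contrasts,
                 background_rate = background_rate, N_range = N_range),
            class = "foci_truth")
}

#' Generate a synthetic foci table over a mask
#'
#' Per contrast: each planted cluster contributes, with its activation
#' probability, one focus drawn from an isotropic normal around the
#' cluster center (SD = dispersion, rejection-truncated to the mask);
#' plus `Poisson(background_rate)` background foci uniform over mask voxel
#' centers.  Sample sizes are uniform integers over `N_range`.
#'
#' @param truth A [foci_truth()] object.
#' @param grid A `volume_grid` (mask non-empty); planted centers must be
#'   inside the mask.
#' @param seed Integer seed.
#' @return List with `foci` (a `foci_table`) and `truth` (echo with seed).
#' @export
gen_foci_dataset <- function(truth, grid, seed = 1) {
  stopifnot(inherits(truth, "foci_truth"), inherits(grid, "volume_grid"))
  set.seed(as.integer(seed))
  mask_idx <- which(grid$mask)
  in_mask <- function(xyz) {
    v <- round(.world_to_vox(rbind(xyz), grid))
    all(v >= 1) && all(v <= grid$dim) &&
      grid$mask[v[1], v[2], v[3]]
  }
  for (pc in truth$planted_clusters)
    if (!in_mask(pc$center))
      stop("planted cluster center outside the mask", call. = FALSE)

  rows <- list()
  for (cc in seq_len(truth$n_contrasts)) {
    pts <- NULL
    for (pc in truth$planted_clusters) {
      if (stats::runif(1) < pc$prob) {
        for (try in 1:200) {
          cand <- pc$center + stats::rnorm(3, 0, pc$dispersion)
          if (in_mask(cand)) break
        }
        pts <- rbind(pts, cand)
      }
    }
    n_bg <- stats::rpois(1, truth$background_rate)
    if (n_bg > 0) {
      bg_idx <- mask_idx[sample.int(length(mask_idx), n_bg, replace = TRUE)]
      pts <- rbind(pts, .vox_to_world(arrayInd(bg_idx, grid$dim), grid))
    }
    if (is.null(pts)) {  # guarantee >= 1 focus per contrast
      bg_idx <- mask_idx[sample.int(length(mask_idx), 1)]
      pts <- .vox_to_world(arrayInd(bg_idx, grid$dim), grid)
    }
    N <- sample(seq(truth$N_range[1], truth$N_range[2]), 1)
    rows[[cc]] <- data.frame(
      study_id = sprintf("study%02d", cc), contrast_id = sprintf("c%02d", cc),
      n = N, space = "MNI", x = pts[, 1], y = pts[, 2], z = pts[, 3],
      stringsAsFactors = FALSE)
  }
  foci <- do.call(rbind, rows)
  rownames(foci) <- NULL
  class(foci) <- c("foci_table", "data.frame")
  echo <- unclass(truth)
  echo$seed <- seed
  list(foci = foci, truth = echo)
}

#' Generate an ellipsoid "brain" mask
#'
#' Deterministic ellipsoid mask centered in a grid whose world origin puts
#' mm (0,0,0) at the grid center -- a stand-in gray-matter volume for
#' simulation and testing.
#'
#' @param shape Voxel counts per axis.
#' @param voxel_size Isotropic voxel size mm.
#' @param semi_axes Ellipsoid semi-axes mm (> 0, must fit in the box).
#' @return A `volume_grid` whose mask is the ellipsoid.
#' @export
gen_mask <- function(shape = c(40, 48, 40), voxel_size = 4,
                     semi_axes = c(70, 85, 70)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), voxel_size > 0,
            length(semi_axes) == 3)
  if (any(semi_axes <= 0)) stop("degenerate semi-axis", call. = FALSE)
  half_extent <- (shape - 1) / 2 * voxel_size
  if (any(semi_axes > half_extent + voxel_size / 2))
    stop("semi-axes do not fit in the box", call. = FALSE)
  origin <- -half_extent
  ax <- (seq_len(shape[1]) - 1) * voxel_size + origin[1]
  ay <- (seq_len(shape[2]) - 1) * voxel_size + origin[2]
  az <- (seq_len(shape[3]) - 1) * voxel_size + origin[3]
  mask <- outer(outer((ax / semi_axes[1])^2, (ay / semi_axes[2])^2, "+"),
                (az / semi_axes[3])^2, "+") <= 1
  volume_grid(shape, voxel_size, origin = origin, mask = mask)
}
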