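# Orchestration of the two analysis arms: the behavioral multilevel
# meta-analysis (overall fit, moderator models, age correlations,
# publication-bias diagnostics, forest/funnel plot data) and the MKDA
# imaging arm (density maps, Monte Carlo thresholds, cluster tables,
# difference maps).  Configs are plain YAML key-value files; every output
# CSV carries a header comment embedding the config hash and seed so a run
# is reproducible from its artifacts.

.config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]  # location-independent
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  # small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", h)
}

.write_csv_stamped <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# affwm config_hash=%s seed=%s", hash,
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an analysis config file
#'
#' Plain YAML key-value config; see [run_behavioral()] and [run_mkda()]
#' for the recognized keys.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

.fit_rows <- function(fit, model) {
  data.frame(model = model, term = names(fit$beta),
             beta = unname(fit$beta), se = unname(fit$se),
             z = unname(fit$z), p = unname(fit$p),
             ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
             k = fit$k, n_studies = fit$n_studies,
             sigma2 = fit$sigma2, row.names = NULL)
}

#' Run the behavioral meta-analysis arm
#'
#' Fits, on one corpus, the model set of the behavioral analysis: the
#' overall random-intercepts model per outcome, the planned moderator
#' models (valence, task relevance, their interaction, population), the
#' age correlation, and both publication-bias diagnostics; and writes the
#' fit, heterogeneity, bias, forest-plot and funnel-plot tables plus a
#' four-cell (task relevance x valence) summary per outcome.
#'
#' @param config Named list (or path handled by [read_config()]) with
#'   keys: `study_table` (CSV path or `data.frame`), `out_dir`, optional
#'   `outcome_filter` (`"accuracy"`/`"rt"`), `population_filter`
#'   (`"healthy"`/`"clinical"`), `moderators` (character vector as in
#'   [moderator_design()]), `ci_level`, `seed`.
#' @return Invisibly, a list of the fitted objects and output paths.
#' @export
run_behavioral <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  effects <- read_study_table(config$study_table)
  hash <- .config_hash(config)
  seed <- config$seed
  ci_level <- config$ci_level %||% 0.95

  if (!is.null(config$outcome_filter)) {
    effects <- effects[effects$outcome == config$outcome_filter, , drop = FALSE]
    if (!nrow(effects))
      stop("outcome_filter '", config$outcome_filter,
           "' excludes all records", call. = FALSE)
  }
  if (!is.null(config$population_filter)) {
    effects <- effects[effects$population == config$population_filter, ,
                       drop = FALSE]
    if (!nrow(effects))
      stop("population_filter '", config$population_filter,
           "' excludes all records", call. = FALSE)
  }

  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fits <- list(overall = fit_multilevel_re(effects, ci_level = ci_level))
  mods <- config$moderators %||%
    intersect(c("valence", "task_relevance", "population"), names(effects))
  for (m in mods)
    fits[[m]] <- fit_multilevel_re(effects, moderator_design(effects, m),
                                   ci_level = ci_level)
  if (all(c("valence", "task_relevance") %in% names(effects))) {
    X <- moderator_design(effects, c("valence", "task_relevance"))
    X <- cbind(X, interaction_vxt = X[, "valence_positive"] *
                 X[, "task_relevance_distractor"])
    fits$valence_x_task <- fit_multilevel_re(effects, X, ci_level = ci_level)
  }

  fit_tab <- do.call(rbind, lapply(names(fits), function(nm)
    .fit_rows(fits[[nm]], nm)))
  het_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, k = f$k, Q = f$Q, Q_df = f$Q_df, Q_p = f$Q_p,
               QM = f$QM, QM_df = f$QM_df, QM_p = f$QM_p, sigma2 = f$sigma2)
  }))

  bias <- list()
  if (nrow(effects) >= 3 && max(effects$v) - min(effects$v) > 1e-12)
    bias$egger <- egger_multilevel(effects)
  if (nrow(effects) >= 10 && max(effects$v) - min(effects$v) > 1e-12)
    bias$rank <- rank_correlation_bias(effects)
  bias_tab <- do.call(rbind, lapply(bias, function(b)
    data.frame(method = b$method, statistic = b$statistic, p = b$p)))

  age_cor <- NULL
  if ("mean_age" %in% names(effects) &&
      length(unique(effects$mean_age)) > 1 && nrow(effects) >= 4)
    age_cor <- correlate_with_moderator(effects, effects$mean_age)

  # four-cell summary (task relevance x valence), one block per outcome
  cell_tab <- NULL
  if (all(c("valence", "task_relevance") %in% names(effects))) {
    cells <- expand.grid(task_relevance = c("target", "distractor"),
                         valence = c("negative", "positive"),
                         stringsAsFactors = FALSE)
    for (oc in unique(effects$outcome)) {
      for (i in seq_len(nrow(cells))) {
        sub <- effects[effects$outcome == oc &
                       effects$valence == cells$valence[i] &
                       effects$task_relevance == cells$task_relevance[i], ,
                       drop = FALSE]
        if (nrow(sub) < 2) next
        f <- fit_multilevel_re(sub, ci_level = ci_level)
        cell_tab <- rbind(cell_tab, data.frame(
          outcome = oc, task_relevance = cells$task_relevance[i],
          valence = cells$valence[i], k = f$k, d = unname(f$beta[1]),
          sem = unname(f$se[1]), ci_low = unname(f$ci_low[1]),
          ci_high = unname(f$ci_high[1]), p = unname(f$p[1]),
          Q = f$Q, Q_df = f$Q_df, Q_p = f$Q_p))
      }
    }
  }

  paths <- c(
    fit_table = .write_csv_stamped(fit_tab,
      file.path(out_dir, "fit_table.csv"), hash, seed),
    heterogeneity = .write_csv_stamped(het_tab,
      file.path(out_dir, "heterogeneity.csv"), hash, seed))
  if (!is.null(bias_tab))
    paths["bias_tests"] <- .write_csv_stamped(bias_tab,
      file.path(out_dir, "bias_tests.csv"), hash, seed)
  if (!is.null(cell_tab))
    paths["cells"] <- .write_csv_stamped(cell_tab,
      file.path(out_dir, "cells_task_by_valence.csv"), hash, seed)
  if (!is.null(age_cor))
    paths["age_correlation"] <- .write_csv_stamped(
      data.frame(r = age_cor$r, ci_low = age_cor$ci[1],
                 ci_high = age_cor$ci[2], p = age_cor$p, df = age_cor$df),
      file.path(out_dir, "age_correlation.csv"), hash, seed)
  paths["forest_data"] <- .write_csv_stamped(
    data.frame(study_id = effects$study_id, es_id = effects$es_id,
               d = effects$d, se = sqrt(effects$v),
               ci_low = effects$d - 1.96 * sqrt(effects$v),
               ci_high = effects$d + 1.96 * sqrt(effects$v)),
    file.path(out_dir, "forest_data.csv"), hash, seed)
  paths["funnel_data"] <- .write_csv_stamped(
    data.frame(d = effects$d, se = sqrt(effects$v)),
    file.path(out_dir, "funnel_data.csv"), hash, seed)

  invisible(list(fits = fits, bias = bias, age_correlation = age_cor,
                 cells = cell_tab, paths = paths, config_hash = hash))
}

#' Run the MKDA imaging arm
#'
#' Builds the weighted density map for a foci table, simulates the Monte
#' Carlo null over the mask, derives voxel and cluster-extent thresholds,
#' extracts surviving clusters, and (when a second foci table is given)
#' computes the difference map with permutation inference.  Density and
#' difference maps are written as NIfTI-1, cluster tables as stamped CSVs.
#'
#' @param config Named list (or YAML path) with keys: `foci` (TSV path or
#'   `data.frame`), optional `foci_b` (second condition for a difference
#'   analysis), `mask` (NIfTI path; default synthetic ellipsoid mask),
#'   `voxel_size` (used for the default mask / [mni_grid()]), `radius`
#'   (default 10), `voxel_p` (0.01), `fwer` (0.05), `n_iterations`
#'   (>= 100), `seed`, `out_dir`.
#' @return Invisibly, list with `density`, `null`, `thresholds`,
#'   `clusters`, optional `difference`, and output paths.
#' @export
run_mkda <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  hash <- .config_hash(config)
  seed <- config$seed %||% 1
  radius <- config$radius %||% 10
  voxel_p <- config$voxel_p %||% 0.01
  fwer <- config$fwer %||% 0.05
  n_iter <- config$n_iterations %||% 5000
  if (n_iter < 100)
    stop("n_iterations must be >= 100; the Monte Carlo thresholds are not ",
         "meaningful below that", call. = FALSE)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  grid <- if (!is.null(config$mask)) read_mask(config$mask)
          else gen_mask(voxel_size = config$voxel_size %||% 4)
  foci <- read_foci(config$foci)

  dens <- mkda_density(foci, grid, radius = radius)
  null <- simulate_null(mkda_structure(foci), grid, n_iterations = n_iter,
                        seed = seed, radius = radius, voxel_p = voxel_p)
  thr <- derive_thresholds(null, voxel_p = voxel_p, fwer = fwer)
  clusters <- extract_clusters(dens, thr$voxel_threshold,
                               thr$cluster_extent_k)

  paths <- c(density = write_volume(dens,
                                    file.path(out_dir, "density.nii.gz")))
  cl_out <- clusters[, c("cluster_id", "size", "maximum",
                         "peak_x", "peak_y", "peak_z")]
  cl_out$region <- character(nrow(cl_out))   # no atlas bundled
  paths["clusters"] <- .write_csv_stamped(cl_out,
    file.path(out_dir, "clusters.csv"), hash, seed)
  .write_csv_stamped(
    data.frame(voxel_threshold = thr$voxel_threshold,
               cluster_extent_k = thr$cluster_extent_k,
               voxel_p = voxel_p, fwer = fwer, n_iterations = n_iter,
               radius = radius, seed = seed),
    file.path(out_dir, "thresholds.csv"), hash, seed)

  difference <- NULL
  if (!is.null(config$foci_b)) {
    foci_b <- read_foci(config$foci_b)
    difference <- difference_map(foci, foci_b, grid,
                                 n_permutations = n_iter, seed = seed,
                                 radius = radius, voxel_p = voxel_p,
                                 fwer = fwer)
    paths["diff_map"] <- write_volume(difference$map,
                                      file.path(out_dir, "difference.nii.gz"))
    for (side in c("clusters_A_gt_B", "clusters_B_gt_A")) {
      tb <- difference[[side]][, c("cluster_id", "size", "maximum",
                                   "peak_x", "peak_y", "peak_z")]
      tb$region <- character(nrow(tb))
      paths[side] <- .write_csv_stamped(tb,
        file.path(out_dir, paste0(side, ".csv")), hash, seed)
    }
  }

  invisible(list(density = dens, null = null, thresholds = thr,
                 clusters = clusters, difference = difference,
                 paths = paths, config_hash = hash, grid = grid))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
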