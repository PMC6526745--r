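#' Summarize one experimental condition
#'
#' Bundles the per-condition summary statistics (sample size, mean, standard
#' deviation) from which a standardized mean difference is computed.  The
#' outcome is either an accuracy proportion or a response time in
#' milliseconds; the condition label records whether the summary comes from
#' the affective or the neutral arm of the contrast.
#'
#' @param n Participant count (>= 2).
#' @param mean Outcome mean (proportion correct for `outcome = "accuracy"`,
#'   milliseconds for `outcome = "rt"`).
#' @param sd Outcome standard deviation, same units as `mean`; must be > 0.
#' @param outcome `"accuracy"` or `"rt"`.
#' @param condition `"affective"` or `"neutral"`.
#' @param check_accuracy_range If `TRUE` (default), accuracy means must lie
#'   in \[0, 1\]; set `FALSE` for d-prime or other unbounded accuracy scales.
#' @return An object of class `condition_summary`.
#' @export
condition_summary <- function(n, mean, sd,
                              outcome = c("accuracy", "rt"),
                              condition = c("affective", "neutral"),
                              check_accuracy_range = TRUE) {
  outcome <- match.arg(outcome)
  condition <- match.arg(condition)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2)
    stop("'n' must be a single finite number >= 2", call. = FALSE)
  if (!is.finite(mean)) stop("'mean' must be finite", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be > 0", call. = FALSE)
  if (outcome == "accuracy" && check_accuracy_range &&
      (mean < 0 || mean > 1))
    stop("accuracy mean must lie in [0, 1] (set check_accuracy_range = FALSE for other scales)",
         call. = FALSE)
  structure(list(n = as.numeric(n), mean = as.numeric(mean),
                 sd = as.numeric(sd), outcome = outcome,
                 condition = condition),
            class = "condition_summary")
}

#' Small-sample bias correction for a standardized mean difference
#'
#' Applies Hedges' correction factor `J = 1 - 3 / (4 df - 1)` to an
#' uncorrected standardized mean difference.  The pooled-SD estimator of the
#' standardization denominator is slightly biased upward in small samples,
#' which inflates |d|; multiplying by J removes the bias to first order.
#'
#' @param d_raw Uncorrected standardized mean difference.
#' @param df Degrees of freedom of the pooled SD (n1 + n2 - 2 for two
#'   independent groups, n - 1 for paired designs); must be >= 2.
#' @return Hedges' g = J * d_raw.  |g| <= |d_raw| always.
#' @export
hedges_correction <- function(d_raw, df) {
  if (any(!is.finite(df)) || any(df < 2))
    stop("'df' must be >= 2", call. = FALSE)
  j <- 1 - 3 / (4 * df - 1)
  j * d_raw
}

#' Sampling variance of a bias-corrected standardized mean difference
#'
#' Large-sample variance of Hedges' g.  For two independent groups
#' `v = (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2))`.  For a paired design
#' (`n2 = NULL`, correlation `r`) `v = 2 (1 - r) / n + g^2 / (2 n)`.  A
#' variance floor keeps downstream inverse-variance weights finite when the
#' paired formula degenerates (r close to 1 and g close to 0).
#'
#' @param n1 First group size (or the pair count for paired designs).
#' @param n2 Second group size, or `NULL` for a paired design.
#' @param g Bias-corrected standardized mean difference.
#' @param r Pre/post correlation for the paired formula (ignored otherwise).
#' @param floor Minimum variance returned; default `1e-8`.
#' @return Sampling variance (>= `floor`).
#' @export
smd_variance <- function(n1, n2 = NULL, g, r = 0.5, floor = 1e-8) {
  if (any(n1 < 2)) stop("'n1' must be >= 2", call. = FALSE)
  if (is.null(n2)) {
    if (any(abs(r) > 1)) stop("'r' must lie in [-1, 1]", call. = FALSE)
    v <- 2 * (1 - r) / n1 + g^2 / (2 * n1)
  } else {
    if (any(n2 < 2)) stop("'n2' must be >= 2", call. = FALSE)
    v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  }
  pmax(v, floor)
}

#' Standardized mean difference between affective and neutral conditions
#'
#' Computes the effect size of the behavioral meta-analysis: the mean
#' difference between the affective and neutral condition divided by the
#' pooled standard deviation, with Hedges' small-sample bias correction
#' applied.  The sign convention is fixed as
#' `d = (affective - neutral) / s_pooled` for both outcomes, so for response
#' times a positive d means slower responding with affective material, and
#' for accuracy a positive d means better performance.
#'
#' @param aff,neut `condition_summary` objects for the affective and
#'   neutral condition; outcomes must match.
#' @param design `"independent"` (two groups; pooled SD with n1 + n2 - 2 df)
#'   or `"paired"` (same participants; requires equal n, uses the mean
#'   per-condition SD and the paired variance formula).
#' @param r_paired Correlation between conditions for `design = "paired"`;
#'   defaults to 0.5, a conventional neutral assumption recorded in the
#'   returned record.
#' @param study_id,es_id Identifiers carried into the record.
#' @param ... Moderators stored on the record (`valence`, `task_relevance`,
#'   `population`, `mean_age`, `emotion_type`, `wm_load`).
#' @return A one-row `data.frame` of class `effect_size_record` with columns
#'   `study_id`, `es_id`, `outcome`, `d_raw` (uncorrected), `d` (Hedges' g),
#'   `v` (sampling variance), `design`, `r_paired`, plus any moderators.
#' @examples
#' a <- condition_summary(20, 0.55, 0.10, "accuracy", "affective")
#' n <- condition_summary(20, 0.50, 0.10, "accuracy", "neutral")
#' compute_smd(a, n, study_id = "s1", es_id = "e1")
#' @export
compute_smd <- function(aff, neut, design = c("independent", "paired"),
                        r_paired = NULL, study_id = NA_character_,
                        es_id = NA_character_, ...) {
  design <- match.arg(design)
  stopifnot(inherits(aff, "condition_summary"),
            inherits(neut, "condition_summary"))
  if (aff$outcome != neut$outcome)
    stop("outcome mismatch between conditions ('", aff$outcome, "' vs '",
         neut$outcome, "')", call. = FALSE)
  if (design == "paired") {
    if (aff$n != neut$n)
      stop("paired design requires equal n in both conditions", call. = FALSE)
    if (is.null(r_paired)) r_paired <- 0.5
    if (abs(r_paired) > 1) stop("'r_paired' must lie in [-1, 1]", call. = FALSE)
    n <- aff$n
    df <- n - 1
    # standardize by the average condition SD so d stays on the raw-score
    # (not change-score) metric
    s_pool <- sqrt((aff$sd^2 + neut$sd^2) / 2)
    d_raw <- (aff$mean - neut$mean) / s_pool
    g <- hedges_correction(d_raw, df)
    v <- smd_variance(n, NULL, g = g, r = r_paired)
  } else {
    r_paired <- NA_real_
    n1 <- aff$n; n2 <- neut$n
    df <- n1 + n2 - 2
    s_pool <- sqrt(((n1 - 1) * aff$sd^2 + (n2 - 1) * neut$sd^2) / df)
    d_raw <- (aff$mean - neut$mean) / s_pool
    g <- hedges_correction(d_raw, df)
    v <- smd_variance(n1, n2, g = g)
  }
  mods <- list(...)
  rec <- data.frame(study_id = study_id, es_id = es_id,
                    outcome = aff$outcome, d_raw = d_raw, d = g, v = v,
                    design = design, r_paired = r_paired,
                    stringsAsFactors = FALSE)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  class(rec) <- c("effect_size_record", "data.frame")
  rec
}

#' Read a study-summary table and compute effect-size records
#'
#' Reads a delimited study-summary table and returns one effect-size record
#' per row.  Two layouts are accepted: per-condition summaries (columns
#' `n_aff`, `mean_aff`, `sd_aff`, `n_neut`, `mean_neut`, `sd_neut`, plus
#' optional `design` and `r_paired`), from which d and v are computed with
#' [compute_smd()]; or precomputed effects (columns `d` and `v`), ingested
#' as-is.  `study_id` and `es_id` are required in both layouts; moderator
#' columns (`outcome`, `valence`, `task_relevance`, `population`,
#' `mean_age`, `emotion_type`, `wm_load`) are carried through when present.
#'
#' @param path Path to a CSV file (header required, UTF-8, decimal point),
#'   or a `data.frame` already in memory.
#' @param check_accuracy_range Passed to [condition_summary()].
#' @return A `data.frame` with one row per effect size, columns
#'   `study_id`, `es_id`, `d`, `v` and any moderators; `es_id` values must
#'   be unique.
#' @export
read_study_table <- function(path, check_accuracy_range = TRUE) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("study_id", "es_id")
  if (!all(need %in% names(tab)))
    stop("study table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$es_id))
    stop("duplicate es_id values in study table", call. = FALSE)
  summary_cols <- c("n_aff", "mean_aff", "sd_aff",
                    "n_neut", "mean_neut", "sd_neut")
  if (all(c("d", "v") %in% names(tab)) && !all(summary_cols %in% names(tab))) {
    if (any(!is.finite(tab$d)) || any(!is.finite(tab$v)) || any(tab$v <= 0))
      stop("precomputed effects require finite d and v > 0", call. = FALSE)
    out <- tab
  } else {
    if (!all(summary_cols %in% names(tab)))
      stop("study table needs either columns d,v or ",
           paste(summary_cols, collapse = ","), call. = FALSE)
    outcome <- if ("outcome" %in% names(tab)) tab$outcome else "accuracy"
    design <- if ("design" %in% names(tab)) tab$design else "independent"
    r_paired <- if ("r_paired" %in% names(tab)) tab$r_paired else NA_real_
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      aff <- condition_summary(tab$n_aff[i], tab$mean_aff[i], tab$sd_aff[i],
                               outcome = outcome[[min(i, length(outcome))]],
                               condition = "affective",
                               check_accuracy_range = check_accuracy_range)
      neut <- condition_summary(tab$n_neut[i], tab$mean_neut[i], tab$sd_neut[i],
                                outcome = outcome[[min(i, length(outcome))]],
                                condition = "neutral",
                                check_accuracy_range = check_accuracy_range)
      compute_smd(aff, neut,
                  design = design[[min(i, length(design))]],
                  r_paired = if (is.na(r_paired[[min(i, length(r_paired))]]))
                    NULL else r_paired[[min(i, length(r_paired))]],
                  study_id = tab$study_id[i], es_id = tab$es_id[i])
    })
    out <- do.call(rbind, rows)
    extra <- setdiff(names(tab), c(names(out), summary_cols))
    for (nm in extra) out[[nm]] <- tab[[nm]]
  }
  rownames(out) <- NULL
  out
}
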