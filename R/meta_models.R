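# Multilevel random/mixed-effects meta-analysis with known sampling
# variances.  Model: y_i = x_i' beta + u_{study(i)} + e_i, with
# e_i ~ N(0, v_i) (v_i known) and u_j ~ N(0, sigma2) shared by all effects
# of study j.  sigma2 is profiled out of the restricted likelihood; beta is
# GLS at sigma2-hat.  The marginal covariance is block diagonal per study,
# V_j = diag(v) + sigma2 * 1 1', so all quantities use the rank-one Woodbury
# identity rather than dense solves.

# Per-sigma2 GLS quantities.  X must be a numeric matrix, study an integer
# factor index aligned with y/v.
.ml_profile <- function(sigma2, y, v, X, study) {
  w <- 1 / v
  k <- length(y)
  p <- ncol(X)
  wX <- X * w
  Sx <- rowsum(wX, study)               # per-study sums of w * x
  Sy <- rowsum(w * y, study)
  Sw <- rowsum(w, study)
  cc <- sigma2 / (1 + sigma2 * Sw)      # Woodbury correction factor
  A <- crossprod(X, wX) - crossprod(Sx, Sx * as.vector(cc))
  b <- crossprod(X, w * y) - crossprod(Sx, Sy * as.vector(cc))
  yVy <- sum(w * y^2) - sum(cc * Sy^2)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
  rss <- yVy - sum(b * beta)            # r' V^{-1} r at the GLS beta
  logdetV <- sum(log(v)) + sum(log1p(sigma2 * Sw))
  logdetA <- 2 * sum(log(diag(R)))
  ll_reml <- -0.5 * ((k - p) * log(2 * pi) + logdetV + logdetA + rss)
  ll_ml <- -0.5 * (k * log(2 * pi) + logdetV + rss)
  list(beta = beta, vcov_chol = R, rss = rss, ll_reml = ll_reml,
       ll_ml = ll_ml, A = A)
}

.ml_objective <- function(sigma2, y, v, X, study, method) {
  pr <- .ml_profile(sigma2, y, v, X, study)
  if (is.null(pr)) return(-Inf)
  if (method == "REML") pr$ll_reml else pr$ll_ml
}

#' Fit a multilevel random-intercept meta-analytic model
#'
#' Fits the two-level meta-analytic model in which effect sizes (level 1)
#' are nested within studies (level 2): `y_i = x_i' beta + u_study(i) + e_i`
#' with known sampling variances `Var(e_i) = v_i` and a between-study
#' variance component `Var(u_j) = sigma2`.  `sigma2` is estimated by
#' bounded numerical maximization of the restricted (default) or full
#' log-likelihood, restarting from several spread points across the search
#' interval; `beta` is the generalized least squares solution at the
#' optimum.  Wald (normal) standard errors, z statistics, p values and
#' confidence intervals are reported per coefficient, together with
#' Cochran's Q computed at the fixed-effect fit and the omnibus moderator
#' statistic QM testing all non-intercept columns jointly.
#'
#' @param effects `data.frame` with columns `d` (observed effect), `v`
#'   (sampling variance > 0) and `study_id` (nesting key).
#' @param design Moderator design matrix (k x p, full column rank), or
#'   `NULL` for an intercept-only model.
#' @param method `"REML"` (default) or `"ML"`.
#' @param ci_level Confidence level for the Wald intervals.
#' @param sigma2_max Upper bound of the variance-component search;
#'   default `max(10 * var(d), 1)`.
#' @param n_restarts Number of equal subintervals of `[0, sigma2_max]`
#'   each searched separately before taking the best optimum; default 5.
#' @return A `meta_fit` object: list with `beta`, `se`, `z`, `p`,
#'   `ci_low`, `ci_high`, `sigma2`, `k`, `n_studies`, `Q`, `Q_df`, `Q_p`,
#'   `QM`, `QM_df`, `QM_p`, `loglik_restricted`, `vcov`, `converged`.
#' @examples
#' set.seed(1)
#' eff <- data.frame(study_id = rep(1:20, each = 2),
#'                   d = rnorm(40, 0.2, 0.2), v = runif(40, 0.02, 0.2))
#' fit_multilevel_re(eff)
#' @export
fit_multilevel_re <- function(effects, design = NULL,
                              method = c("REML", "ML"), ci_level = 0.95,
                              sigma2_max = NULL, n_restarts = 5) {
  method <- match.arg(method)
  stopifnot(is.data.frame(effects),
            all(c("d", "v", "study_id") %in% names(effects)))
  y <- as.numeric(effects$d)
  v <- as.numeric(effects$v)
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0))
    stop("effects need finite d and v > 0", call. = FALSE)
  k <- length(y)
  study <- as.integer(factor(effects$study_id))
  X <- if (is.null(design)) matrix(1, k, 1, dimnames = list(NULL, "intercept"))
       else as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (k < p) stop("fewer effects than design columns", call. = FALSE)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)

  if (is.null(sigma2_max))
    sigma2_max <- max(1, if (k > 1) 10 * stats::var(y) else 1)

  boundary <- k <= p   # no information left for sigma2
  if (boundary) {
    sigma2 <- 0
  } else {
    obj <- function(s2) .ml_objective(s2, y, v, X, study, method)
    best <- list(s2 = 0, ll = obj(0))
    cuts <- seq(0, sigma2_max, length.out = n_restarts + 1)
    for (i in seq_len(n_restarts)) {
      op <- stats::optimize(obj, lower = cuts[i], upper = cuts[i + 1],
                            maximum = TRUE, tol = 1e-8)
      if (op$objective > best$ll) best <- list(s2 = op$maximum, ll = op$objective)
    }
    sigma2 <- best$s2
    # snap to the boundary when the interior optimum is indistinguishable
    if (sigma2 < 1e-8 || obj(0) >= best$ll - 1e-10) {
      if (obj(0) >= best$ll - 1e-10) sigma2 <- 0 else sigma2 <- best$s2
    }
  }
  pr <- .ml_profile(sigma2, y, v, X, study)
  if (is.null(pr))
    stop("model failed to converge: singular GLS system", call. = FALSE)
  Rchol <- pr$vcov_chol
  vcov <- chol2inv(Rchol)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  beta <- as.vector(pr$beta); names(beta) <- colnames(X)
  se <- sqrt(diag(vcov))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)

  # Cochran Q at the fixed-effect (sigma2 = 0) GLS fit
  Q <- Q_df <- Q_p <- NA_real_
  if (k > p) {
    fe <- .ml_profile(0, y, v, X, study)
    Q <- fe$rss
    Q_df <- k - p
    Q_p <- stats::pchisq(Q, Q_df, lower.tail = FALSE)
  }

  # omnibus moderator test on all non-intercept columns
  is_int <- apply(X, 2, function(col) all(col == col[1]))
  mod_cols <- which(!is_int)
  QM <- QM_df <- QM_p <- NA_real_
  if (length(mod_cols)) {
    wt <- .wald_block(beta, vcov, mod_cols)
    QM <- wt$stat; QM_df <- wt$df; QM_p <- wt$p
  }

  structure(list(
    beta = beta, se = se, z = z, p = pval,
    ci_low = beta - zq * se, ci_high = beta + zq * se,
    sigma2 = sigma2, k = k, n_studies = length(unique(study)),
    Q = Q, Q_df = Q_df, Q_p = Q_p, QM = QM, QM_df = QM_df, QM_p = QM_p,
    loglik_restricted = pr$ll_reml, loglik = pr$ll_ml,
    vcov = vcov, method = method, ci_level = ci_level,
    design = X, study = study, y = y, v = v,
    converged = TRUE, boundary = sigma2 == 0,
    degenerate_ci = boundary),
    class = "meta_fit")
}

.wald_block <- function(beta, vcov, cols) {
  b <- beta[cols]
  V <- vcov[cols, cols, drop = FALSE]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) stop("singular coefficient subcovariance", call. = FALSE)
  stat <- sum(backsolve(R, b, transpose = TRUE)^2)
  df <- length(cols)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Multilevel meta-analysis (%s): k = %d effects, %d studies\n",
              x$method, x$k, x$n_studies))
  cat(sprintf("sigma2 = %.4f%s\n", x$sigma2,
              if (x$boundary) " (boundary)" else ""))
  tab <- data.frame(beta = x$beta, se = x$se, z = x$z, p = x$p,
                    ci.lb = x$ci_low, ci.ub = x$ci_high)
  print(round(tab, 4))
  if (is.finite(x$Q))
    cat(sprintf("Q(%d) = %.2f, p = %.4g\n", x$Q_df, x$Q, x$Q_p))
  if (is.finite(x$QM))
    cat(sprintf("QM(%d) = %.2f, p = %.4g\n", x$QM_df, x$QM, x$QM_p))
  invisible(x)
}

#' Cochran's Q test of residual heterogeneity
#'
#' `Q = sum((y_i - x_i' beta_FE)^2 / v_i)` where `beta_FE` is the
#' fixed-effect (sigma2 = 0) weighted least squares fit; under homogeneity
#' Q is chi-square with `k - p` degrees of freedom.
#'
#' @inheritParams fit_multilevel_re
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(effects, design = NULL) {
  y <- as.numeric(effects$d); v <- as.numeric(effects$v)
  k <- length(y)
  X <- if (is.null(design)) matrix(1, k, 1) else as.matrix(design)
  p <- ncol(X)
  if (k <= p) stop("Q requires k > number of design columns", call. = FALSE)
  study <- seq_len(k)  # study structure is irrelevant at sigma2 = 0
  fe <- .ml_profile(0, y, v, X, study)
  list(Q = fe$rss, df = k - p,
       p = stats::pchisq(fe$rss, k - p, lower.tail = FALSE))
}

#' Wald omnibus test of a subset of fitted coefficients
#'
#' Joint chi-square test that the named (or indexed) coefficients are all
#' zero, using their joint covariance from the fitted model; `df` equals the
#' subset size.  This is the moderator omnibus statistic QM restricted to a
#' chosen subset.
#'
#' @param fit A `meta_fit` object.
#' @param columns Character names or integer indices of coefficients.
#' @return List with `QM`, `df`, `p`.
#' @export
moderator_test <- function(fit, columns) {
  stopifnot(inherits(fit, "meta_fit"))
  if (length(columns) == 0) stop("empty coefficient subset", call. = FALSE)
  if (is.character(columns)) {
    idx <- match(columns, names(fit$beta))
    if (anyNA(idx))
      stop("unknown coefficient(s): ",
           paste(columns[is.na(idx)], collapse = ", "), call. = FALSE)
  } else idx <- as.integer(columns)
  wt <- .wald_block(fit$beta, fit$vcov, idx)
  list(QM = wt$stat, df = wt$df, p = wt$p)
}

#' Multilevel Egger-type regression test for funnel asymmetry
#'
#' Refits the multilevel model with the standard error `sqrt(v_i)` added as
#' a moderator and reports the Wald z and two-sided p of its coefficient.
#' Under selective publication, small (high-SE) effects are
#' over-represented at extreme values, inducing a nonzero SE slope.
#'
#' @param effects `data.frame` with `d`, `v`, `study_id`.
#' @param design Optional additional moderators to adjust for.
#' @param method `"multilevel"` (default) refits the full two-level model
#'   with the SE moderator; `"marginal"` is the classic weighted (1/v)
#'   regression of d on SE, ignoring the study nesting.
#' @return List with `method`, `statistic` (z), `p`, and the SE-slope
#'   estimate `slope`.
#' @export
egger_multilevel <- function(effects, design = NULL,
                             method = c("multilevel", "marginal")) {
  method <- match.arg(method)
  k <- nrow(effects)
  if (k < 3) stop("Egger test needs k >= 3", call. = FALSE)
  se <- sqrt(effects$v)
  if (max(se) - min(se) < 1e-12)
    stop("all standard errors equal: SE moderator collinear with intercept",
         call. = FALSE)
  X <- if (is.null(design))
    matrix(1, k, 1, dimnames = list(NULL, "intercept")) else as.matrix(design)
  X <- cbind(X, se = se)
  if (method == "marginal") {
    fit <- stats::lm.wfit(X, effects$d, w = 1 / effects$v)
    # known-variance weighted LS: coefficient covariance is (X'WX)^{-1}
    XtWX <- crossprod(X, X / effects$v)
    vc <- chol2inv(chol(XtWX))
    i <- ncol(X)
    z <- fit$coefficients[i] / sqrt(vc[i, i])
    return(list(method = "egger_marginal", statistic = unname(z),
                p = unname(2 * stats::pnorm(-abs(z))),
                slope = unname(fit$coefficients[i])))
  }
  fit <- fit_multilevel_re(effects, design = X)
  i <- match("se", names(fit$beta))
  list(method = "egger_multilevel", statistic = unname(fit$z[i]),
       p = unname(fit$p[i]), slope = unname(fit$beta[i]), fit = fit)
}

#' Rank-correlation publication-bias test for multilevel data
#'
#' Approximates the Egger test for multilevel data: the multilevel model is
#' refit with the sampling variance `v_i` included as a moderator, and
#' Kendall's tau between the resulting marginal residuals and `v_i` is
#' computed with its normal-approximation two-sided p value.  Including v
#' as a moderator first removes the deterministic part of any
#' variance-effect association so the rank test sees only the residual one.
#'
#' @param effects `data.frame` with `d`, `v`, `study_id`; needs k >= 10.
#' @return List with `method = "rank_correlation"`, `statistic` (tau), `p`.
#' @export
rank_correlation_bias <- function(effects) {
  k <- nrow(effects)
  if (k < 10) stop("rank-correlation test needs k >= 10", call. = FALSE)
  v <- effects$v
  if (max(v) - min(v) < 1e-12)
    stop("zero variance in ranks of v", call. = FALSE)
  X <- cbind(intercept = 1, v = v)
  fit <- fit_multilevel_re(effects, design = X)
  resid <- fit$y - as.vector(fit$design %*% fit$beta)
  tau <- stats::cor(resid, v, method = "kendall")
  # normal approximation for Kendall's tau under independence
  z <- 3 * tau * sqrt(k * (k - 1)) / sqrt(2 * (2 * k + 5))
  list(method = "rank_correlation", statistic = tau,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Correlate effect sizes with a continuous moderator
#'
#' Pearson correlation between observed effect sizes and a continuous
#' moderator (e.g., mean sample age), with a Fisher-z 95% confidence
#' interval and two-sided p value.  By default the correlation is
#' unweighted; `weighted = TRUE` weights observations by inverse sampling
#' variance.
#'
#' @param effects `data.frame` with column `d`.
#' @param moderator Numeric vector aligned with `effects`; must vary.
#' @param weighted Use 1/v weights (default `FALSE`).
#' @param ci_level Confidence level.
#' @return List with `r`, `ci`, `p`, `df`.
#' @export
correlate_with_moderator <- function(effects, moderator, weighted = FALSE,
                                     ci_level = 0.95) {
  d <- effects$d
  ok <- is.finite(d) & is.finite(moderator)
  d <- d[ok]; m <- moderator[ok]
  n <- length(d)
  if (n < 4) stop("need >= 4 paired observations", call. = FALSE)
  if (max(m) - min(m) < 1e-12) stop("constant moderator", call. = FALSE)
  if (weighted) {
    w <- 1 / effects$v[ok]
    mw <- function(x) sum(w * x) / sum(w)
    cw <- function(x, y) sum(w * (x - mw(x)) * (y - mw(y))) / sum(w)
    r <- cw(d, m) / sqrt(cw(d, d) * cw(m, m))
  } else {
    r <- stats::cor(d, m)
  }
  df <- n - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  fz <- atanh(r)
  ci <- tanh(fz + c(-1, 1) * zq / sqrt(n - 3))
  list(r = r, ci = ci, p = p, df = df)
}
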