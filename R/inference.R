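#' @importFrom lme4 lmer refit fixef lmerControl
NULL

# condition coding: numeric when all levels parse as numbers (ordered
# manipulations such as luminance level), categorical otherwise
code_condition <- function(values, condition_as = c("auto", "numeric", "factor")) {
  condition_as <- match.arg(condition_as)
  num <- suppressWarnings(as.numeric(as.character(values)))
  if (condition_as == "numeric" ||
      (condition_as == "auto" && !anyNA(num))) {
    if (anyNA(num)) stop("condition has non-numeric levels", call. = FALSE)
    num
  } else {
    factor(values)
  }
}

# numeric covariate required by the permutation/BF routes (a 2-level factor
# is coded 0/1)
numeric_condition <- function(values, condition_as = "auto") {
  x <- code_condition(values, condition_as)
  if (is.factor(x)) {
    if (nlevels(x) != 2L)
      stop("this test needs a numeric or two-level condition", call. = FALSE)
    x <- as.numeric(x) - 1
  }
  x
}

new_timecourse <- function(table, clusters, method, alpha, adjust = "none") {
  structure(list(table = table, clusters = clusters, method = method,
                 alpha = alpha, adjust = adjust),
            class = "pupil_timecourse")
}

#' @export
print.pupil_timecourse <- function(x, ...) {
  cat("<pupil_timecourse> ", x$method, ": ", nrow(x$table), " timepoints, ",
      sum(x$table$flag, na.rm = TRUE), " flagged (alpha = ", x$alpha,
      ", adjust = ", x$adjust, ")\n", sep = "")
  if (nrow(x$clusters)) {
    cat("  clusters:\n")
    print(x$clusters, row.names = FALSE)
  } else cat("  no clusters\n")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement; the
#' output is aligned with the input order. Missing entries pass through.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  pp <- p[!is.na(p)]
  if (any(pp < 0 | pp > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Contiguous clusters of flagged timepoints
#'
#' Extracts maximal runs of consecutive flagged timepoints as clusters, in
#' temporal order. Cluster bounds are reported in ms (end inclusive). When a
#' statistic vector is supplied, each cluster's mass (sum of the absolute
#' statistic over its timepoints) is included.
#'
#' @param flags logical vector, one entry per timepoint (`NA` counts as not
#'   flagged).
#' @param times timepoint grid in ms, aligned with `flags`.
#' @param statistic optional per-timepoint statistic for cluster mass.
#' @return data frame `start`, `end`, `n`, `mass`; zero rows when nothing is
#'   flagged.
#' @export
find_clusters <- function(flags, times, statistic = NULL) {
  stopifnot(length(flags) == length(times))
  f <- !is.na(flags) & flags
  if (!any(f))
    return(data.frame(start = numeric(), end = numeric(), n = integer(),
                      mass = numeric()))
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start = times[starts[keep]],
    end = times[ends[keep]],
    n = r$lengths[keep],
    mass = vapply(keep, function(j) {
      if (is.null(statistic)) NA_real_ else
        sum(abs(statistic[starts[j]:ends[j]]), na.rm = TRUE)
    }, numeric(1)))
}

# complete-trials matrix plus coded condition, shared by the timecourse tests
timecourse_data <- function(rec, fixed, condition_as = "auto", numeric_only = FALSE) {
  tm <- if (inherits(tm_try <- rec, "trial_matrix")) rec else to_trial_matrix(rec)
  if (!fixed %in% names(tm$row_meta))
    stop("condition '", fixed, "' not found in the data", call. = FALSE)
  if (length(unique(tm$row_meta$subject)) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  x <- if (numeric_only) numeric_condition(tm$row_meta[[fixed]], condition_as)
  else code_condition(tm$row_meta[[fixed]], condition_as)
  list(tm = tm, x = x, subject = factor(tm$row_meta$subject))
}

#' Per-timepoint linear mixed-model time course
#'
#' Fits, for every timepoint of the epoch grid, a linear mixed-effects model
#' of pupil size on the condition with a by-subject random intercept, and
#' tests the fixed effect by a likelihood-ratio test against the nested null
#' (both models fitted by maximum likelihood). Timepoints are flagged at
#' `alpha` after the chosen multiplicity adjustment (Benjamini-Hochberg FDR
#' across timepoints by default) and contiguous flagged runs are reported as
#' clusters. Only complete trials enter (the omission rule of the
#' trial-matrix stage).
#'
#' @param rec an epoched [pupil_recording] (or a `trial_matrix`).
#' @param fixed name of the condition column to test.
#' @param alpha significance level (default 0.05).
#' @param adjust `"BH"` (default) or `"none"`.
#' @param condition_as `"auto"` (numeric when all levels are numbers),
#'   `"numeric"`, or `"factor"`.
#' @return a `pupil_timecourse`: per-timepoint table (`time`, `statistic`
#'   = LRT chi-square, `df`, `p`, `p_adj`, `flag`) and a cluster table.
#'   Timepoints where the fit failed are marked missing.
#' @export
lmem_timecourse <- function(rec, fixed, alpha = 0.05,
                            adjust = c("BH", "none"),
                            condition_as = "auto") {
  adjust <- match.arg(adjust)
  d <- timecourse_data(rec, fixed, condition_as)
  Y <- d$tm$values
  times <- d$tm$col_times
  base <- data.frame(y = Y[, 1L], x = d$x, subject = d$subject)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  m1 <- lme4::lmer(y ~ x + (1 | subject), data = base, REML = FALSE,
                   control = ctrl)
  m0 <- lme4::lmer(y ~ 1 + (1 | subject), data = base, REML = FALSE,
                   control = ctrl)
  df_test <- length(lme4::fixef(m1)) - 1L

  stat <- p <- rep(NA_real_, length(times))
  n_fail <- 0L
  for (j in seq_along(times)) {
    res <- tryCatch(suppressMessages(suppressWarnings({
      f1 <- lme4::refit(m1, newresp = Y[, j])
      f0 <- lme4::refit(m0, newresp = Y[, j])
      lr <- max(0, 2 * (as.numeric(stats::logLik(f1)) -
                          as.numeric(stats::logLik(f0))))
      c(lr, stats::pchisq(lr, df = df_test, lower.tail = FALSE))
    })), error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    stat[j] <- res[1L]; p[j] <- res[2L]
  }
  if (n_fail == length(times))
    stop("mixed-model fit failed at every timepoint", call. = FALSE)
  if (n_fail > 0L)
    warning(n_fail, " timepoint(s) failed to fit and were marked missing",
            call. = FALSE)

  p_adj <- if (adjust == "BH") fdr_adjust(p) else p
  flag <- !is.na(p_adj) & p_adj < alpha
  tab <- data.frame(time = times, statistic = stat, df = df_test, p = p,
                    p_adj = p_adj, flag = flag)
  new_timecourse(tab, find_clusters(flag, times, stat),
                 method = "lmem", alpha = alpha, adjust = adjust)
}

#' Cluster-based permutation time course
#'
#' Controls the family-wise error of the per-timepoint tests by cluster-based
#' permutation. Per timepoint, the condition slope is tested within subjects
#' (ordinary least squares with subjects as additive nuisance); clusters are
#' formed from timepoints whose |t| exceeds the two-sided `cluster_alpha`
#' threshold, and each observed cluster's mass (sum of |t|) is compared with
#' the permutation null distribution of the maximum cluster mass, obtained by
#' shuffling condition labels across trials within each subject. Cluster
#' p-values use the add-one rule `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param rec an epoched [pupil_recording] (or `trial_matrix`).
#' @param fixed condition column name (numeric or two-level).
#' @param n_perm number of permutations (>= 100 recommended; fewer draws a
#'   warning).
#' @param cluster_alpha cluster-forming threshold (two-sided, default 0.05).
#' @param alpha significance level for cluster p-values (default 0.05).
#' @param seed integer seed; the permutation stream is fully reproducible.
#' @return a `pupil_timecourse` with per-timepoint t statistics and a cluster
#'   table carrying `p_cluster`; flagged timepoints are those inside clusters
#'   with `p_cluster <= alpha`.
#' @export
cluster_permutation <- function(rec, fixed, n_perm = 1000,
                                cluster_alpha = 0.05, alpha = 0.05,
                                seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives very coarse cluster p-values",
                            call. = FALSE)
  d <- timecourse_data(rec, fixed, numeric_only = TRUE)
  Y <- d$tm$values
  times <- d$tm$col_times
  ols <- subject_ols_t(Y, d$x, d$subject)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = ols$df)
  obs_flag <- abs(ols$t) > tcrit
  clusters <- find_clusters(obs_flag, times, ols$t)

  # permutation algebra: within-subject shuffles leave subject means of x
  # unchanged, so the centered covariate just gets shuffled within subject
  f <- d$subject
  xt <- d$x - stats::ave(d$x, f)
  xt <- xt / stats::sd(xt)
  Yt <- Y - apply(Y, 2L, function(col) stats::ave(col, f))
  xx <- sum(xt^2)
  ssy <- colSums(Yt^2)
  idx_by_subj <- split(seq_len(nrow(Y)), f)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    xp <- xt
    for (idx in idx_by_subj) xp[idx] <- xt[sample(idx)]
    bb <- drop(crossprod(Yt, xp)) / xx
    rss <- pmax(ssy - bb^2 * xx, 0)
    tb <- bb / sqrt(rss / ols$df / xx)
    fl <- abs(tb) > tcrit
    if (!any(fl)) { null_max[b] <- 0; next }
    r <- rle(fl)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    null_max[b] <- max(vapply(which(r$values), function(j)
      sum(abs(tb[starts[j]:ends[j]])), numeric(1)))
  }

  clusters$p_cluster <- vapply(clusters$mass, function(m)
    (1 + sum(null_max >= m)) / (1 + n_perm), numeric(1))
  flag <- rep(FALSE, length(times))
  for (i in seq_len(nrow(clusters))) {
    if (clusters$p_cluster[i] <= alpha)
      flag[times >= clusters$start[i] & times <= clusters$end[i]] <- TRUE
  }
  tab <- data.frame(time = times, statistic = ols$t, df = ols$df,
                    p = 2 * stats::pt(-abs(ols$t), df = ols$df),
                    p_adj = NA_real_, flag = flag)
  new_timecourse(tab, clusters, method = "cluster_permutation",
                 alpha = alpha, adjust = "cluster")
}

#' Bayes-factor time course
#'
#' Per timepoint, computes the Jeffreys-Zellner-Siow Bayes factor BF10 for
#' the condition effect against the null, with subjects as additive nuisance
#' and a zero-centered Cauchy prior (scale `prior_scale`) on the standardized
#' effect (see [jzs_bf()]). Timepoints with BF10 above `bf_threshold`
#' (default 3, "moderate evidence") are flagged and grouped into clusters.
#'
#' @param rec an epoched [pupil_recording] (or `trial_matrix`).
#' @param fixed condition column name (numeric or two-level).
#' @param prior_scale Cauchy prior scale r (default `sqrt(2)/2`).
#' @param bf_threshold evidence threshold on BF10 (default 3).
#' @return a `pupil_timecourse` whose table carries a `bf` column; timepoints
#'   where the integration failed are marked missing.
#' @export
bf_timecourse <- function(rec, fixed, prior_scale = sqrt(2) / 2,
                          bf_threshold = 3) {
  d <- timecourse_data(rec, fixed, numeric_only = TRUE)
  if (length(unique(d$x)) < 2L) stop("need at least 2 condition levels",
                                     call. = FALSE)
  Y <- d$tm$values
  times <- d$tm$col_times
  ols <- subject_ols_t(Y, d$x, d$subject)
  bf <- vapply(ols$t, function(ti) {
    tryCatch(jzs_bf(ti, ols$df, ols$neff, prior_scale),
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(bf))
    warning(sum(is.na(bf)), " timepoint(s) failed BF integration",
            call. = FALSE)
  flag <- !is.na(bf) & bf > bf_threshold
  tab <- data.frame(time = times, statistic = ols$t, df = ols$df,
                    p = 2 * stats::pt(-abs(ols$t), df = ols$df),
                    p_adj = NA_real_, bf = bf, flag = flag)
  new_timecourse(tab, find_clusters(flag, times, ols$t),
                 method = "bayes_factor", alpha = NA_real_,
                 adjust = paste0("BF>", bf_threshold))
}

#' Mixed-model inference on component scores
#'
#' The recommended "few values" inference path: one linear mixed model per
#' component score, with the condition as fixed effect and a by-subject
#' random intercept. Estimates and standard errors come from the REML fit;
#' the p-value from a likelihood-ratio test of the fixed effect (maximum
#' likelihood refits). If a random slope is requested and the fit is
#' singular, the model is refitted without the slope and a message is
#' emitted.
#'
#' @param scores tidy score table from [scores_table()] or
#'   [rotated_scores()]: `subject`, `trial`, condition column(s), score
#'   columns (named `score_*`, `PC*` or `RC*`).
#' @param fixed condition column name.
#' @param random_slope also give the condition a by-subject random slope.
#' @param condition_as condition coding, as in [lmem_timecourse()].
#' @return data frame with one row per score column: `component`,
#'   `estimate`, `se`, `ci_lo`, `ci_hi` (Wald 95%), `chisq`, `df`, `p`.
#'   For a categorical condition the estimate row reports the first
#'   contrast; the LRT spans all levels.
#' @export
score_model <- function(scores, fixed, random_slope = FALSE,
                        condition_as = "auto") {
  stopifnot(is.data.frame(scores))
  if (!fixed %in% names(scores))
    stop("condition '", fixed, "' not found in the score table", call. = FALSE)
  comp_cols <- grep("^(score_|PC|RC)", names(scores), value = TRUE)
  if (!length(comp_cols)) stop("no score columns found", call. = FALSE)
  x <- code_condition(scores[[fixed]], condition_as)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  out <- lapply(comp_cols, function(cc) {
    d <- data.frame(y = scores[[cc]], x = x,
                    subject = factor(scores$subject))
    form1 <- if (random_slope) y ~ x + (1 + x | subject) else
      y ~ x + (1 | subject)
    m <- tryCatch(lme4::lmer(form1, data = d, REML = TRUE, control = ctrl),
                  error = function(e) NULL)
    if (random_slope &&
        (is.null(m) || lme4::isSingular(m, tol = 1e-5))) {
      message("singular random-slope fit for ", cc,
              "; refitting with intercept only")
      form1 <- y ~ x + (1 | subject)
      m <- lme4::lmer(form1, data = d, REML = TRUE, control = ctrl)
    }
    est <- lme4::fixef(m)[2L]
    se <- sqrt(diag(as.matrix(stats::vcov(m))))[2L]
    m1 <- lme4::lmer(form1, data = d, REML = FALSE, control = ctrl)
    form0 <- if (random_slope) y ~ 1 + (1 + x | subject) else
      y ~ 1 + (1 | subject)
    m0 <- lme4::lmer(form0, data = d, REML = FALSE, control = ctrl)
    lr <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                        as.numeric(stats::logLik(m0))))
    df_test <- length(lme4::fixef(m1)) - 1L
    data.frame(component = cc, estimate = unname(est), se = unname(se),
               ci_lo = unname(est - 1.96 * se),
               ci_hi = unname(est + 1.96 * se),
               chisq = lr, df = df_test,
               p = stats::pchisq(lr, df_test, lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
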