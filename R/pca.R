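#' Temporal principal components analysis of pupil traces
#'
#' Performs PCA on the trials-by-timepoints matrix, treating every timepoint
#' as a standalone variable and every trial as an observation. Because
#' neighbouring pupil samples are strongly autocorrelated, a handful of
#' components typically reconstructs almost all of the signal; each trial is
#' then summarised by its component scores, the coordinates of that trial on
#' the low-dimensional space of trace shapes.
#'
#' Columns are centered and, by default, not rescaled (covariance-based PCA),
#' preserving the amplitude information the scores summarise. Set
#' `scale = TRUE` for correlation-based PCA, the convention used by the
#' factor-analytic rotation stage. Variance proportions are always computed
#' against the total variance of all components, so statements like "three
#' components explain 94% of the data" remain well defined after truncation.
#' Component signs are arbitrary in PCA; a deterministic convention (largest
#' absolute loading made positive) is applied for reproducibility.
#'
#' @param tm a [to_trial_matrix()] result.
#' @param ncomp number of components to keep: an integer `>= 1`, or a
#'   fraction in (0, 1) requesting the smallest number of components whose
#'   cumulative variance share reaches at least that fraction. `NULL` keeps
#'   all components.
#' @param scale logical; standardize columns to unit variance first
#'   (correlation-based PCA).
#' @return a `pupil_pca` object: list with `center` (and `scale` if used),
#'   `eigenvalues` (all, descending), `loadings` (timepoints x k, unit-norm
#'   columns), `var_prop` (variance shares of all components), `ncomp`,
#'   `scores` (trials x k), `row_meta`, `col_times`.
#' @export
temporal_pca <- function(tm, ncomp = NULL, scale = FALSE) {
  check_trial_matrix(tm)
  X <- tm$values
  n <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds < 1e-12))
    stop("zero-variance timepoint column(s) at ",
         paste(utils::head(tm$col_times[sds < 1e-12], 3L), collapse = ", "),
         " ms; epoch the recording to post-onset samples before the PCA",
         call. = FALSE)
  scale_vec <- NULL
  if (scale) {
    scale_vec <- sds
    Xc <- sweep(Xc, 2L, scale_vec, "/")
  }

  sv <- svd(Xc)
  eigenvalues <- sv$d^2 / (n - 1)
  eigenvalues[eigenvalues < 0] <- 0
  total_var <- sum(eigenvalues)
  var_prop <- eigenvalues / total_var

  k <- if (is.null(ncomp)) length(eigenvalues) else select_ncomp(var_prop, ncomp)
  if (k > length(eigenvalues)) {
    warning("ncomp exceeds the rank of the data; clamped to ",
            length(eigenvalues), call. = FALSE)
    k <- length(eigenvalues)
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Xc %*% loadings
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))

  red <- structure(list(center = center, scale = scale_vec,
                        eigenvalues = eigenvalues, loadings = loadings,
                        var_prop = var_prop, ncomp = k, scores = scores,
                        row_meta = tm$row_meta, col_times = tm$col_times),
                   class = "pupil_pca")
  fix_signs(red)
}

#' @export
print.pupil_pca <- function(x, ...) {
  k <- x$ncomp
  cat("<pupil_pca> ", nrow(x$scores), " trials, ", length(x$center),
      " timepoints, ", k, " component(s) retained\n", sep = "")
  cat("  variance shares: ",
      paste(sprintf("%.1f%%", 100 * x$var_prop[seq_len(min(k, 5L))]),
            collapse = ", "),
      if (k > 5L) ", ..." else "",
      "  (cumulative ", sprintf("%.1f%%", 100 * sum(x$var_prop[seq_len(k)])),
      ")\n", sep = "")
  invisible(x)
}

#' Number of components from an explicit count or a variance threshold
#'
#' An integer request is returned as-is; a fractional request `0 < ncomp < 1`
#' returns the smallest number of components whose cumulative variance share
#' is at least `ncomp` (e.g. `0.95` selects the components needed to explain
#' at least 95% of the overall variability).
#'
#' @param var_prop variance proportions of all components, descending.
#' @param ncomp integer `>= 1` or fraction in (0, 1).
#' @return integer component count.
#' @export
select_ncomp <- function(var_prop, ncomp) {
  if (!is.numeric(ncomp) || length(ncomp) != 1L || is.na(ncomp) || ncomp <= 0)
    stop("ncomp must be a positive number", call. = FALSE)
  if (ncomp >= 1) {
    if (abs(ncomp - round(ncomp)) > 1e-8)
      stop("ncomp >= 1 must be an integer count", call. = FALSE)
    return(as.integer(round(ncomp)))
  }
  cum <- cumsum(var_prop)
  k <- which(cum >= ncomp - 1e-12)[1L]
  if (is.na(k)) k <- length(var_prop)
  as.integer(k)
}

#' Apply the deterministic sign convention
#'
#' PCA loadings are defined up to sign: negating an eigenvector (and its
#' scores) gives a mathematically equivalent solution. For reproducibility,
#' each loading column is flipped so its element of maximum absolute value is
#' positive; the matching score column is flipped with it, leaving all
#' reconstructions unchanged.
#'
#' @param red a `pupil_pca`.
#' @return the reduction with signs fixed.
#' @export
fix_signs <- function(red) {
  stopifnot(inherits(red, "pupil_pca"))
  for (j in seq_len(ncol(red$loadings))) {
    v <- red$loadings[, j]
    if (v[which.max(abs(v))] < 0) {
      red$loadings[, j] <- -v
      red$scores[, j] <- -red$scores[, j]
    }
  }
  red
}

# sign rule for a bare loading matrix; returns the +/-1 flips applied
sign_fix_matrix <- function(L) {
  flips <- vapply(seq_len(ncol(L)), function(j) {
    v <- L[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  list(L = sweep(L, 2L, flips, "*"), flips = flips)
}

#' Back-project component scores into trace space
#'
#' Maps score values on one component back to the implied pupil traces:
#' `center + score * loading`. A score of zero returns the grand-mean trace;
#' larger scores express the component's temporal shape more strongly.
#'
#' @param red a `pupil_pca`.
#' @param component component index (`<= ncomp`).
#' @param score_values numeric vector of score values.
#' @return matrix with one row per score value and one column per timepoint.
#' @export
back_project <- function(red, component, score_values) {
  stopifnot(inherits(red, "pupil_pca"))
  if (!(component %in% seq_len(red$ncomp)))
    stop("component index out of range (1..", red$ncomp, ")", call. = FALSE)
  u <- red$loadings[, component]
  if (!is.null(red$scale)) u <- u * red$scale
  out <- outer(score_values, u)
  out <- sweep(out, 2L, red$center, "+")
  colnames(out) <- names(red$center)
  out
}

#' Reconstruct trials from their retained scores
#'
#' @param red a `pupil_pca`.
#' @param scores trials x k score matrix (default: the fitted scores).
#' @return trials x timepoints matrix `center + scores %*% t(loadings)`, on
#'   the original data scale.
#' @export
reconstruct_trials <- function(red, scores = red$scores) {
  stopifnot(inherits(red, "pupil_pca"))
  X <- scores %*% t(red$loadings)
  if (!is.null(red$scale)) X <- sweep(X, 2L, red$scale, "*")
  sweep(X, 2L, red$center, "+")
}

#' Project new trials onto a fitted component space
#'
#' @param red a `pupil_pca`.
#' @param tm a [to_trial_matrix()] result on the same time grid.
#' @return trials x k score matrix for the new data.
#' @export
project_trials <- function(red, tm) {
  stopifnot(inherits(red, "pupil_pca"))
  check_trial_matrix(tm)
  if (length(tm$col_times) != length(red$col_times) ||
      any(abs(tm$col_times - red$col_times) > 1e-6))
    stop("new data are not on the fitting time grid", call. = FALSE)
  Xc <- sweep(tm$values, 2L, red$center)
  if (!is.null(red$scale)) Xc <- sweep(Xc, 2L, red$scale, "/")
  Xc %*% red$loadings
}

#' Tidy per-trial score table
#'
#' Returns one row per trial with the subject/trial identifiers, any
#' requested condition columns from the trial metadata, and one column per
#' retained component score -- the format consumed by [score_model()].
#'
#' @param red a `pupil_pca` or `pupil_rpca`.
#' @param add character vector of condition column names to append from the
#'   row metadata.
#' @return data frame `subject, trial, <conditions>, score_1..score_k`.
#' @export
scores_table <- function(red, add = character()) {
  if (!inherits(red, c("pupil_pca", "pupil_rpca")))
    stop("red must be a pupil_pca or pupil_rpca", call. = FALSE)
  meta <- red$row_meta
  unknown <- setdiff(add, names(meta))
  if (length(unknown))
    stop("unknown condition column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- meta[, c("subject", "trial", add), drop = FALSE]
  sc <- red$scores
  colnames(sc) <- paste0("score_", seq_len(ncol(sc)))
  cbind(out, as.data.frame(sc))
}
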