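#' Eigenvalue-scaled loadings
#'
#' Scales each retained eigenvector by the square root of its eigenvalue.
#' On correlation-based input the scaled loadings are the correlations
#' between the original variables (the timepoints) and the components, which
#' is the quantity factor-analytic rotations operate on.
#'
#' @param red a `pupil_pca`.
#' @return timepoints x k matrix of scaled loadings.
#' @export
scale_loadings <- function(red) {
  stopifnot(inherits(red, "pupil_pca"))
  k <- red$ncomp
  sweep(red$loadings, 2L, sqrt(red$eigenvalues[seq_len(k)]), "*")
}

# varimax criterion: sum over components of the variance of squared loadings
# (computed on Kaiser row-normalized loadings when requested)
varimax_criterion <- function(L, kaiser_normalize = TRUE) {
  if (kaiser_normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  sq <- L^2
  sum(apply(sq, 2L, function(col) mean(col^2) - mean(col)^2))
}

#' Varimax rotation
#'
#' Orthogonal rotation maximizing the varimax criterion (the summed variance
#' of squared loadings across components), which drives every variable
#' toward loading strongly on one component and weakly on the others. Rows
#' are Kaiser-normalized (divided by their communality root) by default and
#' de-normalized afterwards. The solver iterates planewise singular-value
#' steps until the criterion gain drops below `1e-10` or 1,000 sweeps.
#'
#' @param loadings timepoints x k matrix of (scaled) loadings, `k >= 2`
#'   (`k = 1` returns the input with an identity rotation).
#' @param kaiser_normalize logical, Kaiser row normalization (default TRUE).
#' @return list with `loadings` (rotated), `rotmat` (orthogonal k x k
#'   rotation, `loadings %*% rotmat`), and `criterion` (achieved value).
#' @export
rotate_varimax <- function(loadings, kaiser_normalize = TRUE) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 2L)
    return(list(loadings = L, rotmat = diag(1), criterion =
                  varimax_criterion(L, kaiser_normalize)))
  if (nrow(L) < k) stop("need at least as many rows as components",
                        call. = FALSE)
  h <- NULL
  x <- L
  if (kaiser_normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    x <- L / h
  }
  p <- nrow(x)
  R <- diag(k)
  d <- 0
  for (iter in seq_len(1000L)) {
    z <- x %*% R
    B <- crossprod(x, z^3 - z %*% diag(drop(rep(1, p) %*% z^2)) / p)
    sv <- svd(B)
    R <- sv$u %*% t(sv$v)
    d_old <- d
    d <- sum(sv$d)
    if (d - d_old < 1e-10 * max(d, 1)) break
  }
  z <- x %*% R
  if (!is.null(h)) z <- z * h
  list(loadings = z, rotmat = R,
       criterion = varimax_criterion(z, kaiser_normalize))
}

#' Promax rotation
#'
#' Oblique rotation toward simple structure: a varimax solution is first
#' obtained, an idealized target is built by raising its loadings to the
#' power `kappa` (preserving signs), and an oblique transformation is fitted
#' to that target by least squares with column normalization. The resulting
#' components are allowed to correlate; their correlations are returned in
#' `Phi`. The pattern matrix holds regression-style weights, the structure
#' matrix (`pattern %*% Phi`) the variable-component correlations.
#'
#' @param loadings timepoints x k matrix of scaled loadings, `k >= 2`.
#' @param kappa promax power, `>= 1` (default 4, the customary choice).
#' @param kaiser_normalize Kaiser row normalization for the varimax step.
#' @return list with `pattern`, `structure`, `Phi`, `rotmat` (the full
#'   oblique transformation, `pattern = loadings %*% rotmat`), and
#'   `rotation` (`"promax"`, or `"varimax"` after a singular-target
#'   fallback).
#' @export
rotate_promax <- function(loadings, kappa = 4, kaiser_normalize = TRUE) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 2L) stop("promax needs at least 2 components", call. = FALSE)
  if (!is.numeric(kappa) || kappa < 1) stop("kappa must be >= 1",
                                            call. = FALSE)
  vm <- rotate_varimax(L, kaiser_normalize = kaiser_normalize)
  z <- vm$loadings
  Q <- z * abs(z)^(kappa - 1)
  U <- tryCatch({
    U <- solve(crossprod(z), crossprod(z, Q))
    d <- diag(solve(crossprod(U)))
    U %*% diag(sqrt(d), nrow = k)
  }, error = function(e) NULL)
  if (is.null(U)) {
    warning("singular promax target system; falling back to varimax",
            call. = FALSE)
    return(list(pattern = vm$loadings, structure = vm$loadings,
                Phi = diag(k), rotmat = vm$rotmat, rotation = "varimax"))
  }
  pattern <- z %*% U
  rotmat <- vm$rotmat %*% U
  ui <- solve(rotmat)
  Phi <- ui %*% t(ui)
  Phi <- (Phi + t(Phi)) / 2
  diag(Phi) <- 1
  list(pattern = pattern, structure = pattern %*% Phi, Phi = Phi,
       rotmat = rotmat, rotation = "promax")
}

#' Rotated principal components of pupil traces
#'
#' The factor-analytic extension of [temporal_pca()]: eigenvectors are scaled
#' by the square roots of their eigenvalues, rotated (promax by default, so
#' components may correlate), ordered by descending rotated variance share,
#' sign-fixed, and per-trial scores are computed by the regression method
#' (correlation-matrix inverse times the structure matrix, applied to the
#' standardized trial matrix). The rotated pipeline standardizes columns
#' first (correlation-based PCA), the convention of the factor-analytic
#' tradition it borrows from.
#'
#' @param tm a [to_trial_matrix()] result.
#' @param ncomp number of components to rotate (integer, or fraction as in
#'   [select_ncomp()]); unlike plain PCA this choice changes the solution.
#' @param rotation `"promax"` (default), `"varimax"`, or `"none"`.
#' @param kappa promax power (default 4).
#' @param kaiser_normalize Kaiser row normalization (default TRUE).
#' @return a `pupil_rpca` object: `pattern`, `structure`, `Phi`,
#'   `rot_var_prop` (variance shares after rotation), `scores` (regression
#'   scores, one row per trial), `weights` (timepoints x k scoring weights),
#'   `rotation`, `kappa`, plus `center`, `scale`, `col_times`, `row_meta`
#'   and the underlying `pca`.
#' @export
rotated_pca <- function(tm, ncomp = 3, rotation = c("promax", "varimax", "none"),
                        kappa = 4, kaiser_normalize = TRUE) {
  rotation <- match.arg(rotation)
  red <- temporal_pca(tm, ncomp = ncomp, scale = TRUE)
  k <- red$ncomp
  A <- scale_loadings(red)

  if (rotation == "promax" && k >= 2L) {
    pm <- rotate_promax(A, kappa = kappa, kaiser_normalize = kaiser_normalize)
    pattern <- pm$pattern
    Phi <- pm$Phi
    rotation <- pm$rotation
  } else if (rotation == "varimax" && k >= 2L) {
    vm <- rotate_varimax(A, kaiser_normalize = kaiser_normalize)
    pattern <- vm$loadings
    Phi <- diag(k)
  } else {
    pattern <- A
    Phi <- diag(k)
    if (k < 2L) rotation <- "none"
  }
  structure_m <- pattern %*% Phi

  # variance accounted for by each rotated component (correlation metric:
  # total variance = number of timepoints)
  ss <- colSums(pattern * structure_m)
  ord <- order(ss, decreasing = TRUE)
  pattern <- pattern[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  ss <- ss[ord]

  sf <- sign_fix_matrix(pattern)
  pattern <- sf$L
  Phi <- diag(sf$flips, nrow = k) %*% Phi %*% diag(sf$flips, nrow = k)
  structure_m <- pattern %*% Phi
  rot_var_prop <- ss / length(red$center)

  # regression-method scores: weights = R^{-1} %*% structure on standardized
  # columns; ridge-stabilized if the correlation matrix is near singular
  Z <- sweep(sweep(tm$values, 2L, red$center), 2L, red$scale, "/")
  Rm <- stats::cor(tm$values)
  weights <- tryCatch(solve(Rm, structure_m), error = function(e) NULL)
  if (is.null(weights)) {
    message("near-singular timepoint correlation matrix; ",
            "using a ridge-stabilized inverse (1e-8 on the diagonal)")
    weights <- solve(Rm + diag(1e-8, nrow(Rm)), structure_m)
  }
  scores <- Z %*% weights
  dimnames(pattern) <- dimnames(structure_m) <-
    list(names(red$center), paste0("RC", seq_len(k)))
  dimnames(weights) <- dimnames(pattern)
  colnames(scores) <- paste0("RC", seq_len(k))
  dimnames(Phi) <- list(colnames(pattern), colnames(pattern))

  structure(list(pattern = pattern, structure = structure_m, Phi = Phi,
                 rot_var_prop = rot_var_prop, scores = scores,
                 weights = weights, rotation = rotation, kappa = kappa,
                 center = red$center, scale = red$scale,
                 col_times = red$col_times, row_meta = red$row_meta,
                 pca = red),
            class = "pupil_rpca")
}

#' @export
print.pupil_rpca <- function(x, ...) {
  cat("<pupil_rpca> ", nrow(x$scores), " trials, ", ncol(x$pattern),
      " rotated component(s) [", x$rotation, "]\n", sep = "")
  cat("  rotated variance shares: ",
      paste(sprintf("%.1f%%", 100 * x$rot_var_prop), collapse = ", "), "\n",
      sep = "")
  if (ncol(x$Phi) > 1L)
    cat("  max |inter-component correlation|: ",
        sprintf("%.2f", max(abs(x$Phi[upper.tri(x$Phi)]))), "\n", sep = "")
  invisible(x)
}

#' Rotated component scores for (new) trials
#'
#' Applies the fitted regression-method scoring weights to a trial matrix on
#' the same time grid: columns are standardized with the fitting center and
#' scale, then multiplied by the weights.
#'
#' @param tm a [to_trial_matrix()] result on the fitting grid.
#' @param rr a `pupil_rpca`.
#' @return tidy data frame: `subject`, `trial`, conditions, one column per
#'   rotated component score.
#' @export
rotated_scores <- function(tm, rr) {
  stopifnot(inherits(rr, "pupil_rpca"))
  check_trial_matrix(tm)
  if (length(tm$col_times) != length(rr$col_times) ||
      any(abs(tm$col_times - rr$col_times) > 1e-6))
    stop("new data are not on the fitting time grid", call. = FALSE)
  Z <- sweep(sweep(tm$values, 2L, rr$center), 2L, rr$scale, "/")
  sc <- Z %*% rr$weights
  colnames(sc) <- colnames(rr$scores)
  cbind(tm$row_meta, as.data.frame(sc))
}

#' Tucker congruence between two loading matrices
#'
#' The congruence coefficient between loading columns a and b is their cosine
#' similarity, \eqn{\phi = \sum a_i b_i / \sqrt{\sum a_i^2 \sum b_i^2}};
#' values near +/-1 indicate the same temporal shape (conventionally
#' `|phi| >= 0.95` is read as factor equivalence). Columns are compared
#' pairwise; a companion matching pairs each column of `A` with a distinct
#' column of `B` greedily by largest `|phi|` (ties broken by column order).
#'
#' @param A,B loading matrices with the same row count (time grid).
#' @return a `congruence` object: the k_A x k_B matrix of signed
#'   coefficients, with the greedy matching as attribute `"matching"` (data
#'   frame `a`, `b`, `phi`). Zero columns give `NA` entries.
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("loading matrices must share the time grid",
                               call. = FALSE)
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  phi <- crossprod(A, B) / outer(na, nb)
  phi[, nb == 0] <- NA_real_
  phi[na == 0, ] <- NA_real_

  m <- abs(phi)
  m[is.na(m)] <- -Inf
  pairs <- list()
  avail_a <- seq_len(nrow(phi)); avail_b <- seq_len(ncol(phi))
  while (length(avail_a) && length(avail_b)) {
    sub <- m[avail_a, avail_b, drop = FALSE]
    if (all(!is.finite(sub))) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    a <- avail_a[ij[1L]]; b <- avail_b[ij[2L]]
    pairs[[length(pairs) + 1L]] <- data.frame(a = a, b = b, phi = phi[a, b])
    avail_a <- setdiff(avail_a, a); avail_b <- setdiff(avail_b, b)
  }
  matching <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = integer(), b = integer(), phi = numeric())
  matching <- matching[order(matching$a), , drop = FALSE]
  rownames(matching) <- NULL
  structure(phi, matching = matching, class = c("congruence", "matrix"))
}
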