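test_that("scaled loadings are eigenvectors times root eigenvalues", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm)
  A <- scale_loadings(red)
  expect_equal(sqrt(colSums(A^2)), sqrt(red$eigenvalues), tolerance = 1e-10,
               ignore_attr = TRUE)

  # degenerate eigenvalue gives a zero column
  red0 <- red
  red0$eigenvalues[4] <- 0
  expect_equal(scale_loadings(red0)[, 4], rep(0, 4), ignore_attr = TRUE)

  # correlation-based input: scaled loadings are timepoint-component
  # correlations (oracle: correlate raw columns with scores directly)
  redc <- temporal_pca(tm, scale = TRUE)
  Ac <- scale_loadings(redc)
  oracle <- cor(tm$values, redc$scores)
  expect_equal(Ac, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(Ac) <= 1 + 1e-8))
})

test_that("varimax agrees with a brute-force rotation-angle search", {
  set.seed(4)
  L <- matrix(rnorm(16), 8, 2) + cbind(c(rep(2, 4), rep(0, 4)),
                                       c(rep(0, 4), rep(2, 4)))
  vm <- rotate_varimax(L, kaiser_normalize = FALSE)
  # grid search over the planar rotation angle, 1e-4 rad steps
  angles <- seq(0, pi / 2, by = 1e-4)
  crit <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    varimax_best <- L %*% R
    sq <- varimax_best^2
    sum(apply(sq, 2, function(col) mean(col^2) - mean(col)^2))
  }, numeric(1))
  best <- angles[which.max(crit)]
  got <- acos(pmin(1, abs(vm$rotmat[1, 1])))
  # compare angles modulo the column-swap (pi/2 shift) and reflection
  # (pi/2 - theta) symmetries of the two-column varimax solution
  cand <- c(best, pi / 2 - best)
  d <- min(abs(outer(got, c(cand, cand + pi / 2, cand - pi / 2), "-")))
  expect_lt(d, 1e-3)
  expect_gte(vm$criterion + 1e-12, max(crit))
})

test_that("varimax is orthogonal, communality-preserving, and matches stats::varimax", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm, ncomp = 3, scale = TRUE)
  A <- scale_loadings(red)
  vm <- rotate_varimax(A)
  expect_equal(crossprod(vm$rotmat), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rowSums(vm$loadings^2), rowSums(A^2), tolerance = 1e-8)

  ref <- stats::varimax(A, normalize = TRUE, eps = 1e-10)
  # align columns by best |congruence| match, then compare
  mt <- attr(tucker_congruence(vm$loadings, unclass(ref$loadings)),
             "matching")
  expect_equal(sort(mt$b), 1:3)
  for (i in seq_len(3)) {
    a <- vm$loadings[, mt$a[i]]
    b <- unclass(ref$loadings)[, mt$b[i]] * sign(mt$phi[i])
    expect_equal(a, b, tolerance = 1e-5, ignore_attr = TRUE)
  }

  # k = 1 passes through with an identity rotation
  one <- rotate_varimax(A[, 1, drop = FALSE])
  expect_identical(one$loadings, A[, 1, drop = FALSE])

  # perfect simple structure is a fixed point (up to permutation/sign)
  S <- rbind(diag(2) * 2, diag(2) * 2)
  vs <- rotate_varimax(S, kaiser_normalize = FALSE)
  expect_equal(abs(vs$rotmat), diag(2), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("promax matches the classical algorithm and relaxes orthogonality", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm, ncomp = 3, scale = TRUE)
  A <- scale_loadings(red)
  pm <- rotate_promax(A, kappa = 4)

  expect_equal(pm$structure, pm$pattern %*% pm$Phi, tolerance = 1e-10)
  expect_equal(pm$Phi, t(pm$Phi), tolerance = 1e-12)
  expect_equal(diag(pm$Phi), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(eigen(pm$Phi, symmetric = TRUE)$values > -1e-8))
  expect_equal(pm$pattern, A %*% pm$rotmat, tolerance = 1e-10)

  # oracle: stats::promax on the same input (it varimax-rotates with Kaiser
  # normalization internally, at a looser convergence tolerance, hence the
  # comparison tolerance), compared up to column permutation/sign
  ref <- stats::promax(A, m = 4)
  mt <- attr(tucker_congruence(pm$pattern, unclass(ref$loadings)), "matching")
  expect_equal(sort(mt$b), 1:3)
  for (i in seq_len(3)) {
    expect_lt(max(abs(pm$pattern[, mt$a[i]] -
                        unclass(ref$loadings)[, mt$b[i]] * sign(mt$phi[i]))),
              2e-3)
  }
  refPhi <- solve(crossprod(ref$rotmat))
  for (i in seq_len(3)) for (j in seq_len(3)) {
    expect_equal(pm$Phi[mt$a[i], mt$a[j]],
                 sign(mt$phi[i]) * sign(mt$phi[j]) * refPhi[mt$b[i], mt$b[j]],
                 tolerance = 1e-3, ignore_attr = TRUE)
  }

  # an already-orthogonal simple structure stays essentially orthogonal
  S <- rbind(diag(3) * 2, diag(3) * 2)[, 1:3] + 0.01
  ps <- rotate_promax(rbind(S, S), kappa = 4, kaiser_normalize = FALSE)
  expect_lt(max(abs(ps$Phi[upper.tri(ps$Phi)])), 0.05)

  expect_error(rotate_promax(A, kappa = 0.5), "kappa")
  expect_error(rotate_promax(A[, 1, drop = FALSE]), "2 components")
})

test_that("rotation redistributes variance but orthogonal rotations preserve it", {
  spec <- tiny_spec(seed = 21)
  sim <- simulate_pupil_data(spec)
  tm <- to_trial_matrix(sim$recording)
  red <- temporal_pca(tm, ncomp = 3, scale = TRUE)
  A <- scale_loadings(red)
  vm <- rotate_varimax(A)

  # total explained variance preserved under varimax (correlation metric)
  expect_equal(sum(vm$loadings^2), sum(A^2), tolerance = 1e-8)

  # rotated shares are more evenly distributed than unrotated ones
  rr <- rotated_pca(tm, ncomp = 3, rotation = "varimax")
  expect_lt(var(rr$rot_var_prop), var(red$var_prop[1:3]))

  # promax does not preserve communalities; assert the change is real
  pm <- rotate_promax(A)
  expect_gt(max(abs(rowSums(pm$pattern^2) - rowSums(A^2))), 1e-6)

  # non-nesting: adding a component changes the first rotated component
  rr2 <- rotated_pca(tm, ncomp = 2, rotation = "promax")
  rr3 <- rotated_pca(tm, ncomp = 3, rotation = "promax")
  cg <- tucker_congruence(rr2$pattern, rr3$pattern)
  best <- max(abs(cg[1, ]), na.rm = TRUE)
  expect_lt(best, 1 - 1e-6)
})

test_that("regression scores behave in the orthogonal and noiseless cases", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm, ncomp = 3, scale = TRUE)
  A <- scale_loadings(red)
  vm <- rotate_varimax(A)
  rr <- rotated_pca(tm, ncomp = 3, rotation = "varimax")

  # orthogonal case: rotated regression scores = standardized PC scores
  # times the rotation matrix (columns may be reordered/sign-fixed, so
  # compare the spanned score spaces column by column after matching)
  std_scores <- sweep(red$scores, 2, sqrt(red$eigenvalues[1:3]), "/")
  expected <- std_scores %*% vm$rotmat
  mt <- attr(tucker_congruence(expected, rr$scores), "matching")
  expect_equal(sort(mt$b), 1:3)
  for (i in seq_len(3))
    expect_equal(rr$scores[, mt$b[i]] * sign(mt$phi[i]), expected[, mt$a[i]],
                 tolerance = 1e-8, ignore_attr = TRUE)

  # noiseless rank-3 data: the regression-scoring step, given the
  # generating structure (timepoint-component correlations), reproduces the
  # true trial scores (the onset sample is dropped: with zero noise it has
  # zero variance; the ridge-stabilized inverse handles the exactly
  # rank-deficient correlation matrix)
  spec <- tiny_spec(trial_sd = c(0.5, 0.5, 0.5), ar_sd = 0, seed = 8)
  sim <- simulate_pupil_data(spec)
  rec <- suppressWarnings(epoch_trials(sim$recording, 10, 400))
  tm3 <- to_trial_matrix(rec)
  truth <- sim$true_scores
  key <- paste(tm3$row_meta$subject, tm3$row_meta$trial)
  truth <- truth[match(key, paste(truth$subject, truth$trial)), ]
  S_true <- as.matrix(truth[, c("s1", "s2", "s3")])
  Z <- scale(tm3$values)
  Rm <- cor(tm3$values)
  W <- solve(Rm + diag(1e-8, nrow(Rm)), cor(tm3$values, S_true))
  fitted_sc <- Z %*% W
  for (k in 1:3)
    expect_gte(abs(cor(fitted_sc[, k], S_true[, k])), 0.999)
})

test_that("congruence coefficients and matching follow the cosine definition", {
  A <- cbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(diag(unclass(tucker_congruence(A, A))), c(1, 1))
  expect_equal(unclass(tucker_congruence(A[, 1, drop = FALSE],
                                         -A[, 1, drop = FALSE]))[1, 1], -1)
  expect_equal(unclass(tucker_congruence(A[, 1, drop = FALSE],
                                         A[, 2, drop = FALSE]))[1, 1], 0)

  z <- cbind(c(0, 0, 0))
  expect_true(is.na(unclass(tucker_congruence(A[, 1, drop = FALSE], z))[1, 1]))

  # matching recovers a column permutation
  set.seed(3)
  B <- matrix(rnorm(12), 4, 3)
  perm <- c(3, 1, 2)
  cg <- tucker_congruence(B, B[, perm])
  mt <- attr(cg, "matching")
  expect_equal(mt$b[order(mt$a)], order(perm))
  expect_error(tucker_congruence(B, B[1:3, ]), "time grid")
})
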