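test_that("eigen-decomposition matches the brute-force covariance oracle", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm)

  # oracle: eigen-decompose the sample covariance matrix directly
  ev <- eigen(cov(tm$values), symmetric = TRUE)
  expect_equal(red$eigenvalues, pmax(ev$values, 0), tolerance = 1e-10)
  expect_equal(sum(red$eigenvalues), sum(apply(tm$values, 2, var)),
               tolerance = 1e-8)

  # loadings span the same directions (compare up to sign)
  for (j in 1:4)
    expect_equal(abs(sum(red$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)

  # scores are the centered data projected on the loadings
  Xc <- sweep(tm$values, 2, colMeans(tm$values))
  expect_equal(red$scores, Xc %*% red$loadings, tolerance = 1e-8,
               ignore_attr = TRUE)

  # loading columns are orthonormal, score columns uncorrelated
  G <- crossprod(red$loadings)
  expect_equal(G, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  cs <- cor(red$scores)
  expect_lt(max(abs(cs[upper.tri(cs)])), 1e-8)
})

test_that("full-rank reconstruction and monotone held-out error", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm)
  expect_equal(reconstruct_trials(red), tm$values, tolerance = 1e-8,
               ignore_attr = TRUE)

  # held-out rows: reconstruction error never increases with k
  set.seed(2)
  new <- fixture_matrix(seed = 99)
  errs <- sapply(1:4, function(k) {
    sc <- project_trials(red, new)[, 1:k, drop = FALSE]
    Xh <- sweep(sc %*% t(red$loadings[, 1:k, drop = FALSE]), 2,
                red$center, "+")
    sum((Xh - new$values)^2)
  })
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("rank-1 input loads on a single component", {
  u <- c(0.5, -0.5, 0.5, 0.5)
  s <- c(-2, -1, 0, 1, 2, 4)
  X <- outer(s, u) + matrix(1, 6, 4)
  tm <- fixture_matrix()
  tm$values <- X
  # rank-1 data have zero-variance risk only if s is constant; here fine
  red <- temporal_pca(tm)
  expect_equal(red$var_prop[1], 1, tolerance = 1e-8)
})

test_that("component count selection honours count and threshold semantics", {
  vp <- c(0.6, 0.3, 0.08, 0.02)
  expect_identical(select_ncomp(vp, 0.95), 3L)
  expect_identical(select_ncomp(vp, 3), 3L)
  expect_identical(select_ncomp(vp, 0.9), 2L)     # "at least": cum 0.9 at k=2
  expect_identical(select_ncomp(vp, 0.91), 3L)
  expect_identical(select_ncomp(vp, 0.999), 4L)
  expect_error(select_ncomp(vp, 0), "positive")
  expect_error(select_ncomp(vp, -1), "positive")

  tm <- fixture_matrix()
  expect_warning(red <- temporal_pca(tm, ncomp = 10), "clamped")
  expect_equal(red$ncomp, 4L)
})

test_that("sign convention flips loading and score columns together", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm)
  # force a violation, then fix
  red2 <- red
  red2$loadings[, 2] <- -red2$loadings[, 2]
  red2$scores[, 2] <- -red2$scores[, 2]
  fixed <- fix_signs(red2)
  j <- which.max(abs(fixed$loadings[, 2]))
  expect_gt(fixed$loadings[j, 2], 0)
  expect_equal(fixed$loadings[, 2], red$loadings[, 2])
  expect_equal(fixed$scores[, 2], red$scores[, 2])
  # a compliant reduction is a fixed point
  expect_identical(fix_signs(red), red)
  # reconstruction is invariant to the flip
  expect_equal(reconstruct_trials(red2), reconstruct_trials(fixed),
               tolerance = 1e-12)
})

test_that("back-projection maps scores to traces by definition", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm)
  expect_equal(back_project(red, 1, 0)[1, ], red$center, tolerance = 1e-12)
  s <- 2.5
  expect_equal(back_project(red, 2, s)[1, ],
               red$center + s * red$loadings[, 2], tolerance = 1e-12)
  # a trial's own full-rank scores reproduce the trial
  expect_equal(drop(red$center + red$loadings %*% red$scores[3, ]),
               tm$values[3, ], tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(back_project(red, 9, 0), "out of range")
})

test_that("score tables carry metadata and requested conditions", {
  tm <- fixture_matrix()
  red <- temporal_pca(tm, ncomp = 3)
  st <- scores_table(red, add = "lum")
  expect_equal(dim(st), c(6L, 2L + 1L + 3L))
  expect_named(st, c("subject", "trial", "lum", "score_1", "score_2",
                     "score_3"))
  Xc <- sweep(tm$values, 2, colMeans(tm$values))
  expect_equal(as.matrix(st[, 4:6]), Xc %*% red$loadings, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(scores_table(red, add = "nope"), "unknown condition")
})

test_that("zero-variance columns point the user to post-onset epoching", {
  tm <- fixture_matrix()
  tm$values[, 1] <- 7
  expect_error(temporal_pca(tm), "post-onset")
})
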