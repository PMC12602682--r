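test_that("Benjamini-Hochberg adjustment reproduces its closed forms", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(1)
  p <- runif(40)^2
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  # monotone in the order statistics
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  expect_equal(fdr_adjust(c(0.01, NA)), c(0.01, NA))
})

test_that("clusters are maximal runs on the time grid, end inclusive", {
  times <- seq(0, 4490, 10)
  expect_equal(nrow(find_clusters(rep(FALSE, 450), times)), 0L)

  fl <- times >= 440 & times <= 4490
  cl <- find_clusters(fl, times)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 440)
  expect_equal(cl$end, 4490)
  expect_equal(cl$n, sum(fl))

  fl2 <- (times >= 100 & times < 200) | (times >= 1000 & times < 1500)
  st <- rep(2, length(times))
  cl2 <- find_clusters(fl2, times, st)
  expect_equal(cl2$start, c(100, 1000))
  expect_equal(cl2$end, c(190, 1490))
  expect_equal(cl2$mass, c(10 * 2, 50 * 2))

  # NA flags count as unflagged
  fl3 <- c(TRUE, NA, TRUE)
  cl3 <- find_clusters(fl3, c(0, 10, 20))
  expect_equal(nrow(cl3), 2L)
})

test_that("mixed-model time course flags an injected effect window", {
  # effect confined to late timepoints; early ones are null
  set.seed(31)
  n_sub <- 8; n_tr <- 12; times <- seq(0, 190, 10)
  rows <- list(); k <- 0
  for (s in seq_len(n_sub)) {
    u <- rnorm(1, sd = 0.3)
    lev <- rep_len(1:4, n_tr)
    for (tr in seq_len(n_tr)) {
      k <- k + 1
      eff <- ifelse(times >= 100, 0.45 * (lev[tr] - 2.5), 0)
      rows[[k]] <- data.frame(subject = paste0("s", s),
                              trial = paste0("t", tr), time = times,
                              pupil = u + eff + rnorm(length(times), sd = 0.5),
                              level = as.character(lev[tr]))
    }
  }
  rec <- pupil_recording(do.call(rbind, rows), conditions = "level")
  tc <- lmem_timecourse(rec, fixed = "level")
  expect_s3_class(tc, "pupil_timecourse")
  expect_equal(tc$table$time, times)
  expect_true(all(tc$table$p_adj >= tc$table$p - 1e-12, na.rm = TRUE))
  # the flagged cluster overlaps the injected 100-190 ms window
  expect_gt(nrow(tc$clusters), 0)
  expect_true(any(tc$clusters$end >= 100 & tc$clusters$start <= 190))
  # early null timepoints are mostly unflagged
  expect_lt(mean(tc$table$flag[times < 100]), 0.3)

  # Bayes-factor route agrees qualitatively: strong evidence only where the
  # unadjusted mixed-model p is small
  bf <- bf_timecourse(rec, fixed = "level")
  strong <- which(bf$table$bf > 3)
  expect_gt(length(strong), 0)
  expect_true(all(tc$table$p[strong] < 0.05))
})

test_that("cluster permutation is reproducible and respects the add-one rule", {
  set.seed(32)
  n_sub <- 6; n_tr <- 12; times <- seq(0, 150, 10)
  rows <- list(); k <- 0
  for (s in seq_len(n_sub)) {
    lev <- rep_len(1:2, n_tr)
    for (tr in seq_len(n_tr)) {
      k <- k + 1
      eff <- ifelse(times >= 50 & times < 120, 1.2 * (lev[tr] - 1.5), 0)
      rows[[k]] <- data.frame(subject = paste0("s", s),
                              trial = paste0("t", tr), time = times,
                              pupil = eff + rnorm(length(times), sd = 0.4),
                              level = as.character(lev[tr]))
    }
  }
  rec <- pupil_recording(do.call(rbind, rows), conditions = "level")
  tc <- cluster_permutation(rec, "level", n_perm = 999, seed = 5)
  expect_gt(nrow(tc$clusters), 0)
  # an overwhelming effect attains the minimum achievable p of 1/1000
  expect_equal(min(tc$clusters$p_cluster), 1 / 1000)
  expect_true(any(tc$table$flag))

  tc2 <- cluster_permutation(rec, "level", n_perm = 999, seed = 5)
  expect_identical(tc$clusters, tc2$clusters)
  expect_identical(tc$table, tc2$table)

  expect_warning(cluster_permutation(rec, "level", n_perm = 50, seed = 1),
                 "n_perm")
  flat <- rec
  flat$level <- "1"
  flat <- pupil_recording(as.data.frame(flat), conditions = "level")
  expect_error(cluster_permutation(flat, "level", n_perm = 100, seed = 1),
               "vary within|2 condition")
})

test_that("score-level mixed models recover a known slope", {
  set.seed(33)
  n_sub <- 12; n_tr <- 16
  beta <- 0.3
  tab <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    u <- rnorm(1, sd = 0.4)
    lev <- rep_len(1:4, n_tr)
    data.frame(subject = paste0("s", s), trial = paste0("t", seq_len(n_tr)),
               cond = as.character(lev),
               score_1 = u + beta * lev + rnorm(n_tr, sd = 0.5),
               score_2 = u + rnorm(n_tr, sd = 0.5))
  }))
  res <- score_model(tab, fixed = "cond")
  expect_equal(nrow(res), 2L)
  r1 <- res[res$component == "score_1", ]
  expect_lt(abs(r1$estimate - beta), 2.5 * r1$se)
  expect_lt(r1$p, 0.001)
  r2 <- res[res$component == "score_2", ]
  expect_gt(r2$p, 0.001)  # null component should not show strong evidence
  expect_error(score_model(tab, fixed = "nope"), "not found")

  # random-slope request still returns a full summary (falling back to the
  # intercept-only model if the slope fit is singular)
  res2 <- suppressMessages(score_model(tab, fixed = "cond",
                                       random_slope = TRUE))
  expect_equal(nrow(res2), 2L)
  expect_true(all(is.finite(res2$p)))
})
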