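# shared fixtures, all built in code

# long-format recording: subjects x trials on a common grid, values supplied
# or drawn reproducibly
make_recording <- function(n_subjects = 2, n_trials = 3, times = seq(0, 30, 10),
                           values = NULL, conditions = NULL, seed = 1) {
  set.seed(seed)
  rows <- list()
  k <- 0
  for (s in seq_len(n_subjects)) {
    for (tr in seq_len(n_trials)) {
      k <- k + 1
      y <- if (is.null(values)) rnorm(length(times)) else values[[k]]
      d <- data.frame(subject = paste0("s", s), trial = paste0("t", tr),
                      time = times, pupil = y)
      if (!is.null(conditions))
        for (cn in names(conditions)) d[[cn]] <- conditions[[cn]][k]
      rows[[k]] <- d
    }
  }
  pupil_recording(do.call(rbind, rows),
                  conditions = if (is.null(conditions)) character() else
                    names(conditions))
}

# deterministic 6 trials x 4 timepoints matrix used by the reduction oracles
fixture_matrix <- function(seed = 11) {
  set.seed(seed)
  X <- matrix(rnorm(24), nrow = 6, ncol = 4)
  X <- X + outer(rnorm(6, sd = 2), c(1, 2, 1.5, 0.5))  # shared structure
  structure(list(values = X,
                 row_meta = data.frame(subject = rep(c("s1", "s2"), each = 3),
                                       trial = rep(paste0("t", 1:3), 2),
                                       lum = as.character(rep(1:3, 2))),
                 col_times = c(0, 10, 20, 30), dropped = 0L),
            class = "trial_matrix")
}

# small simulation spec for fast end-to-end tests (40 samples per trial)
tiny_spec <- function(...) {
  base <- list(n_subjects = 6, trials_per_subject = 16,
               sampling_rate = 100, epoch = c(0, 400),
               t_max = c(100, 200, 300), n_levels = 4, missing_rate = 0)
  do.call(simulation_spec, utils::modifyList(base, list(...)))
}

# trial-level null data (no condition effect) with by-subject heterogeneity;
# traces are pure noise on a short grid -- used by the calibration checks
null_recording <- function(n_subjects = 10, n_trials = 16, n_times = 2,
                           seed = 1) {
  set.seed(seed)
  times <- seq(0, by = 10, length.out = n_times)
  rows <- list()
  k <- 0
  for (s in seq_len(n_subjects)) {
    u <- rnorm(1, sd = 0.5)
    lev <- rep_len(1:4, n_trials)
    for (tr in seq_len(n_trials)) {
      k <- k + 1
      rows[[k]] <- data.frame(subject = sprintf("s%02d", s),
                              trial = sprintf("t%02d", tr), time = times,
                              pupil = u + rnorm(n_times),
                              level = as.character(lev[tr]))
    }
  }
  pupil_recording(do.call(rbind, rows), conditions = "level")
}

# brute-force two-group JZS Bayes factor by dense 3-D grid quadrature over
# (mu, delta, log sigma); independent of the t-statistic shortcut
bf_quadrature_oracle <- function(y1, y2, r = sqrt(2) / 2,
                                 n_grid = 161) {
  y <- c(y1, y2)
  x <- c(rep(1, length(y1)), rep(0, length(y2)))  # delta*sigma = group diff
  s <- sd(y); m <- mean(y)
  mu_g <- seq(m - 6 * s, m + 6 * s, length.out = n_grid)
  de_g <- seq(-12, 12, length.out = 2 * n_grid)
  ls_g <- seq(log(s) - 4, log(s) + 3, length.out = n_grid)
  loglik <- function(mu, delta, lsig) {
    sig <- exp(lsig)
    resid <- outer(y, mu, "-") - sig * delta * x   # n x length(mu)
    -length(y) * lsig - colSums(resid^2) / (2 * sig^2)
  }
  # numerator: Cauchy prior on delta; denominator: delta = 0; Jeffreys sigma
  num <- den <- 0
  dmu <- diff(mu_g[1:2]); dde <- diff(de_g[1:2]); dls <- diff(ls_g[1:2])
  for (lsig in ls_g) {
    for (delta in de_g) {
      ll <- loglik(mu_g, delta, lsig)
      num <- num + sum(exp(ll)) * dcauchy(delta, 0, r) * dmu * dde * dls
    }
    den <- den + sum(exp(loglik(mu_g, 0, lsig))) * dmu * dls
  }
  num / den
}
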