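#' Specification of a synthetic phasic pupil experiment
#'
#' Describes the generative model for synthetic trace datasets: the
#' statistical twin of a passive luminance experiment (by default 20
#' subjects, 64 trials each, 8 luminance levels, 4,500-ms epochs sampled at
#' 100 Hz, i.e. 450 post-target samples per trial). Each trial's trace is a
#' weighted sum of three latent basis curves plus AR(1) noise; the weights
#' (the trial's true component scores) carry the condition effect, a
#' by-subject random intercept and trial-level noise.
#'
#' The three basis components are gamma-family pupil-response kernels,
#' \deqn{b_k(t) = \mathrm{pol}_k (t/t_{max,k})^{n} e^{n (1 - t/t_{max,k})},}
#' normalized to unit magnitude at their peak, with strictly increasing peak
#' latencies mirroring the physiological ordering: parasympathetic
#' activation (early constriction, negative polarity), parasympathetic
#' inhibition, sympathetic activation (late dilations, positive polarity).
#' The default latencies (900, 1,800, 3,200 ms) place the early
#' constriction's peak inside the 1-1.5 s window where the pupillary light
#' reflex is expected to peak once summed with the grand-mean trace. The
#' kernels overlap in time, so the generating basis is deliberately
#' non-orthogonal -- the regime where oblique rotation has an edge over
#' plain PCA.
#'
#' @param n_subjects number of subjects (default 20).
#' @param trials_per_subject trials per subject (default 64).
#' @param sampling_rate sampling rate in Hz (default 100).
#' @param epoch epoch bounds `(start, end)` in ms, half-open (default
#'   `c(0, 4500)`).
#' @param t_max peak latencies of the three basis curves in ms, strictly
#'   increasing (default `c(900, 1800, 3200)`).
#' @param shape gamma-kernel shape n (default 10.1).
#' @param polarity signs of the three curves (default `c(-1, 1, 1)`: the
#'   early parasympathetic component constricts).
#' @param n_levels number of condition (luminance) levels, balanced across
#'   each subject's trials (default 8).
#' @param beta0 per-component score intercepts (default `c(1.2, 0.6, 0.5)`).
#' @param beta1 per-component condition effects, in score units per level
#'   step (default `c(0.12, 0.04, 0.04)`: luminance mostly drives the
#'   constriction component).
#' @param subject_sd per-component by-subject random-intercept sd (default
#'   0.3 each).
#' @param trial_sd per-component trial-level score sd (default 0.4 each).
#' @param ar_phi AR(1) coefficient of the additive sample noise (default
#'   0.95; pupil noise is strongly autocorrelated).
#' @param ar_sd innovation sd of the AR(1) noise (default 0.03, a
#'   stationary sd just under 0.1 z-units: baseline-corrected, z-scored
#'   pupil traces are smooth enough that a few components reconstruct
#'   almost all of their variance, and the noise floor is set to match that
#'   regime).
#' @param missing_rate per-trial probability of one artifact gap (a
#'   contiguous missing run with duration uniform in 50-400 ms; default
#'   0.05).
#' @param seed integer seed; the stream is partitioned by (subject, trial)
#'   so earlier trials are unchanged when the trial count grows.
#' @return a validated `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 20, trials_per_subject = 64,
                            sampling_rate = 100, epoch = c(0, 4500),
                            t_max = c(900, 1800, 3200), shape = 10.1,
                            polarity = c(-1, 1, 1), n_levels = 8,
                            beta0 = c(1.2, 0.6, 0.5),
                            beta1 = c(0.12, 0.04, 0.04),
                            subject_sd = c(0.3, 0.3, 0.3),
                            trial_sd = c(0.4, 0.4, 0.4),
                            ar_phi = 0.95, ar_sd = 0.03,
                            missing_rate = 0.05, seed = 1) {
  spec <- list(n_subjects = as.integer(n_subjects),
               trials_per_subject = as.integer(trials_per_subject),
               sampling_rate = sampling_rate, epoch = epoch, t_max = t_max,
               shape = shape, polarity = polarity,
               n_levels = as.integer(n_levels),
               beta0 = beta0, beta1 = beta1,
               subject_sd = rep_len(subject_sd, 3L),
               trial_sd = rep_len(trial_sd, 3L),
               ar_phi = ar_phi, ar_sd = ar_sd,
               missing_rate = missing_rate, seed = as.integer(seed))
  if (spec$n_subjects < 1L || spec$trials_per_subject < 1L)
    stop("need at least one subject and one trial", call. = FALSE)
  if (length(spec$t_max) != 3L || any(diff(spec$t_max) <= 0))
    stop("t_max must be three strictly increasing peak latencies",
         call. = FALSE)
  if (!all(spec$polarity %in% c(-1, 1)) || length(spec$polarity) != 3L)
    stop("polarity must be three values in {-1, +1}", call. = FALSE)
  if (abs(spec$ar_phi) >= 1) stop("|ar_phi| must be < 1", call. = FALSE)
  if (any(c(spec$subject_sd, spec$trial_sd, spec$ar_sd) < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  if (spec$missing_rate < 0 || spec$missing_rate > 1)
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  n_samp <- (spec$epoch[2L] - spec$epoch[1L]) * spec$sampling_rate / 1000
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("epoch and sampling rate must give an integer sample count",
         call. = FALSE)
  spec$n_samples <- as.integer(round(n_samp))
  class(spec) <- "simulation_spec"
  spec
}

#' Time grid of a simulation spec
#' @param spec a [simulation_spec()].
#' @return sample times in ms (half-open epoch).
#' @export
spec_times <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  seq(spec$epoch[1L], by = 1000 / spec$sampling_rate,
      length.out = spec$n_samples)
}

#' Latent basis curves of the generator
#'
#' Evaluates the three gamma-family basis kernels on the spec's time grid.
#' Each curve peaks exactly at its `t_max` with unit magnitude (the kernel
#' equals `polarity` at `t = t_max`), so curves are comparable across
#' latencies.
#'
#' @param spec a [simulation_spec()].
#' @return timepoints x 3 matrix of basis curves, columns ordered by peak
#'   latency (parasympathetic activation, parasympathetic inhibition,
#'   sympathetic activation).
#' @export
make_basis <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tt <- spec_times(spec)
  n <- spec$shape
  B <- vapply(1:3, function(k) {
    tm <- spec$t_max[k]
    spec$polarity[k] * (tt / tm)^n * exp(n * (1 - tt / tm))
  }, numeric(length(tt)))
  dimnames(B) <- list(paste0("t", tt),
                      c("parasymp_activation", "parasymp_inhibition",
                        "symp_activation"))
  B
}

# deterministic substream seed from (base seed, subject, trial); Lehmer-style
# mixing keeps results stable when the trial count changes
substream_seed <- function(seed, i, j = 0L) {
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m)
  for (k in c(i + 1, j + 1)) x <- (x * 48271 + k) %% m
  as.integer(x)
}

#' Simulate a phasic pupil trace dataset with known structure
#'
#' Generates the long-format dataset described by a [simulation_spec()]:
#' per trial, true component scores
#' \deqn{s_k = \beta_{0k} + \beta_{1k} (x - \bar x) + u_{k,subject} + e_k,}
#' with `x` the trial's condition level, the trace is the score-weighted sum
#' of the three basis curves plus stationary AR(1) noise, and artifact gaps
#' are optionally inserted as missing runs. The generator is fully
#' deterministic under the spec's seed, with random-number streams
#' partitioned by (subject, trial).
#'
#' @param spec a [simulation_spec()].
#' @return a `pupil_simulation`: list with `recording` (a
#'   [pupil_recording] with condition column `luminance`), `true_scores`
#'   (data frame `subject`, `trial`, `luminance`, `s1`-`s3`), `basis` (the
#'   [make_basis()] matrix), `times` and `spec`.
#' @export
simulate_pupil_data <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tt <- spec_times(spec)
  B <- make_basis(spec)
  p <- length(tt)
  dt <- 1000 / spec$sampling_rate
  sd_stat <- spec$ar_sd / sqrt(1 - spec$ar_phi^2)

  levels_vec <- rep_len(seq_len(spec$n_levels), spec$trials_per_subject)
  x_center <- mean(seq_len(spec$n_levels))

  n_trials <- spec$n_subjects * spec$trials_per_subject
  pupil_all <- matrix(NA_real_, nrow = n_trials, ncol = p)
  meta <- vector("list", n_trials)
  scores <- matrix(NA_real_, nrow = n_trials, ncol = 3L)
  row <- 0L
  for (s in seq_len(spec$n_subjects)) {
    set.seed(substream_seed(spec$seed, s))
    u <- stats::rnorm(3L, 0, spec$subject_sd)
    for (tr in seq_len(spec$trials_per_subject)) {
      row <- row + 1L
      lev <- levels_vec[tr]
      set.seed(substream_seed(spec$seed, s, tr))
      e <- stats::rnorm(3L, 0, spec$trial_sd)
      sk <- spec$beta0 + spec$beta1 * (lev - x_center) + u + e
      noise0 <- stats::rnorm(1L, 0, sd_stat)
      innov <- stats::rnorm(p - 1L, 0, spec$ar_sd)
      noise <- stats::filter(c(noise0, innov), spec$ar_phi,
                             method = "recursive")
      trace <- drop(B %*% sk) + as.numeric(noise)
      if (spec$missing_rate > 0 && stats::runif(1L) < spec$missing_rate) {
        dur <- stats::runif(1L, 50, 400)
        ng <- max(1L, min(p, as.integer(round(dur / dt))))
        start <- sample.int(p - ng + 1L, 1L)
        trace[start:(start + ng - 1L)] <- NA_real_
      }
      pupil_all[row, ] <- trace
      scores[row, ] <- sk
      meta[[row]] <- data.frame(subject = sprintf("s%02d", s),
                                trial = sprintf("t%03d", tr),
                                luminance = as.character(lev),
                                stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  long <- data.frame(
    subject = rep(meta$subject, each = p),
    trial = rep(meta$trial, each = p),
    time = rep(tt, times = n_trials),
    pupil = as.vector(t(pupil_all)),
    luminance = rep(meta$luminance, each = p),
    stringsAsFactors = FALSE)
  rec <- pupil_recording(long, conditions = "luminance")
  true_scores <- cbind(meta,
                       data.frame(s1 = scores[, 1L], s2 = scores[, 2L],
                                  s3 = scores[, 3L]))
  structure(list(recording = rec, true_scores = true_scores, basis = B,
                 times = tt, spec = spec),
            class = "pupil_simulation")
}

#' @export
print.pupil_simulation <- function(x, ...) {
  cat("<pupil_simulation> ", x$spec$n_subjects, " subjects x ",
      x$spec$trials_per_subject, " trials x ", x$spec$n_samples,
      " samples (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

# extract comparable loadings/scores from a fitted reduction; loadings are
# mapped back to data units when the fit standardized the columns
fitted_components <- function(fitted) {
  if (inherits(fitted, "pupil_rpca")) {
    L <- fitted$pattern
    if (!is.null(fitted$scale)) L <- L * fitted$scale
    list(loadings = L, scores = fitted$scores, row_meta = fitted$row_meta)
  } else if (inherits(fitted, "pupil_pca")) {
    L <- fitted$loadings
    if (!is.null(fitted$scale)) L <- L * fitted$scale
    list(loadings = L, scores = fitted$scores, row_meta = fitted$row_meta)
  } else if (is.list(fitted) && all(c("loadings", "scores") %in% names(fitted))) {
    fitted
  } else stop("fitted must be a pupil_pca, pupil_rpca, or a list with ",
              "loadings and scores", call. = FALSE)
}

#' Score a fitted reduction against the generating ground truth
#'
#' Matches fitted components to the generating basis curves by Tucker
#' congruence (greedy on |phi|) and reports, per matched component: the
#' signed congruence, the correlation between fitted and true trial scores,
#' and the estimated condition effect mapped back to true-score units
#' against the generating effect size. The effect estimate comes from a
#' by-subject random-intercept mixed model on the fitted scores; because
#' fitted scores are only defined up to an affine transformation of the true
#' ones, the estimate (and its standard error) is rescaled by the slope of
#' the fitted-on-true score regression before the comparison.
#'
#' @param sim a `pupil_simulation` (the ground truth).
#' @param fitted a `pupil_pca`, `pupil_rpca`, or a list with `loadings`
#'   (timepoints x k) and `scores` (trials x k, rows aligned with either
#'   `row_meta` or the simulation's trial order).
#' @return data frame with one row per true component: `component`,
#'   `matched` (fitted column index), `congruence`, `score_r` (absolute),
#'   `beta_true`, `beta_est`, `beta_se`. Unmatched components (when the
#'   fitted solution has fewer columns) are reported with `NA` metrics.
#' @export
recovery_report <- function(sim, fitted) {
  stopifnot(inherits(sim, "pupil_simulation"))
  fc <- fitted_components(fitted)
  k_true <- 3L
  cg <- tucker_congruence(sim$basis, fc$loadings)
  matching <- attr(cg, "matching")

  truth <- sim$true_scores
  if (!is.null(fc$row_meta)) {
    key_fit <- paste(fc$row_meta$subject, fc$row_meta$trial)
    key_true <- paste(truth$subject, truth$trial)
    idx <- match(key_fit, key_true)
    if (anyNA(idx)) stop("fitted rows do not match simulated trials",
                         call. = FALSE)
    truth <- truth[idx, , drop = FALSE]
  } else if (nrow(fc$scores) != nrow(truth)) {
    stop("fitted scores do not align with simulated trials", call. = FALSE)
  }

  rows <- lapply(seq_len(k_true), function(kk) {
    m <- matching[matching$a == kk, , drop = FALSE]
    if (!nrow(m) || is.na(m$phi))
      return(data.frame(component = colnames(sim$basis)[kk], matched = NA_integer_,
                        congruence = NA_real_, score_r = NA_real_,
                        beta_true = sim$spec$beta1[kk], beta_est = NA_real_,
                        beta_se = NA_real_))
    j <- m$b
    s_fit <- fc$scores[, j]
    s_true <- truth[[paste0("s", kk)]]
    r <- stats::cor(s_fit, s_true)
    # affine calibration of the fitted score onto true-score units
    slope <- stats::cov(s_fit, s_true) / stats::var(s_fit)
    tab <- data.frame(subject = truth$subject, trial = truth$trial,
                      luminance = truth$luminance, score_1 = s_fit)
    sm <- score_model(tab, fixed = "luminance")
    data.frame(component = colnames(sim$basis)[kk], matched = j,
               congruence = m$phi, score_r = abs(r),
               beta_true = sim$spec$beta1[kk],
               beta_est = sm$estimate * slope,
               beta_se = sm$se * abs(slope))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
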