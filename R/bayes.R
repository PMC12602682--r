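#' Jeffreys-Zellner-Siow Bayes factor for one linear-model effect
#'
#' Computes the Bayes factor BF10 comparing a linear model with one effect
#' term against the nested null, with a zero-centered Cauchy prior of scale
#' `prior_scale` on the standardized effect and objective (flat/Jeffreys)
#' priors on nuisance coefficients and the error scale. The Cauchy prior is
#' expressed as a scale mixture of normals, \eqn{\delta | g \sim N(0, g)},
#' \eqn{g \sim} Inverse-Gamma(1/2, r^2/2), which reduces the Bayes factor to
#' a one-dimensional integral over the mixing parameter g; the integrand
#' depends on the data only through the effect's t statistic, its residual
#' degrees of freedom, and the effective sample size.
#'
#' For a two-group comparison, `t` is the two-sample t statistic,
#' `df = n1 + n2 - 2` and `neff = n1 * n2 / (n1 + n2)`. For a regression
#' slope after projecting out nuisance covariates, `t` is the slope's t
#' statistic, `df` its residual degrees of freedom and `neff` the sum of
#' squares of the residualized covariate.
#'
#' @param t t statistic of the effect.
#' @param df residual degrees of freedom.
#' @param neff effective sample size (see Details).
#' @param prior_scale Cauchy prior scale r (default `sqrt(2)/2`).
#' @return the Bayes factor BF10 (a single number).
#' @export
jzs_bf <- function(t, df, neff, prior_scale = sqrt(2) / 2) {
  stopifnot(is.finite(t), df > 0, neff > 0, prior_scale > 0)
  r <- prior_scale
  log_den <- -(df + 1) / 2 * log1p(t^2 / df)
  # integrate over u = log(g) for numerical stability in both tails
  integrand <- function(u) {
    g <- exp(u)
    log_num <- -0.5 * log1p(neff * g) -
      (df + 1) / 2 * log1p(t^2 / ((1 + neff * g) * df))
    log_prior <- 0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * u - r^2 / (2 * g)
    exp(log_num + log_prior + u - log_den)   # + u: Jacobian of g = exp(u)
  }
  int <- stats::integrate(integrand, lower = -30, upper = 30,
                          rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 500L)
  if (int$message != "OK")
    stop("Bayes factor integration failed: ", int$message, call. = FALSE)
  int$value
}

# per-timepoint OLS with subject fixed effects (additive nuisance): returns
# the condition slope's t statistic, residual df, and the residualized
# covariate's sum of squares, vectorized over the columns of Y.
# x must be numeric; it is residualized against subject means (equivalent to
# subject dummy covariates) and standardized to unit sample sd.
subject_ols_t <- function(Y, x, subject, standardize_x = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  f <- factor(subject)
  S <- nlevels(f)
  xt <- x - stats::ave(x, f)
  if (sum(xt^2) < 1e-12)
    stop("condition does not vary within subjects; nothing to test",
         call. = FALSE)
  if (standardize_x) xt <- xt / stats::sd(xt)
  Yt <- Y - apply(Y, 2L, function(col) stats::ave(col, f))
  xx <- sum(xt^2)
  df <- n - S - 1L
  if (df < 1L) stop("not enough trials for within-subject regression",
                    call. = FALSE)
  b <- drop(crossprod(Yt, xt)) / xx
  rss <- colSums(Yt^2) - b^2 * xx
  rss[rss < 0] <- 0
  sigma2 <- rss / df
  tstat <- b / sqrt(sigma2 / xx)
  list(t = tstat, df = df, neff = xx, slope = b)
}
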