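#' Export a reduction as delimited text
#'
#' Writes the loadings (or pattern/structure for rotated solutions), the
#' per-trial score table, the variance table and a sidecar JSON metadata
#' file (time grid, centering/scaling vectors, options, package version)
#' into a directory.
#'
#' @param red a `pupil_pca` or `pupil_rpca`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_reduction <- function(red, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  if (inherits(red, "pupil_rpca")) {
    wt(data.frame(time = red$col_times, red$pattern, check.names = FALSE),
       "pattern.tsv")
    wt(data.frame(time = red$col_times, red$structure, check.names = FALSE),
       "structure.tsv")
    wt(data.frame(component = colnames(red$Phi), red$Phi,
                  check.names = FALSE), "phi.tsv")
    wt(cbind(red$row_meta, as.data.frame(red$scores)), "scores.tsv")
    wt(data.frame(component = colnames(red$pattern),
                  var_share = red$rot_var_prop), "variance.tsv")
    wt(fingerprint_table(red), "fingerprints.tsv")
    meta <- list(kind = "rotated_pca", rotation = red$rotation,
                 kappa = red$kappa, times = red$col_times,
                 center = unname(red$center), scale = unname(red$scale),
                 package_version = as.character(utils::packageVersion("pupilmanifold")))
  } else if (inherits(red, "pupil_pca")) {
    wt(data.frame(time = red$col_times, red$loadings, check.names = FALSE),
       "loadings.tsv")
    wt(cbind(red$row_meta, as.data.frame(red$scores)), "scores.tsv")
    wt(data.frame(component = paste0("PC", seq_along(red$var_prop)),
                  eigenvalue = red$eigenvalues, var_share = red$var_prop),
       "variance.tsv")
    meta <- list(kind = "pca", ncomp = red$ncomp, times = red$col_times,
                 center = unname(red$center), scale = unname(red$scale),
                 package_version = as.character(utils::packageVersion("pupilmanifold")))
  } else stop("red must be a pupil_pca or pupil_rpca", call. = FALSE)
  jsonlite::write_json(meta, file.path(dir, "reduction_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Tidy loading "fingerprint" table
#'
#' Long-format (time, component, loading) table of a solution's loading
#' curves, convenient for external plotting of the component fingerprints.
#'
#' @param red a `pupil_pca` or `pupil_rpca`.
#' @return data frame `time`, `component`, `loading`.
#' @export
fingerprint_table <- function(red) {
  L <- if (inherits(red, "pupil_rpca")) red$pattern else red$loadings
  data.frame(time = rep(red$col_times, times = ncol(L)),
             component = rep(colnames(L), each = nrow(L)),
             loading = as.vector(L))
}

#' Export a time-course result as delimited text
#'
#' @param tc a `pupil_timecourse`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_timecourse <- function(tc, dir) {
  stopifnot(inherits(tc, "pupil_timecourse"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tc$table, file.path(dir, "timecourse.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(tc$clusters, file.path(dir, "clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Benchmark quantities on a deposited example dataset
#'
#' Recomputes, from a local copy of a long-format passive-luminance dataset
#' (columns `Subject`, `Trial`, `Time`, `Luminance`, `Pupil`, already
#' preprocessed: artifacts removed, z-scored, baseline-corrected), the
#' pipeline's reference quantities: post-target samples per trial, the
#' cumulative variance share of the first three principal components, the
#' first component's share, and the significant luminance cluster of the
#' per-timepoint mixed-model time course.
#'
#' @param path path to the downloaded delimited dataset (not shipped with
#'   the package).
#' @param epoch post-target epoch in ms (default `c(0, 4500)`, half-open).
#' @param alpha significance level for the time course (default 0.05).
#' @param adjust multiplicity adjustment for the time course (default
#'   `"BH"`).
#' @return list: `samples_per_trial`, `cum_var_3pc_pct`, `pc1_var_pct`,
#'   `cluster_start_ms`, `cluster_end_ms`.
#' @export
plr_benchmark <- function(path, epoch = c(0, 4500), alpha = 0.05,
                          adjust = "BH") {
  rec <- read_pupil_data(path, conditions = "Luminance")
  rec <- epoch_trials(rec, epoch[1L], epoch[2L])
  tm <- to_trial_matrix(rec)
  red <- temporal_pca(tm, ncomp = 3)
  tc <- lmem_timecourse(tm, fixed = "Luminance", alpha = alpha,
                        adjust = adjust)
  cl <- tc$clusters
  list(samples_per_trial = ncol(tm$values),
       cum_var_3pc_pct = 100 * sum(red$var_prop[1:3]),
       pc1_var_pct = 100 * red$var_prop[1L],
       cluster_start_ms = if (nrow(cl)) min(cl$start) else NA_real_,
       cluster_end_ms = if (nrow(cl)) max(cl$end) else NA_real_)
}
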