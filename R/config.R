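#' Default run configuration
#'
#' Central container for every tunable threshold of the pipeline. Defaults
#' reproduce the study conditions: metabolite-level significance at
#' `q < 0.1` (BH), subpathway enrichment at `q < 0.05`, chemical-cluster
#' enrichment at `q < 0.15`, pathway topology at `q < 0.2`, urine--plasma
#' correlations at `q < 0.15`, member-level alteration at `p < 0.05`, the
#' modified 80% detection rule, a strong-correlation bound of `|R| > 0.7`
#' and a modified z-score outlier threshold of 6.
#'
#' @param lmm_q BH q threshold for per-metabolite contrasts.
#' @param subpathway_q BH q threshold for subpathway enrichment.
#' @param cluster_q BH q threshold for chemical-cluster enrichment.
#' @param topology_q BH q threshold for pathway topology records.
#' @param corr_q BH q threshold for urine--plasma correlations.
#' @param member_p member-level alteration p threshold inside a set.
#' @param detect_frac detection-fraction threshold of the modified 80% rule.
#' @param strong_r strong-correlation bound on `|R|`.
#' @param weak_r criterion-2 bound of the differential screen (`|R|` below
#'   this in the other cohort qualifies).
#' @param outlier_z modified z-score threshold.
#' @param n_perm permutations for the pathway global test.
#' @param df_method degrees-of-freedom method for mixed-model contrasts,
#'   `"satterthwaite"` or `"residual"`.
#' @param vst `"glog10"` (generalized log, finite at zero) or `"log10"`.
#' @param ks_alternative `"greater"` (enrichment-directed one-sided test)
#'   or `"two.sided"`.
#' @param corr_family BH family for correlation q-values: `"per_pairing"`
#'   (within cohort x pairing, the default) or `"global"`.
#' @param seed integer seed used for any stochastic step (permutations).
#' @return A named list with class `"run_config"`.
#' @export
run_config <- function(lmm_q = 0.1, subpathway_q = 0.05, cluster_q = 0.15,
                       topology_q = 0.2, corr_q = 0.15, member_p = 0.05,
                       detect_frac = 0.8, strong_r = 0.7, weak_r = 0.3,
                       outlier_z = 6, n_perm = 9999,
                       df_method = c("satterthwaite", "residual"),
                       vst = c("glog10", "log10"),
                       ks_alternative = c("greater", "two.sided"),
                       corr_family = c("per_pairing", "global"),
                       seed = 1L) {
  cfg <- list(
    lmm_q = lmm_q, subpathway_q = subpathway_q, cluster_q = cluster_q,
    topology_q = topology_q, corr_q = corr_q, member_p = member_p,
    detect_frac = detect_frac, strong_r = strong_r, weak_r = weak_r,
    outlier_z = outlier_z, n_perm = as.integer(n_perm),
    df_method = match.arg(df_method), vst = match.arg(vst),
    ks_alternative = match.arg(ks_alternative),
    corr_family = match.arg(corr_family), seed = as.integer(seed)
  )
  probs <- c("lmm_q", "subpathway_q", "cluster_q", "topology_q", "corr_q",
             "member_p", "detect_frac", "strong_r", "weak_r")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop(sprintf("config field '%s' must be a single value in (0, 1)", nm))
  }
  if (cfg$outlier_z <= 0) stop("outlier_z must be > 0")
  if (cfg$n_perm < 1L) stop("n_perm must be >= 1")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path path to a YAML file whose keys are `run_config()` arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("uromet run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Structured stage log: one message per pipeline stage with counts, so
# filtering provenance is auditable. Silenced via options(uromet.verbose=FALSE).
pipe_log <- function(stage, ...) {
  if (isTRUE(getOption("uromet.verbose", TRUE)))
    message(sprintf("[uromet:%s] %s", stage, sprintf(...)))
  invisible(NULL)
}
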