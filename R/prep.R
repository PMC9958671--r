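# ---------------------------------------------------------------------------
# Raw abundances -> analysis-ready matrix. Fixed stage order:
# normalize (osmolality) -> impute -> median-center -> glog10 -> filter.
# The detection mask always reflects the pre-imputation state, so the
# modified 80% rule is order-independent.
# ---------------------------------------------------------------------------

#' Normalize urine abundances by osmolality
#'
#' Divides every cell of a sample by that sample's osmolality, removing
#' dilution differences between urine collections. Missing cells stay
#' missing.
#'
#' @param raw abundance matrix (samples x metabolites).
#' @param samples sample metadata with `sample_id` and `osmolality`.
#' @return normalized matrix of the same shape.
#' @export
normalize_osmolality <- function(raw, samples) {
  idx <- match(rownames(raw), samples$sample_id)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(rownames(raw)[is.na(idx)][1:min(3, sum(is.na(idx)))],
               collapse = ", "))
  osmo <- samples$osmolality[idx]
  if (any(is.na(osmo) | osmo <= 0))
    stop("missing or non-positive osmolality for sample: ",
         rownames(raw)[is.na(osmo) | osmo <= 0][1L])
  raw / osmo
}

#' Impute missing cells
#'
#' Non-drug metabolites: missing cells are replaced by the minimum observed
#' value of that metabolite across all samples. Drug/tobacco metabolites:
#' missing cells become 0 (absence of an exposure, not a low concentration).
#' An all-missing non-drug metabolite cannot be imputed and is dropped.
#'
#' @param norm normalized abundance matrix.
#' @param annot metabolite annotation (`metabolite_id`,
#'   `is_drug_or_tobacco`).
#' @return list: `values` (imputed matrix, all-missing metabolites removed),
#'   `imputed` (logical matrix, same shape as `values`), `detected`
#'   (pre-imputation detection mask), `dropped` (ids of all-missing
#'   metabolites).
#' @export
impute_missing <- function(norm, annot) {
  idx <- match(colnames(norm), annot$metabolite_id)
  if (anyNA(idx))
    stop("metabolites without annotation: ",
         colnames(norm)[is.na(idx)][1L])
  drug <- annot$is_drug_or_tobacco[idx]
  detected <- !is.na(norm)
  mins <- suppressWarnings(apply(norm, 2L, min, na.rm = TRUE))
  out <- norm
  for (j in seq_len(ncol(norm))) {
    miss <- !detected[, j]
    if (!any(miss)) next
    out[miss, j] <- if (drug[j]) 0 else mins[j]
  }
  all_missing <- !drug & colSums(detected) == 0L
  if (any(all_missing))
    pipe_log("impute", "dropping %d all-missing metabolite(s): %s",
             sum(all_missing),
             paste(colnames(norm)[all_missing], collapse = ", "))
  keep <- !all_missing
  list(values = out[, keep, drop = FALSE],
       imputed = !detected[, keep, drop = FALSE],
       detected = detected[, keep, drop = FALSE],
       dropped = colnames(norm)[all_missing])
}

#' Median-center each metabolite to 1
#'
#' Divides each metabolite by its median across samples. If the median is 0
#' (possible for drug compounds imputed to 0), the smallest positive value
#' of that metabolite is used as the divisor instead; a metabolite with no
#' positive value at all is dropped. Both fallbacks are logged.
#'
#' @param imputed matrix with no missing cells.
#' @return list: `values` (centered matrix), `dropped` (ids removed),
#'   `zero_median` (ids where the fallback divisor was used).
#' @export
median_center <- function(imputed) {
  if (anyNA(imputed)) stop("median_center expects a fully imputed matrix")
  med <- apply(imputed, 2L, stats::median)
  div <- med
  zero_med <- med == 0
  for (j in which(zero_med)) {
    pos <- imputed[, j][imputed[, j] > 0]
    div[j] <- if (length(pos)) min(pos) else NA_real_
  }
  drop <- is.na(div)
  if (any(zero_med & !drop))
    pipe_log("center", "zero median, smallest-positive fallback: %s",
             paste(colnames(imputed)[zero_med & !drop], collapse = ", "))
  if (any(drop))
    pipe_log("center", "no positive value, dropped: %s",
             paste(colnames(imputed)[drop], collapse = ", "))
  keep <- !drop
  list(values = sweep(imputed[, keep, drop = FALSE], 2L, div[keep], "/"),
       dropped = colnames(imputed)[drop],
       zero_median = colnames(imputed)[zero_med & !drop])
}

#' Generalized-log variance-stabilizing transform (base 10)
#'
#' `glog10(x) = log10((x + sqrt(x^2 + lambda^2)) / 2)`. Strictly increasing,
#' asymptotically `log10(x)` for `x >> lambda`, and finite at `x = 0` (where
#' it equals `log10(lambda/2)`), which plain `log10` is not -- needed because
#' drug compounds are imputed to 0. The default calibration sets `lambda` to
#' one tenth of the smallest positive value in the matrix, so values in the
#' measured range are essentially untouched.
#'
#' @param x numeric vector or matrix, values `>= 0`.
#' @param lambda transition scale; `NULL` = smallest positive value / 10.
#' @return transformed object of the same shape; `attr(,"lambda")` records
#'   the scale used.
#' @export
glog10 <- function(x, lambda = NULL) {
  if (any(x < 0, na.rm = TRUE)) stop("glog10 expects non-negative values")
  if (is.null(lambda)) {
    pos <- x[!is.na(x) & x > 0]
    if (!length(pos)) stop("no positive value to calibrate lambda")
    lambda <- min(pos) / 10
  }
  out <- log10((x + sqrt(x^2 + lambda^2)) / 2)
  attr(out, "lambda") <- lambda
  out
}

#' Variance-stabilized log10 transform of a centered matrix
#'
#' @param centered median-centered matrix (no missing cells).
#' @param method `"glog10"` (default) or strict `"log10"` (infinite at 0).
#' @param lambda passed to [glog10()].
#' @return transformed matrix with `attr(,"lambda")`.
#' @export
vst_log10 <- function(centered, method = c("glog10", "log10"),
                      lambda = NULL) {
  method <- match.arg(method)
  if (method == "log10") {
    out <- log10(centered)
    attr(out, "lambda") <- 0
    return(out)
  }
  glog10(centered, lambda)
}

#' Modified 80% detection filter
#'
#' A metabolite is retained iff it was detected (pre-imputation) in at
#' least `detect_frac` of all samples of the control cohort or of the case
#' cohort (both timepoints pooled within cohort). The threshold is
#' non-strict (`>=`).
#'
#' @param detected logical detection matrix (samples x metabolites).
#' @param samples sample metadata covering the rows of `detected`.
#' @param detect_frac detection-fraction threshold (default 0.8).
#' @return data frame (metabolite_id, frac_control, frac_case, retained).
#' @export
filter_80pct <- function(detected, samples, detect_frac = 0.8) {
  idx <- match(rownames(detected), samples$sample_id)
  if (anyNA(idx)) stop("detection mask rows missing from metadata")
  cohort <- samples$cohort[idx]
  fc <- colMeans(detected[cohort == "control", , drop = FALSE])
  fm <- colMeans(detected[cohort == "mecfs", , drop = FALSE])
  res <- data.frame(metabolite_id = colnames(detected),
                    frac_control = fc, frac_case = fm,
                    retained = fc >= detect_frac | fm >= detect_frac,
                    row.names = NULL, stringsAsFactors = FALSE)
  pipe_log("filter", "%d measured -> %d retained (>= %d%% detection rule)",
           nrow(res), sum(res$retained), round(100 * detect_frac))
  res
}

#' Run the full preprocessing chain for one fluid
#'
#' normalize (urine only) -> impute -> median-center -> variance-stabilized
#' log10 -> detection filter. The filter labels metabolites but does not
#' remove them from the matrix: downstream stages choose the retained set
#' (the cross-fluid correlation analysis deliberately uses the unfiltered
#' panel).
#'
#' @param raw raw abundance matrix for one fluid.
#' @param samples sample metadata.
#' @param annot metabolite annotation.
#' @param config a [run_config()].
#' @param osmolality normalize by osmolality first (TRUE for urine).
#' @return list of class `"processed_table"`: `values` (transformed
#'   matrix), `centered` (median-centered pre-transform matrix, the
#'   "normalized concentration" scale), `detected`, `imputed`, `filter`
#'   (the [filter_80pct()] table), `retained` (ids passing the filter),
#'   `dropped`, `lambda`.
#' @export
preprocess <- function(raw, samples, annot, config = run_config(),
                       osmolality = TRUE) {
  norm <- if (osmolality) normalize_osmolality(raw, samples) else raw
  imp <- impute_missing(norm, annot)
  ctr <- median_center(imp$values)
  keep <- colnames(ctr$values)
  vst <- vst_log10(ctr$values, method = config$vst)
  det <- imp$detected[, keep, drop = FALSE]
  filt <- filter_80pct(det, samples, config$detect_frac)
  structure(list(values = vst, centered = ctr$values, detected = det,
                 imputed = imp$imputed[, keep, drop = FALSE],
                 filter = filt,
                 retained = filt$metabolite_id[filt$retained],
                 dropped = c(imp$dropped, ctr$dropped),
                 lambda = attr(vst, "lambda")),
            class = "processed_table")
}

#' Per-subject post/baseline log10 ratios
#'
#' For each subject with both timepoints, `log10_ratio = value(post) -
#' value(base)` on the transformed scale, per metabolite. Subjects lacking
#' either timepoint are omitted (logged).
#'
#' @param values transformed matrix (samples x metabolites).
#' @param samples sample metadata for the rows of `values`.
#' @param post_tp,base_tp timepoint labels, e.g. `"U3"`/`"U1"` for urine or
#'   `"P4"`/`"P1"` for plasma.
#' @return matrix subjects x metabolites of log10 ratios.
#' @export
make_ratios <- function(values, samples, post_tp, base_tp) {
  idx <- match(rownames(values), samples$sample_id)
  if (anyNA(idx)) stop("samples without metadata in ratio construction")
  tp <- samples$timepoint[idx]
  subj <- samples$subject_id[idx]
  post_sub <- subj[tp == post_tp]
  base_sub <- subj[tp == base_tp]
  shared <- intersect(post_sub, base_sub)
  omitted <- setdiff(union(post_sub, base_sub), shared)
  if (length(omitted))
    pipe_log("ratios", "omitting incomplete subject(s) for %s/%s: %s",
             post_tp, base_tp, paste(omitted, collapse = ", "))
  if (!length(shared)) stop("no subject has both timepoints")
  post_rows <- rownames(values)[tp == post_tp][match(shared,
                                                     post_sub)]
  base_rows <- rownames(values)[tp == base_tp][match(shared,
                                                     base_sub)]
  out <- values[post_rows, , drop = FALSE] - values[base_rows, , drop = FALSE]
  rownames(out) <- shared
  out
}

#' Change of base: log10 fold change to log2
#'
#' @param fc value(s) on the log10 scale.
#' @return the same fold change(s) on the log2 scale (`fc / log10(2)`).
#' @export
log2_from_log10 <- function(fc) fc / log10(2)
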