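# ---------------------------------------------------------------------------
# Urine-plasma correlation analysis. Seven subject-paired pairings by
# default: four timepoint pairings (same-day urine and plasma draws) and
# three ratio pairings (urine post/baseline ratio against three plasma
# post-exercise ratios). Pearson R within cohort, t-test against R = 0,
# BH per cohort x pairing family, a strong-correlation census
# (|R| > 0.7), modified z-score outlier removal with timepoint-vs-ratio
# scope, and the three-criteria differential-correlation screen.
# This analysis deliberately runs on the unfiltered shared panel.
# ---------------------------------------------------------------------------

#' Default urine--plasma pairing specification
#'
#' @return data frame: pairing_id, urine (timepoint or ratio label), plasma,
#'   kind (`timepoint`/`ratio`).
#' @export
default_pairings <- function() {
  data.frame(
    pairing_id = c("U1~P1", "U1~P2", "U3~P3", "U3~P4",
                   "U3/U1~P4/P1", "U3/U1~P3/P2", "U3/U1~P3/P1"),
    urine = c("U1", "U1", "U3", "U3", "U3/U1", "U3/U1", "U3/U1"),
    plasma = c("P1", "P2", "P3", "P4", "P4/P1", "P3/P2", "P3/P1"),
    kind = c(rep("timepoint", 4L), rep("ratio", 3L)),
    stringsAsFactors = FALSE)
}

#' Metabolites measured in both fluids
#'
#' @param urine_ids,plasma_ids metabolite id vectors of the two panels.
#' @return character vector of shared ids; empty intersection is an error.
#' @export
shared_metabolites <- function(urine_ids, plasma_ids) {
  shared <- intersect(urine_ids, plasma_ids)
  if (!length(shared)) stop("no metabolite measured in both fluids")
  pipe_log("fluidcorr", "%d compound(s) measured in both fluids",
           length(shared))
  shared
}

#' Pearson correlation with a t-test against R = 0
#'
#' `t = R * sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees of freedom,
#' two-sided. `R = +/-1` yields `p = 0`.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list: `r`, `p`, `n`. Zero variance in either vector returns
#'   `r = NA` with a `degenerate` flag.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(r = r, p = p, n = n, degenerate = FALSE)
}

#' Modified z-score outlier detection
#'
#' `z_i = 0.6745 * (x_i - median) / MAD` with the raw (unscaled) median
#' absolute deviation; `|z| > threshold` flags an outlier. A zero MAD makes
#' outliers uncallable (flagged, none reported).
#'
#' @param values numeric vector, `n >= 3`.
#' @param threshold z threshold (default 6).
#' @return list: `outlier` (logical mask), `z`, `mad_zero`.
#' @export
detect_outliers <- function(values, threshold = 6) {
  v <- values[!is.na(values)]
  if (length(v) < 3L) stop("outlier detection needs n >= 3")
  med <- stats::median(v)
  mad_raw <- stats::median(abs(v - med))
  z <- rep(NA_real_, length(values))
  if (mad_raw == 0)
    return(list(outlier = rep(FALSE, length(values)), z = z,
                mad_zero = TRUE))
  z[!is.na(values)] <- 0.6745 * (v - med) / mad_raw
  list(outlier = !is.na(z) & abs(z) > threshold, z = z, mad_zero = FALSE)
}

# per-subject variable matrices for each pairing side:
# timepoint labels pull transformed values; "A/B" labels pull log10 ratios.
pairing_variable <- function(label, values, samples, fluid) {
  if (grepl("/", label, fixed = TRUE)) {
    tp <- strsplit(label, "/", fixed = TRUE)[[1L]]
    make_ratios(values, samples, tp[1L], tp[2L])
  } else {
    s <- samples[match(rownames(values), samples$sample_id), ]
    sel <- s$fluid == fluid & s$timepoint == label
    out <- values[sel, , drop = FALSE]
    rownames(out) <- s$subject_id[sel]
    out
  }
}

#' Urine--plasma correlation census
#'
#' Computes per metabolite x cohort x pairing Pearson correlations on the
#' shared panel, BH-adjusts within each cohort x pairing family (or one
#' global family), counts strong correlations (`R > 0.7`, `R < -0.7`), and
#' applies compound-level outlier removal: a compound with a modified
#' z-score outlier (cohorts pooled) in any timepoint variable is dropped
#' from all timepoint pairings only; an outlier in any ratio variable drops
#' it from all ratio pairings only.
#'
#' @param urine_values transformed urine matrix (samples x metabolites).
#' @param plasma_values transformed plasma matrix.
#' @param samples sample metadata covering both fluids.
#' @param pairings pairing table, default [default_pairings()].
#' @param config a [run_config()].
#' @return list of class `"fluidcorr"`: `records` (metabolite_id, cohort,
#'   pairing_id, kind, n, r, p, q, outlier_removed, degenerate), `census`
#'   (cohort x pairing counts of strong correlations), `outliers`
#'   (per-compound removal scope).
#' @export
correlation_census <- function(urine_values, plasma_values, samples,
                               pairings = default_pairings(),
                               config = run_config()) {
  shared <- shared_metabolites(colnames(urine_values),
                               colnames(plasma_values))
  u <- urine_values[, shared, drop = FALSE]
  p <- plasma_values[, shared, drop = FALSE]

  # variable matrices per pairing side, subjects in rows
  uvars <- lapply(unique(pairings$urine), pairing_variable,
                  values = u, samples = samples, fluid = "urine")
  names(uvars) <- unique(pairings$urine)
  pvars <- lapply(unique(pairings$plasma), pairing_variable,
                  values = p, samples = samples, fluid = "plasma")
  names(pvars) <- unique(pairings$plasma)

  # compound-level outlier scopes, cohorts pooled, per variable vector
  scope_out <- function(kind) {
    labs <- unique(c(pairings$urine[pairings$kind == kind],
                     pairings$plasma[pairings$kind == kind]))
    mats <- c(uvars[intersect(labs, names(uvars))],
              pvars[intersect(labs, names(pvars))])
    flagged <- rep(FALSE, length(shared))
    for (mat in mats)
      flagged <- flagged | vapply(shared, function(mid)
        any(detect_outliers(mat[, mid], config$outlier_z)$outlier), TRUE)
    names(flagged) <- shared
    flagged
  }
  out_tp <- scope_out("timepoint")
  out_ratio <- scope_out("ratio")
  pipe_log("fluidcorr",
           "outlier removal: %d compound(s) from timepoint pairings, %d from ratio pairings",
           sum(out_tp), sum(out_ratio))

  subj_cohort <- samples$cohort[!duplicated(samples$subject_id)]
  names(subj_cohort) <- samples$subject_id[!duplicated(samples$subject_id)]

  recs <- list()
  for (i in seq_len(nrow(pairings))) {
    pr <- pairings[i, ]
    um <- uvars[[pr$urine]]
    pm <- pvars[[pr$plasma]]
    subj <- intersect(rownames(um), rownames(pm))
    removed <- if (pr$kind == "timepoint") out_tp else out_ratio
    for (co in c("control", "mecfs")) {
      ss <- subj[subj_cohort[subj] == co]
      if (length(ss) < 3L)
        stop("cohort '", co, "' has fewer than 3 paired subjects")
      # column-wise Pearson R between the paired matrices
      a <- scale(um[ss, shared, drop = FALSE])
      b <- scale(pm[ss, shared, drop = FALSE])
      n <- length(ss)
      r <- colSums(a * b) / (n - 1)
      degen <- !is.finite(r)
      r[degen] <- NA_real_
      tv <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
      pv <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tv), n - 2))
      rm <- unname(removed[shared])
      recs[[length(recs) + 1L]] <- data.frame(
        metabolite_id = shared, cohort = co, pairing_id = pr$pairing_id,
        kind = pr$kind,
        n = ifelse(rm, NA_integer_, n),
        r = ifelse(rm, NA_real_, r), p = ifelse(rm, NA_real_, pv),
        outlier_removed = rm, degenerate = !rm & degen,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  records$q <- NA_real_
  if (config$corr_family == "per_pairing") {
    for (co in unique(records$cohort))
      for (pid in unique(records$pairing_id)) {
        sel <- records$cohort == co & records$pairing_id == pid
        records$q[sel] <- bh_adjust(records$p[sel])
      }
  } else {
    records$q <- bh_adjust(records$p)
  }

  census <- do.call(rbind, lapply(split(
    records, list(records$cohort, records$pairing_id)), function(rr)
      data.frame(cohort = rr$cohort[1L], pairing_id = rr$pairing_id[1L],
                 kind = rr$kind[1L],
                 n_strong_pos = sum(rr$r > config$strong_r, na.rm = TRUE),
                 n_strong_neg = sum(rr$r < -config$strong_r, na.rm = TRUE),
                 n_tested = sum(!is.na(rr$r)), stringsAsFactors = FALSE)))
  rownames(census) <- NULL
  census <- census[order(match(census$pairing_id, pairings$pairing_id),
                         census$cohort), ]
  outliers <- data.frame(metabolite_id = shared,
                         removed_timepoint = unname(out_tp),
                         removed_ratio = unname(out_ratio),
                         stringsAsFactors = FALSE)
  structure(list(records = records, census = census, outliers = outliers),
            class = "fluidcorr")
}

#' Three-criteria differential-correlation screen
#'
#' A (metabolite, pairing) is a hit when (1) one cohort has `|R| >
#' strong_r`, `p < 0.05` and `q < corr_q`; (2) the other cohort has either
#' `|R| < weak_r` or an R of opposite sign; (3) outlier-affected compounds
#' were already removed upstream ([correlation_census()]).
#'
#' @param fc a [correlation_census()] result.
#' @param config a [run_config()].
#' @param crit1_p criterion-1 p threshold (default 0.05).
#' @return data frame of hits: metabolite_id, pairing_id, kind, r_case,
#'   r_control, q_case, q_control, sig_cohort (which cohort met criterion
#'   1: `control`, `mecfs` or `both`).
#' @export
differential_screen <- function(fc, config = run_config(), crit1_p = 0.05) {
  r <- fc$records[!fc$records$outlier_removed & !fc$records$degenerate &
                    !is.na(fc$records$r), ]
  ctrl <- r[r$cohort == "control", ]
  case <- r[r$cohort == "mecfs", ]
  key <- paste(ctrl$metabolite_id, ctrl$pairing_id)
  idx <- match(key, paste(case$metabolite_id, case$pairing_id))
  ok <- !is.na(idx)
  ctrl <- ctrl[ok, ]
  case <- case[idx[ok], ]
  crit1 <- function(z) abs(z$r) > config$strong_r & z$p < crit1_p &
    z$q < config$corr_q
  crit2 <- function(z, other) abs(other$r) < config$weak_r |
    sign(other$r) != sign(z$r)
  hit_ctrl <- crit1(ctrl) & crit2(ctrl, case)
  hit_case <- crit1(case) & crit2(case, ctrl)
  sel <- hit_ctrl | hit_case
  out <- if (any(sel)) data.frame(
    metabolite_id = ctrl$metabolite_id[sel],
    pairing_id = ctrl$pairing_id[sel], kind = ctrl$kind[sel],
    r_case = case$r[sel], r_control = ctrl$r[sel],
    q_case = case$q[sel], q_control = ctrl$q[sel],
    sig_cohort = ifelse(hit_ctrl[sel] & hit_case[sel], "both",
                        ifelse(hit_case[sel], "mecfs", "control")),
    stringsAsFactors = FALSE, row.names = NULL) else
    data.frame(metabolite_id = character(), pairing_id = character(),
               kind = character(), r_case = numeric(), r_control = numeric(),
               q_case = numeric(), q_control = numeric(),
               sig_cohort = character(), stringsAsFactors = FALSE)
  pipe_log("screen", "%d (compound, pairing) hit(s)", nrow(out))
  out
}

#' Heatmap-ready table of screen hits
#'
#' Long table with one row per screened cohort R value; cells of
#' (compound, pairing) combinations that did not qualify are absent,
#' mirroring a masked heatmap.
#'
#' @param hits [differential_screen()] output.
#' @return data frame: metabolite_id, pairing_id, kind, cohort, r.
#' @export
screen_heatmap <- function(hits) {
  if (!nrow(hits))
    return(data.frame(metabolite_id = character(), pairing_id = character(),
                      kind = character(), cohort = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  long <- rbind(
    data.frame(metabolite_id = hits$metabolite_id,
               pairing_id = hits$pairing_id, kind = hits$kind,
               cohort = "control", r = hits$r_control,
               stringsAsFactors = FALSE),
    data.frame(metabolite_id = hits$metabolite_id,
               pairing_id = hits$pairing_id, kind = hits$kind,
               cohort = "mecfs", r = hits$r_case, stringsAsFactors = FALSE))
  long[order(long$metabolite_id, long$pairing_id, long$cohort), ]
}
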