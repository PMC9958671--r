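# ---------------------------------------------------------------------------
# Non-overlapping-set enrichment over vendor-annotated subpathways or
# chemical-similarity clusters. Each set is scored by a one-sample
# Kolmogorov-Smirnov test of its members' metabolite-level p-values against
# Uniform(0,1), one-sided toward "stochastically smaller" (the enrichment
# direction); set p-values are BH-adjusted across sets. The altered ratio
# is the fraction of members with p < 0.05 and the increased ratio the
# fraction of altered members whose fold change is positive.
# ---------------------------------------------------------------------------

#' Kolmogorov--Smirnov enrichment test for one member p-value set
#'
#' @param member_p p-values of the set's members (length >= 2).
#' @param alternative `"greater"` (one-sided, members smaller than uniform;
#'   default) or `"two.sided"`.
#' @return list: `statistic` (D or D+), `p`.
#' @export
ks_enrich <- function(member_p, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(member_p) < 2L) stop("KS enrichment needs >= 2 members")
  if (any(member_p < 0 | member_p > 1)) stop("p-values must lie in [0, 1]")
  # alternative = "greater": ECDF of member p lies above the uniform CDF
  kt <- suppressWarnings(stats::ks.test(member_p, stats::punif,
                                        alternative = alternative))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Enrich all sets for one contrast
#'
#' @param results metabolite-level results for a single contrast: data
#'   frame with `metabolite_id` and `p`.
#' @param fc named vector of per-metabolite fold changes on a log scale
#'   (sign determines "increased"); names are metabolite ids.
#' @param sets named assignment: data frame with `metabolite_id` and
#'   `set_id` (plus optional `superpathway`). A metabolite may appear at
#'   most once (non-overlap is enforced).
#' @param member_p member-level alteration threshold (default 0.05).
#' @param alternative KS sidedness, see [ks_enrich()].
#' @return list of class `"enrichment"`: `records` (set_id, superpathway,
#'   set_size, ks_d, ks_p, q, n_altered, altered_ratio, increased_ratio)
#'   ordered superpathway-alphabetically then in set input order, and
#'   `members` (per-member detail: set_id, metabolite_id, p, log_fc,
#'   altered, increased). Sets of size 1 are skipped (logged).
#' @export
enrich_all <- function(results, fc, sets, member_p = 0.05,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (anyDuplicated(sets$metabolite_id))
    stop("overlapping set assignment for metabolite: ",
         sets$metabolite_id[duplicated(sets$metabolite_id)][1L])
  if (!"superpathway" %in% names(sets)) sets$superpathway <- NA_character_
  keep <- sets$metabolite_id %in% results$metabolite_id
  sets <- sets[keep, , drop = FALSE]
  m <- results[match(sets$metabolite_id, results$metabolite_id), ]
  members <- data.frame(set_id = sets$set_id,
                        metabolite_id = sets$metabolite_id,
                        p = m$p, log_fc = unname(fc[sets$metabolite_id]),
                        stringsAsFactors = FALSE)
  members$altered <- members$p < member_p
  members$increased <- members$altered & members$log_fc > 0
  set_order <- unique(sets$set_id)
  rec <- lapply(set_order, function(sid) {
    mm <- members[members$set_id == sid, , drop = FALSE]
    if (nrow(mm) < 2L) {
      pipe_log("enrich", "set '%s' has %d member(s); skipped", sid, nrow(mm))
      return(NULL)
    }
    ks <- ks_enrich(mm$p, alternative)
    n_alt <- sum(mm$altered)
    data.frame(set_id = sid,
               superpathway = sets$superpathway[match(sid, sets$set_id)],
               set_size = nrow(mm), ks_d = ks$statistic, ks_p = ks$p,
               n_altered = n_alt, altered_ratio = n_alt / nrow(mm),
               increased_ratio = if (n_alt > 0)
                 sum(mm$increased) / n_alt else NA_real_,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec)
  if (is.null(records)) stop("no set with >= 2 measured members")
  records$q <- bh_adjust(records$ks_p)
  # fixed reporting order: superpathways alphabetical, then the vendor's
  # within-superpathway (input) order
  records <- records[order(records$superpathway,
                           match(records$set_id, set_order),
                           na.last = TRUE), ]
  rownames(records) <- NULL
  records <- records[, c("set_id", "superpathway", "set_size", "ks_d",
                         "ks_p", "q", "n_altered", "altered_ratio",
                         "increased_ratio")]
  structure(list(records = records, members = members), class = "enrichment")
}

#' Subpathway or cluster assignment from an annotation table
#'
#' @param annot metabolite annotation.
#' @param mode `"subpathway"` (known compounds with a subpathway) or
#'   `"cluster"` (compounds carrying a `cluster_id`).
#' @return data frame with `metabolite_id`, `set_id`, `superpathway`.
#' @export
set_assignment <- function(annot, mode = c("subpathway", "cluster")) {
  mode <- match.arg(mode)
  if (mode == "subpathway") {
    a <- annot[!is.na(annot$subpathway) & annot$status == "known", ]
    data.frame(metabolite_id = a$metabolite_id, set_id = a$subpathway,
               superpathway = a$superpathway, stringsAsFactors = FALSE)
  } else {
    a <- annot[!is.na(annot$cluster_id), ]
    data.frame(metabolite_id = a$metabolite_id, set_id = a$cluster_id,
               superpathway = a$superpathway, stringsAsFactors = FALSE)
  }
}

#' Fold change of the mean normalized concentration, per comparison
#'
#' Enrichment consumes the fold change of the mean normalized (i.e.
#' median-centered, pre-transform) concentration. Returned on the log10
#' scale so the sign codes direction: cohort contrasts are
#' `log10(mean case / mean control)` at the timepoint, within-cohort
#' contrasts `log10(mean post / mean baseline)`, and the interaction is
#' the difference of the cohorts' mean per-subject log10 ratios.
#'
#' @param proc urine `processed_table`.
#' @param samples sample metadata.
#' @return matrix metabolites x 5 contrasts of signed log10 fold changes.
#' @export
fold_changes <- function(proc, samples) {
  s <- samples[match(rownames(proc$centered), samples$sample_id), ]
  grp <- function(co, tp)
    colMeans(proc$centered[s$cohort == co & s$timepoint == tp, ,
                           drop = FALSE])
  ratios <- make_ratios(proc$values, samples, "U3", "U1")
  subj <- samples[match(rownames(ratios), samples$subject_id), ]
  ctrl <- colMeans(ratios[subj$cohort == "control", , drop = FALSE])
  case <- colMeans(ratios[subj$cohort == "mecfs", , drop = FALSE])
  cbind(case_vs_ctrl_baseline = log10(grp("mecfs", "U1") / grp("control", "U1")),
        case_vs_ctrl_post = log10(grp("mecfs", "U3") / grp("control", "U3")),
        post_vs_base_ctrl = log10(grp("control", "U3") / grp("control", "U1")),
        post_vs_base_case = log10(grp("mecfs", "U3") / grp("mecfs", "U1")),
        interaction = case - ctrl)
}

#' Bubble-plot table across comparisons
#'
#' Long, plot-ready table keeping only sets below the q threshold for each
#' comparison: bubble size is the altered ratio, color the increased ratio.
#'
#' @param enrichments named list of [enrich_all()] results (one per
#'   comparison).
#' @param q_threshold significance threshold on the set q-value.
#' @return data frame: comparison, set_id, superpathway, set_size,
#'   altered_ratio, increased_ratio, q.
#' @export
bubble_table <- function(enrichments, q_threshold) {
  out <- lapply(names(enrichments), function(nm) {
    r <- enrichments[[nm]]$records
    r <- r[!is.na(r$q) & r$q < q_threshold, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    cbind(comparison = nm,
          r[, c("set_id", "superpathway", "set_size", "altered_ratio",
                "increased_ratio", "q")])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(comparison = character(), set_id = character(),
                      superpathway = character(), set_size = integer(),
                      altered_ratio = numeric(), increased_ratio = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
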