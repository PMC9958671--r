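# ---------------------------------------------------------------------------
# Subject clustering on selected metabolites (Ward.D2 on Euclidean
# distances) and assembly of the plot-ready report tables.
# ---------------------------------------------------------------------------

#' Agglomerative hierarchical clustering of subjects
#'
#' Ward.D2 agglomeration (Lance--Williams update with squared distances
#' inside the criterion) on Euclidean distances between subject profiles.
#' Deterministic given the input order.
#'
#' @param mat numeric matrix, subjects in rows, selected metabolites in
#'   columns; no missing cells.
#' @param k number of clusters to cut.
#' @return list of class `"cluster_result"`: `hclust` (the merge tree),
#'   `assignment` (named cluster index per subject), `order` (dendrogram
#'   leaf order), `k`.
#' @export
cluster_subjects <- function(mat, k) {
  if (anyNA(mat)) stop("clustering input must have no missing cells")
  if (k > nrow(mat)) stop("k exceeds the number of subjects")
  if (k < 1L) stop("k must be >= 1")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  assignment <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, assignment = assignment,
                 order = rownames(mat)[hc$order], k = k),
            class = "cluster_result")
}

#' Serialize a dendrogram as a merge table
#'
#' @param cl a [cluster_subjects()] result.
#' @return data frame (node_a, node_b, height, new_id); negative ids are
#'   leaves (subjects, by input position), positive ids earlier merges.
#' @export
merge_table <- function(cl) {
  m <- cl$hclust$merge
  data.frame(node_a = m[, 1L], node_b = m[, 2L],
             height = cl$hclust$height, new_id = seq_len(nrow(m)))
}

#' Run the full exercise-response analysis
#'
#' End-to-end driver: design validation, preprocessing of both fluids,
#' per-metabolite mixed models with the five contrast families, subpathway
#' (and, when cluster ids are present, chemical-cluster) enrichment,
#' optional pathway topology, the urine--plasma correlation census and
#' differential screen, and subject clustering on the post-exercise
#' discriminating compounds.
#'
#' @param urine,plasma raw abundance matrices (plasma may be `NULL` to
#'   skip the cross-biofluid stage).
#' @param samples sample metadata for all provided fluids.
#' @param annot metabolite annotation.
#' @param graphs optional pathway graph list for the topology stage.
#' @param config a [run_config()].
#' @param cluster_k clusters for the subject heatmap (default 3).
#' @return list of class `"uromet_run"` with every stage's output and a
#'   `summary` of counts at the configured thresholds.
#' @export
run_pipeline <- function(urine, plasma = NULL, samples, annot,
                         graphs = NULL, config = run_config(),
                         cluster_k = 3L) {
  design <- validate_design(samples)
  proc_u <- preprocess(urine, samples, annot, config, osmolality = TRUE)
  panel <- fit_all_lmm(proc_u, samples, config = config)
  fc <- fold_changes(proc_u, samples)

  contrast_names <- rownames(contrast_matrix())
  enr_sub <- list(); enr_clu <- list()
  sub_assign <- set_assignment(annot, "subpathway")
  sub_assign <- sub_assign[sub_assign$metabolite_id %in% proc_u$retained, ]
  clu_assign <- set_assignment(annot, "cluster")
  clu_assign <- clu_assign[clu_assign$metabolite_id %in% proc_u$retained, ]
  for (cn in setdiff(contrast_names, "post_vs_base_case")) {
    res_cn <- panel$results[panel$results$contrast == cn, ]
    if (nrow(sub_assign))
      enr_sub[[cn]] <- enrich_all(res_cn, fc[, cn], sub_assign,
                                  config$member_p, config$ks_alternative)
    if (nrow(clu_assign))
      enr_clu[[cn]] <- enrich_all(res_cn, fc[, cn], clu_assign,
                                  config$member_p, config$ks_alternative)
  }
  # the within-case change is evaluated too; it simply tends to be empty
  res_case <- panel$results[panel$results$contrast == "post_vs_base_case", ]
  if (nrow(sub_assign))
    enr_sub$post_vs_base_case <- enrich_all(res_case,
                                            fc[, "post_vs_base_case"],
                                            sub_assign, config$member_p,
                                            config$ks_alternative)

  topology <- NULL
  if (!is.null(graphs) && length(graphs)) {
    mapping <- match_hmdb(annot, graphs, proc_u$retained)
    s_u <- samples[match(rownames(proc_u$values), samples$sample_id), ]
    post <- s_u$timepoint == "U3"
    topo_tp <- topology_report(
      graphs, mapping, proc_u$values[post, , drop = FALSE],
      s_u$cohort[post], config$n_perm, config$seed, config$topology_q)
    subj <- samples$cohort[match(rownames(panel$ratios),
                                 samples$subject_id)]
    topo_ratio <- topology_report(
      graphs, mapping, panel$ratios, subj, config$n_perm,
      config$seed + 1L, config$topology_q)
    topology <- list(post = topo_tp, ratio = topo_ratio)
  }

  fluid <- NULL; hits <- NULL
  if (!is.null(plasma)) {
    proc_p <- preprocess(plasma, samples, annot, config, osmolality = FALSE)
    fluid <- correlation_census(proc_u$values, proc_p$values, samples,
                                config = config)
    hits <- differential_screen(fluid, config)
  } else proc_p <- NULL

  # post-exercise discriminators: q < lmm_q in the case-vs-control contrast
  # at the post timepoint; heatmap values are normalized concentrations
  rpost <- panel$results[panel$results$contrast == "case_vs_ctrl_post", ]
  disc <- rpost$metabolite_id[!is.na(rpost$q) & rpost$q < config$lmm_q]
  clus <- NULL
  if (length(disc)) {
    s_u <- samples[match(rownames(proc_u$centered), samples$sample_id), ]
    post_rows <- s_u$timepoint == "U3"
    hm <- proc_u$centered[post_rows, disc, drop = FALSE]
    rownames(hm) <- s_u$subject_id[post_rows]
    clus <- cluster_subjects(hm, min(cluster_k, nrow(hm)))
  }

  run <- structure(list(
    design = design, config = config, proc_urine = proc_u,
    proc_plasma = proc_p, lmm = panel, fold_changes = fc,
    enrichment_subpathway = enr_sub, enrichment_cluster = enr_clu,
    topology = topology, fluidcorr = fluid, screen_hits = hits,
    cluster = clus, discriminators = disc,
    samples = samples, annotation = annot), class = "uromet_run")
  run$summary <- run_summary(run)
  run
}

#' Summary counts of a pipeline run
#' @param run a `uromet_run`.
#' @return named list of counts at the configured thresholds.
#' @export
run_summary <- function(run) {
  cfg <- run$config
  res <- run$lmm$results
  sig <- function(cn) sum(res$q[res$contrast == cn] < cfg$lmm_q,
                          na.rm = TRUE)
  enr_n <- function(e, thr) if (is.null(e)) 0L else
    sum(vapply(e, function(x)
      sum(x$records$q < thr, na.rm = TRUE), 0L))
  list(
    n_metabolites_measured = nrow(run$proc_urine$filter) +
      length(run$proc_urine$dropped),
    n_metabolites_retained = length(run$proc_urine$retained),
    n_sig_case_vs_ctrl_baseline = sig("case_vs_ctrl_baseline"),
    n_sig_case_vs_ctrl_post = sig("case_vs_ctrl_post"),
    n_sig_post_vs_base_ctrl = sig("post_vs_base_ctrl"),
    n_sig_post_vs_base_case = sig("post_vs_base_case"),
    n_sig_interaction = sig("interaction"),
    n_enriched_subpathways = enr_n(run$enrichment_subpathway,
                                   cfg$subpathway_q),
    n_enriched_clusters = enr_n(run$enrichment_cluster, cfg$cluster_q),
    n_sig_pathways_post = if (is.null(run$topology)) 0L else
      sum(run$topology$post$significant),
    n_sig_pathways_ratio = if (is.null(run$topology)) 0L else
      sum(run$topology$ratio$significant),
    n_shared_compounds = if (is.null(run$fluidcorr)) 0L else
      nrow(run$fluidcorr$outliers),
    n_screen_hits = if (is.null(run$screen_hits)) 0L else
      nrow(run$screen_hits),
    n_cluster_subjects = if (is.null(run$cluster)) 0L else
      length(run$cluster$assignment))
}

#' Write the report bundle
#'
#' Emits the nine plot-ready tables (volcano, enrichment records and
#' bubbles, topology, subject heatmap, subject trajectories, correlation
#' census, correlation records, screen heatmap) plus a JSON run summary.
#' Every table is sliced from the canonical stage outputs; nothing is
#' recomputed at report time.
#'
#' @param run a `uromet_run`.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
report_bundle <- function(run, dir) {
  if (is.null(run$lmm)) stop("report_bundle: missing stage 'lmm'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  cfg <- run$config
  volc <- do.call(rbind, lapply(rownames(contrast_matrix()), function(cn)
    cbind(contrast = cn, volcano_table(run$lmm, cn, cfg$lmm_q))))
  w(volc, "volcano.tsv")
  enr <- do.call(rbind, lapply(names(run$enrichment_subpathway), function(nm)
    cbind(comparison = nm, run$enrichment_subpathway[[nm]]$records)))
  w(enr, "enrichment_subpathway.tsv")
  w(bubble_table(run$enrichment_subpathway, cfg$subpathway_q),
    "enrichment_bubble.tsv")
  topo <- if (is.null(run$topology))
    data.frame(comparison = character(), pathway_id = character()) else
      rbind(cbind(comparison = "case_vs_ctrl_post", run$topology$post),
            cbind(comparison = "interaction", run$topology$ratio))
  w(topo, "topology.tsv")
  hm <- if (is.null(run$cluster))
    data.frame(subject_id = character(), metabolite_id = character(),
               value = numeric(), cluster = integer()) else {
      s_u <- run$samples[match(rownames(run$proc_urine$centered),
                               run$samples$sample_id), ]
      post_rows <- which(s_u$timepoint == "U3")
      vals <- run$proc_urine$centered[post_rows, run$discriminators,
                                      drop = FALSE]
      data.frame(subject_id = rep(s_u$subject_id[post_rows],
                                  ncol(vals)),
                 metabolite_id = rep(colnames(vals),
                                     each = nrow(vals)),
                 value = as.vector(vals),
                 cluster = rep(unname(
                   run$cluster$assignment[s_u$subject_id[post_rows]]),
                   ncol(vals)), stringsAsFactors = FALSE)
    }
  w(hm, "cluster_heatmap.tsv")
  # per-subject trajectories of interaction-significant compounds
  ri <- run$lmm$results[run$lmm$results$contrast == "interaction", ]
  traj_ids <- ri$metabolite_id[!is.na(ri$q) & ri$q < cfg$lmm_q]
  s_u <- run$samples[match(rownames(run$proc_urine$values),
                           run$samples$sample_id), ]
  traj <- if (length(traj_ids)) {
    vals <- run$proc_urine$values[, traj_ids, drop = FALSE]
    data.frame(subject_id = rep(s_u$subject_id, ncol(vals)),
               cohort = rep(s_u$cohort, ncol(vals)),
               timepoint = rep(s_u$timepoint, ncol(vals)),
               metabolite_id = rep(colnames(vals), each = nrow(vals)),
               value = as.vector(vals), stringsAsFactors = FALSE)
  } else data.frame(subject_id = character(), cohort = character(),
                    timepoint = character(), metabolite_id = character(),
                    value = numeric(), stringsAsFactors = FALSE)
  w(traj, "trajectories.tsv")
  cens <- if (is.null(run$fluidcorr))
    data.frame(cohort = character(), pairing_id = character()) else
      run$fluidcorr$census
  w(cens, "correlation_census.tsv")
  recs <- if (is.null(run$fluidcorr))
    data.frame(metabolite_id = character()) else run$fluidcorr$records
  w(recs, "correlation_records.tsv")
  empty_hits <- data.frame(metabolite_id = character(),
                           pairing_id = character(), kind = character(),
                           r_case = numeric(), r_control = numeric(),
                           q_case = numeric(), q_control = numeric(),
                           sig_cohort = character(), stringsAsFactors = FALSE)
  w(screen_heatmap(if (is.null(run$screen_hits)) empty_hits else
    run$screen_hits), "screen_heatmap.tsv")
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(dir, "summary.json"))
  invisible(paths)
}
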