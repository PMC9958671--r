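# ---------------------------------------------------------------------------
# Pathway quantitative enrichment + topology impact. Each pathway graph is
# scored two ways: (i) a global test of whether its matched metabolites
# separate the cohorts -- the score statistic Q = ||X'(y - ybar)||^2 / m on
# the column-standardized matched matrix, with inference by label
# permutation; (ii) an impact score, the sum over matched nodes of the
# relative betweenness centrality (per-pathway max-normalized).
# ---------------------------------------------------------------------------

#' Match annotated metabolites to pathway nodes by HMDB id
#'
#' Only metabolites with an HMDB id participate. When several metabolites
#' share one HMDB id, only the first in annotation order is kept (the
#' duplicates are logged as dropped).
#'
#' @param annot metabolite annotation (`metabolite_id`, `hmdb_id`).
#' @param graphs pathway graph list ([read_pathway_graphs()] format).
#' @param metabolites optional restriction (e.g. the filter-retained set).
#' @return data frame `metabolite_id`, `hmdb_id` for compounds whose id
#'   occurs in at least one pathway; attribute `"dropped_duplicates"` lists
#'   the later duplicates.
#' @export
match_hmdb <- function(annot, graphs, metabolites = NULL) {
  a <- annot[!is.na(annot$hmdb_id), , drop = FALSE]
  if (!is.null(metabolites))
    a <- a[a$metabolite_id %in% metabolites, , drop = FALSE]
  dup <- duplicated(a$hmdb_id)
  dropped <- a$metabolite_id[dup]
  if (length(dropped))
    pipe_log("topology", "first-duplicate rule dropped %d metabolite(s): %s",
             length(dropped), paste(utils::head(dropped, 5L), collapse = ", "))
  a <- a[!dup, , drop = FALSE]
  all_nodes <- unique(unlist(lapply(graphs, `[[`, "nodes")))
  a <- a[a$hmdb_id %in% all_nodes, , drop = FALSE]
  pipe_log("topology", "%d metabolite(s) matched to pathway nodes", nrow(a))
  out <- data.frame(metabolite_id = a$metabolite_id, hmdb_id = a$hmdb_id,
                    stringsAsFactors = FALSE)
  attr(out, "dropped_duplicates") <- dropped
  out
}

#' Relative betweenness centrality of pathway nodes
#'
#' Betweenness with standard Brandes semantics (unweighted shortest paths,
#' fractional credit for ties, endpoints excluded), divided by the pathway
#' maximum so the most central node scores 1. If every centrality is 0
#' (complete graphs, 2-node graphs, isolated nodes) all importances are 0.
#'
#' @param graph one pathway graph (list with `edges`, `nodes`).
#' @return named numeric vector of importances in `[0, 1]`.
#' @export
node_importance <- function(graph) {
  nodes <- graph$nodes
  g <- igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  b <- b[nodes]
  mx <- max(b)
  if (mx > 0) b / mx else b * 0
}

#' Permutation global test for one pathway
#'
#' Score statistic `Q = ||X'(y - ybar)||^2 / m` with `X` the
#' column-standardized matched-metabolite matrix (n samples x m matched
#' metabolites) and `y` the 0/1 cohort labels; null hypothesis: no
#' metabolite in the pathway differs between the groups. The p-value is
#' empirical over `n_perm` label permutations with add-one smoothing,
#' `p = (1 + #{Q_perm >= Q_obs}) / (n_perm + 1)`.
#'
#' @param X matrix of matched metabolite values, rows = samples/subjects.
#' @param y binary labels (0/1 or a two-level factor).
#' @param n_perm number of permutations.
#' @return list: `Q`, `p`, `m` (matched metabolites used).
#' @export
global_test <- function(X, y, n_perm = 9999L) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) y <- as.numeric(factor(y)) - 1
  if (length(unique(y)) != 2L) stop("global test needs both labels present")
  if (ncol(X) < 2L) stop("global test needs >= 2 matched metabolites")
  keep <- apply(X, 2L, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 1L) stop("no matched metabolite with variance")
  Xs <- scale(X)
  m <- ncol(Xs)
  qstat <- function(yy) sum(crossprod(Xs, yy - mean(yy))^2) / m
  q_obs <- qstat(y)
  q_perm <- vapply(seq_len(n_perm), function(i) qstat(sample(y)), 0)
  list(Q = q_obs, p = (1 + sum(q_perm >= q_obs - 1e-12)) / (n_perm + 1),
       m = m)
}

#' Pathway topology report
#'
#' Runs the global test and the impact score over every pathway with at
#' least two matched metabolites present in the value matrix, then
#' BH-adjusts the global-test p-values across pathways.
#'
#' @param graphs pathway graph list.
#' @param mapping [match_hmdb()] output.
#' @param values matrix rows = analysis units (samples for a timepoint
#'   comparison, subjects for a ratio comparison), columns = metabolites.
#' @param labels cohort label per row of `values`.
#' @param n_perm permutations per pathway.
#' @param seed integer seed for the permutations.
#' @param topology_q significance threshold.
#' @return data frame: pathway_id, n_matched, Q, global_p, q, impact,
#'   significant.
#' @export
topology_report <- function(graphs, mapping, values, labels,
                            n_perm = 9999L, seed = 1L, topology_q = 0.2) {
  set.seed(seed)
  rows <- lapply(graphs, function(g) {
    map <- mapping[mapping$hmdb_id %in% g$nodes, , drop = FALSE]
    map <- map[map$metabolite_id %in% colnames(values), , drop = FALSE]
    if (nrow(map) < 2L) {
      pipe_log("topology", "pathway '%s': %d matched metabolite(s); skipped",
               g$pathway_id, nrow(map))
      return(NULL)
    }
    imp <- node_importance(g)
    gt <- global_test(values[, map$metabolite_id, drop = FALSE], labels,
                      n_perm)
    data.frame(pathway_id = g$pathway_id, n_matched = nrow(map),
               Q = gt$Q, global_p = gt$p,
               impact = sum(imp[map$hmdb_id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway_id = character(), n_matched = integer(),
                      Q = numeric(), global_p = numeric(), q = numeric(),
                      impact = numeric(), significant = logical()))
  out$q <- bh_adjust(out$global_p)
  out$significant <- out$q < topology_q
  rownames(out) <- NULL
  pipe_log("topology", "%d pathway(s) tested, %d significant at q<%g",
           nrow(out), sum(out$significant), topology_q)
  out[, c("pathway_id", "n_matched", "Q", "global_p", "q", "impact",
          "significant")]
}
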