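# ---------------------------------------------------------------------------
# Synthetic paired urine + plasma study generator. The generative model for
# the log10 latent urine value of subject j, metabolite m at timepoint t is
#
#   x = mu_m + u_j + a_m*age_j + b_m*bmi_j + delta_m*[case]
#       + gamma_m*[t=U3] + eta_m*[case & t=U3] + z_jm + r_jm*[t=U3] + eps
#
# with subject intercept u_j ~ N(0, sigma_u^2), a subject-by-metabolite
# deviate z_jm shared (with correlation rho_m) between fluids, a
# post-exercise response deviate r_jm (also rho_m-coupled across fluids),
# and residual eps ~ N(0, sigma_e^2). The raw stored urine value is
# osmolality_s * 10^x; cells with 10^x below the per-metabolite detection
# limit L_m are left-censored to missing. "Responder" subpathways carry
# gamma_m > 0 and eta_m = -gamma_m, i.e. a post-exercise increase in
# controls that the cases do not show.
# ---------------------------------------------------------------------------

#' Construct a simulation scenario
#'
#' Defaults mirror the emulated study: 8 control + 10 case female subjects,
#' 2 urine timepoints (baseline U1, 24 h post-exercise U3), 4 plasma
#' timepoints (P1--P4), 1403 metabolites of which roughly 63% are known and
#' annotated into non-overlapping subpathways, responder subpathways with a
#' post-exercise increase of 0.3 log10 units in controls only, left-censored
#' missingness calibrated so that roughly 80% of metabolites survive the
#' modified 80% rule, and per-sample log-normal urine osmolality.
#'
#' @param n_control,n_case subjects per cohort.
#' @param n_metabolites total metabolites on the panel.
#' @param layout optional subpathway layout, a data frame with columns
#'   `subpathway`, `superpathway`, `size`; default built by
#'   [default_layout()].
#' @param responder_frac fraction of subpathways designated responders.
#' @param gamma post-exercise log10 increase in controls for responder
#'   metabolites.
#' @param delta cohort (case - control) baseline offset for responder
#'   metabolites; 0 reproduces the "no baseline differences" regime.
#' @param sigma_u subject random-intercept SD (log10 units).
#' @param sigma_e residual SD (log10 units).
#' @param sigma_met subject-by-metabolite deviate SD (shared across fluids).
#' @param sigma_resp subject-by-metabolite post-exercise response SD.
#' @param rho cross-fluid coupling of the latent deviates, in `[-1, 1]`.
#' @param age_slope_sd,bmi_slope_sd SDs of per-metabolite covariate slopes.
#' @param drug_frac fraction of metabolites flagged drug/tobacco.
#' @param osmo_meanlog,osmo_sdlog log-normal parameters of urine osmolality
#'   (mOsm/kg).
#' @param miss_hi_frac fraction of metabolites with high censoring rates.
#' @param miss_lo_max upper bound of the (low) censoring rate of the
#'   remaining metabolites; 0 disables censoring for them entirely.
#' @param seed integer; fully determines the generated study.
#' @return list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_control = 8L, n_case = 10L, n_metabolites = 1403L,
                         layout = NULL, responder_frac = 0.1,
                         gamma = 0.3, delta = 0,
                         sigma_u = 0.1, sigma_e = 0.15,
                         sigma_met = 0.2, sigma_resp = 0.1, rho = 0.8,
                         age_slope_sd = 0.003, bmi_slope_sd = 0.005,
                         drug_frac = 0.03,
                         osmo_meanlog = log(600), osmo_sdlog = 0.35,
                         miss_hi_frac = 0.2, miss_lo_max = 0.05,
                         seed = 20230212L) {
  if (n_control < 1L || n_case < 1L || n_metabolites < 1L)
    stop("cohort sizes and metabolite count must be positive")
  if (any(c(sigma_u, sigma_e, sigma_met, sigma_resp) < 0))
    stop("SDs must be >= 0")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  structure(list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    n_metabolites = as.integer(n_metabolites), layout = layout,
    responder_frac = responder_frac, gamma = gamma, delta = delta,
    sigma_u = sigma_u, sigma_e = sigma_e, sigma_met = sigma_met,
    sigma_resp = sigma_resp, rho = rho,
    age_slope_sd = age_slope_sd, bmi_slope_sd = bmi_slope_sd,
    drug_frac = drug_frac, osmo_meanlog = osmo_meanlog,
    osmo_sdlog = osmo_sdlog, miss_hi_frac = miss_hi_frac,
    miss_lo_max = miss_lo_max,
    seed = as.integer(seed)), class = "sim_scenario")
}

#' Default subpathway layout
#'
#' Splits a panel into known / partially characterized / unknown compounds
#' in the proportions of a typical untargeted urine panel (886 : 64 : 453
#' out of 1403) and assigns the known compounds to non-overlapping
#' subpathways of ~10 members nested in six superpathways.
#'
#' @param n_metabolites panel size.
#' @return data frame with one row per subpathway plus attributes
#'   `n_known`, `n_partial`, `n_unknown`.
#' @export
default_layout <- function(n_metabolites) {
  n_known <- max(1L, round(n_metabolites * 886 / 1403))
  n_partial <- round(n_metabolites * 64 / 1403)
  n_unknown <- n_metabolites - n_known - n_partial
  supers <- c("Amino Acid", "Carbohydrate", "Cofactors and Vitamins",
              "Lipid", "Nucleotide", "Xenobiotics")
  n_sub <- max(length(supers), round(n_known / 10))
  base <- n_known %/% n_sub
  sizes <- rep(base, n_sub)
  extra <- n_known - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  df <- data.frame(
    subpathway = sprintf("Subpathway %02d", seq_len(n_sub)),
    superpathway = supers[((seq_len(n_sub) - 1L) %% length(supers)) + 1L],
    size = sizes, stringsAsFactors = FALSE)
  attr(df, "n_known") <- n_known
  attr(df, "n_partial") <- n_partial
  attr(df, "n_unknown") <- n_unknown
  df
}

# correlated pair of standard-normal matrices: (a, rho*a + sqrt(1-rho^2)*b)
rho_pair <- function(n, m, rho, sd) {
  a <- matrix(stats::rnorm(n * m), n, m)
  b <- matrix(stats::rnorm(n * m), n, m)
  list(x = sd * a, y = sd * (rho * a + sqrt(1 - rho^2) * b))
}

#' Simulate a paired urine + plasma exercise-response study
#'
#' @param scenario a [sim_scenario()].
#' @return list with components `urine` and `plasma` (raw abundance
#'   matrices, samples x metabolites, `NA` = not detected), `samples`
#'   (metadata for both fluids), `annotation`, and `truth` (per-metabolite
#'   generative parameters plus the responder subpathway list).
#' @export
simulate_study <- function(scenario = sim_scenario()) {
  sc <- scenario
  set.seed(sc$seed)
  n_subj <- sc$n_control + sc$n_case
  subject_id <- c(sprintf("C%02d", seq_len(sc$n_control)),
                  sprintf("M%02d", seq_len(sc$n_case)))
  cohort <- rep(c("control", "mecfs"), c(sc$n_control, sc$n_case))
  is_case <- cohort == "mecfs"
  age <- round(stats::runif(n_subj, 45, 60), 1)
  bmi <- round(ifelse(is_case, stats::rnorm(n_subj, 25, 4),
                      stats::rnorm(n_subj, 33, 4)), 1)
  bmi <- pmax(bmi, 18)

  layout <- if (is.null(sc$layout)) default_layout(sc$n_metabolites) else
    sc$layout
  n_known <- if (!is.null(attr(layout, "n_known"))) attr(layout, "n_known") else
    sum(layout$size)
  n_partial <- if (!is.null(attr(layout, "n_partial")))
    attr(layout, "n_partial") else 0L
  n_unknown <- sc$n_metabolites - n_known - n_partial
  if (sum(layout$size) != n_known)
    stop("layout sizes must sum to the known-compound count")
  m <- sc$n_metabolites

  status <- rep(c("known", "partially_characterized", "unknown"),
                c(n_known, n_partial, n_unknown))
  subpath <- c(rep(layout$subpathway, layout$size),
               rep(NA_character_, n_partial + n_unknown))
  superpath <- c(rep(layout$superpathway, layout$size),
                 rep(NA_character_, n_partial + n_unknown))
  metabolite_id <- sprintf("MET%04d", seq_len(m))
  name <- ifelse(status == "known", sprintf("compound-%04d", seq_len(m)),
                 ifelse(status == "unknown", sprintf("X-%05d", 10000 + seq_len(m)),
                        sprintf("partial-%04d", seq_len(m))))
  hmdb_id <- ifelse(status == "known", sprintf("HMDB%07d", seq_len(m)),
                    NA_character_)
  is_drug <- superpath %in% "Xenobiotics" &
    stats::runif(m) < sc$drug_frac / mean(superpath %in% "Xenobiotics",
                                          na.rm = TRUE)
  is_drug[is.na(is_drug)] <- FALSE
  # chemical-similarity clusters: a coarser regrouping of the known panel
  cluster_id <- rep(NA_character_, m)
  kn <- which(status == "known")
  cluster_id[kn] <- sprintf("CL%03d", ((seq_along(kn) - 1L) %/% 15L) + 1L)

  n_resp_sub <- max(1L, round(nrow(layout) * sc$responder_frac))
  responder_subpathways <- layout$subpathway[seq_len(n_resp_sub)]
  responder <- subpath %in% responder_subpathways

  mu <- stats::rnorm(m, 5, 1)
  a_m <- stats::rnorm(m, 0, sc$age_slope_sd)
  b_m <- stats::rnorm(m, 0, sc$bmi_slope_sd)
  delta_m <- ifelse(responder, sc$delta, 0)
  gamma_m <- ifelse(responder, sc$gamma, 0)
  eta_m <- -gamma_m
  rho_m <- rep(sc$rho, m)

  # per-metabolite censoring probability: mostly near zero, a tail high
  hi <- stats::runif(m) < sc$miss_hi_frac
  p_miss <- ifelse(hi, stats::runif(m, 0.15, 0.7),
                   stats::runif(m, 0, sc$miss_lo_max))
  p_miss[is_drug] <- stats::runif(sum(is_drug), 0.3, 0.9)
  sd_marg <- sqrt(sc$sigma_u^2 + sc$sigma_met^2 + sc$sigma_e^2)
  L_m <- 10^(mu + stats::qnorm(p_miss) * pmax(sd_marg, 1e-12))
  L_m[p_miss <= 0] <- 0

  u_j <- stats::rnorm(n_subj, 0, sc$sigma_u)
  zz <- rho_pair(n_subj, m, sc$rho, sc$sigma_met)   # shared level deviate
  rr <- rho_pair(n_subj, m, sc$rho, sc$sigma_resp)  # shared response deviate

  cov_term <- outer(age, a_m) + outer(bmi, b_m) +
    outer(rep(1, n_subj), mu) + u_j + outer(as.numeric(is_case), delta_m)

  latent_urine <- function(tp) {
    x <- cov_term + zz$x
    if (tp == "U3")
      x <- x + outer(rep(1, n_subj), gamma_m) +
        outer(as.numeric(is_case), eta_m) + rr$x
    x + matrix(stats::rnorm(n_subj * m, 0, sc$sigma_e), n_subj, m)
  }
  mu_shift <- stats::rnorm(m, 0, 0.3)  # fluid-specific baseline offset
  latent_plasma <- function(tp) {
    x <- cov_term + zz$y + outer(rep(1, n_subj), mu_shift)
    if (tp %in% c("P3", "P4"))
      x <- x + rr$y
    x + matrix(stats::rnorm(n_subj * m, 0, sc$sigma_e), n_subj, m)
  }

  osmo <- stats::rlnorm(2L * n_subj, sc$osmo_meanlog, sc$osmo_sdlog)
  utp <- c("U1", "U3")
  urine <- matrix(NA_real_, 2L * n_subj, m,
                  dimnames = list(paste(rep(subject_id, 2L),
                                        rep(utp, each = n_subj), sep = "_"),
                                  metabolite_id))
  for (k in 1:2) {
    x <- latent_urine(utp[k])
    raw <- 10^x
    raw[sweep(raw, 2L, L_m, "<")] <- NA_real_
    rows <- seq_len(n_subj) + (k - 1L) * n_subj
    urine[rows, ] <- raw * osmo[rows]
  }
  ptp <- c("P1", "P2", "P3", "P4")
  plasma <- matrix(NA_real_, 4L * n_subj, m,
                   dimnames = list(paste(rep(subject_id, 4L),
                                         rep(ptp, each = n_subj), sep = "_"),
                                   metabolite_id))
  for (k in 1:4) {
    x <- latent_plasma(ptp[k])
    raw <- 10^x
    raw[sweep(raw, 2L, L_m, "<")] <- NA_real_
    plasma[seq_len(n_subj) + (k - 1L) * n_subj, ] <- raw
  }

  samples <- rbind(
    data.frame(sample_id = rownames(urine),
               subject_id = rep(subject_id, 2L),
               cohort = rep(cohort, 2L), fluid = "urine",
               timepoint = rep(utp, each = n_subj),
               age = rep(age, 2L), bmi = rep(bmi, 2L),
               osmolality = osmo, stringsAsFactors = FALSE),
    data.frame(sample_id = rownames(plasma),
               subject_id = rep(subject_id, 4L),
               cohort = rep(cohort, 4L), fluid = "plasma",
               timepoint = rep(ptp, each = n_subj),
               age = rep(age, 4L), bmi = rep(bmi, 4L),
               osmolality = NA_real_, stringsAsFactors = FALSE))

  annotation <- data.frame(
    metabolite_id = metabolite_id, name = name, superpathway = superpath,
    subpathway = subpath, is_drug_or_tobacco = is_drug, status = status,
    hmdb_id = hmdb_id, cluster_id = cluster_id, stringsAsFactors = FALSE)

  truth <- list(
    params = data.frame(metabolite_id = metabolite_id, mu = mu,
                        delta = delta_m, gamma = gamma_m, eta = eta_m,
                        rho = rho_m, age_slope = a_m, bmi_slope = b_m,
                        detect_limit = L_m, p_miss = p_miss,
                        responder = responder, stringsAsFactors = FALSE),
    responder_subpathways = responder_subpathways,
    subjects = data.frame(subject_id = subject_id, cohort = cohort,
                          age = age, bmi = bmi, intercept = u_j,
                          stringsAsFactors = FALSE))
  list(urine = urine, plasma = plasma, samples = validate_sample_info(samples),
       annotation = validate_annotation(annotation), truth = truth)
}

#' Small deterministic fixture for tests and examples
#'
#' A 4 control + 4 case study with 60 metabolites in 6 subpathways
#' (the first designated responder), amended so that the edge cases the
#' preprocessing stage must handle are guaranteed present: one all-missing
#' non-drug metabolite, one drug/tobacco metabolite with missing cells, and
#' a detection-filter boundary pair (one metabolite seen in 7/8 control
#' urine samples, passing the 80% rule, one seen in 6/8, failing it, both
#' absent from every case sample).
#'
#' @param seed integer seed (same seed, byte-identical output).
#' @return same structure as [simulate_study()].
#' @export
fixture_small <- function(seed = 42L) {
  layout <- data.frame(
    subpathway = sprintf("Sub%02d", 1:6),
    superpathway = rep(c("Amino Acid", "Lipid", "Xenobiotics"), each = 2),
    size = c(9L, 9L, 9L, 9L, 9L, 9L), stringsAsFactors = FALSE)
  attr(layout, "n_known") <- 54L
  attr(layout, "n_partial") <- 2L
  attr(layout, "n_unknown") <- 4L
  sim <- simulate_study(sim_scenario(
    n_control = 4L, n_case = 4L, n_metabolites = 60L, layout = layout,
    responder_frac = 1 / 6, miss_hi_frac = 0.1, drug_frac = 0, seed = seed))
  ur <- sim$samples[sim$samples$fluid == "urine", ]
  ctrl_samp <- ur$sample_id[ur$cohort == "control"]
  case_samp <- ur$sample_id[ur$cohort == "mecfs"]
  # all-missing non-drug metabolite
  sim$urine[, "MET0058"] <- NA_real_
  # drug metabolite with missing cells (imputed as 0 downstream)
  sim$annotation$is_drug_or_tobacco[sim$annotation$metabolite_id ==
                                      "MET0050"] <- TRUE
  sim$urine[ctrl_samp[1:3], "MET0050"] <- NA_real_
  # detection-filter boundary pair: 7/8 passes, 6/8 fails (cases all missing)
  sim$urine[, c("MET0059", "MET0060")] <- 10^5
  sim$urine[case_samp, c("MET0059", "MET0060")] <- NA_real_
  sim$urine[ctrl_samp[1L], "MET0059"] <- NA_real_
  sim$urine[ctrl_samp[1:2], "MET0060"] <- NA_real_
  sim
}

#' Build toy pathway graphs from an annotation table
#'
#' One undirected graph per subpathway over its known members' HMDB ids:
#' a path over the members plus a few chords, deterministic given the seed.
#' Used to exercise the topology stage without shipping any reference
#' database.
#'
#' @param annot metabolite annotation with `hmdb_id` and `subpathway`.
#' @param seed integer seed for the chord placement.
#' @return named list of pathway graphs in the [read_pathway_graphs()]
#'   format.
#' @export
toy_pathway_graphs <- function(annot, seed = 1L) {
  set.seed(seed)
  known <- annot[!is.na(annot$subpathway) & !is.na(annot$hmdb_id), ]
  out <- list()
  for (sp in unique(known$subpathway)) {
    nodes <- known$hmdb_id[known$subpathway == sp]
    if (length(nodes) < 2L) next
    edges <- cbind(nodes[-length(nodes)], nodes[-1L])
    if (length(nodes) >= 4L) {
      i <- sample(seq_len(length(nodes) - 3L), 1L)
      edges <- rbind(edges, c(nodes[i], nodes[i + 3L]))
    }
    pid <- paste0("path_", gsub("[^A-Za-z0-9]", "_", sp))
    out[[pid]] <- list(pathway_id = pid, edges = unname(edges), nodes = nodes)
  }
  out
}

#' Write a simulated study to disk
#'
#' Emits the five tabular artifacts (urine and plasma abundance TSVs,
#' sample metadata, annotation, pathway edge list) plus a JSON ground-truth
#' file.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(sim$urine, file.path(dir, "urine_raw.tsv"))
  write_abundance(sim$plasma, file.path(dir, "plasma_raw.tsv"))
  write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  graphs <- toy_pathway_graphs(sim$annotation)
  edges <- do.call(rbind, lapply(graphs, function(g)
    data.frame(pathway_id = g$pathway_id, node_a = g$edges[, 1L],
               node_b = g$edges[, 2L], stringsAsFactors = FALSE)))
  write_tsv(edges, file.path(dir, "pathway_graphs.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
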