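# ---------------------------------------------------------------------------
# Abundance tables are plain numeric matrices, samples in rows, metabolites
# in columns, NA marking a non-detected (missing) cell. Missing is a state
# distinct from 0: a 0 is a legal measured value (drug compounds are imputed
# to 0 downstream and must survive).
# ---------------------------------------------------------------------------

validate_abundance <- function(mat, what = "abundance table") {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop(what, " must have sample row names and metabolite column names")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate sample id(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate metabolite id(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  vals <- mat[!is.na(mat)]
  if (any(!is.finite(vals))) stop(what, " contains non-finite values")
  if (any(vals < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at sample '%s', metabolite '%s'",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  mat
}

#' Read a sample-by-metabolite abundance matrix
#'
#' Accepts either wide format (first column sample ids, remaining columns one
#' per metabolite) or long format (exactly three columns: sample id,
#' metabolite id, value); the layout is autodetected from the header. Empty
#' cells, `""` and `"NA"` parse as missing. Values must be finite and
#' non-negative; duplicate keys are a hard error naming the offender.
#'
#' @param path path to a delimited text file.
#' @param dialect `"tsv"` or `"csv"`; default guessed from the extension.
#' @return numeric matrix (samples x metabolites) with `NA` for missing.
#' @export
read_abundance <- function(path, dialect = c("auto", "tsv", "csv")) {
  stopifnot(file.exists(path))
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("NA", ""), check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("abundance file needs at least two columns")
  long <- ncol(df) == 3L && !is.numeric(df[[2L]])
  if (long) {
    key <- paste(df[[1L]], df[[2L]], sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE]
      stop(sprintf("duplicate (sample, metabolite) pair: ('%s', '%s')",
                   d[1L, 1L], d[1L, 2L]))
    }
    samp <- unique(as.character(df[[1L]]))
    met <- unique(as.character(df[[2L]]))
    mat <- matrix(NA_real_, length(samp), length(met),
                  dimnames = list(samp, met))
    mat[cbind(match(df[[1L]], samp), match(df[[2L]], met))] <-
      as.numeric(df[[3L]])
  } else {
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate sample id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mat <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- ids
  }
  validate_abundance(mat)
}

#' Write an abundance matrix
#'
#' Wide format is canonical on output. Doubles are serialized with 17
#' significant digits so that a read/write round trip is bit-exact; missing
#' cells are written as empty fields.
#'
#' @param mat numeric matrix, samples in rows.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(mat, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  validate_abundance(mat)
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  chr[is.na(mat)] <- ""
  lines <- c(paste(c("sample_id", colnames(mat)), collapse = sep),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i], chr[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Required columns: `sample_id`, `subject_id`, `cohort`
#' (`control`/`mecfs`), `fluid` (`urine`/`plasma`), `timepoint`
#' (`U1`/`U3` for urine, `P1`--`P4` for plasma), `age`, `bmi`, and
#' `osmolality` (may be missing for plasma rows).
#'
#' @param path delimited text file (TSV or CSV by extension).
#' @return validated data frame.
#' @export
read_sample_info <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  validate_sample_info(df)
}

#' Validate sample metadata
#'
#' Enforces the design invariants: legal cohort/fluid/timepoint levels, at
#' most one sample per (subject, fluid, timepoint), positive osmolality on
#' every urine sample, and age/BMI constant within subject.
#'
#' @param samples data frame of sample metadata.
#' @return the validated data frame (invisibly the same object).
#' @export
validate_sample_info <- function(samples) {
  need <- c("sample_id", "subject_id", "cohort", "fluid", "timepoint",
            "age", "bmi")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"osmolality" %in% names(samples)) samples$osmolality <- NA_real_
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  if (!all(samples$cohort %in% c("control", "mecfs")))
    stop("cohort must be 'control' or 'mecfs'")
  if (!all(samples$fluid %in% c("urine", "plasma")))
    stop("fluid must be 'urine' or 'plasma'")
  uok <- samples$fluid != "urine" | samples$timepoint %in% c("U1", "U3")
  pok <- samples$fluid != "plasma" |
    samples$timepoint %in% c("P1", "P2", "P3", "P4")
  if (!all(uok & pok)) stop("illegal timepoint for fluid")
  key <- with(samples, paste(subject_id, fluid, timepoint))
  if (anyDuplicated(key))
    stop("duplicate (subject, fluid, timepoint): ", key[duplicated(key)][1L])
  ur <- samples$fluid == "urine"
  if (any(ur & (is.na(samples$osmolality) | samples$osmolality <= 0)))
    stop("every urine sample needs osmolality > 0; offender: ",
         samples$sample_id[ur & (is.na(samples$osmolality) |
                                   samples$osmolality <= 0)][1L])
  for (v in c("age", "bmi")) {
    spread <- tapply(samples[[v]], samples$subject_id,
                     function(x) diff(range(x)))
    if (any(spread > 1e-8))
      stop(v, " must be constant within subject; offender: ",
           names(spread)[spread > 1e-8][1L])
  }
  samples
}

#' Read metabolite annotation
#'
#' Required columns: `metabolite_id`, `name`, `superpathway`, `subpathway`,
#' `is_drug_or_tobacco` (logical), `status` (`known`,
#' `partially_characterized`, `unknown`); optional `hmdb_id`, `cluster_id`.
#' Subpathway assignments are non-overlapping by construction (one row,
#' hence one subpathway, per metabolite).
#'
#' @param path delimited text file (TSV or CSV by extension).
#' @return validated data frame.
#' @export
read_annotation <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  validate_annotation(df)
}

#' Validate metabolite annotation
#' @param annot data frame of metabolite annotation.
#' @return the validated data frame.
#' @export
validate_annotation <- function(annot) {
  need <- c("metabolite_id", "name", "superpathway", "subpathway",
            "is_drug_or_tobacco", "status")
  miss <- setdiff(need, names(annot))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"hmdb_id" %in% names(annot)) annot$hmdb_id <- NA_character_
  if (!"cluster_id" %in% names(annot)) annot$cluster_id <- NA_character_
  if (anyDuplicated(annot$metabolite_id))
    stop("duplicate metabolite_id: ",
         annot$metabolite_id[duplicated(annot$metabolite_id)][1L])
  if (!all(annot$status %in% c("known", "partially_characterized", "unknown")))
    stop("status must be known / partially_characterized / unknown")
  annot$is_drug_or_tobacco <- as.logical(annot$is_drug_or_tobacco)
  if (anyNA(annot$is_drug_or_tobacco))
    stop("is_drug_or_tobacco must be TRUE/FALSE")
  annot
}

#' Read pathway graphs from a three-column edge list
#'
#' Format: TSV with columns `pathway_id`, `node_a`, `node_b` (node ids in
#' the HMDB namespace); an optional companion node-list file (`pathway_id`,
#' `node`) declares isolated nodes. Self-loops are rejected.
#'
#' @param path edge-list TSV.
#' @param node_path optional node-list TSV for isolated nodes.
#' @return named list of pathway graphs, each a list with `edges`
#'   (2-column character matrix) and `nodes` (character vector).
#' @export
read_pathway_graphs <- function(path, node_path = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "node_a", "node_b") %in% names(df)))
    stop("edge list needs columns pathway_id, node_a, node_b")
  if (any(df$node_a == df$node_b)) stop("self-loop in pathway edge list")
  extra <- NULL
  if (!is.null(node_path)) {
    extra <- utils::read.table(node_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    if (!all(c("pathway_id", "node") %in% names(extra)))
      stop("node list needs columns pathway_id, node")
  }
  ids <- unique(c(df$pathway_id, extra$pathway_id))
  out <- lapply(ids, function(pid) {
    e <- as.matrix(df[df$pathway_id == pid, c("node_a", "node_b"),
                      drop = FALSE])
    n <- unique(c(e[, 1L], e[, 2L],
                  if (!is.null(extra)) extra$node[extra$pathway_id == pid]))
    list(pathway_id = pid, edges = unname(e), nodes = n)
  })
  names(out) <- ids
  out
}

#' Summarize and validate the study design
#'
#' Reports subjects per cohort x fluid x timepoint, flags subjects missing
#' a timepoint (paired analyses downstream only use complete pairs), and
#' warns when a cohort has fewer than 3 subjects (a Pearson correlation at
#' n < 3 has no degrees of freedom and errors downstream).
#'
#' @param samples validated sample metadata.
#' @return list with `counts` (cohort x fluid x timepoint table of subject
#'   counts), `subjects_per_cohort`, and `incomplete` (data frame of
#'   subject/fluid combinations lacking a timepoint).
#' @export
validate_design <- function(samples) {
  samples <- validate_sample_info(samples)
  counts <- with(samples, table(cohort = cohort, fluid = fluid,
                                timepoint = timepoint))
  subj <- unique(samples[, c("subject_id", "cohort")])
  per_cohort <- table(subj$cohort)
  expected <- list(urine = c("U1", "U3"), plasma = c("P1", "P2", "P3", "P4"))
  inc <- list()
  for (fl in unique(samples$fluid)) {
    sf <- samples[samples$fluid == fl, ]
    for (sid in unique(sf$subject_id)) {
      missing_tp <- setdiff(expected[[fl]],
                            sf$timepoint[sf$subject_id == sid])
      if (length(missing_tp))
        inc[[length(inc) + 1L]] <- data.frame(
          subject_id = sid, fluid = fl,
          missing = paste(missing_tp, collapse = ","))
    }
  }
  inc <- if (length(inc)) do.call(rbind, inc) else
    data.frame(subject_id = character(), fluid = character(),
               missing = character())
  for (co in c("control", "mecfs")) {
    n <- if (co %in% names(per_cohort)) per_cohort[[co]] else 0L
    if (n < 3L)
      warning(sprintf("cohort '%s' has %d subject(s); correlations need >= 3",
                      co, n))
  }
  if (sum(samples$fluid == "urine") == 0L)
    warning("no urine samples in metadata")
  pipe_log("design", "%d subjects (%s); %d incomplete subject/fluid pairs",
           nrow(subj),
           paste(sprintf("%s: %d", names(per_cohort), per_cohort),
                 collapse = ", "),
           nrow(inc))
  list(counts = counts, subjects_per_cohort = per_cohort, incomplete = inc)
}

# Subjects of a fluid having every expected timepoint (complete pairs rule).
complete_subjects <- function(samples, fluid,
                              timepoints = if (fluid == "urine")
                                c("U1", "U3") else c("P1", "P2", "P3", "P4")) {
  sf <- samples[samples$fluid == fluid, ]
  keep <- vapply(unique(sf$subject_id), function(sid)
    all(timepoints %in% sf$timepoint[sf$subject_id == sid]), TRUE)
  unique(sf$subject_id)[keep]
}

#' Write a results data frame as TSV
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
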