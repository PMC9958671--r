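# ---------------------------------------------------------------------------
# Per-metabolite linear mixed model
#
#   value ~ cohort * timepoint + age + bmi + (1 | subject)
#
# fitted by REML with the single variance ratio theta = sigma_u^2/sigma_e^2
# profiled out: for fixed theta, GLS gives beta(theta) and sigma_e^2(theta)
# in closed form, and theta is found by a coarse log-grid followed by
# golden-section refinement. Because the random structure (Z Z', with Z the
# subject incidence matrix) is identical for every metabolite, it is
# eigendecomposed once per dataset; each theta evaluation is then a
# diagonally weighted least squares, which keeps a full-panel fit cheap.
# Contrast inference uses Satterthwaite degrees of freedom computed from
# the analytic gradient of the contrast variance and the REML information
# of the variance components.
# ---------------------------------------------------------------------------

#' Build the fixed-effect design for the two-timepoint urine model
#'
#' Treatment coding with control/baseline as the reference cell and
#' age/BMI centered at their sample means (contrasts are invariant to the
#' centering; it only makes the intercept a cell mean).
#'
#' @param samples urine sample metadata (one row per sample).
#' @return list: `X` (n x 6 design: intercept, case, post, age, bmi,
#'   case:post), `Z` (n x S subject incidence), `subjects`, `samples`.
#' @export
lmm_design <- function(samples) {
  s <- samples[samples$fluid == "urine", , drop = FALSE]
  keep_subj <- complete_subjects(s, "urine")
  s <- s[s$subject_id %in% keep_subj, , drop = FALSE]
  s <- s[order(s$subject_id, s$timepoint), , drop = FALSE]
  case <- as.numeric(s$cohort == "mecfs")
  post <- as.numeric(s$timepoint == "U3")
  X <- cbind(intercept = 1, case = case, post = post,
             age = s$age - mean(s$age), bmi = s$bmi - mean(s$bmi),
             case_post = case * post)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  subjects <- unique(s$subject_id)
  Z <- outer(s$subject_id, subjects, "==") * 1
  colnames(Z) <- subjects
  n_per <- table(s$cohort[!duplicated(s$subject_id)])
  for (co in c("control", "mecfs"))
    if (!co %in% names(n_per) || n_per[[co]] < 2L)
      stop("need >= 2 subjects with both timepoints in cohort ", co)
  list(X = X, Z = Z, subjects = subjects, samples = s)
}

# One-time spectral precomputation shared by every metabolite:
# ZZ' = Q diag(lam) Q'; in the rotated basis Sigma(theta) is diagonal.
lmm_precompute <- function(design) {
  ZZt <- tcrossprod(design$Z)
  eig <- eigen(ZZt, symmetric = TRUE)
  Q <- eig$vectors
  lam <- pmax(eig$values, 0)
  list(Q = Q, lam = lam, Xt = crossprod(Q, design$X), X = design$X,
       n = nrow(design$X), p = ncol(design$X), design = design)
}

# Profiled REML deviance (up to an additive constant); smaller is better.
reml_dev <- function(theta, yt, pre) {
  w <- 1 / (1 + theta * pre$lam)
  XtW <- pre$Xt * w
  XtWX <- crossprod(pre$Xt, XtW)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XtW, yt)))
  r <- yt - pre$Xt %*% beta
  rss <- sum(w * r^2)
  if (rss <= 0) return(-Inf)
  (pre$n - pre$p) * log(rss) - sum(log(w)) + 2 * sum(log(diag(ch)))
}

golden_section <- function(f, lo, hi, tol = 1e-9, max_iter = 200L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (i in seq_len(max_iter)) {
    if (b - a < tol) break
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2) }
  }
  if (f1 <= f2) c1 else c2
}

#' Fit the linear mixed model for one metabolite
#'
#' @param y response vector on the transformed scale, ordered as
#'   `design$samples`.
#' @param design output of [lmm_design()] (or a precomputed structure from
#'   repeated fitting).
#' @param theta_max upper search bound for the variance ratio.
#' @return list of class `"lmm_fit"`: `beta` (6 fixed effects), `sigma2_u`,
#'   `sigma2_e`, `theta`, `vcov_beta`, `reml_dev`, `converged`, `boundary`,
#'   plus spectral internals used by [lmm_contrasts()].
#' @export
fit_lmm <- function(y, design, theta_max = 1e6) {
  pre <- if (!is.null(design$Q)) design else lmm_precompute(design)
  stopifnot(length(y) == pre$n)
  yt <- crossprod(pre$Q, y)
  f <- function(lt) reml_dev(exp(lt), yt, pre)
  # coarse bracket on log theta, including the theta = 0 boundary
  lts <- log(10) * seq(-6, log10(theta_max), length.out = 25L)
  devs <- vapply(lts, f, 0)
  dev0 <- reml_dev(0, yt, pre)
  best <- which.min(devs)
  if (is.finite(devs[best]) && devs[best] < dev0) {
    lo <- lts[max(1L, best - 1L)]
    hi <- lts[min(length(lts), best + 1L)]
    lt <- golden_section(f, lo, hi, tol = 1e-10)
    theta <- exp(lt)
    dev <- f(lt)
    if (dev0 <= dev) { theta <- 0; dev <- dev0 }
  } else {
    theta <- 0; dev <- dev0
  }
  boundary <- theta == 0 || theta >= theta_max * (1 - 1e-6)
  converged <- is.finite(dev)
  w <- 1 / (1 + theta * pre$lam)
  XtW <- pre$Xt * w
  XtWX <- crossprod(pre$Xt, XtW)
  beta <- drop(solve(XtWX, crossprod(XtW, yt)))
  r <- drop(yt - pre$Xt %*% beta)
  sigma2_e <- sum(w * r^2) / (pre$n - pre$p)
  names(beta) <- colnames(pre$X)
  structure(list(beta = beta, sigma2_u = theta * sigma2_e,
                 sigma2_e = sigma2_e, theta = theta,
                 vcov_beta = solve(XtWX) * sigma2_e,
                 reml_dev = dev, converged = converged, boundary = boundary,
                 pre = pre, yt = drop(yt)),
            class = "lmm_fit")
}

# Satterthwaite df for contrast c: df = 2 f^2 / (g' A g) with
# f = c' Cov(beta) c, g its gradient w.r.t. (sigma2_u, sigma2_e), and A the
# inverse REML information of the variance components. Everything is
# evaluated in the rotated basis where Sigma = diag(sigma2_u*lam + sigma2_e).
satterthwaite_df <- function(fit, cvec) {
  pre <- fit$pre
  d <- fit$sigma2_u * pre$lam + fit$sigma2_e
  w <- 1 / d
  XtW <- pre$Xt * w
  XtWX <- crossprod(pre$Xt, XtW)
  C <- solve(XtWX)
  f <- drop(t(cvec) %*% C %*% cvec)
  u <- drop(pre$Xt %*% (C %*% cvec))
  g1 <- sum(u^2 * w^2 * pre$lam)   # d f / d sigma2_u
  g2 <- sum(u^2 * w^2)             # d f / d sigma2_e
  # REML information: I_ij = tr(P G_i P G_j)/2, P = W - W X (X'WX)^-1 X'W
  P <- diag(w) - XtW %*% C %*% t(XtW)
  M <- P * P
  lam <- pre$lam
  info <- matrix(c(sum(M * outer(lam, lam)), sum(M %*% lam),
                   sum(M %*% lam), sum(M)), 2L, 2L) / 2
  A <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(A)) return(NA_real_)
  den <- drop(t(c(g1, g2)) %*% A %*% c(g1, g2))
  if (den <= 0) return(NA_real_)
  2 * f^2 / den
}

contrast_matrix <- function() {
  rbind(case_vs_ctrl_baseline = c(0, 1, 0, 0, 0, 0),
        case_vs_ctrl_post     = c(0, 1, 0, 0, 0, 1),
        post_vs_base_ctrl     = c(0, 0, 1, 0, 0, 0),
        post_vs_base_case     = c(0, 0, 1, 0, 0, 1),
        interaction           = c(0, 0, 0, 0, 0, 1))
}

#' Five contrast families from a fitted metabolite model
#'
#' Cohort differences at each timepoint, within-cohort changes over time,
#' and the cohort-by-timepoint interaction (the difference of the two
#' within-cohort changes). Covariates carry zero contrast weight, so the
#' estimates are marginal comparisons at equal age/BMI. Two-sided p-values
#' use a t reference with Satterthwaite (default) or residual
#' (`n_subjects - n_fixed`) degrees of freedom.
#'
#' @param fit an [fit_lmm()] object.
#' @param df_method `"satterthwaite"` or `"residual"`.
#' @return data frame: contrast, estimate, se, df, t, p.
#' @export
lmm_contrasts <- function(fit, df_method = c("satterthwaite", "residual")) {
  df_method <- match.arg(df_method)
  cm <- contrast_matrix()
  n_subj <- ncol(fit$pre$design$Z)
  out <- lapply(rownames(cm), function(nm) {
    cvec <- cm[nm, ]
    est <- drop(cvec %*% fit$beta)
    se <- sqrt(drop(t(cvec) %*% fit$vcov_beta %*% cvec))
    df <- if (df_method == "satterthwaite") satterthwaite_df(fit, cvec) else
      n_subj - fit$pre$p
    if (!is.finite(df) || df <= 0) df <- n_subj - fit$pre$p
    tval <- est / se
    data.frame(contrast = nm, estimate = est, se = se, df = df, t = tval,
               p = 2 * stats::pt(-abs(tval), df), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m p_(j) / j`, mapped back
#' to input order and capped at 1.
#'
#' @param p vector of p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  q
}

#' Fit the mixed model across a metabolite panel
#'
#' Fits every requested metabolite, assembles the five contrast families,
#' and BH-adjusts p-values separately within each contrast family across
#' metabolites. Fold changes on the log2 scale follow the reporting
#' convention: for the interaction the ratio of ratios (mean case
#' post/baseline log10 ratio minus the control one), for single-timepoint
#' contrasts the difference of cohort means of transformed values at that
#' timepoint, and for within-cohort contrasts the mean paired difference.
#'
#' @param proc a `processed_table` for urine (see [preprocess()]).
#' @param samples sample metadata.
#' @param metabolites ids to fit; default the filter-retained set.
#' @param config a [run_config()].
#' @return list of class `"lmm_panel"`: `results` (long data frame:
#'   metabolite_id, contrast, estimate, se, df, t, p, q, log2fc),
#'   `fits_failed` (ids), `design`.
#' @export
fit_all_lmm <- function(proc, samples, metabolites = proc$retained,
                        config = run_config()) {
  design <- lmm_design(samples)
  pre <- lmm_precompute(design)
  vals <- proc$values[design$samples$sample_id, , drop = FALSE]
  metabolites <- intersect(metabolites, colnames(vals))
  ratios <- make_ratios(proc$values, samples, "U3", "U1")
  subj_cohort <- design$samples$cohort[!duplicated(design$samples$subject_id)]
  names(subj_cohort) <- design$samples$subject_id[
    !duplicated(design$samples$subject_id)]
  ctrl_subj <- names(subj_cohort)[subj_cohort == "control"]
  case_subj <- names(subj_cohort)[subj_cohort == "mecfs"]
  s <- design$samples
  rows_u1_ctrl <- s$sample_id[s$timepoint == "U1" & s$cohort == "control"]
  rows_u1_case <- s$sample_id[s$timepoint == "U1" & s$cohort == "mecfs"]
  rows_u3_ctrl <- s$sample_id[s$timepoint == "U3" & s$cohort == "control"]
  rows_u3_case <- s$sample_id[s$timepoint == "U3" & s$cohort == "mecfs"]

  res <- vector("list", length(metabolites))
  failed <- character()
  for (i in seq_along(metabolites)) {
    mid <- metabolites[i]
    fit <- fit_lmm(vals[, mid], pre)
    if (!fit$converged) failed <- c(failed, mid)
    ct <- lmm_contrasts(fit, config$df_method)
    ct$metabolite_id <- mid
    ct$boundary <- fit$boundary
    # reporting-scale fold changes (log10, converted below)
    fc10 <- c(
      case_vs_ctrl_baseline = mean(vals[rows_u1_case, mid]) -
        mean(vals[rows_u1_ctrl, mid]),
      case_vs_ctrl_post = mean(vals[rows_u3_case, mid]) -
        mean(vals[rows_u3_ctrl, mid]),
      post_vs_base_ctrl = mean(ratios[intersect(ctrl_subj, rownames(ratios)),
                                      mid]),
      post_vs_base_case = mean(ratios[intersect(case_subj, rownames(ratios)),
                                      mid]),
      interaction = mean(ratios[intersect(case_subj, rownames(ratios)), mid]) -
        mean(ratios[intersect(ctrl_subj, rownames(ratios)), mid]))
    ct$log2fc <- log2_from_log10(unname(fc10[ct$contrast]))
    res[[i]] <- ct
  }
  results <- do.call(rbind, res)
  results$q <- NA_real_
  for (nm in unique(results$contrast)) {
    sel <- results$contrast == nm
    results$q[sel] <- bh_adjust(results$p[sel])
  }
  results <- results[, c("metabolite_id", "contrast", "estimate", "se", "df",
                         "t", "p", "q", "log2fc", "boundary")]
  pipe_log("lmm", "%d metabolites fitted; significant at q<%g: %s",
           length(metabolites), config$lmm_q,
           paste(vapply(unique(results$contrast), function(nm)
             sprintf("%s=%d", nm,
                     sum(results$q[results$contrast == nm] < config$lmm_q,
                         na.rm = TRUE)), ""), collapse = ", "))
  structure(list(results = results, fits_failed = failed, design = design,
                 ratios = ratios),
            class = "lmm_panel")
}

#' Volcano-plot table for one contrast
#'
#' @param panel an [fit_all_lmm()] result.
#' @param contrast one of the five contrast names.
#' @param lmm_q significance threshold on q.
#' @return data frame: metabolite_id, log2fc, neg_log10_q, significant.
#' @export
volcano_table <- function(panel, contrast, lmm_q = 0.1) {
  r <- panel$results[panel$results$contrast == contrast, , drop = FALSE]
  if (!nrow(r)) stop("unknown contrast: ", contrast)
  data.frame(metabolite_id = r$metabolite_id, log2fc = r$log2fc,
             neg_log10_q = -log10(r$q), significant = r$q < lmm_q,
             row.names = NULL, stringsAsFactors = FALSE)
}
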