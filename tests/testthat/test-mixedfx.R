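test_that("profiled REML matches an independent grid/golden-section maximizer", {
  rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-8)
  for (seed in 1:20) {
    d <- random_small_dataset(seed)
    fit <- fit_lmm(d$y, d$des)
    orc <- oracle_reml(d$y, d$des$X, d$des$Z)
    # 4 significant digits on estimates and variance components
    expect_lt(max(rel_err(fit$beta, orc$beta)), 1e-4)
    expect_lt(rel_err(fit$sigma2_e, orc$sigma2_e), 1e-4)
    if (orc$sigma2_u > 1e-6 * orc$sigma2_e)
      expect_lt(rel_err(fit$sigma2_u, orc$sigma2_u), 1e-3)
    # contrast SEs from the oracle covariance agree
    cm <- rbind(c(0, 1, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 1))
    for (k in 1:2) {
      se_fit <- sqrt(drop(t(cm[k, ]) %*% fit$vcov_beta %*% cm[k, ]))
      se_orc <- sqrt(drop(t(cm[k, ]) %*% orc$vcov_beta %*% cm[k, ]))
      expect_lt(rel_err(se_fit, se_orc), 1e-4)
    }
  }
})

test_that("the REML criterion at the returned theta beats a dense grid", {
  d <- random_small_dataset(101)
  fit <- fit_lmm(d$y, d$des)
  pre <- uromet:::lmm_precompute(d$des)
  yt <- crossprod(pre$Q, d$y)
  grid <- c(0, 10^seq(-6, 6, length.out = 1000L))
  devs <- vapply(grid, uromet:::reml_dev, 0, yt = yt, pre = pre)
  expect_lte(fit$reml_dev, min(devs) + 1e-6)
})

test_that("estimates and Satterthwaite inference agree with lmerTest", {
  skip_if_not_installed("lmerTest")
  for (seed in c(3, 17)) {
    d <- random_small_dataset(seed)
    fit <- fit_lmm(d$y, d$des)
    ct <- lmm_contrasts(fit)
    df <- data.frame(y = d$y, cohort = factor(d$des$samples$cohort),
                     tp = factor(d$des$samples$timepoint),
                     age = d$des$samples$age - mean(d$des$samples$age),
                     bmi = d$des$samples$bmi - mean(d$des$samples$bmi),
                     subject = d$des$samples$subject_id)
    lf <- suppressMessages(lmerTest::lmer(
      y ~ cohort * tp + age + bmi + (1 | subject), data = df))
    expect_equal(unname(fit$beta), unname(lme4::fixef(lf)),
                 tolerance = 1e-6)
    sm <- stats::coef(summary(lf))
    mine <- ct[match(c("case_vs_ctrl_baseline", "post_vs_base_ctrl",
                       "interaction"), ct$contrast), ]
    theirs <- sm[c("cohortmecfs", "tpU3", "cohortmecfs:tpU3"), ]
    expect_equal(mine$estimate, unname(theirs[, "Estimate"]),
                 tolerance = 1e-6)
    expect_equal(mine$se, unname(theirs[, "Std. Error"]), tolerance = 1e-5)
    expect_equal(mine$df, unname(theirs[, "df"]), tolerance = 1e-3)
    expect_equal(mine$p, unname(theirs[, "Pr(>|t|)"]), tolerance = 1e-5)
  }
})

test_that("noise-free fits recover the generative coefficients", {
  s <- toy_samples(4, 4)
  des <- lmm_design(s)
  beta <- c(1, 0.5, 0.3, -0.01, 0.02, -0.3)
  set.seed(1)
  y <- drop(des$X %*% beta) + rnorm(nrow(des$X), 0, 1e-8)
  fit <- fit_lmm(y, des)
  expect_lt(max(abs(fit$beta - beta)), 1e-6)
  ct <- lmm_contrasts(fit)
  est <- setNames(ct$estimate, ct$contrast)
  expect_equal(unname(est["case_vs_ctrl_baseline"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(est["case_vs_ctrl_post"]), 0.2, tolerance = 1e-6)
  expect_equal(unname(est["post_vs_base_ctrl"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(est["post_vs_base_case"]), 0.0, tolerance = 1e-6)
  expect_equal(unname(est["interaction"]), -0.3, tolerance = 1e-6)
})

test_that("in a balanced design the interaction equals the difference of mean paired differences", {
  # covariates are subject-constant, so the within-subject contrasts
  # reduce to ordinary means of paired differences in a balanced design
  des <- lmm_design(toy_samples(4, 4))
  set.seed(2)
  y <- rnorm(nrow(des$X))
  fit <- fit_lmm(y, des)
  ct <- lmm_contrasts(fit)
  sdf <- des$samples
  paired_diff <- function(co) {
    subj <- unique(sdf$subject_id[sdf$cohort == co])
    mean(y[match(paste0(subj, "_U3"), sdf$sample_id)] -
           y[match(paste0(subj, "_U1"), sdf$sample_id)])
  }
  expect_equal(ct$estimate[ct$contrast == "interaction"],
               paired_diff("mecfs") - paired_diff("control"),
               tolerance = 1e-8)
})

test_that("contrast estimates satisfy the sum identity per metabolite", {
  sim <- fixture_cached()
  proc <- preprocess(sim$urine, sim$samples, sim$annotation)
  panel <- fit_all_lmm(proc, sim$samples)
  r <- panel$results
  wide <- reshape(r[, c("metabolite_id", "contrast", "estimate")],
                  idvar = "metabolite_id", timevar = "contrast",
                  direction = "wide")
  gap <- wide$estimate.case_vs_ctrl_post -
    wide$estimate.case_vs_ctrl_baseline - wide$estimate.interaction
  expect_lt(max(abs(gap)), 1e-10)
  gap2 <- wide$estimate.post_vs_base_case -
    wide$estimate.post_vs_base_ctrl - wide$estimate.interaction
  expect_lt(max(abs(gap2)), 1e-10)
})

test_that("rank-deficient designs fail loudly naming the aliased column", {
  s <- toy_samples(3, 3)
  s$bmi <- s$age  # bmi aliased with age
  expect_error(lmm_design(s), "aliased")
})

test_that("BH adjustment matches hand computation, bounds, and p.adjust", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.2)),
               c(0.004, 0.04, 0.04, 0.2))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (i in 1:5) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p))
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("volcano tables carry fold changes and significance flags", {
  sim <- fixture_cached()
  proc <- preprocess(sim$urine, sim$samples, sim$annotation)
  panel <- fit_all_lmm(proc, sim$samples)
  v <- volcano_table(panel, "interaction", lmm_q = 0.1)
  expect_setequal(names(v),
                  c("metabolite_id", "log2fc", "neg_log10_q", "significant"))
  expect_equal(nrow(v), length(proc$retained))
  expect_identical(v$significant, v$neg_log10_q > 1)
  # ratio-of-ratios on the log2 scale: case mean 0, control mean 0.30103 -> -1
  expect_equal(log2_from_log10(0 - 0.30103), -1, tolerance = 1e-5)
  expect_error(volcano_table(panel, "nope"), "unknown contrast")
})

test_that("interaction p-values are calibrated on null data", {
  # all-null generator: no cohort, time, or interaction effects anywhere
  sc <- sim_scenario(n_metabolites = 400, responder_frac = 1e-9,
                     gamma = 0, miss_hi_frac = 0, miss_lo_max = 0,
                     drug_frac = 0, seed = 31)
  sim <- simulate_study(sc)
  expect_true(all(sim$truth$params$gamma == 0))
  proc <- preprocess(sim$urine, sim$samples, sim$annotation)
  panel <- fit_all_lmm(proc, sim$samples)
  p <- panel$results$p[panel$results$contrast == "interaction"]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)))
})
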