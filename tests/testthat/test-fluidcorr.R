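test_that("the t-test on R matches the closed form and an independent oracle", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, 2 * x + 1)$p, 0)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    pr <- pearson_r(a, b)
    ct <- cor.test(a, b)   # independent t-distribution route
    expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pr$p, ct$p.value, tolerance = 1e-12)
  }
  # R = 0.9, n = 10 -> t = 5.84 on 8 df
  r <- 0.9; n <- 10
  tval <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(tval, 5.84, tolerance = 1e-3)
  expect_equal(2 * pt(-tval, 8), 0.000388, tolerance = 1e-2)
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
  expect_true(pearson_r(rep(1, 5), rnorm(5))$degenerate)
})

test_that("null correlation p-values are uniform", {
  set.seed(25)
  p <- vapply(1:4000, function(i) pearson_r(rnorm(8), rnorm(8))$p, 0)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("modified z-scores reproduce the hand example and degenerate rules", {
  d <- detect_outliers(c(1, 2, 3, 4, 100))
  # median 3, raw MAD 1: z(100) = 0.6745 * 97 = 65.4
  expect_equal(d$z[5], 65.4, tolerance = 1e-2)
  expect_identical(d$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(d$mad_zero)
  expect_identical(detect_outliers(c(1, 2, 3))$outlier, rep(FALSE, 3))
  dc <- detect_outliers(rep(7, 5))
  expect_true(dc$mad_zero)
  expect_false(any(dc$outlier))
  expect_error(detect_outliers(c(1, 2)), "n >= 3")
})

test_that("shared panels intersect by id and reject disjoint panels", {
  expect_setequal(shared_metabolites(letters[1:10], letters[1:10]),
                  letters[1:10])
  expect_length(shared_metabolites(letters[1:5], letters[3:8]), 3L)
  expect_error(shared_metabolites("a", "b"), "both fluids")
})

# small paired study with programmable cross-fluid structure
corr_fixture <- function(seed = 3, rho_ctrl = 0.9, rho_case = 0.9,
                         n_met = 25) {
  sc <- sim_scenario(n_control = 8, n_case = 10, n_metabolites = n_met,
                     rho = rho_ctrl, miss_hi_frac = 0, miss_lo_max = 0,
                     drug_frac = 0, seed = seed)
  sim <- simulate_study(sc)
  list(sim = sim,
       proc_u = preprocess(sim$urine, sim$samples, sim$annotation),
       proc_p = preprocess(sim$plasma, sim$samples, sim$annotation,
                           osmolality = FALSE))
}

test_that("strong cross-fluid coupling fills the strong-positive census", {
  fx <- corr_fixture(seed = 33, rho_ctrl = 0.97)
  # make the latent deviate dominate so the timepoint R approaches rho
  sc <- sim_scenario(n_control = 8, n_case = 10, n_metabolites = 25,
                     rho = 0.97, sigma_met = 0.5, sigma_e = 0.05,
                     sigma_u = 0, miss_hi_frac = 0, miss_lo_max = 0,
                     drug_frac = 0, seed = 33)
  sim <- simulate_study(sc)
  proc_u <- preprocess(sim$urine, sim$samples, sim$annotation)
  proc_p <- preprocess(sim$plasma, sim$samples, sim$annotation,
                       osmolality = FALSE)
  fc <- correlation_census(proc_u$values, proc_p$values, sim$samples)
  cen <- fc$census[fc$census$pairing_id == "U1~P1", ]
  expect_gte(min(cen$n_strong_pos / cen$n_tested), 0.8)
})

test_that("uncoupled fluids leave the strong-correlation census near the null rate", {
  sc <- sim_scenario(n_control = 8, n_case = 10, n_metabolites = 40,
                     rho = 0, sigma_met = 0.3, sigma_u = 0,
                     age_slope_sd = 0, bmi_slope_sd = 0,
                     miss_hi_frac = 0, miss_lo_max = 0, drug_frac = 0,
                     seed = 44)
  sim <- simulate_study(sc)
  proc_u <- preprocess(sim$urine, sim$samples, sim$annotation)
  proc_p <- preprocess(sim$plasma, sim$samples, sim$annotation,
                       osmolality = FALSE)
  fc <- correlation_census(proc_u$values, proc_p$values, sim$samples)
  cen <- fc$census[fc$census$kind == "timepoint", ]
  # P(|R| > 0.7) at n = 8 is ~0.05; allow generous Monte-Carlo slack
  frac <- sum(cen$n_strong_pos + cen$n_strong_neg) / sum(cen$n_tested)
  expect_lt(frac, 0.2)
})

test_that("census counts match a brute-force recomputation", {
  fx <- corr_fixture(seed = 55)
  fc <- correlation_census(fx$proc_u$values, fx$proc_p$values,
                           fx$sim$samples)
  s <- fx$sim$samples
  for (co in c("control", "mecfs")) {
    subj <- sort(unique(s$subject_id[s$cohort == co]))
    u1 <- fx$proc_u$values[paste0(subj, "_U1"), , drop = FALSE]
    p1 <- fx$proc_p$values[paste0(subj, "_P1"), , drop = FALSE]
    removed <- fc$outliers$metabolite_id[fc$outliers$removed_timepoint]
    ids <- setdiff(colnames(u1), removed)
    rs <- vapply(ids, function(mid) cor(u1[, mid], p1[, mid]), 0)
    cen <- fc$census[fc$census$pairing_id == "U1~P1" &
                       fc$census$cohort == co, ]
    expect_equal(cen$n_strong_pos, sum(rs > 0.7))
    expect_equal(cen$n_strong_neg, sum(rs < -0.7))
    # record-level agreement too
    rec <- fc$records[fc$records$pairing_id == "U1~P1" &
                        fc$records$cohort == co, ]
    expect_equal(rec$r[match(ids, rec$metabolite_id)], unname(rs),
                 tolerance = 1e-12)
  }
})

test_that("an injected spike is excluded from ratio pairings but kept in timepoint pairings", {
  fx <- corr_fixture(seed = 66)
  u <- fx$proc_u$values
  s <- fx$sim$samples
  tr <- fx$sim$truth$params
  mid <- intersect(tr$metabolite_id[!tr$responder], colnames(u))[1]
  # push one subject's post/baseline ratio far out (opposite-signed nudges
  # at the two timepoints) so only the ratio scope trips the z > 6 rule
  u["C01_U3", mid] <- u["C01_U3", mid] + 1.3
  u["C01_U1", mid] <- u["C01_U1", mid] - 1.3
  fc <- correlation_census(u, fx$proc_p$values, s)
  row <- fc$outliers[fc$outliers$metabolite_id == mid, ]
  expect_true(row$removed_ratio)
  expect_false(row$removed_timepoint)
  rec <- fc$records[fc$records$metabolite_id == mid, ]
  expect_true(all(is.na(rec$r[rec$kind == "ratio"])))
  expect_true(all(rec$outlier_removed[rec$kind == "ratio"]))
  expect_true(all(!is.na(rec$r[rec$kind == "timepoint"])))
})

test_that("the three-criteria screen reproduces the inverted-correlation pattern", {
  # one compound with rho = +0.8 in cases and -0.8 in controls, the rest null
  set.seed(7)
  n_met <- 30
  subj <- c(sprintf("C%02d", 1:8), sprintf("M%02d", 1:10))
  cohort <- rep(c("control", "mecfs"), c(8, 10))
  mk <- function(tp, fluid) data.frame(
    sample_id = paste(subj, tp, sep = "_"), subject_id = subj,
    cohort = cohort, fluid = fluid, timepoint = tp, age = 50, bmi = 25,
    osmolality = if (fluid == "urine") 600 else NA_real_,
    stringsAsFactors = FALSE)
  samples <- rbind(mk("U1", "urine"), mk("U3", "urine"),
                   mk("P1", "plasma"), mk("P2", "plasma"),
                   mk("P3", "plasma"), mk("P4", "plasma"))
  mets <- sprintf("MET%03d", 1:n_met)
  base_u <- matrix(rnorm(18 * n_met), 18, n_met,
                   dimnames = list(paste0(subj, "_U1"), mets))
  base_p <- matrix(rnorm(18 * n_met), 18, n_met,
                   dimnames = list(paste0(subj, "_P1"), mets))
  # latent response deviate per subject drives both ratios
  r_lat <- rnorm(18)
  du <- matrix(rnorm(18 * n_met, 0, 1), 18, n_met)
  dp <- matrix(rnorm(18 * n_met, 0, 1), 18, n_met)
  rho <- ifelse(cohort == "mecfs", 0.8, -0.8)
  du[, 1] <- r_lat + rnorm(18, 0, 0.3)
  dp[, 1] <- rho * r_lat + rnorm(18, 0, 0.3)
  u <- rbind(base_u, base_u + du)
  rownames(u) <- c(paste0(subj, "_U1"), paste0(subj, "_U3"))
  p <- rbind(base_p, base_p + matrix(rnorm(18 * n_met), 18),
             base_p + dp, base_p + dp + matrix(rnorm(18 * n_met, 0, .2), 18))
  rownames(p) <- c(paste0(subj, "_P1"), paste0(subj, "_P2"),
                   paste0(subj, "_P3"), paste0(subj, "_P4"))
  fc <- correlation_census(u, p, samples)
  hits <- differential_screen(fc)
  hit1 <- hits[hits$metabolite_id == "MET001" &
                 hits$pairing_id == "U3/U1~P4/P1", ]
  expect_equal(nrow(hit1), 1L)
  expect_gt(hit1$r_case, 0.7)
  expect_lt(hit1$r_control, 0)
})

test_that("screen criteria follow the strong/weak/opposite-sign rules", {
  mk_rec <- function(r_ctrl, r_case, q_ctrl = 0.01, q_case = 0.01,
                     p_ctrl = 1e-4, p_case = 1e-4)
    structure(list(records = data.frame(
      metabolite_id = "m1", cohort = c("control", "mecfs"),
      pairing_id = "U1~P1", kind = "timepoint", n = 8L,
      r = c(r_ctrl, r_case), p = c(p_ctrl, p_case),
      q = c(q_ctrl, q_case), outlier_removed = FALSE, degenerate = FALSE,
      stringsAsFactors = FALSE)), class = "fluidcorr")
  # inverted pair (both significant): hit via opposite sign
  h <- differential_screen(mk_rec(-0.77, 0.74))
  expect_equal(nrow(h), 1L)
  expect_equal(h$sig_cohort, "both")
  # both strong, same sign: not a hit
  expect_equal(nrow(differential_screen(mk_rec(0.85, 0.9))), 0L)
  # strong vs weak same sign: hit
  h2 <- differential_screen(mk_rec(0.2, 0.9))
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$sig_cohort, "mecfs")
  # criterion 1 fails on q: no hit
  expect_equal(nrow(differential_screen(mk_rec(0.2, 0.9, q_case = 0.5))),
               0L)
  # swapping cohort labels yields the mirrored hit set
  h3 <- differential_screen(mk_rec(0.9, 0.2))
  expect_equal(h3$sig_cohort, "control")
  expect_equal(h3$r_control, h2$r_case)
})
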