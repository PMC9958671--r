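toy_annot <- function(ids, drug = rep(FALSE, length(ids))) {
  data.frame(metabolite_id = ids, name = ids, superpathway = "Amino Acid",
             subpathway = "SubA", is_drug_or_tobacco = drug,
             status = "known", hmdb_id = NA_character_,
             cluster_id = NA_character_, stringsAsFactors = FALSE)
}

test_that("osmolality normalization divides per sample and keeps missing cells", {
  m <- matrix(c(100, 30, NA, 8), 2, 2,
              dimnames = list(c("C01_U1", "C01_U3"), c("m1", "m2")))
  s <- data.frame(sample_id = c("C01_U1", "C01_U3"), osmolality = c(2, 1))
  n <- normalize_osmolality(m, s)
  expect_equal(n["C01_U1", "m1"], 50)
  expect_equal(n["C01_U3", "m1"], 30)
  expect_true(is.na(n["C01_U1", "m2"]))
  # unit osmolality is the identity
  s$osmolality <- 1
  expect_equal(normalize_osmolality(m, s), m)
  s$osmolality <- c(2, NA)
  expect_error(normalize_osmolality(m, s), "osmolality")
})

test_that("normalization exactly inverts the generator's osmolality distortion", {
  sim <- simulate_study(noise_free_scenario(n_metabolites = 10, seed = 2))
  norm <- normalize_osmolality(sim$urine, sim$samples)
  # noise-free latent for a control baseline sample: mu + a*age + b*bmi
  tr <- sim$truth$params
  su <- sim$truth$subjects
  for (mid in tr$metabolite_id[1:4]) {
    i <- match(mid, tr$metabolite_id)
    expected <- 10^(tr$mu[i] + tr$age_slope[i] * su$age +
                      tr$bmi_slope[i] * su$bmi +
                      tr$delta[i] * (su$cohort == "mecfs"))
    got <- norm[paste0(su$subject_id, "_U1"), mid]
    cmp <- !is.na(got)
    expect_equal(unname(got[cmp]), expected[cmp], tolerance = 1e-9)
  }
})

test_that("imputation uses the metabolite minimum, zero for drugs, drops all-missing", {
  m <- matrix(c(NA, 4, 2,  NA, 7, 3,  NA, NA, NA), 3, 3,
              dimnames = list(c("s1", "s2", "s3"), c("m1", "drug", "gone")))
  annot <- toy_annot(colnames(m), drug = c(FALSE, TRUE, FALSE))
  imp <- impute_missing(m, annot)
  expect_equal(unname(imp$values[, "m1"]), c(2, 4, 2))
  expect_equal(unname(imp$imputed[, "m1"]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(imp$values[, "drug"]), c(0, 7, 3))
  expect_equal(imp$dropped, "gone")
  expect_false("gone" %in% colnames(imp$values))
  # detection mask reflects the pre-imputation state
  expect_identical(imp$detected, !imp$imputed)
})

test_that("median centering scales every metabolite to median 1 with a zero-median fallback", {
  m <- cbind(a = c(50, 100, 200), b = c(3, 3, 3), d = c(0, 0, 5))
  rownames(m) <- paste0("s", 1:3)
  ctr <- median_center(m)
  expect_equal(unname(ctr$values[, "a"]), c(0.5, 1, 2))
  expect_equal(unname(ctr$values[, "b"]), c(1, 1, 1))
  # zero median: divide by smallest positive value instead
  expect_equal(unname(ctr$values[, "d"]), c(0, 0, 1))
  expect_equal(ctr$zero_median, "d")
  # no positive value at all: dropped
  m2 <- cbind(a = c(1, 2, 3), z = c(0, 0, 0))
  rownames(m2) <- paste0("s", 1:3)
  ctr2 <- median_center(m2)
  expect_equal(ctr2$dropped, "z")
  expect_false("z" %in% colnames(ctr2$values))
})

test_that("per-metabolite medians equal 1 to machine precision after centering", {
  set.seed(4)
  m <- matrix(rlnorm(600, 8, 2), 20, 30,
              dimnames = list(paste0("s", 1:20), paste0("m", 1:30)))
  ctr <- median_center(m)
  meds <- apply(ctr$values, 2, median)
  expect_lt(max(abs(meds - 1)), 1e-12)
})

test_that("the generalized log10 transform matches its closed form and is monotone", {
  # identity point: glog10(1) -> 0 as lambda -> 0
  expect_equal(unname(glog10(1, lambda = 1e-12))[1], 0, tolerance = 1e-12)
  # finite at zero: log10(lambda/2)
  expect_equal(unname(glog10(0, lambda = 0.01))[1], log10(0.005),
               tolerance = 1e-12)
  expect_equal(log10(0.005), -2.301, tolerance = 1e-3)
  # ~log10 far above lambda
  expect_equal(unname(glog10(1000, lambda = 0.01))[1], 3, tolerance = 1e-8)
  # strict monotonicity on random inputs
  set.seed(8)
  x <- sort(runif(200, 0, 50))
  g <- glog10(x, lambda = 0.3)
  expect_true(all(diff(g) > 0))
  expect_error(glog10(-1), "non-negative")
  # strict log10 mode is available
  expect_identical(unname(vst_log10(cbind(10), method = "log10"))[1], 1)
})

test_that("the modified 80% rule pools timepoints within cohort and is non-strict", {
  samples <- rbind(toy_samples(8, 10))
  det <- matrix(TRUE, nrow(samples), 3,
                dimnames = list(samples$sample_id, c("keep", "edge", "drop")))
  ctrl <- samples$sample_id[samples$cohort == "control"]   # 16 samples
  case <- samples$sample_id[samples$cohort == "mecfs"]     # 20 samples
  # edge: 13/16 control (0.8125), 2/20 case -> retained
  det[ctrl[1:3], "edge"] <- FALSE
  det[case[3:20], "edge"] <- FALSE
  # drop: 12/16 (0.75) and 15/20 (0.75) -> dropped
  det[ctrl[1:4], "drop"] <- FALSE
  det[case[1:5], "drop"] <- FALSE
  filt <- filter_80pct(det, samples)
  expect_true(filt$retained[filt$metabolite_id == "keep"])
  expect_true(filt$retained[filt$metabolite_id == "edge"])
  expect_false(filt$retained[filt$metabolite_id == "drop"])
  expect_equal(filt$frac_control[filt$metabolite_id == "edge"], 13 / 16)
})

test_that("ratios are post minus baseline per subject, omitting incomplete pairs", {
  m <- matrix(c(0, 0.301, 1, 1, 2, NA), 3, 2,
              dimnames = list(c("C01_U1", "C01_U3", "C02_U1"),
                              c("m1", "m2")))
  s <- data.frame(sample_id = rownames(m),
                  subject_id = c("C01", "C01", "C02"),
                  cohort = "control", fluid = "urine",
                  timepoint = c("U1", "U3", "U1"),
                  age = 50, bmi = 25, osmolality = 1,
                  stringsAsFactors = FALSE)
  r <- make_ratios(m, s, "U3", "U1")
  expect_equal(rownames(r), "C01")
  expect_equal(unname(r["C01", "m1"]), 0.301)
  expect_equal(unname(r["C01", "m2"]), 1)
  # post == base gives identically zero ratios
  m2 <- m; m2["C01_U3", ] <- m2["C01_U1", ]
  expect_equal(unname(make_ratios(m2, s, "U3", "U1")["C01", ]), c(0, 0))
})

test_that("log2 conversion applies the change of base", {
  expect_equal(log2_from_log10(0.30103), 1, tolerance = 1e-5)
  expect_equal(log2_from_log10(0), 0)
  expect_equal(log2_from_log10(-0.60206), -2, tolerance = 1e-5)
})

test_that("the noise-free prep chain recovers generator ratios exactly", {
  sim <- simulate_study(noise_free_scenario(n_metabolites = 24, seed = 13))
  # strict log10 mode: the chain is exactly invertible
  proc <- preprocess(sim$urine, sim$samples, sim$annotation,
                     run_config(vst = "log10"))
  ratios <- make_ratios(proc$values, sim$samples, "U3", "U1")
  tr <- sim$truth$params
  su <- sim$truth$subjects
  ctrl <- su$subject_id[su$cohort == "control"]
  case <- su$subject_id[su$cohort == "mecfs"]
  resp <- intersect(tr$metabolite_id[tr$responder], colnames(ratios))
  expect_gt(length(resp), 0)
  for (mid in resp) {
    expect_equal(unname(ratios[ctrl, mid]), rep(0.3, length(ctrl)),
                 tolerance = 1e-12)
    expect_equal(unname(ratios[case, mid]), rep(0, length(case)),
                 tolerance = 1e-12)
  }
  # the default generalized log agrees far from its transition scale
  proc_g <- preprocess(sim$urine, sim$samples, sim$annotation)
  ratios_g <- make_ratios(proc_g$values, sim$samples, "U3", "U1")
  expect_equal(unname(ratios_g[ctrl, resp[1]]), rep(0.3, length(ctrl)),
               tolerance = 5e-3)
})

test_that("preprocess returns a coherent processed table on the fixture", {
  sim <- fixture_cached()
  proc <- preprocess(sim$urine, sim$samples, sim$annotation)
  expect_false(anyNA(proc$values))
  expect_identical(dim(proc$values), dim(proc$detected))
  # imputed exactly where not detected
  expect_identical(proc$imputed, !proc$detected)
  expect_true(all(proc$retained %in% colnames(proc$values)))
  expect_true("MET0058" %in% proc$dropped)
})
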