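options(uromet.verbose = FALSE)

# fixture cache: the small deterministic study is reused across files
fixture_cached <- local({
  env <- new.env()
  function() {
    if (is.null(env$sim)) env$sim <- fixture_small()
    env$sim
  }
})

# noise-free scenario: every stochastic latent term switched off
noise_free_scenario <- function(n_control = 4L, n_case = 4L,
                                n_metabolites = 30L, seed = 11L, ...) {
  sim_scenario(n_control = n_control, n_case = n_case,
               n_metabolites = n_metabolites,
               sigma_u = 0, sigma_e = 0, sigma_met = 0, sigma_resp = 0,
               miss_hi_frac = 0, miss_lo_max = 0, drug_frac = 0,
               seed = seed, ...)
}

# tiny urine-only metadata builder for unit tests
toy_samples <- function(n_ctrl = 3L, n_case = 3L) {
  subj <- c(sprintf("C%02d", seq_len(n_ctrl)),
            sprintf("M%02d", seq_len(n_case)))
  cohort <- rep(c("control", "mecfs"), c(n_ctrl, n_case))
  do.call(rbind, lapply(c("U1", "U3"), function(tp)
    data.frame(sample_id = paste(subj, tp, sep = "_"), subject_id = subj,
               cohort = cohort, fluid = "urine", timepoint = tp,
               age = seq(48, by = 1, length.out = length(subj)),
               bmi = 24 + 3 * (seq_along(subj) %% 3) +
                 0.4 * seq_along(subj),
               osmolality = 1, stringsAsFactors = FALSE)))
}

# random small urine study with known mixed-model structure
random_small_dataset <- function(seed) {
  set.seed(seed)
  n_ctrl <- sample(3:5, 1); n_case <- sample(3:5, 1)
  s <- toy_samples(n_ctrl, n_case)
  s$age <- s$age + rnorm(nrow(s) / 2)[match(s$subject_id,
                                            unique(s$subject_id))]
  des <- lmm_design(s)
  sigma_u <- runif(1, 0, 0.3); sigma_e <- runif(1, 0.05, 0.3)
  u <- rnorm(ncol(des$Z), 0, sigma_u)
  beta <- rnorm(6, 0, 0.3)
  y <- drop(des$X %*% beta + des$Z %*% u +
              rnorm(nrow(des$X), 0, sigma_e))
  list(y = y, des = des)
}

# independent brute-force REML maximizer: direct dense-matrix criterion on
# a theta grid refined by golden-section, no spectral shortcut
oracle_reml <- function(y, X, Z, theta_max = 1e6) {
  n <- nrow(X); p <- ncol(X)
  dev <- function(theta) {
    Sig <- diag(n) + theta * tcrossprod(Z)
    Si <- solve(Sig)
    XtSiX <- t(X) %*% Si %*% X
    beta <- solve(XtSiX, t(X) %*% Si %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Si %*% r)
    (n - p) * log(rss) + determinant(Sig)$modulus +
      determinant(XtSiX)$modulus
  }
  grid <- c(0, 10^seq(-6, log10(theta_max), length.out = 241L))
  devs <- vapply(grid, dev, 0)
  i <- which.min(devs)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  for (k in 1:200) {
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    if (dev(c1) <= dev(c2)) b <- c2 else a <- c1
    if (b - a < 1e-12 * (1 + b)) break
  }
  theta <- (a + b) / 2
  if (dev(0) <= dev(theta)) theta <- 0
  Sig <- diag(n) + theta * tcrossprod(Z)
  Si <- solve(Sig)
  XtSiX <- t(X) %*% Si %*% X
  beta <- drop(solve(XtSiX, t(X) %*% Si %*% y))
  r <- y - X %*% beta
  sigma2_e <- drop(t(r) %*% Si %*% r) / (n - p)
  list(theta = theta, beta = beta, sigma2_e = sigma2_e,
       sigma2_u = theta * sigma2_e, vcov_beta = solve(XtSiX) * sigma2_e)
}
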