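# Independent oracles and shared fixtures for the test suite.

# Longhand inverse-variance weighted estimate: explicit loop over
# instruments, accumulating the weighted sums term by term.
oracle_ivw <- function(beta_x, se_y, beta_y) {
  num <- 0
  den <- 0
  for (j in seq_along(beta_x)) {
    w <- 1 / se_y[j]^2
    num <- num + w * beta_y[j] * beta_x[j]
    den <- den + w * beta_x[j]^2
  }
  list(theta = num / den, se = sqrt(1 / den))
}

oracle_cochran_q <- function(beta_x, se_y, beta_y, theta) {
  q <- 0
  for (j in seq_along(beta_x)) {
    w <- beta_x[j]^2 / se_y[j]^2
    q <- q + w * (beta_y[j] / beta_x[j] - theta)^2
  }
  q
}

# Exact HWE p-value from the closed-form conditional probability of each
# heterozygote count given the allele counts (Levene/Haldane form).
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  hs <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- sapply(hs, function(h) {
    lfactorial(n) + lfactorial(na) + lfactorial(nb) + h * log(2) -
      lfactorial((na - h) / 2) - lfactorial(h) - lfactorial((nb - h) / 2) -
      lfactorial(2 * n)
  })
  p <- exp(logp)
  p_obs <- p[match(n_ab, hs)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# Three-SNP toy harmonized set from the worked example.
toy_hset <- function() {
  data.frame(rsid = c("s1", "s2", "s3"),
             beta_x = c(0.10, 0.08, 0.05),
             se_x = c(0.01, 0.01, 0.01),
             beta_y = c(0.05, 0.04, 0.025),
             se_y = c(0.02, 0.02, 0.04),
             stringsAsFactors = FALSE)
}

random_hset <- function(k, seed = NULL) {
  gen <- function() {
    data.frame(rsid = paste0("r", seq_len(k)),
               beta_x = stats::rnorm(k, 0.05, 0.03),
               se_x = stats::runif(k, 0.004, 0.02),
               beta_y = stats::rnorm(k, 0, 0.05),
               se_y = stats::runif(k, 0.01, 0.08),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Case-control cohort built from the package generators: panel genotypes,
# standardized GRS, covariates with effect 0.5, logistic outcome.
make_cc_cohort <- function(n, theta, seed) {
  panel <- flip_to_shorter(load_instrument_panel())
  set.seed(seed)
  gm <- simulate_genotypes(n, panel$records$eaf)
  colnames(gm) <- panel$records$rsid
  grs <- compute_grs(gm, panel)
  cov <- simulate_covariates(n)
  eta <- grs$standardized * theta + 0.5 * cov$x1 + 0.5 * cov$x2
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  list(cohort = case_control_cohort(y, cov), grs = grs)
}

# Survival cohort analogue with Weibull(1, 0.01) times and 50% censoring.
make_surv_cohort <- function(n, theta, seed) {
  cfg <- sim_config(theta = theta, seed = seed)
  simulate_survival(cfg, n)
}

# Table 1 as printed (for frozen-value tests).
printed_f <- c(49.0, 27.9, 205.4, 30.2, 93.4, 186.8, 30.8, 34.0, 46.7,
               83.6, 33.6, 36.0, 34.0, 31.0, 38.0, 60.8, 55.4)
printed_pve <- c(6.23e-4, 3.55e-4, 2.61e-3, 3.85e-4, 1.19e-3, 2.37e-3,
                 3.91e-4, 4.33e-4, 5.94e-4, 1.06e-3, 4.28e-4, 4.58e-4,
                 4.33e-4, 3.95e-4, 4.84e-4, 7.74e-4, 7.05e-4)

write_panel_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
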