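#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards; with `seed = NULL` the expression simply advances the
#' current stream.
#'
#' @param seed Integer seed or NULL.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive reproducible sub-seeds from a master seed
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds below 2^31.
#' @export
substream_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

default_panel_shorter <- function() {
  flip_to_shorter(load_instrument_panel())
}

#' Simulation configuration for cohort-level generators
#'
#' Defaults reproduce the study's Monte-Carlo design: genotypes for 17
#' independent SNPs at the telomere-length panel allele frequencies under
#' Hardy-Weinberg equilibrium, a binary and a continuous covariate each
#' with effect 0.5, a 2,000,000-person logistic population for
#' case-control subsampling, Weibull(shape 1, scale 0.01) survival times
#' with 50% random censoring, 1,000 replicates, and a rejection threshold
#' of 1.67E-3 (Bonferroni for 30 cancer types).
#'
#' @param theta GRS effect (log-OR or log-HR per SD of the GRS).
#' @param mafs Effect-allele frequencies (default: panel EAFs).
#' @param weights Per-SNP GRS weights (default: panel betas oriented to
#'   shorter telomere length).
#' @param cov_effects Effects of the binary and continuous covariate.
#' @param population_n Logistic population size.
#' @param n_cases,n_controls Case-control subsample sizes.
#' @param weibull_shape,weibull_scale Weibull hazard parameters.
#' @param censor_rate Fraction censored, in `[0, 1)`.
#' @param n_reps Monte-Carlo replicates.
#' @param alpha Rejection threshold for power.
#' @param seed Optional integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(theta = 0, mafs = NULL, weights = NULL,
                       cov_effects = c(0.5, 0.5),
                       population_n = 2e6, n_cases = 50L,
                       n_controls = 3e5, weibull_shape = 1,
                       weibull_scale = 0.01, censor_rate = 0.5,
                       n_reps = 1000L, alpha = 1.67e-3, seed = NULL) {
  if (is.null(mafs) || is.null(weights)) {
    panel <- default_panel_shorter()
    if (is.null(mafs)) mafs <- panel$records$eaf
    if (is.null(weights)) weights <- panel$records$beta
  }
  stopifnot(length(mafs) == length(weights))
  if (any(mafs <= 0 | mafs >= 1)) stop("allele frequencies must lie in (0,1)",
                                       call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  }
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  structure(list(theta = theta, mafs = mafs, weights = weights,
                 cov_effects = cov_effects, population_n = population_n,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 censor_rate = censor_rate, n_reps = as.integer(n_reps),
                 alpha = alpha, seed = seed),
            class = "sim_config")
}

#' Simulate independent genotypes under Hardy-Weinberg equilibrium
#'
#' `dosage_ij ~ Binomial(2, maf_j)`, independent across samples and SNPs.
#'
#' @param n Number of samples.
#' @param mafs Per-SNP effect-allele frequencies in (0,1).
#' @param seed Optional integer seed.
#' @return Numeric `n x length(mafs)` matrix with `snp_*` colnames.
#' @export
simulate_genotypes <- function(n, mafs, seed = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (any(mafs <= 0 | mafs >= 1)) stop("allele frequencies must lie in (0,1)",
                                       call. = FALSE)
  with_seed(seed, {
    k <- length(mafs)
    gm <- matrix(stats::rbinom(n * k, 2L, rep(mafs, each = n)), n, k)
    colnames(gm) <- paste0("snp_", seq_len(k))
    storage.mode(gm) <- "double"
    gm
  })
}

#' Simulate the two adjustment covariates
#'
#' `X1 ~ Bernoulli(0.5)` and `X2 ~ Normal(0,1)`, independent.
#'
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return data.frame with columns `x1`, `x2`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, {
    data.frame(x1 = stats::rbinom(n, 1L, 0.5), x2 = stats::rnorm(n))
  })
}

sim_linear_predictor <- function(n, cfg, standardize = TRUE) {
  gm <- simulate_genotypes(n, cfg$mafs)
  raw <- as.vector(gm %*% cfg$weights)
  grs <- if (standardize) (raw - mean(raw)) / stats::sd(raw) else raw
  cov <- simulate_covariates(n)
  eta <- grs * cfg$theta + cfg$cov_effects[1] * cov$x1 +
    cfg$cov_effects[2] * cov$x2
  list(grs = grs, cov = cov, eta = eta)
}

#' Simulate a case-control cohort from a logistic population
#'
#' Creates `population_n` individuals with
#' `eta = GRS_std * theta + 0.5 X1 + 0.5 X2` (GRS standardized within the
#' population), draws disease status with probability
#' `exp(eta)/(1+exp(eta))`, and subsamples the configured numbers of
#' cases and controls without replacement.
#'
#' @param cfg A `sim_config`.
#' @return List with `cohort` (`case_control_cohort`), `grs` (standardized
#'   values for the subsample) and `config`.
#' @export
simulate_case_control <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    sim <- sim_linear_predictor(cfg$population_n, cfg)
    y <- stats::rbinom(cfg$population_n, 1L, stats::plogis(sim$eta))
    cases <- which(y == 1L)
    controls <- which(y == 0L)
    if (length(cases) < cfg$n_cases) {
      stop(sprintf(
        "only %d cases in population; increase population_n (currently %g)",
        length(cases), cfg$population_n), call. = FALSE)
    }
    if (length(controls) < cfg$n_controls) {
      stop("insufficient controls in population", call. = FALSE)
    }
    pick <- c(sample(cases, cfg$n_cases), sample(controls, cfg$n_controls))
    list(cohort = case_control_cohort(y[pick], sim$cov[pick, , drop = FALSE]),
         grs = sim$grs[pick], config = cfg)
  })
}

#' Simulate a survival cohort with Weibull event times
#'
#' Event times follow a Weibull proportional-hazards model,
#' `T = (-log(U) / (scale * exp(eta)))^(1/shape)` with `U ~ Uniform(0,1)`
#' (inverse-probability transform), where
#' `eta = GRS * theta + 0.5 X1 + 0.5 X2` and the GRS is standardized
#' within the replicate by default. Exactly `round(censor_rate * n)`
#' individuals, chosen uniformly at random, are censored at a time drawn
#' uniformly on `(0, T_i)`; the rest are observed events.
#'
#' @param cfg A `sim_config`.
#' @param n Cohort size (>= 2).
#' @param standardize_grs Standardize the GRS within the replicate
#'   (default TRUE).
#' @return List with `cohort` (`survival_cohort`), `grs` and `config`.
#' @export
simulate_survival <- function(cfg, n, standardize_grs = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  with_seed(cfg$seed, {
    sim <- sim_linear_predictor(n, cfg, standardize = standardize_grs)
    u <- stats::runif(n)
    t_event <- (-log(u) / (cfg$weibull_scale * exp(sim$eta)))^
      (1 / cfg$weibull_shape)
    n_cens <- round(cfg$censor_rate * n)
    event <- rep(1L, n)
    time <- t_event
    if (n_cens > 0L) {
      idx <- sample.int(n, n_cens)
      event[idx] <- 0L
      time[idx] <- stats::runif(n_cens, 0, t_event[idx])
    }
    list(cohort = survival_cohort(time, event, sim$cov),
         grs = sim$grs, config = cfg)
  })
}

#' Configuration for two-sample summary-statistic simulation
#'
#' @param k Number of instruments.
#' @param causal_theta True causal slope.
#' @param outcome_n Effective outcome GWAS sample size (sets `se_y` via
#'   `1/sqrt(2 f (1-f) n)`). The default 10,000 reflects a case-limited
#'   binary outcome: a cancer with ~2,500 cases against ~300,000 controls
#'   has effective n = 4/(1/n_case + 1/n_control) of about this size, so
#'   outcome standard errors dwarf the exposure panel's.
#' @param heterogeneity_sd SD of per-SNP effect heterogeneity added to
#'   the outcome effect.
#' @param pleiotropy_mean Mean directional pleiotropic effect added to
#'   every outcome effect.
#' @param outlier_index,outlier_shift Optional single outlier: index of
#'   the displaced SNP and displacement in units of its `se_y`.
#' @param seed Optional integer seed.
#' @return List of class `summary_sim_config`.
#' @export
summary_sim_config <- function(k = 17L, causal_theta = 0,
                               outcome_n = 10000,
                               heterogeneity_sd = 0,
                               pleiotropy_mean = 0,
                               outlier_index = NULL, outlier_shift = 0,
                               seed = NULL) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (outcome_n <= k) stop("outcome_n must exceed k", call. = FALSE)
  structure(list(k = as.integer(k), causal_theta = causal_theta,
                 outcome_n = outcome_n,
                 heterogeneity_sd = heterogeneity_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 outlier_index = outlier_index,
                 outlier_shift = outlier_shift, seed = seed),
            class = "summary_sim_config")
}

#' Simulate two-sample GWAS summary statistics
#'
#' True per-SNP exposure effects and exposure SEs are resampled from the
#' telomere-length panel (shorter orientation); observed effects are
#' `beta_x ~ N(true, se_x)` and
#' `beta_y ~ N(causal_theta * true + pleiotropy + heterogeneity, se_y)`,
#' with `se_y` set from the effective outcome sample size and allele
#' frequency. Pleiotropic and heterogeneity effects are directional with
#' respect to the exposure-increasing allele (applied with the sign of the
#' true exposure effect), matching the orientation convention of the Egger
#' intercept. An optional single outlier displaces one observed `beta_y`
#' by `outlier_shift * se_y`. Alleles are emitted as non-palindromic A/G
#' so that harmonization is exercised but unambiguous.
#'
#' @param cfg A `summary_sim_config`.
#' @return List with `panel` (`instrument_panel`, orientation shorter),
#'   `outcome` (`outcome_summary`), `hset` (pre-harmonized set) and
#'   `truth` (true effects and slope).
#' @export
simulate_two_sample_summary <- function(cfg) {
  stopifnot(inherits(cfg, "summary_sim_config"))
  ref <- default_panel_shorter()$records
  with_seed(cfg$seed, {
    pick <- sample.int(nrow(ref), cfg$k, replace = cfg$k > nrow(ref))
    bx_true <- ref$beta[pick]
    se_x <- ref$se[pick]
    eaf <- ref$eaf[pick]
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$outcome_n)
    pleio <- cfg$pleiotropy_mean +
      if (cfg$heterogeneity_sd > 0)
        stats::rnorm(cfg$k, 0, cfg$heterogeneity_sd) else 0
    # pleiotropy is directional relative to the exposure-increasing allele,
    # so it is applied in the orientation with positive exposure effects
    by_true <- cfg$causal_theta * bx_true + sign(bx_true) * pleio
    bx <- stats::rnorm(cfg$k, bx_true, se_x)
    by <- stats::rnorm(cfg$k, by_true, se_y)
    if (!is.null(cfg$outlier_index)) {
      j <- cfg$outlier_index
      by[j] <- by[j] + cfg$outlier_shift * se_y[j]
    }
    rsid <- paste0("sim_snp_", seq_len(cfg$k))
    records <- data.frame(
      rsid = rsid, chr = "1", pos = seq_len(cfg$k), gene = "simulated",
      a1 = "A", a2 = "G", eaf = eaf, beta = bx, se = se_x,
      pvalue = pmax(2 * stats::pnorm(-abs(bx / se_x)), 1e-300),
      stringsAsFactors = FALSE)
    panel <- instrument_panel(records, gwas_n = LTL_GWAS_N,
                              orientation = "shorter")
    outcome <- outcome_summary_from_df(data.frame(
      rsid = rsid, a1 = "A", a2 = "G", beta = by, se = se_y,
      pvalue = pmax(2 * stats::pnorm(-abs(by / se_y)), 1e-300),
      eaf = eaf, stringsAsFactors = FALSE))
    list(panel = panel, outcome = outcome,
         hset = harmonize(panel, outcome),
         truth = list(beta_x = bx_true, beta_y = by_true,
                      causal_theta = cfg$causal_theta, config = cfg))
  })
}
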