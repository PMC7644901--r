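test_that("Wald ratio arithmetic and guards", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(w$theta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$theta, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "nonzero")
})

test_that("fixed-effect IVW equals the longhand oracle", {
  d <- toy_hset()
  est <- mr_ivw(d, "fixed")
  o <- oracle_ivw(d$beta_x, d$se_y, d$beta_y)
  expect_equal(est$theta, o$theta, tolerance = 1e-12)
  expect_equal(est$se, o$se, tolerance = 1e-12)

  for (i in 1:30) {
    d <- random_hset(sample(2:20, 1), seed = 500 + i)
    est <- mr_ivw(d, "fixed")
    o <- oracle_ivw(d$beta_x, d$se_y, d$beta_y)
    expect_equal(est$theta, o$theta, tolerance = 1e-12)
    expect_equal(est$se, o$se, tolerance = 1e-12)
  }
})

test_that("IVW reduces to the Wald ratio at k = 1 and scales with se_y", {
  d <- toy_hset()[1, ]
  est <- mr_ivw(d, "fixed")
  w <- wald_ratio(d$beta_x, d$se_x, d$beta_y, d$se_y)
  expect_equal(est$theta, w$theta)
  expect_equal(est$se, w$se)

  d3 <- toy_hset()
  base <- mr_ivw(d3, "fixed")
  d3$se_y <- d3$se_y * 2.5
  scaled <- mr_ivw(d3, "fixed")
  expect_equal(scaled$theta, base$theta)
  expect_equal(scaled$se, base$se * 2.5)

  expect_error(mr_ivw(toy_hset()[1, ], "random"), "k >= 2")
})

test_that("random-effects IVW inflates the SE only under heterogeneity", {
  d <- toy_hset()
  q <- cochran_q(d)
  fixed <- mr_ivw(d, "fixed")
  random <- mr_ivw(d, "random")
  expect_equal(random$theta, fixed$theta)
  expect_equal(random$se, fixed$se * max(1, sqrt(q$Q / q$df)))
})

test_that("Cochran's Q matches the longhand oracle and its edge cases", {
  d <- toy_hset()
  q <- cochran_q(d)
  theta <- mr_ivw(d, "fixed")$theta
  expect_equal(q$Q, oracle_cochran_q(d$beta_x, d$se_y, d$beta_y, theta),
               tolerance = 1e-12)
  expect_equal(q$df, 2L)

  prop <- data.frame(beta_x = c(0.1, 0.2, 0.4), se_x = 0.01,
                     beta_y = c(0.05, 0.10, 0.20), se_y = 0.02)
  qq <- cochran_q(prop)
  expect_equal(qq$Q, 0, tolerance = 1e-20)
  expect_equal(qq$pvalue, 1)

  two <- data.frame(beta_x = c(0.1, 0.2), se_x = 0.01,
                    beta_y = c(0.05, 0.1), se_y = 0.02)
  expect_equal(cochran_q(two)$Q, 0, tolerance = 1e-20)
  expect_error(cochran_q(two[1, ]), "k >= 2")
})

test_that("weighted median interpolates the weighted ratio distribution", {
  eq3 <- data.frame(beta_x = 1, se_x = 0.01, beta_y = c(1, 2, 3), se_y = 1)
  expect_equal(mr_weighted_median(eq3, n_boot = 10, seed = 1)$theta, 2)
  eq4 <- data.frame(beta_x = 1, se_x = 0.01, beta_y = c(1, 2, 3, 4),
                    se_y = 1)
  expect_equal(mr_weighted_median(eq4, n_boot = 10, seed = 1)$theta, 2.5)
  expect_error(mr_weighted_median(toy_hset()[1:2, ]), "k >= 3")

  # bootstrap SE is bit-identical under a fixed seed
  d <- toy_hset()
  a <- mr_weighted_median(d, n_boot = 300, seed = 42)
  b <- mr_weighted_median(d, n_boot = 300, seed = 42)
  expect_identical(a$se, b$se)
  c2 <- mr_weighted_median(d, n_boot = 300, seed = 43)
  expect_false(identical(a$se, c2$se))
})

test_that("maximum likelihood matches a grid-search oracle and IVW", {
  d <- toy_hset()
  est <- mr_max_likelihood(d)
  # independent grid search over the profile likelihood
  grid <- seq(est$theta - 0.5, est$theta + 0.5, length.out = 20001)
  ll <- vapply(grid, function(th) {
    prec <- 1 / d$se_x^2 + th^2 / d$se_y^2
    mu <- (d$beta_x / d$se_x^2 + th * d$beta_y / d$se_y^2) / prec
    sum(dnorm(d$beta_x, mu, d$se_x, log = TRUE) +
          dnorm(d$beta_y, th * mu, d$se_y, log = TRUE))
  }, numeric(1))
  expect_equal(est$theta, grid[which.max(ll)], tolerance = 1e-4)
  expect_gt(est$se, 0)
  expect_error(mr_max_likelihood(d[1, ]), "k >= 2")

  # asymptotically equivalent to fixed IVW when the exposure effects are
  # measured essentially without error and there is no heterogeneity
  d2 <- random_hset(17, seed = 300)
  d2$se_x <- 1e-6
  ml <- mr_max_likelihood(d2)
  ivw <- mr_ivw(d2, "fixed")
  expect_equal(ml$theta, ivw$theta, tolerance = 1e-3)
  expect_equal(ml$se, ivw$se, tolerance = 1e-3)
})

test_that("Egger through the origin equals IVW; intercept guards pleiotropy", {
  d <- toy_hset()
  ivw <- mr_ivw(d, "fixed")
  origin <- mr_egger(d, fit_intercept = FALSE)
  expect_equal(origin$theta, ivw$theta, tolerance = 1e-12)

  est <- mr_egger(d)
  expect_true(all(c("intercept", "intercept_se", "intercept_p") %in%
                    names(est)))
  expect_error(mr_egger(d[1:2, ]), "k >= 3")
  coll <- data.frame(beta_x = 0.1, se_x = 0.01,
                     beta_y = c(0.05, 0.06, 0.04), se_y = 0.02)
  expect_error(mr_egger(coll), "collinear")
})

test_that("Egger intercept calibration and power under directional pleiotropy", {
  reject_null <- vapply(1:200, function(i) {
    sim <- simulate_two_sample_summary(
      summary_sim_config(k = 17, causal_theta = 0.2, seed = 7000 + i))
    mr_egger(sim$hset)$intercept_p < 0.05
  }, logical(1))
  expect_lte(mean(reject_null), 0.09)

  reject_pleio <- vapply(1:100, function(i) {
    sim <- simulate_two_sample_summary(
      summary_sim_config(k = 17, causal_theta = 0.2,
                         pleiotropy_mean = 0.05, seed = 8000 + i))
    mr_egger(sim$hset)$intercept_p < 0.05
  }, logical(1))
  expect_gt(mean(reject_pleio), 0.5)
})

test_that("leave-one-out reduces, stays stable, and localizes outliers", {
  two <- data.frame(rsid = c("a", "b"), beta_x = c(0.1, 0.2), se_x = 0.01,
                    beta_y = c(0.05, 0.12), se_y = c(0.02, 0.03))
  loo <- leave_one_out(two)
  expect_equal(loo$theta[loo$rsid_omitted == "a"],
               wald_ratio(0.2, 0.01, 0.12, 0.03)$theta)
  expect_equal(loo$theta[loo$rsid_omitted == "b"],
               wald_ratio(0.1, 0.01, 0.05, 0.02)$theta)
  expect_error(leave_one_out(two[1, ]), "k >= 2")

  sim <- simulate_two_sample_summary(
    summary_sim_config(k = 17, causal_theta = 0.3, seed = 99))
  full <- mr_ivw(sim$hset, "fixed")
  loo2 <- leave_one_out(sim$hset)
  expect_true(all(abs(loo2$theta - full$theta) < full$se))

  out <- simulate_two_sample_summary(
    summary_sim_config(k = 17, causal_theta = 0.3, outlier_index = 5,
                       outlier_shift = 12, seed = 100))
  full_o <- mr_ivw(out$hset, "fixed")
  loo_o <- leave_one_out(out$hset)
  shifts <- abs(loo_o$theta - full_o$theta)
  expect_equal(which.max(shifts), 5L)
})

test_that("MR-PRESSO is deterministic, calibrated, and flags outliers", {
  sim <- simulate_two_sample_summary(
    summary_sim_config(k = 17, causal_theta = 0.3, seed = 11))
  a <- mr_presso(sim$hset, n_sim = 400, seed = 5)
  b <- mr_presso(sim$hset, n_sim = 400, seed = 5)
  expect_identical(a$global_p, b$global_p)
  expect_length(a$outliers, 17L)
  expect_error(mr_presso(toy_hset(), n_sim = 100), "k >= 4")

  clean_ok <- vapply(1:60, function(i) {
    s <- simulate_two_sample_summary(
      summary_sim_config(k = 17, causal_theta = 0.2, seed = 9000 + i))
    p <- mr_presso(s$hset, n_sim = 400, seed = i)
    p$global_p > 0.05 && !any(p$outliers)
  }, logical(1))
  expect_gte(mean(clean_ok), 0.9)

  flagged <- vapply(1:40, function(i) {
    s <- simulate_two_sample_summary(
      summary_sim_config(k = 17, causal_theta = 0.2, outlier_index = 3,
                         outlier_shift = 10, seed = 9500 + i))
    p <- mr_presso(s$hset, n_sim = 1000, seed = i)
    unname(p$outliers[3])
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})

test_that("all estimators are invariant to ordering and joint sign flips", {
  d <- random_hset(10, seed = 314)
  perm <- c(7, 2, 9, 1, 10, 4, 3, 8, 5, 6)
  flip <- rep(c(1, -1), 5)
  d_perm <- d[perm, ]
  d_flip <- d
  d_flip$beta_x <- d$beta_x * flip
  d_flip$beta_y <- d$beta_y * flip

  for (est in list(function(x) mr_ivw(x, "fixed"),
                   function(x) mr_ivw(x, "random"),
                   mr_max_likelihood,
                   function(x) mr_weighted_median(x, n_boot = 50,
                                                  seed = 77))) {
    base <- est(d)
    expect_equal(est(d_perm)$theta, base$theta, tolerance = 1e-9)
    expect_equal(abs(est(d_flip)$theta), abs(base$theta),
                 tolerance = 1e-9)
  }
  # Egger pre-orients to beta_x >= 0, so joint flips are exact no-ops
  expect_equal(mr_egger(d_flip)$theta, mr_egger(d)$theta, tolerance = 1e-12)
  expect_equal(cochran_q(d_flip)$Q, cochran_q(d)$Q, tolerance = 1e-12)
})

test_that("the battery applies the robustness decision rule", {
  eff <- simulate_two_sample_summary(
    summary_sim_config(k = 17, causal_theta = 0.5, seed = 21))
  b <- run_mr_battery(eff$hset, n_boot = 200, presso_n_sim = 400, seed = 3)
  expect_equal(b$decision, "robust")
  expect_setequal(b$estimates$method,
                  c("ivw_fixed", "weighted_median", "max_likelihood",
                    "egger"))
  ivw_row <- b$estimates[b$estimates$method == "ivw_fixed", ]
  expect_lt(abs(ivw_row$theta - 0.5), 3.5 * ivw_row$se)
  expect_equal(nrow(b$loo), 17L)

  null_dec <- vapply(1:30, function(i) {
    s <- simulate_two_sample_summary(
      summary_sim_config(k = 17, causal_theta = 0, seed = 600 + i))
    run_mr_battery(s$hset, n_boot = 50, presso_n_sim = 200,
                   seed = i)$decision
  }, character(1))
  expect_gte(sum(null_dec == "null"), 24)

  pleio <- simulate_two_sample_summary(
    summary_sim_config(k = 17, causal_theta = 0.4, pleiotropy_mean = 0.08,
                       seed = 22))
  bp <- run_mr_battery(pleio$hset, n_boot = 200, presso_n_sim = 400,
                       seed = 4)
  expect_false(bp$decision == "robust")
})
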