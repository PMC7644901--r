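mr_estimate <- function(method, theta, se, k, pvalue = NULL,
                        intercept = NULL, intercept_se = NULL,
                        intercept_p = NULL, df = NULL) {
  if (is.null(pvalue)) {
    pvalue <- if (is.null(df)) {
      2 * stats::pnorm(-abs(theta / se))
    } else {
      2 * stats::pt(-abs(theta / se), df = df)
    }
  }
  out <- data.frame(method = method, theta = theta, se = se,
                    or_ = exp(theta),
                    ci_lower = exp(theta - 1.96 * se),
                    ci_upper = exp(theta + 1.96 * se),
                    pvalue = pvalue, k = k, stringsAsFactors = FALSE)
  if (!is.null(intercept)) {
    out$intercept <- intercept
    out$intercept_se <- intercept_se
    out$intercept_p <- intercept_p
  }
  out
}

#' Single-instrument Wald ratio
#'
#' `theta = beta_y / beta_x` with first-order standard error
#' `|se_y / beta_x|`.
#'
#' @param beta_x,se_x Exposure effect and SE.
#' @param beta_y,se_y Outcome effect and SE.
#' @return One-row MR estimate data.frame.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("beta_x must be nonzero", call. = FALSE)
  if (se_y <= 0) stop("se_y must be > 0", call. = FALSE)
  mr_estimate("wald_ratio", beta_y / beta_x, abs(se_y / beta_x), 1L)
}

#' Inverse-variance weighted causal estimate
#'
#' Fixed-effect estimator: with weights `w_j = 1/var(beta_yj)`,
#' `theta = sum(w b_y b_x) / sum(w b_x^2)` and
#' `var(theta) = 1 / sum(w b_x^2)`. The random-effects variant inflates
#' the SE by `max(1, sqrt(Q/(k-1)))` (multiplicative random effects).
#'
#' @param hset `harmonized_set` or data.frame with
#'   `beta_x, se_x, beta_y, se_y`.
#' @param model `"fixed"` (default) or `"random"`.
#' @return One-row MR estimate data.frame (methods `ivw_fixed` /
#'   `ivw_random`).
#' @export
mr_ivw <- function(hset, model = c("fixed", "random")) {
  model <- match.arg(model)
  d <- as_harmonized_df(hset)
  k <- nrow(d)
  if (k < 1L) stop("at least one instrument required", call. = FALSE)
  if (model == "random" && k < 2L) {
    stop("random-effects IVW needs k >= 2", call. = FALSE)
  }
  if (all(d$beta_x == 0)) stop("all beta_x are zero", call. = FALSE)
  if (k == 1L) {
    # exact algebraic reduction to the Wald ratio
    theta <- d$beta_y / d$beta_x
    se <- abs(d$se_y / d$beta_x)
  } else {
    w <- 1 / d$se_y^2
    denom <- sum(w * d$beta_x^2)
    theta <- sum(w * d$beta_y * d$beta_x) / denom
    se <- sqrt(1 / denom)
  }
  if (model == "random") {
    q <- cochran_q(d, theta = theta)
    se <- se * max(1, sqrt(q$Q / q$df))
  }
  mr_estimate(paste0("ivw_", model), theta, se, k)
}

#' Cochran's Q heterogeneity test across instruments
#'
#' `Q = sum w_j (beta_yj/beta_xj - theta)^2` with
#' `w_j = beta_xj^2 / var(beta_yj)`, referred to a chi-square with `k - 1`
#' degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @param theta Pooled estimate; defaults to the fixed-effect IVW slope.
#' @return List with `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(hset, theta = NULL) {
  d <- as_harmonized_df(hset)
  k <- nrow(d)
  if (k < 2L) stop("Cochran's Q needs k >= 2", call. = FALSE)
  if (any(d$beta_x == 0)) stop("per-SNP ratios need nonzero beta_x",
                               call. = FALSE)
  if (is.null(theta)) theta <- mr_ivw(d, "fixed")$theta
  w <- d$beta_x^2 / d$se_y^2
  q <- sum(w * (d$beta_y / d$beta_x - theta)^2)
  list(Q = q, df = k - 1L,
       pvalue = stats::pchisq(q, df = k - 1L, lower.tail = FALSE))
}

weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(cum)] <= 0.5) return(b[length(b)])
  i <- max(which(cum < 0.5))
  b[i] + (b[i + 1] - b[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

#' Weighted median causal estimate
#'
#' Per-SNP Wald ratios are ordered and the estimate is the linear
#' interpolation of the inverse-variance-weighted empirical distribution
#' at cumulative weight one half; consistent when at least half the
#' weight comes from valid instruments. The SE is obtained by parametric
#' bootstrap (resampling `beta_x` and `beta_y` from their reported
#' normal sampling distributions).
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap resamples for the SE (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return One-row MR estimate data.frame.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000L, seed = NULL) {
  d <- as_harmonized_df(hset)
  k <- nrow(d)
  if (k < 3L) stop("weighted median needs k >= 3", call. = FALSE)
  if (any(d$beta_x == 0)) stop("per-SNP ratios need nonzero beta_x",
                               call. = FALSE)
  ratio <- d$beta_y / d$beta_x
  w <- d$beta_x^2 / d$se_y^2   # inverse first-order variance of the ratio
  theta <- weighted_median_point(ratio, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, d$beta_x, d$se_x)
      by <- stats::rnorm(k, d$beta_y, d$se_y)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / d$se_y[ok]^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", theta, stats::sd(boot), k)
}

maxlik_profile_loglik <- function(theta, d) {
  # per-SNP true exposure effects profiled out in closed form
  prec <- 1 / d$se_x^2 + theta^2 / d$se_y^2
  mu <- (d$beta_x / d$se_x^2 + theta * d$beta_y / d$se_y^2) / prec
  sum(stats::dnorm(d$beta_x, mu, d$se_x, log = TRUE) +
        stats::dnorm(d$beta_y, theta * mu, d$se_y, log = TRUE))
}

#' Maximum-likelihood causal estimate
#'
#' Maximizes the bivariate normal likelihood of the observed
#' (`beta_x`, `beta_y`) pairs with the per-SNP true exposure effects as
#' nuisance parameters (profiled out in closed form) and a single causal
#' slope; the SE comes from the curvature of the profile log-likelihood
#' at the maximum. Asymptotically equivalent to fixed-effect IVW when
#' there is no heterogeneity.
#'
#' @inheritParams mr_ivw
#' @return One-row MR estimate data.frame (method `max_likelihood`).
#' @export
mr_max_likelihood <- function(hset) {
  d <- as_harmonized_df(hset)
  k <- nrow(d)
  if (k < 2L) stop("maximum likelihood needs k >= 2", call. = FALSE)
  start <- mr_ivw(d, "fixed")
  # 1-D profile likelihood: bracket the IVW solution generously and use
  # golden-section/parabolic search, then curvature by central difference
  half <- max(10 * start$se, 1, abs(start$theta))
  opt <- stats::optimize(function(th) -maxlik_profile_loglik(th, d),
                         interval = start$theta + c(-half, half),
                         tol = 1e-10)
  theta <- opt$minimum
  if (abs(theta - start$theta) >= half * 0.999) {
    stop(sprintf(
      "ML optimizer hit the search boundary (theta = %.4g, IVW start %.4g)",
      theta, start$theta), call. = FALSE)
  }
  h <- max(1e-6, abs(theta) * 1e-4)
  info <- -(maxlik_profile_loglik(theta + h, d) -
              2 * maxlik_profile_loglik(theta, d) +
              maxlik_profile_loglik(theta - h, d)) / h^2
  if (!is.finite(info) || info <= 0) {
    stop("ML information matrix not positive definite", call. = FALSE)
  }
  mr_estimate("max_likelihood", theta, sqrt(1 / info), k)
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_y` on `beta_x` with an unconstrained
#' intercept and weights `1/var(beta_y)`, after orienting every SNP so
#' that `beta_x >= 0` (required for the intercept's interpretation). The
#' intercept estimates the average directional pleiotropic effect; its
#' p-value is the pleiotropy test (intercept p > 0.05 read as no
#' pleiotropy). Standard errors use the multiplicative random-effects
#' convention (residual dispersion not allowed below 1) with t(k-2)
#' reference distributions.
#'
#' @inheritParams mr_ivw
#' @param fit_intercept Set `FALSE` to constrain the intercept to zero
#'   (internal check: then the slope equals fixed-effect IVW).
#' @return One-row MR estimate data.frame with `intercept`,
#'   `intercept_se`, `intercept_p` columns.
#' @export
mr_egger <- function(hset, fit_intercept = TRUE) {
  d <- as_harmonized_df(hset)
  k <- nrow(d)
  if (k < 3L) stop("MR-Egger needs k >= 3", call. = FALSE)
  s <- ifelse(d$beta_x < 0, -1, 1)
  bx <- d$beta_x * s
  by <- d$beta_y * s
  if (stats::sd(bx) == 0) stop("beta_x are collinear (all equal)",
                               call. = FALSE)
  w <- 1 / d$se_y^2
  if (fit_intercept) {
    fit <- stats::lm(by ~ bx, weights = w)
    sigma <- suppressWarnings(summary(fit)$sigma)
    infl <- max(1, sigma)
    # unscaled (fixed-effect) covariance from the weighted design, then
    # inflated multiplicatively when the residual dispersion exceeds 1
    X <- cbind(1, bx)
    v_fixed <- diag(solve(crossprod(X * sqrt(w))))
    se_int <- sqrt(v_fixed[1]) * infl
    se_slope <- sqrt(v_fixed[2]) * infl
    dfree <- k - 2L
    slope <- unname(stats::coef(fit)["bx"])
    intc <- unname(stats::coef(fit)["(Intercept)"])
    mr_estimate("egger", slope, se_slope, k,
                pvalue = 2 * stats::pt(-abs(slope / se_slope), dfree),
                intercept = intc, intercept_se = se_int,
                intercept_p = 2 * stats::pt(-abs(intc / se_int), dfree),
                df = dfree)
  } else {
    fit <- stats::lm(by ~ bx - 1, weights = w)
    # fixed-effect SE directly from the weighted information
    mr_estimate("egger_origin", unname(stats::coef(fit)["bx"]),
                sqrt(1 / sum(w * bx^2)), k)
  }
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect omitting each instrument in turn; a
#' single influential or outlying instrument shows up as a large shift in
#' the estimate when omitted.
#'
#' @inheritParams mr_ivw
#' @param estimator Function of a harmonized data.frame returning a
#'   one-row MR estimate (default fixed-effect IVW).
#' @return data.frame with one row per omitted rsid.
#' @export
leave_one_out <- function(hset, estimator = function(d) mr_ivw(d, "fixed")) {
  d <- as_harmonized_df(hset)
  k <- nrow(d)
  if (k < 2L) stop("leave-one-out needs k >= 2", call. = FALSE)
  rows <- lapply(seq_len(k), function(j) {
    est <- estimator(d[-j, , drop = FALSE])
    cbind(data.frame(rsid_omitted = d$rsid[j], stringsAsFactors = FALSE),
          est)
  })
  do.call(rbind, rows)
}

presso_rss <- function(bx, by, w) {
  # LOO-predicted residual sum of squares, weights 1/var(beta_y)
  s1 <- sum(w * by * bx)
  s2 <- sum(w * bx^2)
  theta_loo <- (s1 - w * by * bx) / (s2 - w * bx^2)
  resid2 <- w * (by - theta_loo * bx)^2
  list(rss = sum(resid2), resid2 = resid2, theta_loo = theta_loo)
}

#' MR-PRESSO global and outlier test
#'
#' Computes the observed leave-one-out-predicted residual sum of squares
#' and compares it with a null distribution obtained by simulating
#' `beta_y` from the LOO-fitted values with the reported variances. The
#' global p-value is the rank-based tail probability with a +1
#' correction; per-SNP outlier flags compare each observed squared
#' residual with its simulated distribution at level 0.05 with Bonferroni
#' correction over k.
#'
#' @inheritParams mr_ivw
#' @param n_sim Number of parametric simulations (default 1000).
#' @param seed Optional integer seed.
#' @param outlier_alpha Per-family outlier level before Bonferroni
#'   (default 0.05).
#' @return List (class `presso_result`) with `rss_observed`, `global_p`,
#'   `outliers` (logical per SNP, rsid-named), `outlier_p`, `n_sim`,
#'   `seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000L, seed = NULL,
                      outlier_alpha = 0.05) {
  d <- as_harmonized_df(hset)
  k <- nrow(d)
  if (k < 4L) stop("MR-PRESSO needs k >= 4", call. = FALSE)
  w <- 1 / d$se_y^2
  obs <- presso_rss(d$beta_x, d$beta_y, w)
  pred <- obs$theta_loo * d$beta_x
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      by_sim <- stats::rnorm(k, pred, d$se_y)
      sim <- presso_rss(d$beta_x, by_sim, w)
      c(sim$rss, sim$resid2)
    }, numeric(1 + k))
  })
  rss_sim <- sims[1, ]
  resid2_sim <- sims[-1, , drop = FALSE]
  global_p <- (1 + sum(rss_sim >= obs$rss)) / (n_sim + 1)
  outlier_p <- vapply(seq_len(k), function(j) {
    (1 + sum(resid2_sim[j, ] >= obs$resid2[j])) / (n_sim + 1)
  }, numeric(1))
  names(outlier_p) <- d$rsid
  outliers <- outlier_p < outlier_alpha / k
  structure(list(rss_observed = obs$rss, global_p = global_p,
                 outliers = outliers, outlier_p = outlier_p,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d sims)\n",
              x$rss_observed, x$global_p, x$n_sim))
  if (any(x$outliers)) {
    cat("  outliers:", paste(names(x$outliers)[x$outliers], collapse = ", "),
        "\n")
  } else cat("  no outliers detected\n")
  invisible(x)
}

#' Full MR estimator and sensitivity battery
#'
#' Runs fixed-effect IVW (switching the headline estimate to
#' random-effects when Cochran's Q rejects at 0.05), weighted median,
#' maximum likelihood and MR-Egger, plus leave-one-out and MR-PRESSO
#' (when k >= 4). The decision rule mirrors the study design: the
#' association is `"robust"` if the IVW, weighted-median and likelihood
#' p-values are all below `alpha`, the Egger intercept p-value is above
#' 0.05 and MR-PRESSO flags no outlier; `"null"` if the headline IVW
#' p-value is at or above `alpha`; otherwise `"non_robust"`.
#'
#' @inheritParams mr_ivw
#' @param alpha Significance level for the decision rule (default 0.05).
#' @param n_boot Bootstrap resamples for the weighted median.
#' @param presso_n_sim Simulations for MR-PRESSO.
#' @param seed Optional integer seed (drives the bootstrap and PRESSO).
#' @return List (class `mr_battery`) with `estimates` (one row per
#'   method), `heterogeneity`, `loo`, `presso`, `decision`, `k`.
#' @export
run_mr_battery <- function(hset, alpha = 0.05, n_boot = 1000L,
                           presso_n_sim = 1000L, seed = NULL) {
  d <- as_harmonized_df(hset)
  k <- nrow(d)
  if (k < 3L) stop("the full battery needs k >= 3", call. = FALSE)
  seeds <- if (is.null(seed)) c(NA, NA) else substream_seeds(seed, 2)
  het <- cochran_q(d)
  ivw_model <- if (het$pvalue > 0.05) "fixed" else "random"
  ivw <- mr_ivw(d, ivw_model)
  wm <- mr_weighted_median(d, n_boot = n_boot,
                           seed = if (is.na(seeds[1])) NULL else seeds[1])
  ml <- mr_max_likelihood(d)
  eg <- mr_egger(d)
  presso <- if (k >= 4L) {
    mr_presso(d, n_sim = presso_n_sim,
              seed = if (is.na(seeds[2])) NULL else seeds[2])
  } else NULL
  no_outlier <- is.null(presso) || !any(presso$outliers)
  decision <- if (ivw$pvalue >= alpha) {
    "null"
  } else if (wm$pvalue < alpha && ml$pvalue < alpha &&
             eg$intercept_p > 0.05 && no_outlier) {
    "robust"
  } else {
    "non_robust"
  }
  estimates <- merge_estimate_rows(list(ivw, wm, ml, eg))
  structure(list(estimates = estimates, heterogeneity = het,
                 loo = leave_one_out(d), presso = presso,
                 decision = decision, k = k),
            class = "mr_battery")
}

merge_estimate_rows <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[cols]
  }))
}

#' @export
print.mr_battery <- function(x, ...) {
  cat(sprintf("MR battery on %d instruments (decision: %s)\n", x$k,
              x$decision))
  cat(sprintf("Cochran's Q = %.3f (df %d, p = %.3g)\n",
              x$heterogeneity$Q, x$heterogeneity$df,
              x$heterogeneity$pvalue))
  print(x$estimates[, c("method", "theta", "se", "or_", "ci_lower",
                        "ci_upper", "pvalue")], row.names = FALSE)
  invisible(x)
}
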