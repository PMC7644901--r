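#' End-to-end GRS association pipeline
#'
#' QC -> GRS -> batch logistic association -> FDR -> classification, with
#' per-stage record counts logged via `message()`.
#'
#' @param gm Samples x variants dosage matrix (already oriented to the
#'   panel effect alleles).
#' @param pheno Phenotype data.frame aligned with `gm` rows.
#' @param outcome_cols,covariate_cols Column names in `pheno`.
#' @param panel An `instrument_panel`; flipped to shorter orientation
#'   internally if needed.
#' @param call_rate_min,maf_min,hwe_p_min QC thresholds.
#' @param min_cases Minimum case count per outcome.
#' @param out_dir Optional directory: writes `grs_association.tsv` and
#'   `qc_report.tsv`.
#' @return The association table (see [run_association_batch()]), with
#'   the QC report and GRS attached as attributes.
#' @export
run_grs_assoc <- function(gm, pheno, outcome_cols, covariate_cols,
                          panel = load_instrument_panel(),
                          call_rate_min = 0.95, maf_min = 0.01,
                          hwe_p_min = 1e-4, min_cases = 60L,
                          out_dir = NULL) {
  if (panel$orientation == "longer") panel <- flip_to_shorter(panel)
  message(sprintf("input: %d samples x %d variants", nrow(gm), ncol(gm)))
  qc <- qc_genotypes(gm, call_rate_min, maf_min, hwe_p_min)
  message(sprintf("QC retained %d/%d variants", ncol(qc$genotypes),
                  ncol(gm)))
  grs <- compute_grs(qc$genotypes, panel)
  message(sprintf("GRS built on %d panel SNPs", grs$n_snps_used))
  res <- run_association_batch(pheno, outcome_cols, covariate_cols, grs,
                               min_cases = min_cases)
  message(sprintf("association: %d outcomes fitted, %d excluded",
                  nrow(res), nrow(attr(res, "excluded"))))
  attr(res, "qc_report") <- qc$report
  attr(res, "grs") <- grs
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res, file.path(out_dir, "grs_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' End-to-end two-sample MR pipeline
#'
#' flip-to-shorter -> harmonize -> Bonferroni pleiotropy prescreen ->
#' full estimator/sensitivity battery; the dropped-SNP ledger is carried
#' in the report.
#'
#' @param panel An `instrument_panel` (longer orientation as published,
#'   or already shorter).
#' @param outcome An `outcome_summary`.
#' @param palindromic_policy Passed to [harmonize()].
#' @param prescreen_alpha Level for [prescreen_pleiotropy()]; `NULL`
#'   skips the prescreen.
#' @param seed,n_boot,presso_n_sim Passed to [run_mr_battery()].
#' @return List with `battery` (`mr_battery`), `hset`, `dropped`.
#' @export
run_mr <- function(panel, outcome,
                   palindromic_policy = c("eaf_infer", "drop"),
                   prescreen_alpha = 0.05, seed = NULL,
                   n_boot = 1000L, presso_n_sim = 1000L) {
  palindromic_policy <- match.arg(palindromic_policy)
  if (panel$orientation == "longer") panel <- flip_to_shorter(panel)
  hset <- harmonize(panel, outcome, palindromic_policy)
  message(sprintf("harmonized %d/%d instruments", nrow(hset$data),
                  nrow(panel$records)))
  if (!is.null(prescreen_alpha)) {
    hset <- prescreen_pleiotropy(hset, prescreen_alpha)
    message(sprintf("%d instruments after pleiotropy prescreen",
                    nrow(hset$data)))
  }
  if (nrow(hset$data) == 0L) stop("no instruments remain", call. = FALSE)
  battery <- run_mr_battery(hset, seed = seed, n_boot = n_boot,
                            presso_n_sim = presso_n_sim)
  list(battery = battery, hset = hset, dropped = hset$dropped)
}

#' Power-grid driver
#'
#' Runs both Monte-Carlo power designs over the study's grid (GRS effects
#' 0.05/0.10/0.20; survival cohort sizes or case counts 100/300/500) and
#' optionally writes TSV output.
#'
#' @param cfg A `sim_config`.
#' @param design `"surv"`, `"cc"` or `"both"`.
#' @param n_grid Sizes (cohort sizes for survival, case counts for
#'   case-control).
#' @param theta_grid GRS effects.
#' @param out_dir Optional output directory for `power_<design>.tsv`.
#' @return data.frame combining the requested grids.
#' @export
run_power <- function(cfg, design = c("both", "surv", "cc"),
                      n_grid = c(100L, 300L, 500L),
                      theta_grid = c(0.05, 0.10, 0.20),
                      out_dir = NULL) {
  design <- match.arg(design)
  grids <- list()
  if (design %in% c("both", "surv")) {
    grids$surv <- power_survival(cfg, n_grid, theta_grid)
  }
  if (design %in% c("both", "cc")) {
    grids$cc <- power_case_control(cfg, n_grid, theta_grid)
  }
  out <- do.call(rbind, grids)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(grids)) {
      utils::write.table(grids[[nm]],
                         file.path(out_dir, paste0("power_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
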