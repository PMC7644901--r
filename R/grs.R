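#' Weighted, standardized genetic risk score
#'
#' Computes the per-individual weighted allele score
#' `raw_i = sum_j dosage_ij * beta_j` over the SNPs shared between the
#' genotype matrix and the panel, then standardizes it to mean 0 and
#' variance 1 within the analysis sample. Weights are the panel betas,
#' which must be oriented to shorter telomere length so that positive
#' scores mean genetically shorter telomeres.
#'
#' @param gm Numeric samples x variants dosage matrix in `[0,2]` counting
#'   the panel effect allele; NA = missing.
#' @param panel An `instrument_panel` with orientation `"shorter"`.
#' @param missing_policy `"mean_impute"` (default; missing dosages replaced
#'   by `2 * eaf` from the panel) or `"drop_sample"` (samples with any
#'   missing used dosage removed).
#' @return Object of class `grs_vector`: list with `sample_id`, `raw`,
#'   `standardized`, `n_snps_used`, `snps_used`.
#' @examples
#' panel <- flip_to_shorter(load_instrument_panel())
#' gm <- simulate_genotypes(100, panel$records$eaf, seed = 1)
#' colnames(gm) <- panel$records$rsid
#' grs <- compute_grs(gm, panel)
#' round(mean(grs$standardized), 12)
#' @export
compute_grs <- function(gm, panel,
                        missing_policy = c("mean_impute", "drop_sample")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(panel, "instrument_panel"))
  if (panel$orientation != "shorter") {
    stop("compute_grs expects a shorter-oriented panel; ",
         "call flip_to_shorter() first", call. = FALSE)
  }
  validate_dosages(gm)
  rec <- panel$records
  shared <- intersect(rec$rsid, colnames(gm))
  if (length(shared) == 0L) {
    stop("no panel SNPs present in the genotype matrix", call. = FALSE)
  }
  sub <- gm[, shared, drop = FALSE]
  idx <- match(shared, rec$rsid)
  w <- rec$beta[idx]
  if (missing_policy == "mean_impute") {
    if (anyNA(sub)) {
      fill <- 2 * rec$eaf[idx]
      for (j in seq_along(shared)) {
        miss <- is.na(sub[, j])
        if (any(miss)) sub[miss, j] <- fill[j]
      }
    }
  } else {
    complete <- stats::complete.cases(sub)
    if (!any(complete)) stop("no samples with complete dosages",
                             call. = FALSE)
    sub <- sub[complete, , drop = FALSE]
  }
  raw <- as.vector(sub %*% w)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    stop("raw GRS has zero variance; cannot standardize", call. = FALSE)
  }
  structure(list(sample_id = rownames(sub) %||% seq_along(raw),
                 raw = raw,
                 standardized = (raw - mean(raw)) / s,
                 n_snps_used = length(shared),
                 snps_used = shared),
            class = "grs_vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grs_vector <- function(x, ...) {
  cat(sprintf("GRS over %d SNPs for %d samples (raw mean %.4g, sd %.4g)\n",
              x$n_snps_used, length(x$raw), mean(x$raw), stats::sd(x$raw)))
  invisible(x)
}
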