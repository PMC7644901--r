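complement_base <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(a1, a2) a1 == complement_base(a2)

#' Load outcome GWAS summary statistics
#'
#' Reads a tab-separated outcome file with a configurable column mapping,
#' so that arbitrary GWAS header dialects (e.g. Pan-UKB style) can be
#' absorbed without rewriting files.
#'
#' @param path Path to the TSV file.
#' @param col_map Named character vector mapping the standard names
#'   (`rsid, effect_allele, other_allele, beta, se, pvalue, eaf`) to the
#'   column names present in the file. `eaf` and `pvalue` are optional.
#' @return data.frame with standardized columns; class `outcome_summary`.
#' @export
load_outcome_summary <- function(path,
                                 col_map = c(rsid = "rsid",
                                             effect_allele = "a1",
                                             other_allele = "a2",
                                             beta = "beta",
                                             se = "se",
                                             pvalue = "pvalue",
                                             eaf = "eaf")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  outcome_summary_from_df(df, col_map)
}

#' @rdname load_outcome_summary
#' @param df data.frame already in memory.
#' @export
outcome_summary_from_df <- function(df,
                                    col_map = c(rsid = "rsid",
                                                effect_allele = "a1",
                                                other_allele = "a2",
                                                beta = "beta",
                                                se = "se",
                                                pvalue = "pvalue",
                                                eaf = "eaf")) {
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  for (std in required) {
    src <- col_map[[std]]
    if (is.null(src) || !src %in% names(df)) {
      stop(sprintf("outcome summary lacks required column '%s' (mapped from '%s')",
                   std, if (is.null(src)) "<unmapped>" else src),
           call. = FALSE)
    }
  }
  out <- data.frame(
    rsid = as.character(df[[col_map[["rsid"]]]]),
    effect_allele = toupper(as.character(df[[col_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(df[[col_map[["other_allele"]]]])),
    beta = as.numeric(df[[col_map[["beta"]]]]),
    se = as.numeric(df[[col_map[["se"]]]]),
    stringsAsFactors = FALSE)
  out$pvalue <- if (!is.na(col_map["pvalue"]) && col_map[["pvalue"]] %in% names(df))
    as.numeric(df[[col_map[["pvalue"]]]]) else NA_real_
  out$eaf <- if (!is.na(col_map["eaf"]) && col_map[["eaf"]] %in% names(df))
    as.numeric(df[[col_map[["eaf"]]]]) else NA_real_
  if (any(out$se <= 0, na.rm = TRUE)) {
    stop("outcome summary contains se <= 0", call. = FALSE)
  }
  class(out) <- c("outcome_summary", "data.frame")
  out
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns per-SNP outcome effects to the panel's effect allele. Outcome
#' records whose alleles match after swapping have `beta_y` negated; strand
#' (complement) matches are resolved likewise. Palindromic (A/T or C/G)
#' SNPs are handled per `palindromic_policy`: `"eaf_infer"` aligns by
#' effect-allele-frequency concordance when both frequencies fall outside
#' the ambiguity band, otherwise drops; `"drop"` always drops. SNPs absent
#' from the outcome are dropped with reason `"missing"`; irreconcilable
#' allele pairs with reason `"allele_mismatch"`.
#'
#' @param panel An `instrument_panel`, oriented `"shorter"` for reporting.
#' @param outcome An `outcome_summary` data.frame.
#' @param palindromic_policy `"eaf_infer"` (default) or `"drop"`.
#' @param ambiguity_band Frequency band within which EAF cannot resolve a
#'   palindromic SNP; default `c(0.42, 0.58)`.
#' @return Object of class `harmonized_set`: list with `data` (rsid,
#'   beta_x, se_x, beta_y, se_y, pvalue_y, eaf_x, eaf_y) and `dropped`
#'   (rsid, reason).
#' @export
harmonize <- function(panel, outcome,
                      palindromic_policy = c("eaf_infer", "drop"),
                      ambiguity_band = c(0.42, 0.58)) {
  stopifnot(inherits(panel, "instrument_panel"))
  palindromic_policy <- match.arg(palindromic_policy)
  if (panel$orientation != "shorter") {
    stop("harmonize expects a panel oriented to shorter telomere length; ",
         "call flip_to_shorter() first", call. = FALSE)
  }
  rec <- panel$records
  kept <- list()
  dropped <- list()
  drop <- function(rsid, reason) {
    dropped[[length(dropped) + 1L]] <<- data.frame(rsid = rsid,
                                                   reason = reason,
                                                   stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    j <- match(r$rsid, outcome$rsid)
    if (is.na(j)) { drop(r$rsid, "missing"); next }
    o <- outcome[j, ]
    e <- o$effect_allele; oth <- o$other_allele
    flip <- NA
    if (is_palindromic(r$a1, r$a2)) {
      if (!setequal(c(e, oth), c(r$a1, r$a2))) {
        drop(r$rsid, "allele_mismatch"); next
      }
      if (palindromic_policy == "drop") { drop(r$rsid, "palindromic"); next }
      if (is.na(o$eaf)) { drop(r$rsid, "palindromic_no_eaf"); next }
      ambiguous <- function(f) f >= ambiguity_band[1] & f <= ambiguity_band[2]
      if (ambiguous(r$eaf) || ambiguous(o$eaf)) {
        drop(r$rsid, "palindromic_ambiguous"); next
      }
      # strand labels are uninformative; align by frequency concordance
      flip <- (r$eaf < 0.5) != (o$eaf < 0.5)
    } else if (setequal(c(e, oth), c(r$a1, r$a2))) {
      flip <- e != r$a1
    } else if (setequal(c(complement_base(e), complement_base(oth)),
                        c(r$a1, r$a2))) {
      flip <- complement_base(e) != r$a1
    } else {
      drop(r$rsid, "allele_mismatch"); next
    }
    beta_y <- if (flip) -o$beta else o$beta
    eaf_y <- if (is.na(o$eaf)) NA_real_ else if (flip) 1 - o$eaf else o$eaf
    kept[[length(kept) + 1L]] <- data.frame(
      rsid = r$rsid, beta_x = r$beta, se_x = r$se,
      beta_y = beta_y, se_y = o$se, pvalue_y = o$pvalue,
      eaf_x = r$eaf, eaf_y = eaf_y, stringsAsFactors = FALSE)
  }
  data <- if (length(kept)) do.call(rbind, kept) else
    data.frame(rsid = character(), beta_x = numeric(), se_x = numeric(),
               beta_y = numeric(), se_y = numeric(), pvalue_y = numeric(),
               eaf_x = numeric(), eaf_y = numeric())
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(rsid = character(), reason = character())
  structure(list(data = data, dropped = dropped), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %d SNPs retained, %d dropped\n",
              nrow(x$data), nrow(x$dropped)))
  if (nrow(x$dropped)) {
    cat(paste0("  dropped ", x$dropped$rsid, " (", x$dropped$reason, ")\n"),
        sep = "")
  }
  invisible(x)
}

#' Bonferroni prescreen for instrument-outcome pleiotropy
#'
#' Removes instruments whose outcome association p-value is below
#' `alpha / k` (k = number of retained SNPs before screening), i.e. SNPs
#' whose Bonferroni-adjusted outcome p is below `alpha` and which may
#' therefore affect the outcome through a path other than the exposure.
#'
#' @param hset A `harmonized_set` whose retained SNPs carry `pvalue_y`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return The screened `harmonized_set`, with removals recorded under
#'   reason `"pleiotropy_prescreen"`.
#' @export
prescreen_pleiotropy <- function(hset, alpha = 0.05) {
  stopifnot(inherits(hset, "harmonized_set"))
  d <- hset$data
  if (nrow(d) == 0L) stop("no instruments remain", call. = FALSE)
  if (anyNA(d$pvalue_y)) {
    stop("every retained SNP needs an outcome p-value for prescreening",
         call. = FALSE)
  }
  k <- nrow(d)
  hit <- d$pvalue_y < alpha / k
  if (all(hit)) stop("no instruments remain", call. = FALSE)
  if (any(hit)) {
    hset$dropped <- rbind(hset$dropped,
                          data.frame(rsid = d$rsid[hit],
                                     reason = "pleiotropy_prescreen",
                                     stringsAsFactors = FALSE))
    hset$data <- d[!hit, , drop = FALSE]
    rownames(hset$data) <- NULL
  }
  hset
}

#' Coerce MR inputs to a harmonized data.frame
#'
#' Accepts a `harmonized_set` or a data.frame with columns
#' `beta_x, se_x, beta_y, se_y` (optionally `rsid`).
#' @param x Input object.
#' @return data.frame with an `rsid` column.
#' @keywords internal
as_harmonized_df <- function(x) {
  d <- if (inherits(x, "harmonized_set")) x$data else as.data.frame(x)
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(d))) {
    stop("harmonized data must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(d$rsid)) d$rsid <- paste0("snp_", seq_len(nrow(d)))
  if (any(d$se_x <= 0) || any(d$se_y <= 0)) {
    stop("all standard errors must be > 0", call. = FALSE)
  }
  d
}
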