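VALID_BASES <- c("A", "C", "G", "T")

#' Path to the packaged telomere-length instrument panel
#'
#' Tab-separated panel of the 17 independent index SNPs associated with
#' leukocyte telomere length in the European-ancestry exposure GWAS
#' (N = 78,592), with effect sizes oriented to *longer* telomere length
#' as published.
#'
#' @return Filesystem path to the TSV fixture.
#' @export
ltl_panel_path <- function() {
  system.file("extdata", "ltl_instruments.tsv", package = "grsmr",
              mustWork = TRUE)
}

#' Sample size of the telomere-length exposure GWAS
#' @export
LTL_GWAS_N <- 78592L

validate_instrument_records <- function(df) {
  required <- c("rsid", "a1", "a2", "eaf", "beta", "se", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("instrument panel is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("eaf", "beta", "se", "pvalue")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s' at row %d ('%s')",
                     col, bad[1L], v[bad[1L]]), call. = FALSE)
      }
      df[[col]] <- vn
    }
    if (anyNA(df[[col]])) {
      stop(sprintf("missing value in column '%s' at row %d",
                   col, which(is.na(df[[col]]))[1L]), call. = FALSE)
    }
  }
  if (anyDuplicated(df$rsid)) {
    stop("duplicate rsid(s): ",
         paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "),
         call. = FALSE)
  }
  df$a1 <- toupper(df$a1)
  df$a2 <- toupper(df$a2)
  if (!all(df$a1 %in% VALID_BASES) || !all(df$a2 %in% VALID_BASES)) {
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  }
  if (any(df$a1 == df$a2)) {
    stop("effect and other allele identical for: ",
         paste(df$rsid[df$a1 == df$a2], collapse = ", "), call. = FALSE)
  }
  if (any(df$eaf <= 0 | df$eaf >= 1)) {
    stop("eaf must lie strictly in (0,1); offending rsid: ",
         df$rsid[which(df$eaf <= 0 | df$eaf >= 1)[1L]], call. = FALSE)
  }
  if (any(df$se <= 0)) {
    stop("se must be > 0; offending rsid: ",
         df$rsid[which(df$se <= 0)[1L]], call. = FALSE)
  }
  if (any(df$pvalue <= 0 | df$pvalue > 1)) {
    stop("pvalue must lie in (0,1]; offending rsid: ",
         df$rsid[which(df$pvalue <= 0 | df$pvalue > 1)[1L]], call. = FALSE)
  }
  df
}

#' Load an exposure instrument panel
#'
#' Reads a tab-separated instrument file (columns `rsid, chr, pos, gene,
#' a1, a2, eaf, beta, se, pvalue`; `a1` is the effect allele) and returns a
#' validated panel. As published, effect sizes are oriented to *longer*
#' telomere length; use [flip_to_shorter()] before score construction or
#' harmonization so that associations refer to shorter telomeres.
#'
#' @param path Path to the TSV file (default: the packaged 17-SNP panel).
#' @param gwas_n Sample size of the exposure GWAS; must exceed the number
#'   of instruments by more than one.
#' @param orientation Orientation of the betas in the file.
#' @return An object of class `instrument_panel`: list with `records`
#'   (data.frame), `orientation` and `gwas_n`.
#' @examples
#' panel <- load_instrument_panel()
#' nrow(panel$records)
#' @export
load_instrument_panel <- function(path = ltl_panel_path(),
                                  gwas_n = LTL_GWAS_N,
                                  orientation = c("longer", "shorter")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df <- validate_instrument_records(df)
  gwas_n <- as.integer(gwas_n)
  if (is.na(gwas_n) || gwas_n <= nrow(df) + 1L) {
    stop("gwas_n must exceed the number of instruments + 1", call. = FALSE)
  }
  structure(list(records = df, orientation = orientation, gwas_n = gwas_n),
            class = "instrument_panel")
}

#' Construct an instrument panel from a data.frame
#'
#' @inheritParams load_instrument_panel
#' @param records data.frame with the panel columns.
#' @export
instrument_panel <- function(records, gwas_n,
                             orientation = c("longer", "shorter")) {
  orientation <- match.arg(orientation)
  records <- validate_instrument_records(as.data.frame(records))
  gwas_n <- as.integer(gwas_n)
  if (is.na(gwas_n) || gwas_n <= nrow(records) + 1L) {
    stop("gwas_n must exceed the number of instruments + 1", call. = FALSE)
  }
  structure(list(records = records, orientation = orientation,
                 gwas_n = gwas_n),
            class = "instrument_panel")
}

#' @export
print.instrument_panel <- function(x, ...) {
  cat(sprintf("Instrument panel: %d SNPs, orientation = %s, GWAS n = %d\n",
              nrow(x$records), x$orientation, x$gwas_n))
  invisible(x)
}

#' Re-orient a panel so effects refer to shorter telomere length
#'
#' Negates every beta; alleles, EAF, SE and p-values are unchanged. Guards
#' against double application.
#'
#' @param panel An `instrument_panel` with orientation `"longer"`.
#' @return The panel with orientation `"shorter"`.
#' @seealso [flip_to_longer()] for the explicit inverse.
#' @export
flip_to_shorter <- function(panel) {
  stopifnot(inherits(panel, "instrument_panel"))
  if (panel$orientation != "longer") {
    stop("panel is already oriented to shorter telomere length", call. = FALSE)
  }
  panel$records$beta <- -panel$records$beta
  panel$orientation <- "shorter"
  panel
}

#' @rdname flip_to_shorter
#' @export
flip_to_longer <- function(panel) {
  stopifnot(inherits(panel, "instrument_panel"))
  if (panel$orientation != "shorter") {
    stop("panel is already oriented to longer telomere length", call. = FALSE)
  }
  panel$records$beta <- -panel$records$beta
  panel$orientation <- "longer"
  panel
}

#' Instrument-strength F statistic
#'
#' The squared Wald ratio `(beta/se)^2`; values above 10 conventionally
#' rule out weak-instrument bias.
#'
#' @param beta Effect size(s).
#' @param se Standard error(s), all > 0.
#' @return Vector of F statistics, >= 0.
#' @examples
#' f_statistic(0.086, 0.006) # 205.4
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  (beta / se)^2
}

#' Proportion of exposure variance explained by an instrument
#'
#' `PVE = F / (F + n - 2)` where `F` is the instrument F statistic and `n`
#' the exposure GWAS sample size; equivalent to
#' `beta^2 / (beta^2 + se^2 (n - 2))`.
#'
#' @param f F statistic(s), >= 0.
#' @param gwas_n Exposure GWAS sample size, > 2.
#' @return PVE in `[0, 1)`.
#' @export
proportion_variance_explained <- function(f, gwas_n) {
  if (any(f < 0)) stop("F must be >= 0", call. = FALSE)
  if (gwas_n <= 2) stop("gwas_n must be > 2", call. = FALSE)
  f / (f + gwas_n - 2)
}

#' Per-SNP and aggregate instrument strength
#'
#' @param panel An `instrument_panel`.
#' @param weak_f_threshold F below which a SNP is flagged as weak.
#' @return List with `per_snp` (rsid, F, PVE, weak flag), `total_pve`,
#'   `f_min`, `f_mean`, `f_max`, `n_weak`.
#' @export
summarize_instrument_strength <- function(panel, weak_f_threshold = 10) {
  stopifnot(inherits(panel, "instrument_panel"))
  rec <- panel$records
  if (nrow(rec) == 0L) stop("panel is empty", call. = FALSE)
  f <- f_statistic(rec$beta, rec$se)
  pve <- proportion_variance_explained(f, panel$gwas_n)
  per_snp <- data.frame(rsid = rec$rsid, f = f, pve = pve,
                        weak = f < weak_f_threshold,
                        stringsAsFactors = FALSE)
  list(per_snp = per_snp,
       total_pve = sum(pve),
       f_min = min(f), f_mean = mean(f), f_max = max(f),
       n_weak = sum(per_snp$weak))
}
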