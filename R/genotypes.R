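validate_dosages <- function(gm) {
  if (!is.matrix(gm) || !is.numeric(gm)) {
    stop("genotype matrix must be a numeric matrix (samples x variants)",
         call. = FALSE)
  }
  if (is.null(colnames(gm))) stop("variant names (colnames) required",
                                  call. = FALSE)
  if (anyDuplicated(colnames(gm))) stop("duplicate variant ids",
                                        call. = FALSE)
  rng <- range(gm, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  invisible(gm)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional-on-allele-counts exact test: enumerates every heterozygote
#' count compatible with the observed allele counts and sums the
#' probabilities of configurations no more likely than the observed one
#' (no mid-p correction).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0L) return(1)
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  # heterozygote counts share the parity of the rare-allele count
  h <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  log_prob <- h * log(2) +
    lfactorial(n) - lfactorial((n_rare - h) / 2) - lfactorial(h) -
    lfactorial(n - (n_rare + h) / 2)
  log_prob <- log_prob - max(log_prob)
  prob <- exp(log_prob)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, h)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Removes variants failing any of: call rate below `call_rate_min`, minor
#' allele frequency below `maf_min`, or exact Hardy-Weinberg p-value below
#' `hwe_p_min`. The HWE test uses hard calls (dosages rounded to the
#' nearest integer) on non-missing samples only; MAF and call rate use the
#' dosages as given.
#'
#' @param gm Numeric samples x variants dosage matrix in `[0,2]`,
#'   NA = missing.
#' @param call_rate_min Minimum fraction of non-missing genotypes
#'   (default 0.95).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param hwe_p_min Minimum exact HWE p-value (default 1e-4).
#' @return List with `genotypes` (filtered matrix) and `report`
#'   (data.frame rsid, filter, value for each removed variant).
#' @export
qc_genotypes <- function(gm, call_rate_min = 0.95, maf_min = 0.01,
                         hwe_p_min = 1e-4) {
  validate_dosages(gm)
  if (ncol(gm) == 0L || nrow(gm) == 0L) stop("empty genotype matrix",
                                             call. = FALSE)
  report <- list()
  fail <- function(rsid, filter, value) {
    report[[length(report) + 1L]] <<- data.frame(
      rsid = rsid, filter = filter, value = value, stringsAsFactors = FALSE)
  }
  keep <- rep(TRUE, ncol(gm))
  for (j in seq_len(ncol(gm))) {
    d <- gm[, j]
    cr <- mean(!is.na(d))
    if (cr < call_rate_min) { keep[j] <- FALSE
      fail(colnames(gm)[j], "call_rate", cr); next }
    af <- mean(d, na.rm = TRUE) / 2
    maf <- min(af, 1 - af)
    if (maf < maf_min) { keep[j] <- FALSE
      fail(colnames(gm)[j], "maf", maf); next }
    hard <- round(d[!is.na(d)])
    p <- hwe_exact_test(sum(hard == 0), sum(hard == 1), sum(hard == 2))
    if (p < hwe_p_min) { keep[j] <- FALSE
      fail(colnames(gm)[j], "hwe", p) }
  }
  if (!any(keep)) stop("all variants removed by QC", call. = FALSE)
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(rsid = character(), filter = character(), value = numeric())
  list(genotypes = gm[, keep, drop = FALSE], report = report)
}

#' Read genotype dosages from VCF or TSV
#'
#' For VCF input, uses the `DS` FORMAT field when present, otherwise
#' counts ALT alleles in `GT`. Dosages are oriented to the panel's effect
#' allele: records whose ALT is the panel's *other* allele are recoded as
#' `2 - dosage`; records matching neither allele configuration are
#' excluded with a warning. TSV input is a samples x variants numeric
#' table (first column = sample id) assumed already to count the panel
#' effect allele.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"`.
#' @param panel Optional `instrument_panel` used to orient VCF alleles
#'   (required for `format = "vcf"`).
#' @return Numeric samples x variants matrix with rsid colnames.
#' @export
read_dosages <- function(path, format = c("tsv", "vcf"), panel = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    gm <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(gm) <- "double"
    rownames(gm) <- as.character(df[[1]])
    validate_dosages(gm)
    return(gm)
  }
  if (is.null(panel)) {
    stop("VCF input requires an instrument panel to orient alleles",
         call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix  # matrix with CHROM/POS/ID/REF/ALT columns, even for 1 row
  fix <- as.data.frame(fix[, c("ID", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  colnames(fix) <- c("ID", "REF", "ALT")
  fmt <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                  error = function(e) NULL)
  if (is.null(fmt) || all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fmt <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  rec <- panel$records
  cols <- list()
  for (i in seq_len(nrow(fix))) {
    rsid <- fix$ID[i]
    k <- match(rsid, rec$rsid)
    if (is.na(k)) next
    ref <- toupper(fix$REF[i]); alt <- toupper(fix$ALT[i])
    e <- rec$a1[k]; o <- rec$a2[k]
    d <- fmt[i, ]
    if (alt == e && ref == o) {
      cols[[rsid]] <- d
    } else if (alt == o && ref == e) {
      cols[[rsid]] <- 2 - d
    } else {
      warning(sprintf("variant %s (%s/%s) matches neither panel allele pair (%s/%s); excluded",
                      rsid, ref, alt, e, o), call. = FALSE)
    }
  }
  if (!length(cols)) stop("no VCF variants matched the panel", call. = FALSE)
  gm <- do.call(cbind, cols)
  rownames(gm) <- colnames(fmt)
  validate_dosages(gm)
  gm
}
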