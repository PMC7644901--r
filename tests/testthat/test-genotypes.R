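test_that("exact HWE test matches an independent enumeration oracle", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(10, 20, 70), c(0, 0, 50),
                c(3, 1, 0), c(12, 36, 2), c(88, 10, 2))
  for (cc in cases) {
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 oracle_hwe(cc[1], cc[2], cc[3]), tolerance = 1e-10,
                 info = paste(cc, collapse = "/"))
  }
  expect_gt(hwe_exact_test(25, 50, 25), 0.99)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-4)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    p <- runif(1, 0.05, 0.95)
    g <- tabulate(rbinom(n, 2, p) + 1L, nbins = 3)
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 oracle_hwe(g[1], g[2], g[3]), tolerance = 1e-10)
  }
})

test_that("genotype QC applies call-rate, MAF and HWE filters", {
  set.seed(5)
  n <- 200
  gm <- cbind(
    good = rbinom(n, 2, 0.3),
    rare = rbinom(n, 2, 0.005),           # MAF below 0.01
    noisy = rbinom(n, 2, 0.4),            # call rate pushed below 0.95
    hwe_bad = c(rep(0, 100), rep(2, 100)) # no heterozygotes at MAF 0.5
  )
  storage.mode(gm) <- "double"
  gm[1:20, "noisy"] <- NA
  qc <- qc_genotypes(gm)
  expect_equal(colnames(qc$genotypes), "good")
  expect_setequal(qc$report$rsid, c("rare", "noisy", "hwe_bad"))
  expect_equal(qc$report$filter[qc$report$rsid == "rare"], "maf")
  expect_equal(qc$report$filter[qc$report$rsid == "noisy"], "call_rate")
  expect_equal(qc$report$filter[qc$report$rsid == "hwe_bad"], "hwe")

  perfect <- matrix(rep(c(0, 1, 2), times = c(25, 50, 25)), ncol = 1,
                    dimnames = list(NULL, "bal"))
  expect_equal(ncol(qc_genotypes(perfect)$genotypes), 1L)

  all_bad <- matrix(rbinom(n, 2, 0.001), ncol = 1,
                    dimnames = list(NULL, "x"))
  expect_error(qc_genotypes(all_bad), "all variants removed")
})

test_that("TSV dosage input validates its range", {
  df <- data.frame(sample_id = c("s1", "s2"), rs1 = c(0, 2), rs2 = c(1, 0.5))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- read_dosages(path, format = "tsv")
  expect_equal(dim(gm), c(2L, 2L))
  expect_equal(rownames(gm), c("s1", "s2"))

  df$rs2[1] <- 2.3
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dosages(path, format = "tsv"), "\\[0, 2\\]")
})

write_test_vcf <- function(ref, alt, rsid = "rs228595") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("11", "108105593", rsid, ref, alt, ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t")), path)
  path
}

test_that("VCF dosages are oriented to the panel effect allele", {
  panel <- load_instrument_panel()  # rs228595 effect A, other G
  gm <- read_dosages(write_test_vcf("G", "A"), format = "vcf", panel = panel)
  expect_equal(unname(gm[, "rs228595"]), c(0, 1, 2))

  gm2 <- read_dosages(write_test_vcf("A", "G"), format = "vcf",
                      panel = panel)
  expect_equal(unname(gm2[, "rs228595"]), c(2, 1, 0))

  expect_warning(
    expect_error(read_dosages(write_test_vcf("C", "A"), format = "vcf",
                              panel = panel), "no VCF variants matched"),
    "neither panel allele pair")
})

test_that("compute_grs reproduces a hand-worked weighted sum", {
  rec <- load_instrument_panel()$records[1:3, ]
  rec$beta <- c(-0.086, 0.05, 0.02)
  rec$eaf <- c(0.24, 0.5, 0.3)
  panel <- instrument_panel(rec, gwas_n = 1000, orientation = "shorter")
  gm <- matrix(c(2, 1, 0, 1, 2,
                 0, 1, 2, 2, 0,
                 1, 1, 1, 0, 2), nrow = 5,
               dimnames = list(paste0("s", 1:5), rec$rsid))
  grs <- compute_grs(gm, panel)
  hand <- c(2 * -0.086 + 0 * 0.05 + 1 * 0.02,
            1 * -0.086 + 1 * 0.05 + 1 * 0.02,
            0 * -0.086 + 2 * 0.05 + 1 * 0.02,
            1 * -0.086 + 2 * 0.05 + 0 * 0.02,
            2 * -0.086 + 0 * 0.05 + 2 * 0.02)
  expect_equal(grs$raw, hand)
  expect_equal(mean(grs$standardized), 0)
  expect_equal(stats::var(grs$standardized), 1)

  # one SNP, dosages 2 and 0: raw is dosage times weight
  two <- compute_grs(matrix(c(2, 0), 2, 1,
                            dimnames = list(c("s1", "s2"), rec$rsid[1])),
                     instrument_panel(rec[1, ], gwas_n = 1000,
                                      orientation = "shorter"))
  expect_equal(two$raw, c(-0.172, 0))
})

test_that("compute_grs guards degenerate inputs and orientations", {
  panel <- flip_to_shorter(load_instrument_panel())
  gm0 <- matrix(0, 4, 2,
                dimnames = list(NULL, panel$records$rsid[1:2]))
  expect_error(compute_grs(gm0, panel), "zero variance")
  gm <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "rs_absent"))
  expect_error(compute_grs(gm, panel), "no panel SNPs")
  expect_error(compute_grs(gm, load_instrument_panel()), "shorter")
})

test_that("missing-dosage policies agree on complete data and impute 2*EAF", {
  panel <- flip_to_shorter(load_instrument_panel())
  gm <- simulate_genotypes(50, panel$records$eaf, seed = 8)
  colnames(gm) <- panel$records$rsid
  a <- compute_grs(gm, panel, missing_policy = "mean_impute")
  b <- compute_grs(gm, panel, missing_policy = "drop_sample")
  expect_identical(a$raw, b$raw)

  gm_na <- gm
  gm_na[1, 1] <- NA
  imp <- compute_grs(gm_na, panel, missing_policy = "mean_impute")
  expected_first <- a$raw[1] +
    (2 * panel$records$eaf[1] - gm[1, 1]) * panel$records$beta[1]
  expect_equal(imp$raw[1], unname(expected_first))
  drp <- compute_grs(gm_na, panel, missing_policy = "drop_sample")
  expect_equal(length(drp$raw), 49L)
})

test_that("the GRS is affine-invariant and equivariant to ordering", {
  panel <- flip_to_shorter(load_instrument_panel())
  gm <- simulate_genotypes(80, panel$records$eaf, seed = 21)
  colnames(gm) <- panel$records$rsid
  base <- compute_grs(gm, panel)

  scaled <- panel
  scaled$records$beta <- scaled$records$beta * 3.7
  expect_equal(compute_grs(gm, scaled)$standardized, base$standardized)

  set.seed(4)
  perm <- sample(nrow(gm))
  expect_equal(compute_grs(gm[perm, ], panel)$standardized,
               base$standardized[perm])

  vperm <- sample(ncol(gm))
  expect_equal(compute_grs(gm[, vperm], panel)$raw, base$raw)
})
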