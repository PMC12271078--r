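# Reading, writing, validating summary statistics; panels; LD; harmonisation.

test_that("summary statistics survive a write/read round trip", {
  ss <- make_ss(100, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait_id = "trait")
  expect_equal(back$variant_id, ss$variant_id)
  expect_equal(back$effect_allele, ss$effect_allele)
  expect_equal(back$other_allele, ss$other_allele)
  for (col in c("chrom", "pos", "eaf", "beta", "se", "pval", "n")) {
    expect_equal(back[[col]], ss[[col]], tolerance = 1e-12)
  }
  # empty and single-record tables
  e <- ss_from_z(1)[0, ]
  empty <- summary_stats(e, "t")
  p2 <- withr::local_tempfile()
  write_summary_stats(empty, p2)
  expect_length(readLines(p2), 1L)
  one <- make_ss(1)
  write_summary_stats(one, p2)
  expect_length(readLines(p2), 2L)
})

test_that("validation rejects rows violating hard invariants, with reasons", {
  df <- make_ss_df(6)
  df$se[2] <- 0
  df$eaf[3] <- 1.2
  df$chrom[4] <- 23
  df$other_allele[5] <- "A"   # identical alleles
  df$variant_id[6] <- df$variant_id[1]
  ss <- summary_stats(df, "t")
  expect_equal(nrow(ss), 1L)
  rej <- attr(ss, "rejected")
  expect_setequal(rej$reason,
                  c("nonpositive se", "eaf outside (0,1)",
                    "chromosome outside 1-22", "identical alleles",
                    "duplicate variant id"))
  # indel rejected at read time
  df2 <- make_ss_df(2)
  df2$effect_allele[1] <- "AT"
  ss2 <- summary_stats(df2, "t")
  expect_equal(attr(ss2, "rejected")$reason, "non-SNV allele")
  # p inconsistent with beta/se warns but keeps the row
  df3 <- make_ss_df(2)
  df3$pval[1] <- 0.9
  df3$beta[1] <- 0.5; df3$se[1] <- 0.01
  expect_warning(ss3 <- summary_stats(df3, "t"), "inconsistent")
  expect_equal(nrow(ss3), 2L)
})

test_that("read_summary_stats maps dialect columns and enforces presence", {
  df <- make_ss_df(5)
  names(df) <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE", "P", "N")
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dialect <- c(variant_id = "SNP", chrom = "CHR", pos = "BP",
               effect_allele = "A1", other_allele = "A2", eaf = "FRQ",
               beta = "BETA", se = "SE", pval = "P", n = "N")
  ss <- read_summary_stats(path, "t", dialect = dialect)
  expect_equal(nrow(ss), 5L)
  expect_error(read_summary_stats(path, "t"), "missing mandatory column")
})

test_that("dosage panels read from text, impute missing calls by the mean", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rs1\trs2", "0\t2", "1\t2", "2\tNA"), path)
  panel <- read_genotype_panel(path)
  expect_equal(dim(panel), c(3L, 2L))
  expect_equal(panel[, "rs1"], c(0, 1, 2), ignore_attr = TRUE)
  expect_equal(unname(panel[3, "rs2"]), 2)  # mean of the observed 2, 2
  expect_equal(attr(panel, "n_imputed"), 1L)
  writeLines(c("rs1\trs2", "0\tNA", "1\tNA"), path)
  expect_error(read_genotype_panel(path), "rs2")
  writeLines(c("rs1", "3"), path)
  expect_error(read_genotype_panel(path), "outside")
})

test_that("VCF genotypes convert to ALT-dosages", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t./."), path)
  panel <- read_genotype_panel(path)
  expect_equal(panel[, "rs1"], c(S1 = 0, S2 = 1, S3 = 2))
  expect_equal(unname(panel[1:2, "rs2"]), c(1, 2))
  expect_equal(unname(panel[3, "rs2"]), 1.5)  # imputed to the variant mean
})

test_that("LD matrix matches brute-force pairwise correlation", {
  set.seed(11)
  panel <- matrix(sample(0:2, 50 * 10, replace = TRUE), 50, 10)
  colnames(panel) <- sprintf("v%02d", 1:10)
  ld <- compute_ld_matrix(panel)
  expect_equal(unclass(ld), oracle_cor_matrix(panel), tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated and reflected columns
  p2 <- cbind(a = panel[, 1], b = panel[, 1], c = 2 - panel[, 1])
  ld2 <- compute_ld_matrix(p2)
  expect_equal(ld2["a", "b"], 1)
  expect_equal(ld2["a", "c"], -1)
  # zero-variance and missing variants are errors that name the culprit
  p3 <- cbind(panel, zz = rep(1, 50))
  expect_error(compute_ld_matrix(p3), "zz")
  expect_error(compute_ld_matrix(panel, c("v01", "nope")), "nope")
})

test_that("cis windows are 1-based inclusive and clipped at 1", {
  g <- list(gene_id = "G", chrom = 1, start = 1e6, end = 1.01e6)
  w <- cis_window(g, 500)
  expect_equal(w$start, 5e5)
  expect_equal(w$end, 1.51e6)
  w0 <- cis_window(g, 0)
  expect_equal(c(w0$start, w0$end), c(1e6, 1.01e6))
  wc <- cis_window(list(gene_id = "G", chrom = 2, start = 1e5, end = 2e5), 500)
  expect_equal(wc$start, 1)
})

test_that("harmonisation flips swapped alleles and resolves palindromes by eaf", {
  base <- make_ss_df(4)
  base$effect_allele <- c("A", "A", "A", "A")
  base$other_allele <- c("G", "T", "G", "G")
  base$eaf <- c(0.3, 0.49, 0.3, 0.3)
  base$beta <- c(0.3, 0.2, 0.1, 0.15)
  base$pval <- 2 * pnorm(-abs(base$beta / base$se))
  exp_ss <- summary_stats(base, "exp")

  out <- base
  out$effect_allele <- c("G", "A", "A", "C")  # swapped / palindrome / same / mismatch
  out$other_allele <- c("A", "T", "G", "A")
  out$eaf <- c(0.7, 0.51, 0.3, 0.3)
  out$beta <- c(-0.2, 0.2, 0.2, 0.2)
  out$pval <- 2 * pnorm(-abs(out$beta / out$se))
  out_ss <- summary_stats(out, "out")

  hs <- harmonise(exp_ss, out_ss, palindrome_eaf_window = 0.08)
  expect_equal(hs$variant_id, c("rs0001", "rs0003"))
  expect_equal(hs$beta_out, c(0.2, 0.2))     # swap negates the raw -0.2
  expect_equal(hs$eaf_out, c(0.3, 0.3))
  expect_equal(hs$flipped, c(TRUE, FALSE))
  dropped <- attr(hs, "dropped")
  expect_setequal(dropped$reason, c("ambiguous palindrome", "allele mismatch"))
})

test_that("harmonisation handles strand-complement reports", {
  e <- make_ss_df(2)
  e$effect_allele <- c("A", "A"); e$other_allele <- c("G", "G")
  o <- e
  o$effect_allele <- c("T", "C"); o$other_allele <- c("C", "T")
  o$beta <- c(0.25, 0.25)
  o$pval <- 2 * pnorm(-abs(o$beta / o$se))
  hs <- harmonise(summary_stats(e, "e"), summary_stats(o, "o"))
  expect_equal(hs$flipped, c(FALSE, TRUE))   # complement-same vs complement-swapped
  expect_equal(hs$beta_out, c(0.25, -0.25))
})

test_that("harmonisation is idempotent on an aligned pair", {
  e <- make_ss(10, seed = 5)
  o <- make_ss(10, seed = 6, trait = "out")
  hs1 <- harmonise(e, o)
  expect_false(any(hs1$flipped))
  # feed the harmonised outcome back through: nothing changes
  o2 <- summary_stats(data.frame(
    variant_id = hs1$variant_id, chrom = hs1$chrom, pos = hs1$pos,
    effect_allele = hs1$effect_allele, other_allele = hs1$other_allele,
    eaf = hs1$eaf_out, beta = hs1$beta_out, se = hs1$se_out,
    pval = hs1$p_out, n = hs1$n_out), "out")
  hs2 <- harmonise(e, o2)
  expect_equal(hs2$beta_out, hs1$beta_out)
  expect_false(any(hs2$flipped))
})

test_that("allele-mismatch drops do not depend on within-record allele order", {
  e <- make_ss_df(1); e$effect_allele <- "A"; e$other_allele <- "G"
  o1 <- e; o1$effect_allele <- "A"; o1$other_allele <- "C"
  o2 <- e; o2$effect_allele <- "C"; o2$other_allele <- "A"
  for (o in list(o1, o2)) {
    hs <- harmonise(summary_stats(e, "e"), summary_stats(o, "o"))
    expect_equal(nrow(hs), 0L)
    expect_equal(attr(hs, "dropped")$reason, "allele mismatch")
  }
})
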