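test_that("read_sumstats converts each dialect to the standardized scale", {
  f <- write_ss_file(data.frame(SNP = c("rs1", "rs2"), CHR = 1, POS = c(100, 200),
                                A1 = "A", A2 = "G",
                                BETA = c(0, 0.2), SE = c(1, 0.1)))
  ss <- read_sumstats(f, n_gwas = 400)
  expect_equal(ss$beta_hat, c(0, (0.2 / 0.1) / sqrt(400)))
  expect_equal(ss$beta_hat[2], 0.1)

  fz <- write_ss_file(data.frame(SNP = "rs1", A1 = "A", A2 = "G", Z = 3))
  expect_equal(read_sumstats(fz, 900, "z")$beta_hat, 0.1)

  fp <- write_ss_file(data.frame(SNP = "rs1", A1 = "A", A2 = "G",
                                 P = 0.05, BETA = -1))
  expect_equal(read_sumstats(fp, 10000, "pval_sign")$beta_hat,
               -abs(qnorm(0.025)) / 100, tolerance = 1e-6)
  expect_equal(read_sumstats(fp, 10000, "pval_sign")$beta_hat,
               -0.01959964, tolerance = 1e-6)
})

test_that("read_sumstats validates inputs and cleans rows", {
  f <- write_ss_file(data.frame(SNP = "rs1", A1 = "A", A2 = "G", BETA = 0.1))
  expect_error(read_sumstats(f, 100), "SE")
  expect_error(read_sumstats(write_ss_file(data.frame(A1 = "A", A2 = "G",
                                                      BETA = 1, SE = 1)), 100),
               "SNP/ID")
  f2 <- write_ss_file(data.frame(SNP = "rs1", A1 = "A", A2 = "G",
                                 BETA = 0.1, SE = 0.05))
  expect_error(read_sumstats(f2, 0), "n_gwas")

  # non-finite effects dropped, duplicates keep first
  f3 <- write_ss_file(data.frame(SNP = c("rs1", "rs2", "rs1"), A1 = "A",
                                 A2 = "G", BETA = c(0.1, 0.2, 9),
                                 SE = c(0.05, 0, 1)))
  expect_message(expect_message(ss <- read_sumstats(f3, 100), "non-finite"),
                 "duplicate")
  expect_equal(ss$variant_id, "rs1")
  expect_equal(ss$beta_hat, 0.2)

  # OR column is log-transformed
  f4 <- write_ss_file(data.frame(SNP = "rs1", A1 = "A", A2 = "G",
                                 OR = exp(0.3), SE = 0.1))
  expect_equal(read_sumstats(f4, 100, "beta_se")$beta_hat, 3 / 10)
})

test_that("match_alleles keeps, flips and drops correctly in panel order", {
  panel <- toy_panel(matrix(rbinom(40, 2, 0.4), 10, 4),
                     a1 = c("A", "A", "A", "C"), a2 = c("G", "G", "T", "T"))
  ss <- toy_sumstats(c(0.1, 0.1, 0.1, 0.1),
                     a1 = c("A", "G", "A", "C"), a2 = c("G", "A", "T", "T"),
                     ids = c("rs1", "rs2", "rs3", "rs4"))
  out <- match_alleles(ss, panel)
  # rs3 is A/T strand-ambiguous -> dropped; rs2 swapped -> sign flip
  expect_equal(out$variant_id, c("rs1", "rs2", "rs4"))
  expect_equal(out$beta_hat, c(0.1, -0.1, 0.1))
  expect_equal(attr(out, "n_flipped"), 1L)

  # shuffled input comes back in panel order
  out2 <- match_alleles(ss[c(4, 2, 1, 3), ], panel)
  expect_equal(out2$variant_id, c("rs1", "rs2", "rs4"))

  expect_error(match_alleles(toy_sumstats(0.1, ids = "nope"), panel),
               "genome build")
})

test_that("allele matching is involutive on a panel's own variants", {
  set.seed(1)
  panel <- toy_panel(matrix(rbinom(200, 2, 0.3), 20, 10),
                     a1 = rep(c("A", "C"), 5), a2 = rep(c("G", "T"), 5))
  ss <- toy_sumstats(rnorm(10), a1 = panel$variants$a1, a2 = panel$variants$a2)
  out <- match_alleles(ss, panel)
  expect_equal(out$variant_id, ss$variant_id)
  expect_equal(out$beta_hat, ss$beta_hat)
})

test_that("posterior weight files round-trip and conserve rows", {
  eff <- data.frame(variant_id = c("rs1", "rs2", "rs3"), a1 = "A",
                    effect = c(0.123456789, 0, -2.5e-7))
  f <- tempfile()
  write_posterior(eff, f)
  back <- read_posterior(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$effect[2], 0)
  expect_lt(max(abs(back$effect - eff$effect)), 1e-6)
  expect_error(write_posterior(data.frame(variant_id = "a", a1 = "A",
                                          effect = NaN), f), "finite")
})

test_that("sumstats read -> write -> read is a fixed point", {
  f <- write_ss_file(data.frame(SNP = paste0("rs", 1:5), CHR = 1, POS = 1:5,
                                A1 = "A", A2 = "G",
                                BETA = c(-0.2, 0, 0.1, 0.4, 0.02),
                                SE = c(0.1, 0.2, 0.1, 0.25, 0.01)))
  ss1 <- read_sumstats(f, 2500)
  f2 <- tempfile()
  write_sumstats(ss1, f2)
  ss2 <- read_sumstats(f2, 2500, dialect = "z")
  expect_equal(ss2$beta_hat, ss1$beta_hat, tolerance = 1e-9)
  expect_equal(ss2$variant_id, ss1$variant_id)
})

test_that("panel standardization centres, scales and imputes", {
  X <- matrix(c(0, 1, 2, 2, NA, 1, 0, 1, 1, 2, 0, 2), 4, 3)
  p <- standardize_panel(toy_panel(X))
  expect_true(p$standardized)
  expect_lt(max(abs(colMeans(p$X))), 1e-8)
  # population variance exactly 1
  expect_lt(max(abs(colMeans(p$X^2) - 1)), 1e-6)
  expect_false(anyNA(p$X))

  mono <- toy_panel(matrix(c(1, 1, 1, 0, 1, 2), 3, 2))
  expect_error(standardize_panel(mono), "monomorphic")
})

test_that("plain-text panels and PLINK filesets read back identically", {
  set.seed(2)
  X <- matrix(rbinom(60, 2, 0.4), 10, 6)
  panel <- toy_panel(X)
  pre <- tempfile()
  write_panel(panel, pre)
  back <- read_panel(pre)
  expect_equal(back$X, panel$X, ignore_attr = TRUE)
  expect_equal(back$variants$variant_id, panel$variants$variant_id)

  # write a tiny SNP-major .bed by hand: codes 00=hom A1, 10=het, 11=hom A2
  pre2 <- tempfile()
  bim <- data.frame(chrom = 1, id = c("v1", "v2"), cm = 0, pos = c(10, 20),
                    a1 = "A", a2 = "G")
  write.table(bim, paste0(pre2, ".bim"), col.names = FALSE, row.names = FALSE,
              quote = FALSE, sep = "\t")
  fam <- data.frame(fid = 1:3, iid = paste0("i", 1:3), pa = 0, ma = 0,
                    sex = 0, phe = -9)
  write.table(fam, paste0(pre2, ".fam"), col.names = FALSE, row.names = FALSE,
              quote = FALSE, sep = "\t")
  con <- file(paste0(pre2, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  # variant 1: samples (2, 1, 0) -> codes 00, 10, 11 -> bits 00 01 11 00 (LSB first)
  writeBin(as.raw(c(bitwOr(bitwOr(0L, bitwShiftL(2L, 2)), bitwShiftL(3L, 4)),
                    bitwOr(bitwOr(3L, bitwShiftL(2L, 2)), bitwShiftL(1L, 4)))),
           con)
  close(con)
  bp <- read_plink(pre2)
  expect_equal(as.numeric(bp$X[, 1]), c(2, 1, 0))
  # variant 2: codes 11, 10, 01 -> dosages 0, 1, NA
  expect_equal(as.numeric(bp$X[, 2]), c(0, 1, NA))
})
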