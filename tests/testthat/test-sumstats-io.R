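test_that("readSumStats parses well-formed tables and counts bad rows", {
  path <- write_fixture_tsv(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t100\tA\tG\t0.2\t0.10\t0.02\t5e-7\t10000",
    "rs2\t1\t200\tC\tT\t0.5\t-0.05\t0.01\t1e-6\t10000",
    "rs3\t1\t300\tG\tA\t0.8\t0.01\t0.02\t0.6\t10000"))
  x <- readSumStats(path, traitId = "toy")
  expect_s4_class(x, "SumStats")
  expect_equal(nVariants(x), 3L)
  expect_equal(attr(x, "diagnostics")$unparseable, 0L)
  expect_equal(records(x)$snp, c("rs1", "rs2", "rs3"))
  expect_equal(records(x)$beta, c(0.10, -0.05, 0.01))

  ## comma-delimited variant of the same table
  csv <- write_fixture_tsv(c("SNP,CHR,POS,EA,OA,BETA,SE",
                             "rs1,1,100,A,G,0.1,0.02"))
  expect_equal(nVariants(readSumStats(csv)), 1L)
})

test_that("readSumStats drops unparseable rows and reports them", {
  path <- write_fixture_tsv(c(
    "SNP\tCHR\tPOS\tEA\tOA\tBETA\tSE",
    "rs1\t1\t100\tA\tG\t0.1\t0.02",
    "rs2\t1\t200\tA\tG\tNA\t0.02",
    "rs3\t1\t300\tA\tG\t0.2\t0.02",
    "rs4\t1\t400\tA\tG\t0.3\t0.02",
    "rs5\t1\t500\tA\tG\t0.4\t0.02"))
  x <- readSumStats(path)
  expect_equal(nVariants(x), 4L)
  expect_equal(attr(x, "diagnostics")$unparseable, 1L)
  expect_equal(records(x)$snp, c("rs1", "rs3", "rs4", "rs5"))
})

test_that("readSumStats errors name the missing column and reject empty files", {
  path <- write_fixture_tsv(c("SNP\tCHR\tPOS\tEA\tOA\tBETA",
                              "rs1\t1\t100\tA\tG\t0.1"))
  expect_error(readSumStats(path), "se")
  empty <- write_fixture_tsv(character(0))
  expect_error(readSumStats(empty), "empty")
  hdr_only <- write_fixture_tsv("SNP\tCHR\tPOS\tEA\tOA\tBETA\tSE")
  expect_error(readSumStats(hdr_only), "no data rows")
})

test_that("schema remapping reads non-canonical headers", {
  path <- write_fixture_tsv(c("rsid\tchromosome\tbp\teffect\tother\tb\tstderr",
                              "rs9\t2\t500\tT\tC\t0.3\t0.05"))
  x <- readSumStats(path, schema = c(snp = "rsid", chrom = "chromosome",
                                     pos = "bp", ea = "effect", oa = "other",
                                     beta = "b", se = "stderr"))
  expect_equal(records(x)$snp, "rs9")
  expect_equal(records(x)$beta, 0.3)
})

test_that("write/read round-trips record-for-record and is byte-deterministic", {
  sim <- simulateTraitSumstats(makeLd(50, "ar1", 0.5),
                               c(rs0025 = 0.1), n = 10000, seed = 11)
  p1 <- tempfile(); p2 <- tempfile()
  writeSumStats(sim, p1)
  back <- readSumStats(p1, traitId = traitId(sim))
  expect_equal(records(back), records(sim), tolerance = 1e-12)

  writeSumStats(sim, p2)
  expect_identical(readLines(p1), readLines(p2))

  ## missing eaf serialized with the NA token
  x <- mk_sumstats("rs1", 0.1, 0.02, eaf = NA)
  p3 <- tempfile()
  writeSumStats(x, p3)
  expect_match(readLines(p3)[2], "\tNA\t")
  expect_true(is.na(records(readSumStats(p3))$eaf))
})

test_that("LD matrix file round-trips", {
  ld <- makeLd(6, "ar1", 0.7)
  p <- tempfile()
  writeLDMatrix(ld, p)
  back <- readLDMatrix(p)
  expect_equal(variantIds(back), variantIds(ld))
  expect_equal(corMatrix(back), corMatrix(ld), tolerance = 1e-12)
})

test_that("harmonize keeps, flips, and drops as specified", {
  exp <- mk_sumstats(c("rs1", "rs2", "rs3", "rs4"),
                     beta = c(0.1, 0.1, 0.2, 0.3), se = 0.02,
                     ea = c("A", "A", "A", "A"), oa = c("G", "G", "T", "G"),
                     eaf = c(0.3, 0.3, 0.2, 0.3))
  out <- mk_sumstats(c("rs1", "rs2", "rs3", "rs4"),
                     beta = c(0.05, 0.05, 0.05, 0.05), se = 0.01,
                     ea = c("A", "G", "A", "A"), oa = c("G", "A", "T", "C"),
                     eaf = c(0.3, 0.3, 0.5, 0.3))
  h <- harmonize(exp, out)
  expect_equal(nrow(h), 4L)  # conservation: one row per shared variant
  expect_equal(h$action,
               c("kept", "flipped", "dropped_palindromic",
                 "dropped_incompatible"))
  ## swapped alleles: beta negated, eaf complemented
  expect_equal(h$beta_out[2], -0.05)
  expect_equal(h$eaf_out[2], 0.7)
  ## kept row untouched
  expect_equal(h$beta_out[1], 0.05)
})

test_that("palindromic variants follow the eaf-window and orientation rules", {
  pal_exp <- mk_sumstats("rs1", 0.1, 0.02, ea = "A", oa = "T", eaf = 0.2)
  ## usable: both eafs clear of 0.5 and on the same side
  pal_out1 <- mk_sumstats("rs1", 0.05, 0.01, ea = "A", oa = "T", eaf = 0.25)
  expect_equal(harmonize(pal_exp, pal_out1)$action, "kept")
  ## inside the default 0.42-0.58 window: ambiguous
  pal_out2 <- mk_sumstats("rs1", 0.05, 0.01, ea = "A", oa = "T", eaf = 0.5)
  expect_equal(harmonize(pal_exp, pal_out2)$action, "dropped_palindromic")
  ## frequencies contradict the nominal alignment
  pal_out3 <- mk_sumstats("rs1", 0.05, 0.01, ea = "A", oa = "T", eaf = 0.8)
  expect_equal(harmonize(pal_exp, pal_out3)$action, "dropped_palindromic")
  ## missing eaf: ambiguous
  pal_out4 <- mk_sumstats("rs1", 0.05, 0.01, ea = "A", oa = "T", eaf = NA)
  expect_equal(harmonize(pal_exp, pal_out4)$action, "dropped_palindromic")
  ## the window is configurable
  expect_equal(harmonize(pal_exp, pal_out2,
                         palindromeEafWindow = 0)$action[1],
               "dropped_palindromic")  # 0.5 is never usable
})

test_that("strand flips are inferred before declaring incompatibility", {
  exp <- mk_sumstats("rs1", 0.1, 0.02, ea = "A", oa = "G")
  ## T/C is A/G on the other strand
  out_same <- mk_sumstats("rs1", 0.05, 0.01, ea = "T", oa = "C")
  expect_equal(harmonize(exp, out_same)$action, "kept")
  out_swap <- mk_sumstats("rs1", 0.05, 0.01, ea = "C", oa = "T", eaf = 0.3)
  h <- harmonize(exp, out_swap)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.05)
  ## indels match directly or swapped but never via strand logic
  iexp <- mk_sumstats("rs2", 0.1, 0.02, ea = "AT", oa = "A")
  iout <- mk_sumstats("rs2", 0.07, 0.01, ea = "A", oa = "AT")
  expect_equal(harmonize(iexp, iout)$action, "flipped")
})

test_that("harmonization is idempotent and flipping is an involution", {
  exp <- mk_sumstats(c("rs1", "rs2"), c(0.1, -0.2), 0.02, eaf = c(0.3, 0.7))
  out <- mk_sumstats(c("rs1", "rs2"), c(0.05, 0.08), 0.01,
                     ea = c("G", "A"), oa = c("A", "G"), eaf = c(0.6, 0.2))
  h1 <- harmonize(exp, out)
  ## rebuild the outcome from the harmonized values (now on exposure alleles)
  out2 <- mk_sumstats(h1$snp, h1$beta_out, h1$se_out, ea = h1$ea, oa = h1$oa,
                      eaf = h1$eaf_out)
  h2 <- harmonize(exp, out2)
  expect_equal(h2$action, rep("kept", 2))
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)

  ## flipping twice restores the original record
  flip <- function(b, f) list(beta = -b, eaf = 1 - f)
  once <- flip(0.05, 0.6)
  twice <- flip(once$beta, once$eaf)
  expect_equal(twice$beta, 0.05)
  expect_equal(twice$eaf, 0.6)
})

test_that("harmonize requires a non-empty intersection", {
  a <- mk_sumstats("rs1", 0.1, 0.02)
  b <- mk_sumstats("rs2", 0.1, 0.02)
  expect_error(harmonize(a, b), "no shared variants")
})

test_that("SumStats validity enforces the record invariants", {
  expect_error(mk_sumstats(c("rs1", "rs1"), c(0.1, 0.2), 0.02), "unique")
  expect_error(mk_sumstats("rs1", 0.1, -0.02), "se")
  expect_error(mk_sumstats("rs1", 0.1, 0.02, eaf = 1.2), "eaf")
  bad_n <- data.frame(snp = "rs1", chrom = "1", pos = 1, ea = "A", oa = "G",
                      beta = 0.1, se = 0.02, n = 100, ncase = 10,
                      ncontrol = 20)
  expect_error(SumStats(bad_n, "x", "case_control"), "ncase")
})
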