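test_that("scoring files parse, reject malformed rows, and round-trip", {
  f <- write_scoring_fixture(c(
    "rs1\t1\t1000\tA\tG\t0.12",
    "rs2\t2\t2000\tC\tT\t-0.30",
    "rs3\t3\t3000\tG\tA\t0.0"))
  sc <- read_scoring_file(f)
  expect_s3_class(sc, "prs_scoring")
  expect_equal(nrow(sc), 3)
  expect_equal(sc$beta[3], 0)          # zero beta parses; filtering is downstream
  expect_equal(attr(sc, "n_rejected"), 0L)

  f2 <- write_scoring_fixture(c(
    "rs1\t1\t1000\tA\tG\t0.12",
    "rs2\t2\t2000\tN\tT\t0.3"))
  expect_warning(sc2 <- read_scoring_file(f2), "rejected 1")
  expect_equal(nrow(sc2), 1)
  expect_equal(attr(sc2, "n_rejected"), 1L)

  # missing required column
  bad <- write_tsv_fixture(c("rsID\tchr_name\teffect_allele\tother_allele\teffect_weight",
                             "rs1\t1\tA\tG\t0.1"))
  expect_error(read_scoring_file(bad), "chr_position")

  # write/read round trip is field-identical
  out <- tempfile(fileext = ".tsv")
  write_scoring_file(sc, out)
  back <- read_scoring_file(out)
  expect_equal(as.data.frame(back), as.data.frame(sc), ignore_attr = TRUE)
})

test_that("custom dialects map arbitrary headers", {
  f <- write_tsv_fixture(c("id\tchr\tbp\tea\toa\tw", "rs9\t5\t500\tT\tC\t0.4"))
  sc <- read_scoring_file(f, dialect = c(variant_id = "id", chrom = "chr",
                                         pos = "bp", effect_allele = "ea",
                                         other_allele = "oa", beta = "w"))
  expect_equal(sc$pos, 500L)
  expect_equal(sc$beta, 0.4)
  expect_error(read_scoring_file(f, dialect = "nope"), "unknown scoring dialect")
})

test_that("VCF genotypes load via GT and DS with not-found bookkeeping", {
  sc <- admixprs:::new_prs_scoring(tibble::tibble(
    variant_id = c("v1", "v2", "v3"), chrom = c("1", "1", "2"),
    pos = c(100L, 200L, 300L), effect_allele = c("G", "C", "G"),
    other_allele = c("A", "T", "A"), beta = c(0.1, 0.2, 0.3)))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=DS,Number=A,Type=Float,Description="DS">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT:DS\t0/1:1.37\t1/1:2.0",
    "1\t200\tv2\tT\tC\t.\tPASS\t.\tGT:DS\t0/0:0.02\t./.:."), vcf)
  # DS preferred
  gm <- read_genotypes(vcf, sc, prefer_dosage = TRUE)
  expect_equal(unname(gm$dosages["S1", "v1"]), 1.37)
  expect_equal(nrow(attr(gm, "not_found")), 1)
  expect_equal(attr(gm, "not_found")$variant_id, "v3")
  # GT path: het -> 1, missing -> NA
  gm2 <- read_genotypes(vcf, sc, prefer_dosage = FALSE)
  expect_equal(unname(gm2$dosages["S1", "v1"]), 1)
  expect_equal(unname(gm2$dosages["S2", "v1"]), 2)
  expect_true(is.na(gm2$dosages["S2", "v2"]))
})

test_that("multi-allelic records split and match the right alternate", {
  sc <- admixprs:::new_prs_scoring(tibble::tibble(
    variant_id = "v1", chrom = "1", pos = 100L,
    effect_allele = "T", other_allele = "A", beta = 0.1))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\tm1\tA\tG,T\t.\tPASS\t.\tGT\t1/2"), vcf)
  gm <- read_genotypes(vcf, sc, prefer_dosage = FALSE)
  expect_equal(gm$variants$alt, "T")             # second alternate chosen
  expect_equal(unname(gm$dosages["S1", "v1"]), 1) # one copy of allele 2
})

test_that("VCF written by the simulator round-trips through read_genotypes", {
  co <- simulate_cohort(sim_config(n_cases = 20, n_controls = 30,
                                   n_variants = 40, seed = 11))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(co$genotypes, vcf)
  gm_gt <- read_genotypes(vcf, co$scoring, prefer_dosage = FALSE)
  expect_equal(unname(gm_gt$dosages), unname(co$genotypes$dosages))
  gm_ds <- read_genotypes(vcf, co$scoring, prefer_dosage = TRUE)
  expect_lt(max(abs(gm_ds$dosages - co$genotypes$dosages)), 1e-6)
  expect_error(read_genotypes(tempfile(), co$scoring), "not found")
})

test_that("cohort side tables join, renormalize and reject as documented", {
  meta <- write_tsv_fixture(c(
    "sample_id\tstatus\tsex\tBRCA1\tATM",
    paste0("S", 1:5, "\t", c("case", "case", "control", "control", "control"),
           "\tF\tFALSE\tFALSE")))
  kin <- write_tsv_fixture(c("sample_a\tsample_b\tdegree",
                             "S1\tS2\t1", "S3\tS3\t1", "S4\tSX\t1"))
  anc <- write_tsv_fixture(c(
    "sample_id\tEUR\tAFR\tEAS\tAMR",
    "S1\t0.80\t0.10\t0.04\t0.04",    # sums to 0.98 -> renormalized
    "S2\t0.70\t0.10\t0.10\t0.10",
    "S3\t0.50\t0.20\t0.10\t0.10"))   # sums to 0.90 -> rejected
  w <- testthat::capture_warnings(
    tabs <- read_cohort_tables(meta, kin, anc))
  expect_length(w, 3)   # self-pair, unknown-sample pair, bad ancestry row
  expect_equal(nrow(tabs$samples), 5)
  expect_equal(nrow(tabs$kinship), 1)          # self-pair + unknown dropped
  s1 <- tabs$samples[tabs$samples$sample_id == "S1", ]
  expect_equal(s1$EUR + s1$AFR + s1$EAS + s1$AMR, 1, tolerance = 1e-9)
  expect_true(is.na(tabs$samples$EUR[tabs$samples$sample_id == "S3"]))

  dup <- write_tsv_fixture(c("sample_id\tstatus", "S1\tcase", "S1\tcontrol"))
  expect_error(read_sample_metadata(dup), "duplicate")
})

test_that("BED intervals convert from 0-based half-open", {
  bed <- write_tsv_fixture(c("chr1\t99\t200", "2\t0\t50"),
                           tempfile(fileext = ".bed"))
  b <- read_bed(bed)
  expect_equal(b$start, c(100L, 1L))
  expect_equal(b$end, c(200L, 50L))
  expect_equal(b$chrom, c("1", "2"))
})
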