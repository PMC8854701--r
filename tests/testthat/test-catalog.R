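test_that("MAF classification matches the trimodal thresholds and partitions [0,1]", {
  expect_equal(as.character(classify_maf(0.10)), "subclonal")
  expect_equal(as.character(classify_maf(0.25)), "clonal")
  expect_equal(as.character(classify_maf(0.80)), "clonal_imbalanced")
  expect_equal(as.character(classify_maf(0.75)), "clonal_imbalanced")
  expect_error(classify_maf(-0.1), "0, 1")
  expect_error(classify_maf(1.2), "0, 1")
  # partition property: every value maps to exactly one category
  grid <- seq(0, 1, by = 0.001)
  cls <- classify_maf(grid)
  expect_false(any(is.na(cls)))
  expect_equal(sum(cls == "subclonal") + sum(cls == "clonal") +
                 sum(cls == "clonal_imbalanced"), length(grid))
})

test_that("somatic filter applies criteria with fixed-order rejection attribution", {
  recs <- dplyr::bind_rows(
    make_records(depth = 19L, alt_reads = 10L),                      # depth
    make_records(depth = 32L, alt_reads = 8L),                       # kept: all boundaries inclusive
    make_records(depth = 40L, alt_reads = 20L, blood_depth = 50L,
                 blood_alt_reads = 3L),                              # blood 0.06
    make_records(depth = 40L, alt_reads = 5L),                       # alt_reads
    make_records(depth = 40L, alt_reads = 20L, pop_freq = 0.001),    # pop_freq
    make_records(depth = 0L, alt_reads = 0L),                        # no coverage
    make_records(depth = 40L, alt_reads = 9L)                        # maf 0.225
  )
  flt <- filter_somatic_calls(recs, mode = "wgs")
  expect_equal(nrow(flt$kept), 1)
  expect_equal(flt$kept$alt_reads, 8L)  # 8 reads at MAF exactly 0.25
  got <- setNames(flt$tally$n_rejected, flt$tally$criterion)
  expect_equal(got[["depth"]], 1L)
  expect_equal(got[["blood_maf"]], 1L)
  expect_equal(got[["alt_reads"]], 1L)
  expect_equal(got[["pop_freq"]], 1L)
  expect_equal(got[["no_coverage"]], 1L)
  expect_equal(got[["maf"]], 1L)
  # counting identity: kept + tallies = input
  expect_equal(nrow(flt$kept) + sum(flt$tally$n_rejected), nrow(recs))
  # first-failing-criterion attribution: quality outranks depth
  both <- make_records(depth = 10L, alt_reads = 2L, quality_pass = FALSE)
  expect_equal(filter_somatic_calls(both, "wgs")$rejected$reject_reason, "quality")
})

test_that("filtering is idempotent and target mode skips read-level criteria", {
  set.seed(42)
  recs <- make_records(50, depth = sample(10:60, 50, replace = TRUE),
                       alt_reads = sample(0:30, 50, replace = TRUE))
  recs$alt_reads <- pmin(recs$alt_reads, recs$depth)
  flt <- filter_somatic_calls(recs, "wgs")
  again <- filter_somatic_calls(flt$kept, "wgs")
  expect_equal(nrow(again$rejected), 0)
  expect_equal(again$kept, flt$kept)
  # target mode keeps low-depth records as long as quality/popfreq pass
  tgt <- filter_somatic_calls(make_records(depth = 12L, alt_reads = 3L), "target")
  expect_equal(nrow(tgt$kept), 1)
  expect_s3_class(tidy(flt), "tbl_df")
  expect_equal(glance(flt)$n_input, 50)
})

test_that("gland QC passes strictly above 70% coverage at 20 reads", {
  g <- make_glands(c("a", "b", "c"))
  g$coverage20_fraction <- c(0.935, 0.70, 0.71)
  expect_equal(gland_qc(g)$qc_pass, c(TRUE, FALSE, TRUE))
  g$coverage20_fraction[1] <- NA
  expect_error(gland_qc(g), "coverage20_fraction")
})

test_that("binomial imbalance test equals exact tail enumeration", {
  expect_equal(binomial_imbalance_test(10, 20), 1.0)
  expect_equal(binomial_imbalance_test(20, 20), 2 * 0.5^20, tolerance = 1e-12)
  expect_lt(binomial_imbalance_test(90, 100), 1e-5)
  # oracle comparison across a grid of cases
  for (case in list(c(15, 20), c(3, 30), c(55, 80), c(40, 40), c(0, 25))) {
    expect_equal(binomial_imbalance_test(case[1], case[2]),
                 binom_twosided_oracle(case[1], case[2]),
                 tolerance = 1e-9,
                 info = paste(case, collapse = "/"))
  }
  expect_error(binomial_imbalance_test(5, 10, p0 = 1), "p0")
})

test_that("CNMC follows the configurable cycle-accrual formula", {
  clin <- tibble::tibble(subject_id = c("a", "b", "c"),
                         age = c(21, 31, 31),
                         menarche_age = c(21, 11, 11),
                         parity = c(0, 0, 2))
  out <- compute_cnmc(clin)
  expect_equal(out$cnmc, c(0, 260, 230))
  # parameters are configurable and the floor at zero holds
  out2 <- compute_cnmc(clin, cycles_per_year = 12, cycles_lost_per_parity = 200)
  expect_equal(out2$cnmc, c(0, 240, 0))
  clin$menarche_age[1] <- 25
  expect_error(compute_cnmc(clin), "menarche")
})

test_that("mutation TSV and VCF readers emit the same record shape", {
  recs <- make_records(5, gland_id = "gA", alt_reads = c(8L, 10L, 12L, 14L, 16L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_tsv(recs, path)
  back <- read_mutation_tsv(path)
  expect_equal(back$alt_reads, recs$alt_reads)
  expect_equal(back$context, recs$context)

  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"context\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tglandA\tblood",
    "chr1\t100\t.\tC\tT\t.\tPASS\tCTX=ACA\tAD:DP\t20,20:40\t40,0:40",
    "chr2\t200\t.\tG\tA\t.\tPASS\tCTX=TGT\tAD:DP\t30,10:40\t40,0:40"
  ), vcf)
  v <- read_mutation_vcf(vcf, "glandA", "blood")
  expect_equal(nrow(v), 2)
  expect_equal(v$alt_reads, c(20L, 10L))
  expect_equal(v$depth, c(40L, 40L))
  expect_equal(v$blood_alt_reads, c(0L, 0L))
  expect_equal(v$context, c("ACA", "TGT"))
})
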