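test_that("burden pools counts over glands exactly as the per-Mbp formula", {
  glands <- make_glands(c("g1", "g2"), callable_bases = 1e6)
  recs <- dplyr::bind_rows(
    make_records(2, gland_id = "g1"),
    make_records(3, gland_id = "g2", pos = c(900L, 901L, 902L))
  )
  b <- mutation_burden(recs, glands)
  expect_equal(b$burden, 2.5)
  one <- mutation_burden(make_records(5, pos = 1:5 * 10L), make_glands("g1"))
  expect_equal(one$burden, 5.0)
  # invariance to the partition of mutations among glands
  recs2 <- recs
  recs2$gland_id <- "g1"
  expect_equal(mutation_burden(recs2, glands)$burden, 2.5)
  # burden equals the sum over the six substitution burdens
  expect_equal(b$burden,
               sum(unlist(b[paste0("burden_", c("CA", "CG", "CT",
                                               "TA", "TC", "TG"))])))
  expect_error(mutation_burden(recs, make_glands("g1", callable_bases = 0)),
               "callable_bases")
})

test_that("low-MAF SNVs and indels are excluded from the burden numerator", {
  glands <- make_glands("g1")
  recs <- dplyr::bind_rows(
    make_records(alt_reads = 20L),               # MAF 0.5, counted
    make_records(alt_reads = 5L, pos = 7L),      # MAF 0.125, excluded
    make_records(ref = "CTT", alt = "C", pos = 9L)  # indel, excluded
  )
  expect_equal(mutation_burden(recs, glands)$n_snvs, 1L)
})

test_that("96-class spectrum collapses purine-reference SNVs to the pyrimidine strand", {
  # G>A in AGA is T[C>T]T after reverse complement; C>T in ACG stays A[C>T]G
  recs <- dplyr::bind_rows(
    make_records(ref = "G", alt = "A", context = "AGA"),
    make_records(ref = "C", alt = "T", context = "ACG", pos = 2L)
  )
  sp <- spectrum_96(recs)
  expect_equal(sp$count[sp$class == "T[C>T]T"], 1L)
  expect_equal(sp$count[sp$class == "A[C>T]G"], 1L)
  expect_equal(sum(sp$count), 2L)

  # one SNV per class covers the full vector with ones
  cls <- sbs96_classes()
  p <- endoclone:::parse_sbs96(cls)
  all96 <- make_records(96, ref = p$ref, alt = p$alt,
                        context = paste0(p$f5, p$ref, p$f3), pos = 1:96)
  expect_equal(spectrum_96(all96)$count, rep(1L, 96))

  # invalid contexts are skipped with a warning and tracked
  bad <- make_records(context = "NNN")
  expect_warning(spb <- spectrum_96(bad), "skipped")
  expect_equal(sum(spb$count), 0L)
  expect_equal(attr(spb, "n_skipped"), 1L)
})

test_that("covariate association returns Pearson r, slope CI and partial correlation", {
  d <- tibble::tibble(subject_id = letters[1:6],
                      age = c(25, 30, 35, 40, 45, 50),
                      burden = c(1.0, 1.4, 1.7, 2.2, 2.4, 2.9))
  # a self-correlated covariate is a degenerate regression; the lm warning
  # about a perfect fit is expected
  self <- suppressWarnings(
    covariate_association(dplyr::mutate(d, cov = burden), "burden", "cov"))
  expect_equal(self$r, 1)
  expect_lt(self$p_value, 1e-10)

  # orthogonal covariate by construction: centered dot product zero
  d$cov <- c(1, -1, 0, 0, 1, -1)
  d$cov <- d$cov - mean(d$cov)
  resid_b <- d$burden - mean(d$burden)
  d$cov <- d$cov - sum(d$cov * resid_b) / sum(resid_b^2) * resid_b
  orth <- covariate_association(d, "burden", "cov")
  expect_equal(orth$r, 0, tolerance = 1e-10)

  unadj <- covariate_association(d, "burden", "age")
  expect_gt(unadj$r, 0.99)
  expect_true(unadj$slope_low < unadj$slope & unadj$slope < unadj$slope_high)

  # age adjustment: residual-residual correlation of a pure age surrogate is ~0
  d$cnmc <- 13 * (d$age - 12)
  expect_error(covariate_association(d, "burden", "cnmc", adjust_age = TRUE),
               "collinear")
  expect_error(covariate_association(dplyr::mutate(d, flat = 1),
                                     "burden", "flat"), "variance")
})

test_that("planted linear burden-age slope is recovered within the 95% CI", {
  set.seed(11)
  covered <- 0
  n_rep <- 150
  for (i in seq_len(n_rep)) {
    age <- runif(20, 20, 55)
    burden <- 0.05 * age + rnorm(20, 0, 0.15)
    a <- covariate_association(tibble::tibble(age = age, burden = burden),
                               "burden", "age")
    covered <- covered + (a$slope_low <= 0.05 && 0.05 <= a$slope_high)
  }
  expect_gte(covered / n_rep, 0.90)
})

test_that("driver burden counts nonsilent high-MAF mutations per gland", {
  glands <- make_glands(c("g1", "g2"))
  recs <- dplyr::bind_rows(
    make_records(gene = "KRAS", consequence = "missense", gland_id = "g1"),
    make_records(3, gene = "PTEN", consequence = "frameshift", gland_id = "g2",
                 ref = "CA", alt = "C", pos = 11:13 * 5L)
  )
  db <- driver_burden(recs, glands)
  expect_equal(db$driver_burden, 2.0)
  syn <- make_records(gene = "KRAS", consequence = "synonymous")
  expect_equal(driver_burden(syn, glands)$driver_burden, 0)
  # non-panel genes and subclonal hits do not count
  other <- dplyr::bind_rows(
    make_records(gene = "GAPDH", consequence = "missense"),
    make_records(gene = "TP53", consequence = "missense", alt_reads = 4L)
  )
  expect_equal(driver_burden(other, glands)$driver_burden, 0)
  expect_error(driver_burden(recs, glands[0, ]), "empty")
})

test_that("rank-sum comparison is exact for small groups", {
  expect_equal(group_difference_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(group_difference_test(c(2, 2, 2), c(2, 2)), 1)
  set.seed(3)
  a <- rnorm(40); b <- rnorm(40) + 2
  expect_lt(group_difference_test(a, b), 0.05)
  expect_error(group_difference_test(numeric(0), 1), "nonempty")
})

test_that("driver counts planted by the simulator are recovered exactly", {
  cfg <- simulation_config(n_subjects = 1, ages = 45, drivers_per_gland = 2)
  co <- simulate_cohort(cfg, seed = 21)
  truth_n <- sum(co$truth$mutation_truth$sharing == "driver")
  db <- driver_burden(co$mutations, co$glands)
  expect_equal(db$n_driver, truth_n)
})
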