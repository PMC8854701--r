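test_that("site opportunities match codon-level enumeration", {
  # Met codon: all 9 substitutions are missense
  met <- count_site_opportunities("AATGC", gene = "met")
  expect_equal(unname(colSums(met$L)), c(9, 0, 0))
  # Trp codon: TAG and TGA are nonsense, no synonymous change exists
  trp <- count_site_opportunities("ATGGA", gene = "trp")
  expect_equal(unname(colSums(trp$L)), c(7, 2, 0))
  # Leu codon CTG: CTA/CTC/CTT and TTG all encode Leu -> 4 synonymous paths
  leu <- count_site_opportunities("ACTGA", gene = "leu")
  expect_equal(unname(colSums(leu$L)["s"]), 4)
  expect_error(count_site_opportunities("ATAGA"), "stop codon")
  expect_error(count_site_opportunities("ANTGC"), "ACGT")
  expect_error(count_site_opportunities("AATGCC"), "multiple of 3")
})

test_that("opportunity conservation holds on random gene models", {
  models <- simulate_gene_models(25, cds_length = 300, seed = 7)
  for (m in models) {
    expect_equal(sum(m$L), 3 * m$cds_length)
  }
})

test_that("context rates are opportunity-corrected, mean one, scale invariant", {
  fx <- dnds_fixture()
  uniform <- estimate_context_rates(rep(50, 96), rep(1000, 96),
                                    fx$models, observed_total = 100)
  expect_equal(unname(uniform$r), rep(1, 96))
  # doubling counts leaves relative rates unchanged
  r1 <- estimate_context_rates(fx$catalog, NULL, fx$models, 100)
  r2 <- estimate_context_rates(fx$catalog * 2, NULL, fx$models, 100)
  expect_equal(r1$r, r2$r)
  expect_equal(mean(r1$r), 1)
  # observed_total = 0 gives t = 0
  expect_equal(estimate_context_rates(fx$catalog, NULL, fx$models, 0)$t, 0)
  expect_error(estimate_context_rates(rep(0, 96), NULL, fx$models, 10), "counts")
})

test_that("the calibrated baseline rate makes expected equal observed totals", {
  fx <- dnds_fixture()
  counts <- simulate_selection_catalog(fx$models, rates = fx$rates, seed = 31)
  total <- sum(counts$missense + counts$nonsense + counts$synonymous)
  rates <- estimate_context_rates(fx$catalog, NULL, fx$models, total)
  E <- endoclone:::expected_counts(fx$models, rates)
  expect_equal(sum(E), total, tolerance = 1e-9)
})

test_that("omega estimation matches ratio arithmetic and the brute-force MLE", {
  fit <- estimate_omega(10, 5, 4, 4)
  expect_equal(fit$omega, 2)
  # boundary: equal rates give omega 1 and p 1
  flat <- estimate_omega(6, 3, 8, 4)
  expect_equal(flat$omega, 1)
  expect_equal(flat$p_value, 1)
  # brute-force grid MLE agreement on small instances
  for (case in list(c(7, 3.1, 4, 2.7), c(12, 2.5, 3, 4.1), c(2, 1.2, 6, 2.0))) {
    closed <- estimate_omega(case[1], case[2], case[3], case[4])
    grid <- grid_mle_omega(case[1], case[2], case[3], case[4])
    expect_equal(closed$omega, grid$omega, tolerance = 1e-3,
                 info = paste(case, collapse = "/"))
  }
  # zero synonymous counts: omega undefined, dN and dS still reported
  zs <- estimate_omega(9, 3, 0, 2)
  expect_true(is.na(zs$omega))
  expect_equal(zs$dn, 3)
  expect_equal(zs$ds, 0)
})

test_that("gene-set estimates are consistent and neutral sets sit near one", {
  fx <- dnds_fixture()
  counts <- simulate_selection_catalog(fx$models, rates = fx$rates, seed = 41)
  total <- sum(counts$missense + counts$nonsense + counts$synonymous)
  rates <- estimate_context_rates(fx$catalog, NULL, fx$models, total)
  all_fit <- gene_set_dnds(counts, fx$models, rates, set_name = "all")
  expect_equal(all_fit$omega[all_fit$class == "missense"], 1, tolerance = 0.25)
  # a single-gene set equals the per-gene arithmetic
  g <- names(fx$models)[1]
  one <- gene_set_dnds(counts, fx$models, rates, genes = g, set_name = g)
  E1 <- endoclone:::expected_counts(fx$models[g], rates)
  manual <- estimate_omega(counts$missense[counts$gene == g], E1[["m"]],
                           counts$synonymous[counts$gene == g], E1[["s"]])
  expect_equal(one$omega[one$class == "missense"], manual$omega)
})

test_that("per-gene testing applies the eligibility rules and BH threshold", {
  fx <- dnds_fixture()
  omega_map <- setNames(rep(1, 20), names(fx$models))
  omega_map[c("G001", "G002")] <- 8
  counts <- simulate_selection_catalog(fx$models, omega_map = omega_map,
                                       rates = fx$rates, seed = 55)
  total <- sum(counts$missense + counts$nonsense + counts$synonymous)
  rates <- estimate_context_rates(fx$catalog, NULL, fx$models, total)
  res <- per_gene_selection(counts, fx$models, rates)
  hits <- res$gene[res$class == "missense" & res$significant]
  expect_true(all(c("G001", "G002") %in% hits))
  # genes below the SNV floor are never tested
  few <- counts
  few$missense <- 0L; few$nonsense <- 0L; few$synonymous <- 2L
  expect_equal(nrow(per_gene_selection(few, fx$models, rates)), 0)
  # observed <= expected means the class is not tested
  under <- counts[counts$gene == "G003", ]
  under$missense <- 0L
  res_u <- per_gene_selection(under, fx$models, rates)
  expect_false(any(res_u$gene == "G003" & res_u$class == "missense"))
})

test_that("neutral catalogs keep the false-positive rate near nominal", {
  fx <- dnds_fixture()
  set.seed(66)
  n_rep <- 50
  omegas <- numeric(n_rep)
  reject <- 0L
  for (i in seq_len(n_rep)) {
    counts <- simulate_selection_catalog(fx$models, rates = fx$rates)
    total <- sum(counts$missense + counts$nonsense + counts$synonymous)
    rates <- estimate_context_rates(fx$catalog, NULL, fx$models, total)
    fit <- gene_set_dnds(counts, fx$models, rates)
    m <- fit[fit$class == "missense", ]
    omegas[i] <- m$omega
    reject <- reject + (m$p_value < 0.05)
  }
  expect_gt(mean(omegas), 0.9)
  expect_lt(mean(omegas), 1.1)
  expect_lte(reject / n_rep, 0.10)
})

test_that("driver fractions and BH adjustment match hand calculations", {
  expect_equal(round(driver_fraction(14.5), 3), 0.931)
  expect_equal(round(driver_fraction(11.1), 3), 0.910)
  expect_equal(driver_fraction(1), 0)
  expect_equal(driver_fraction(0.5), 0)  # floored at zero under negative selection
  expect_error(driver_fraction(0), "positive")
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # monotone non-decreasing after sorting
  set.seed(2)
  p <- runif(30)
  expect_true(all(diff(sort(bh_fdr(p))) >= -1e-12))
})

test_that("gene models round-trip through FASTA", {
  models <- simulate_gene_models(3, cds_length = 30, seed = 77)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(unlist(lapply(models, function(m) {
    c(paste0(">", m$gene), m$sequence)
  })), fa)
  back <- read_gene_models(fa)
  expect_equal(names(back), names(models))
  expect_equal(back[[1]]$L, models[[1]]$L)
})
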