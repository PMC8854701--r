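# Build a MAF matrix with two planted clones (disjoint mutation sets) plus
# noise glands, through the simulator's read model.
two_clone_cohort <- function(depth = 60, seed = 17) {
  cfg <- simulation_config(
    n_subjects = 1, ages = 50,
    clusters = tibble::tibble(subject_id = "S01",
                              cluster_id = c("S01_c1", "S01_c2"),
                              n_glands = c(5L, 4L),
                              expansion_age = c(25, 30)),
    singleton_glands = 2, depth_mean = depth
  )
  simulate_cohort(cfg, seed = seed)
}

test_that("MAF matrix excludes blood-contaminated sites and fills absences with zero", {
  recs <- dplyr::bind_rows(
    make_records(gland_id = "g1", pos = 10L),
    make_records(gland_id = "g2", pos = 20L),
    make_records(gland_id = "g1", pos = 30L, blood_alt_reads = 4L)  # blood MAF 0.1
  )
  m <- maf_matrix(recs, make_glands(c("g1", "g2", "g3")))
  expect_equal(dim(m), c(2L, 3L))
  expect_false("chr1:30" %in% rownames(m))
  expect_equal(m["chr1:10", ], c(g1 = 0.5, g2 = 0, g3 = 0))
})

test_that("informative-mutation selection enforces the two-gland clonal rule", {
  m <- rbind(
    one_gland   = c(0.5, 0, 0),
    two_glands  = c(0.5, 0.5, 0),
    border      = c(0.30, 0.12, 0)
  )
  colnames(m) <- paste0("g", 1:3)
  expect_warning(kept <- select_informative_mutations(m[1, , drop = FALSE]),
                 "no informative")
  expect_equal(nrow(kept), 0)
  kept <- select_informative_mutations(m)
  expect_equal(rownames(kept), "two_glands")
  # the 0.10 co-sharing criterion marks supporting glands
  m2 <- rbind(site = c(0.5, 0.3, 0.12, 0.05))
  colnames(m2) <- paste0("g", 1:4)
  kept2 <- select_informative_mutations(m2)
  expect_equal(unname(attr(kept2, "support")[1, ]), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("hierarchical clustering with the defining-mutation rule recovers planted clones", {
  co <- two_clone_cohort()
  m <- maf_matrix(co$mutations, co$glands)
  mi <- select_informative_mutations(m)
  cl <- cluster_glands(mi)
  expect_equal(nrow(cl$clusters), 2)
  truth_cluster <- c(rep("A", 5), rep("B", 4), NA, NA)
  asg <- tidy(cl)$cluster_id
  # same partition as the truth (labels may differ)
  expect_equal(length(unique(asg[1:5])), 1)
  expect_equal(length(unique(asg[6:9])), 1)
  expect_false(asg[1] == asg[6])
  expect_true(all(is.na(asg[10:11])))
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(asg[1:9], truth_cluster[1:9])
  expect_equal(ari, 1)
})

test_that("identical columns form one cluster; pure-noise matrices form none", {
  m <- matrix(0.5, 5, 4, dimnames = list(paste0("s", 1:5), paste0("g", 1:4)))
  cl <- cluster_glands(m)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_glands, 4L)
  noise <- matrix(runif(40, 0, 0.09), 10, 4,
                  dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  cln <- cluster_glands(noise)
  expect_equal(nrow(cln$clusters), 0)
  expect_true(all(is.na(tidy(cln)$cluster_id)))
  expect_error(cluster_glands(m[, 1, drop = FALSE]), "two glands")
})

test_that("grid footprints and 4-neighborhood contiguity are computed per cluster", {
  co <- two_clone_cohort()
  m <- select_informative_mutations(maf_matrix(co$mutations, co$glands))
  cl <- cluster_glands(m)
  fp <- map_clusters_to_grid(cl, co$glands)
  expect_equal(nrow(fp), 2)
  # clusters occupy contiguous runs of the lattice by construction
  expect_true(all(fp$contiguous))
  expect_equal(sort(unlist(fp[fp$n_glands == 5, ]$footprint)),
               as.character(1:5))
  # two glands in non-adjacent cells are flagged non-contiguous
  g2 <- make_glands(c("x", "y"))
  g2$grid_row <- c(1L, 3L); g2$grid_col <- c(1L, 4L)
  cl2 <- cluster_glands(matrix(0.5, 3, 2,
                               dimnames = list(paste0("s", 1:3), c("x", "y"))))
  fp2 <- map_clusters_to_grid(cl2, g2)
  expect_false(fp2$contiguous)
  # missing grid assignments are dropped with a warning
  g2$grid_id[2] <- NA
  expect_warning(map_clusters_to_grid(cl2, g2), "grid")
})

test_that("sharing classification partitions cluster mutations", {
  m <- rbind(
    pub  = c(0.5, 0.5, 0.5, 0.5, 0.5),
    ps   = c(0.5, 0.5, 0, 0, 0),
    priv = c(0.5, 0, 0, 0, 0),
    none = c(0, 0, 0, 0, 0)
  )
  colnames(m) <- paste0("g", 1:5)
  prof <- classify_sharing(m, colnames(m))
  expect_equal(prof$label[prof$site == "pub"], "public")
  expect_equal(prof$label[prof$site == "ps"], "partial")
  expect_equal(prof$label[prof$site == "priv"], "private")
  expect_false("none" %in% prof$site)
  counts <- sharing_counts(prof)
  expect_equal(sum(counts), nrow(prof))  # partition property
  # planted counts recovered through the read model at high depth
  cfg <- simulation_config(n_subjects = 1, ages = 48, depth_mean = 200,
                           singleton_glands = 0)
  co <- simulate_cohort(cfg, seed = 23)
  mm <- maf_matrix(co$mutations, co$glands)
  members <- co$glands$gland_id
  got <- sharing_counts(classify_sharing(mm, members))
  tru <- table(co$truth$mutation_truth$sharing)
  expect_equal(unname(got[c("mb_pub", "mb_ps", "mb_priv")]),
               unname(c(tru[["public"]], tru[["partial"]], tru[["private"]])))
})
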