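# Synthetic-cohort generator. Emits per-gland somatic call tables with the
# statistical structure the downstream analyses assume -- per-subject clone
# clusters with public / partially shared / private mutations, binomial read
# sampling at configurable depth, clock-like context-biased accrual
# proportional to age, arm-level CN-LOH with a planted occurrence age and
# cellular fraction, and genes under configurable omega -- together with the
# full ground truth, so every stage has a recovery test.

#' A deterministic synthetic signature matrix
#'
#' Three well-separated synthetic mutational processes over the 96 classes:
#' a CpG-deamination-like process (C>T at NpCpG), a flat clock-like process,
#' and an oxidative-damage-like C>A process. Columns sum to one. Real
#' COSMIC matrices load through [read_signature_matrix()] and are
#' interchangeable with this one.
#'
#' @return 96 x 3 probability matrix with class rownames.
#' @export
synthetic_signature_matrix <- function() {
  cls <- sbs96_classes()
  p <- parse_sbs96(cls)
  sub <- paste0(p$ref, ">", p$alt)
  cpg <- as.numeric(sub == "C>T" & p$f3 == "G") +
    0.02 * as.numeric(sub == "C>T" & p$f3 != "G")
  flat <- rep(1, 96)
  oxo <- as.numeric(sub == "C>A") + 0.05 * as.numeric(sub == "T>A")
  m <- cbind(sig_cpg = cpg, sig_flat = flat, sig_oxo = oxo)
  rownames(m) <- cls
  sweep(m, 2, colSums(m), "/")
}

# Draw ref/alt/context for n mutations from a signature mixture; half the
# sites are reported on the purine strand to exercise pyrimidine collapsing.
draw_substitutions <- function(n, signature_mix, signatures) {
  prob <- drop(signatures %*% signature_mix)
  cls <- sample(sbs96_classes(), n, replace = TRUE, prob = prob)
  p <- parse_sbs96(cls)
  ref <- p$ref; alt <- p$alt
  ctx <- paste0(p$f5, p$ref, p$f3)
  flip <- runif(n) < 0.5
  ref[flip] <- complement(ref[flip])
  alt[flip] <- complement(alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  tibble(ref = ref, alt = alt, context = ctx, class = cls)
}

#' Build a simulation configuration
#'
#' Defaults describe a small multi-gland cohort: one clone cluster per
#' subject occupying contiguous cells of a rectangular grid plus a few
#' unrelated singleton glands, clock-like accrual of cluster-lineage SNVs,
#' pure binomial read sampling (an optional beta-binomial overdispersion
#' knob exists because real sequencing is noisier, but is off by default so
#' recovery oracles stay exact), and blood samples free of the somatic
#' variants unless a germline-contamination rate is set.
#'
#' @param subjects Tibble (`subject_id`, `age`, `menarche_age`, `parity`,
#'   `bmi`, `pack_years`, `disease`); built from `n_subjects`/`ages` when
#'   omitted.
#' @param n_subjects,ages Shortcut cohort layout when `subjects` is `NULL`.
#' @param clusters Tibble (`subject_id`, `cluster_id`, `n_glands`,
#'   `expansion_age`); default one cluster of 6 glands per subject with
#'   expansion at half the subject's age.
#' @param cnloh Optional tibble of planted copy-neutral LOH events
#'   (`subject_id`, `cluster_id`, `chrom`, `event_age`, `rho`); the event
#'   age must precede the cluster's expansion age.
#' @param snvs_per_year Cluster-lineage SNVs accrued per year over the
#'   callable region.
#' @param region_snvs_per_year Accrual rate restricted to a CN-LOH arm.
#' @param partial_fraction Fraction of post-expansion mutations shared by a
#'   subset (>= 2) of glands rather than private.
#' @param singleton_glands Unrelated glands per subject (private mutations
#'   only).
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param target_mb Callable megabases per gland.
#' @param signature_mix,signatures Mutation-class mixture; defaults to
#'   `c(0.3, 0.5, 0.2)` over [synthetic_signature_matrix()].
#' @param drivers_per_gland Mean planted nonsilent driver mutations per
#'   gland (Poisson).
#' @param overdispersion Beta-binomial overdispersion in (0, 1); 0 = pure
#'   binomial.
#' @param blood_contamination Per-read probability of the mutant allele in
#'   blood (models germline leakage for filter tests).
#' @param grid_dims `c(nrow, ncol)` of the spatial lattice.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(subjects = NULL, n_subjects = 4, ages = NULL,
                              clusters = NULL, cnloh = NULL,
                              snvs_per_year = 8, region_snvs_per_year = 2,
                              partial_fraction = 0.4, singleton_glands = 2,
                              depth_mean = 100, target_mb = 30,
                              signature_mix = c(0.3, 0.5, 0.2),
                              signatures = synthetic_signature_matrix(),
                              drivers_per_gland = 0,
                              overdispersion = 0, blood_contamination = 0,
                              grid_dims = c(4, 6)) {
  if (is.null(subjects)) {
    if (is.null(ages)) ages <- round(seq(25, 50, length.out = n_subjects))
    subjects <- tibble(
      subject_id = sprintf("S%02d", seq_along(ages)),
      age = ages,
      menarche_age = 12,
      parity = rep_len(c(0L, 1L, 2L), length(ages)),
      bmi = 22,
      pack_years = 0,
      disease = "none"
    )
  }
  subjects <- as_tibble(subjects)
  if (is.null(clusters)) {
    clusters <- tibble(
      subject_id = subjects$subject_id,
      cluster_id = paste0(subjects$subject_id, "_c1"),
      n_glands = 6L,
      expansion_age = subjects$age / 2
    )
  }
  clusters <- as_tibble(clusters)
  if (!is.null(cnloh)) {
    cnloh <- as_tibble(cnloh)
    key <- match(cnloh$cluster_id, clusters$cluster_id)
    if (any(is.na(key)) || any(cnloh$event_age >= clusters$expansion_age[key])) {
      stop("CN-LOH events must reference existing clusters and precede expansion",
           call. = FALSE)
    }
    if (any(cnloh$rho <= 0 | cnloh$rho > 1)) stop("rho must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(depth_mean > 0, target_mb > 0, snvs_per_year >= 0,
            all(abs(sum(signature_mix) - 1) < 1e-8),
            overdispersion >= 0, overdispersion < 1)
  ok <- match(clusters$subject_id, subjects$subject_id)
  if (any(is.na(ok)) || any(clusters$expansion_age >= subjects$age[ok])) {
    stop("cluster expansion ages must precede the subject's age at sampling",
         call. = FALSE)
  }
  structure(list(
    subjects = subjects, clusters = clusters, cnloh = cnloh,
    snvs_per_year = snvs_per_year,
    region_snvs_per_year = region_snvs_per_year,
    partial_fraction = partial_fraction, singleton_glands = singleton_glands,
    depth_mean = depth_mean, target_mb = target_mb,
    signature_mix = signature_mix, signatures = signatures,
    drivers_per_gland = drivers_per_gland,
    overdispersion = overdispersion,
    blood_contamination = blood_contamination, grid_dims = grid_dims
  ), class = "simulation_config")
}

draw_depth <- function(n, mean) pmax(1L, rpois(n, mean))

draw_alt <- function(depth, maf, overdispersion) {
  if (overdispersion > 0) {
    shape <- (1 - overdispersion) / overdispersion
    maf <- ifelse(maf %in% c(0, 1), maf,
                  stats::rbeta(length(depth), maf * shape, (1 - maf) * shape))
  }
  rbinom(length(depth), depth, maf)
}

#' Simulate a multi-gland cohort with ground truth
#'
#' See [simulation_config()] for the generative model. Public mutations are
#' carried by every gland of their cluster at expected MAF 0.5 (or `rho` /
#' `rho/2` inside a CN-LOH region for mutations that pre- or post-date the
#' event); partially shared mutations occupy a contiguous block of member
#' glands; private and singleton-gland mutations sit in one gland. Mutant
#' read counts are Binomial(depth, expected MAF). Mutations that pre-date a
#' CN-LOH are thinned by half before emission (the copy on the lost allele
#' disappears), which is exactly the loss the downstream doubling in
#' [time_cnloh()] corrects for.
#'
#' @param config A `simulation_config`.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An `endo_cohort` list: `mutations` (record tibble), `glands`,
#'   `clinical`, and `truth` (list of `mutation_truth`, `cluster_truth`,
#'   `cnloh_truth`).
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  cfg <- config
  clinical <- compute_cnmc(cfg$subjects)

  glands <- list(); muts <- list(); truth <- list()
  site_counter <- 0L
  new_sites <- function(n, chrom = NULL) {
    pos <- site_counter + seq_len(n)
    site_counter <<- site_counter + n
    if (is.null(chrom)) chrom <- sample(paste0("chr", 1:12), n, replace = TRUE)
    tibble(chrom = chrom, pos = 1000L * pos + sample.int(999L, n, replace = TRUE))
  }
  cnloh_chroms <- if (is.null(cfg$cnloh)) character(0) else unique(cfg$cnloh$chrom)

  emit <- function(subject_id, gland_ids, carrier, sites, subs, maf_exp,
                   sharing, cluster_id, cnloh_status) {
    # carrier: logical matrix sites x glands; maf_exp same shape
    n_site <- nrow(sites)
    rows <- which(carrier, arr.ind = TRUE)
    if (!nrow(rows)) return(NULL)
    depth_v <- draw_depth(nrow(rows), cfg$depth_mean)
    alt_v <- draw_alt(depth_v, maf_exp[rows], cfg$overdispersion)
    blood_depth_v <- draw_depth(nrow(rows), cfg$depth_mean)
    blood_alt_v <- rbinom(nrow(rows), blood_depth_v, cfg$blood_contamination)
    rec <- tibble(
      gland_id = gland_ids[rows[, 2]],
      subject_id = subject_id,
      chrom = sites$chrom[rows[, 1]],
      pos = sites$pos[rows[, 1]],
      ref = subs$ref[rows[, 1]],
      alt = subs$alt[rows[, 1]],
      depth = depth_v, alt_reads = alt_v,
      blood_depth = blood_depth_v, blood_alt_reads = blood_alt_v,
      context = subs$context[rows[, 1]],
      consequence = "noncoding", gene = "", pop_freq = 0
    )
    tru <- tibble(
      subject_id = subject_id,
      cluster_id = cluster_id,
      chrom = sites$chrom, pos = sites$pos,
      sharing = sharing,
      cnloh_status = cnloh_status,
      n_carriers = rowSums(carrier),
      expected_maf = apply(maf_exp, 1, max)
    )
    list(rec = rec, tru = tru)
  }

  nrow_grid <- cfg$grid_dims[1]; ncol_grid <- cfg$grid_dims[2]
  n_cells <- nrow_grid * ncol_grid

  for (si in seq_len(nrow(cfg$subjects))) {
    subj <- cfg$subjects$subject_id[si]
    age <- cfg$subjects$age[si]
    cl <- cfg$clusters[cfg$clusters$subject_id == subj, , drop = FALSE]
    n_cluster_glands <- sum(cl$n_glands)
    n_glands <- n_cluster_glands + cfg$singleton_glands
    gid <- sprintf("%s_g%02d", subj, seq_len(n_glands))
    cell <- ((seq_len(n_glands) - 1L) %% n_cells) + 1L
    # snake (boustrophedon) order: consecutive cells are always 4-adjacent,
    # so clusters occupy contiguous lattice runs
    g_row <- (cell - 1L) %/% ncol_grid + 1L
    g_col_raw <- (cell - 1L) %% ncol_grid + 1L
    g_col <- ifelse(g_row %% 2L == 1L, g_col_raw, ncol_grid + 1L - g_col_raw)
    glands[[subj]] <- tibble(
      gland_id = gid, subject_id = subj,
      grid_id = as.character(cell),
      grid_row = g_row,
      grid_col = g_col,
      callable_bases = cfg$target_mb * 1e6,
      coverage20_fraction = round(runif(n_glands, 0.85, 0.99), 3)
    )
    offset <- 0L
    for (ci in seq_len(nrow(cl))) {
      members <- gid[offset + seq_len(cl$n_glands[ci])]
      offset <- offset + cl$n_glands[ci]
      texp <- cl$expansion_age[ci]
      n_total <- rpois(1, cfg$snvs_per_year * age)
      is_pub <- runif(n_total) < texp / age
      n_pub <- sum(is_pub); n_other <- n_total - n_pub
      can_partial <- length(members) > 2
      is_partial <- !is_pub & can_partial &
        runif(n_total) < cfg$partial_fraction
      sharing <- ifelse(is_pub, "public", ifelse(is_partial, "partial", "private"))

      sites <- new_sites(n_total)
      keep <- !sites$chrom %in% cnloh_chroms
      sites <- sites[keep, , drop = FALSE]; sharing <- sharing[keep]
      n_total <- nrow(sites)
      subs <- draw_substitutions(n_total, cfg$signature_mix, cfg$signatures)
      carrier <- matrix(FALSE, n_total, length(members))
      for (j in seq_len(n_total)) {
        carrier[j, ] <- switch(
          sharing[j],
          public = rep(TRUE, length(members)),
          partial = {
            k <- sample(2:(length(members) - 1), 1)
            start <- sample(length(members) - k + 1, 1)
            seq_len(length(members)) %in% (start:(start + k - 1))
          },
          private = seq_len(length(members)) == sample(length(members), 1)
        )
      }
      maf_exp <- carrier * 0.5
      out <- emit(subj, members, carrier, sites, subs, maf_exp,
                  sharing, cl$cluster_id[ci], NA_character_)
      if (!is.null(out)) { muts[[length(muts) + 1]] <- out$rec; truth[[length(truth) + 1]] <- out$tru }

      # planted CN-LOH events for this cluster
      ev <- if (is.null(cfg$cnloh)) NULL else
        cfg$cnloh[cfg$cnloh$cluster_id == cl$cluster_id[ci], , drop = FALSE]
      if (!is.null(ev) && nrow(ev)) {
        for (ei in seq_len(nrow(ev))) {
          rate <- cfg$region_snvs_per_year
          n_pre_raw <- rpois(1, rate * ev$event_age[ei])
          n_pre <- rbinom(1, n_pre_raw, 0.5)  # copies on the lost allele vanish
          n_post <- rpois(1, rate * (texp - ev$event_age[ei]))
          n_reg <- n_pre + n_post
          if (n_reg == 0) next
          status <- c(rep("pre", n_pre), rep("post", n_post))
          sites_r <- new_sites(n_reg, chrom = rep(ev$chrom[ei], n_reg))
          subs_r <- draw_substitutions(n_reg, cfg$signature_mix, cfg$signatures)
          carrier_r <- matrix(TRUE, n_reg, length(members))
          maf_r <- matrix(ifelse(status == "pre", ev$rho[ei], ev$rho[ei] / 2),
                          n_reg, length(members))
          out <- emit(subj, members, carrier_r, sites_r, subs_r, maf_r,
                      "public", cl$cluster_id[ci], status)
          if (!is.null(out)) { muts[[length(muts) + 1]] <- out$rec; truth[[length(truth) + 1]] <- out$tru }
        }
      }
    }
    # unrelated singleton glands: private mutations only
    if (cfg$singleton_glands > 0) {
      singles <- gid[n_cluster_glands + seq_len(cfg$singleton_glands)]
      for (g in singles) {
        n_priv <- rpois(1, cfg$snvs_per_year * age)
        if (n_priv == 0) next
        sites_s <- new_sites(n_priv)
        sites_s <- sites_s[!sites_s$chrom %in% cnloh_chroms, , drop = FALSE]
        n_priv <- nrow(sites_s)
        if (n_priv == 0) next
        subs_s <- draw_substitutions(n_priv, cfg$signature_mix, cfg$signatures)
        carrier_s <- matrix(TRUE, n_priv, 1)
        out <- emit(subj, g, carrier_s, sites_s, subs_s, carrier_s * 0.5,
                    "private", NA_character_, NA_character_)
        if (!is.null(out)) { muts[[length(muts) + 1]] <- out$rec; truth[[length(truth) + 1]] <- out$tru }
      }
    }
    # planted driver mutations
    if (cfg$drivers_per_gland > 0) {
      for (g in gid) {
        n_drv <- rpois(1, cfg$drivers_per_gland)
        if (n_drv == 0) next
        sites_d <- new_sites(n_drv)
        subs_d <- draw_substitutions(n_drv, cfg$signature_mix, cfg$signatures)
        out <- emit(subj, g, matrix(TRUE, n_drv, 1), sites_d, subs_d,
                    matrix(0.5, n_drv, 1), "private", NA_character_,
                    NA_character_)
        out$rec$consequence <- "missense"
        out$rec$gene <- sample(DRIVER_GENES, n_drv, replace = TRUE)
        out$tru$sharing <- "driver"
        muts[[length(muts) + 1]] <- out$rec; truth[[length(truth) + 1]] <- out$tru
      }
    }
  }

  mutations <- dplyr::bind_rows(muts)
  mutation_truth <- dplyr::bind_rows(truth)
  cluster_truth <- dplyr::left_join(
    cfg$clusters,
    dplyr::select(cfg$subjects, "subject_id", "age"),
    by = "subject_id"
  )
  structure(list(
    mutations = mutations,
    glands = dplyr::bind_rows(glands),
    clinical = clinical,
    truth = list(mutation_truth = mutation_truth,
                 cluster_truth = cluster_truth,
                 cnloh_truth = cfg$cnloh),
    config = cfg, seed = seed
  ), class = "endo_cohort")
}

#' @export
print.endo_cohort <- function(x, ...) {
  cat("<endo_cohort>", nrow(x$clinical), "subjects,", nrow(x$glands),
      "glands,", nrow(x$mutations), "gland-level mutation records\n")
  invisible(x)
}

#' Simulate a noncoding 96-class SNV catalog
#'
#' Multinomial draw of `n_snvs` noncoding SNVs from the class probabilities
#' implied by a signature mixture; stands in for a large public catalog of
#' noncoding somatic SNVs when estimating relative context rates.
#'
#' @param signature_mix Exposure vector over the columns of `signatures`.
#' @param signatures 96 x K signature matrix.
#' @param n_snvs Catalog size (>= 1).
#' @param seed Optional integer seed.
#' @return Named 96-vector of counts summing to `n_snvs`.
#' @export
simulate_noncoding_catalog <- function(signature_mix,
                                       signatures = synthetic_signature_matrix(),
                                       n_snvs = 1.1e6, seed = NULL) {
  if (!length(signature_mix) || sum(signature_mix) <= 0) {
    stop("empty signature mixture", call. = FALSE)
  }
  stopifnot(n_snvs >= 1)
  if (!is.null(seed)) set.seed(seed)
  prob <- drop(signatures %*% (signature_mix / sum(signature_mix)))
  setNames(drop(rmultinom(1, n_snvs, prob)), sbs96_classes())
}

#' Simulate per-gene substitution counts under known selection
#'
#' Draws missense, nonsense and synonymous counts for each gene from the
#' context-wise Poisson rates `t * r_i * L_i^j * omega_j(gene)`, with
#' `omega = 1` for synonymous sites.
#'
#' @param models Named list of `gene_model`s.
#' @param omega_map Named numeric vector: true missense omega per gene
#'   (genes absent default to 1). Nonsense omega follows `omega_n_map` or
#'   the same values.
#' @param rates `context_rates` (fields `r`, `t`).
#' @param omega_n_map Optional nonsense omegas.
#' @param seed Optional integer seed.
#' @return Tibble: `gene`, `missense`, `nonsense`, `synonymous`,
#'   `true_omega_m`, `true_omega_n`.
#' @export
simulate_selection_catalog <- function(models, omega_map = NULL, rates,
                                       omega_n_map = NULL, seed = NULL) {
  stopifnot(rates$t >= 0, all(rates$r >= 0))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(models), function(g) {
    wm <- if (!is.null(omega_map) && g %in% names(omega_map)) omega_map[[g]] else 1
    wn <- if (!is.null(omega_n_map) && g %in% names(omega_n_map)) omega_n_map[[g]] else wm
    if (wm < 0 || wn < 0) stop("negative omega", call. = FALSE)
    L <- models[[g]]$L
    lam <- rates$t * rates$r
    tibble(
      gene = g,
      missense = sum(rpois(96, lam * L[, "m"] * wm)),
      nonsense = sum(rpois(96, lam * L[, "n"] * wn)),
      synonymous = sum(rpois(96, lam * L[, "s"])),
      true_omega_m = wm, true_omega_n = wn
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate random gene models
#'
#' Random coding sequences built from non-stop codons (so opportunity
#' counting never hits an internal stop), with random flanking bases.
#'
#' @param n_genes Number of genes.
#' @param cds_length CDS length in bp (multiple of 3).
#' @param seed Optional integer seed.
#' @return Named list of `gene_model`s.
#' @export
simulate_gene_models <- function(n_genes = 5, cds_length = 999, seed = NULL) {
  stopifnot(cds_length %% 3 == 0)
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  models <- lapply(seq_len(n_genes), function(i) {
    cds <- paste(sample(codons, cds_length / 3, replace = TRUE), collapse = "")
    s <- paste0(sample(BASES, 1), cds, sample(BASES, 1))
    count_site_opportunities(s, gene = sprintf("G%03d", i))
  })
  setNames(models, vapply(models, `[[`, "", "gene"))
}

#' Write a simulated cohort to TSV files
#'
#' Emits `mutations.tsv`, `glands.tsv`, `clinical.tsv`, the ground-truth
#' tables and a `config.yaml` snapshot into `dir`.
#'
#' @param cohort An `endo_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mutation_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  readr::write_tsv(cohort$glands, file.path(dir, "glands.tsv"), progress = FALSE)
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth$mutation_truth,
                   file.path(dir, "truth_mutations.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth$cluster_truth,
                   file.path(dir, "truth_clusters.tsv"), progress = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(list(
    seed = cohort$seed,
    n_subjects = nrow(cfg$subjects),
    snvs_per_year = cfg$snvs_per_year,
    depth_mean = cfg$depth_mean,
    target_mb = cfg$target_mb,
    grid_dims = cfg$grid_dims
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}
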