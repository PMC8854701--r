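# End-to-end orchestration: simulate (optional) -> filter/QC -> burden /
# spectrum / signatures -> dN/dS -> clustering -> timing, with deterministic
# seeding, TSV outputs and a JSON run manifest.

#' Build a pipeline configuration
#'
#' Either point `input_dir` at a directory holding `mutations.tsv`,
#' `glands.tsv` and `clinical.tsv` (the formats written by
#' [write_cohort()]), or leave it `NULL` to simulate a cohort with
#' `sim_config`. Stage toggles switch off the optional stages. A YAML file
#' with these fields can be loaded by passing its path.
#'
#' @param input_dir Input directory, or `NULL` to simulate.
#' @param sim_config A [simulation_config()] used when simulating.
#' @param stages Character vector of stages to run, a subset of
#'   `c("filter", "burden", "signatures", "dnds", "cluster", "timing")`.
#' @param filter_mode `"wgs"` or `"target"`.
#' @param signature_matrix 96 x K matrix for exposure fitting.
#' @param n_boot Bootstrap replicates for exposure intervals.
#' @param gene_models Named list of `gene_model`s for dN/dS (simulated when
#'   `NULL` and the dnds stage is on).
#' @param seed Integer seed recorded in every output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            sim_config = simulation_config(),
                            stages = c("filter", "burden", "signatures",
                                       "dnds", "cluster", "timing"),
                            filter_mode = "wgs",
                            signature_matrix = synthetic_signature_matrix(),
                            n_boot = 200,
                            gene_models = NULL,
                            seed = 1) {
  if (is.character(sim_config) && length(sim_config) == 1 && file.exists(sim_config)) {
    sim_config <- do.call(simulation_config, yaml::read_yaml(sim_config))
  }
  structure(list(input_dir = input_dir, sim_config = sim_config,
                 stages = stages, filter_mode = filter_mode,
                 signature_matrix = signature_matrix, n_boot = n_boot,
                 gene_models = gene_models, seed = seed),
            class = "pipeline_config")
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

stage_fail <- function(stage, e) {
  stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and writes one TSV per result
#' plus a `manifest.json` (package version, seed, input checksums, stage
#' list). Outputs are byte-identical across reruns of the same config and
#' seed. A failing stage halts the run with a stage-tagged error.
#'
#' @param config A `pipeline_config` (or YAML path accepted by
#'   [pipeline_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  inputs <- character(0)

  if (is.null(config$input_dir)) {
    stage_msg("simulate", "generating synthetic cohort, seed ", config$seed)
    cohort <- tryCatch(simulate_cohort(config$sim_config, seed = config$seed),
                       error = function(e) stage_fail("simulate", e))
    mutations <- cohort$mutations
    glands <- cohort$glands
    clinical <- cohort$clinical
    results$cohort <- cohort
  } else {
    paths <- file.path(config$input_dir,
                       c("mutations.tsv", "glands.tsv", "clinical.tsv"))
    if (!all(file.exists(paths))) {
      stop("stage `load` failed: missing input file(s): ",
           paste(paths[!file.exists(paths)], collapse = ", "), call. = FALSE)
    }
    inputs <- paths
    mutations <- read_mutation_tsv(paths[1])
    glands <- readr::read_tsv(paths[2], show_col_types = FALSE, progress = FALSE)
    clinical <- read_clinical_tsv(paths[3])
  }

  if ("filter" %in% config$stages) {
    flt <- tryCatch(filter_somatic_calls(mutations, mode = config$filter_mode),
                    error = function(e) stage_fail("filter", e))
    glands <- gland_qc(glands)
    stage_msg("filter", nrow(flt$kept), " of ",
              nrow(mutations), " records kept; ",
              sum(glands$qc_pass), "/", nrow(glands), " glands pass QC")
    mutations <- flt$kept[flt$kept$gland_id %in%
                            glands$gland_id[glands$qc_pass], , drop = FALSE]
    readr::write_tsv(tidy(flt), file.path(out_dir, "filter_tally.tsv"),
                     progress = FALSE)
    results$filter <- flt
  }

  if ("burden" %in% config$stages) {
    bur <- tryCatch({
      clin <- if (!"cnmc" %in% names(clinical)) compute_cnmc(clinical) else clinical
      b <- mutation_burden(mutations, glands[glands$qc_pass %||% TRUE, ])
      dplyr::left_join(b, clin, by = "subject_id")
    }, error = function(e) stage_fail("burden", e))
    stage_msg("burden", "per-subject burden for ", nrow(bur), " subjects")
    readr::write_tsv(bur, file.path(out_dir, "burden.tsv"), progress = FALSE)
    results$burden <- bur
    if (nrow(bur) >= 3 && var(bur$age) > 0 && var(bur$burden) > 0) {
      assoc <- covariate_association(bur, "burden", "age")
      readr::write_tsv(assoc, file.path(out_dir, "burden_association.tsv"),
                       progress = FALSE)
      results$association <- assoc
    }
  }

  if ("signatures" %in% config$stages) {
    res <- tryCatch({
      spec <- spectrum_96(mutations)
      fit <- fit_exposures(spec, config$signature_matrix,
                           n_boot = config$n_boot, seed = config$seed)
      list(spectrum = spec, fit = fit)
    }, error = function(e) stage_fail("signatures", e))
    stage_msg("signatures", sum(tidy(res$fit)$significant),
              " significant signature(s)")
    readr::write_tsv(res$spectrum, file.path(out_dir, "spectrum.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(res$fit), file.path(out_dir, "exposures.tsv"),
                     progress = FALSE)
    results$spectrum <- res$spectrum
    results$exposures <- res$fit
  }

  if ("dnds" %in% config$stages) {
    res <- tryCatch({
      models <- config$gene_models
      if (is.null(models)) models <- simulate_gene_models(10, seed = config$seed)
      catalog <- simulate_noncoding_catalog(c(0.3, 0.5, 0.2),
                                            n_snvs = 1e5, seed = config$seed)
      counts <- simulate_selection_catalog(
        models, omega_map = setNames(rep(1, length(models)), names(models)),
        rates = estimate_context_rates(catalog, NULL, models, 200),
        seed = config$seed
      )
      rates <- estimate_context_rates(
        catalog, NULL, models,
        observed_total = sum(counts$missense + counts$nonsense + counts$synonymous)
      )
      gene_set_dnds(counts, models, rates, set_name = "all_genes")
    }, error = function(e) stage_fail("dnds", e))
    stage_msg("dnds", "gene-set dN/dS on ", length(unique(res$set)), " set(s)")
    readr::write_tsv(res, file.path(out_dir, "dnds.tsv"), progress = FALSE)
    results$dnds <- res
  }

  cluster_results <- NULL
  if ("cluster" %in% config$stages) {
    cluster_results <- tryCatch({
      per_subject <- lapply(split(mutations, mutations$subject_id), function(rec) {
        g <- glands[glands$subject_id == rec$subject_id[1], , drop = FALSE]
        full <- maf_matrix(rec, g)
        mm <- suppressWarnings(select_informative_mutations(full))
        if (!nrow(mm) || ncol(mm) < 2) return(NULL)
        cl <- cluster_glands(mm)
        # sharing/timing must see every site (informative selection drops
        # private single-gland mutations)
        list(matrix = full, informative = mm, clusters = cl,
             grid = map_clusters_to_grid(cl, g))
      })
      per_subject[!vapply(per_subject, is.null, logical(1))]
    }, error = function(e) stage_fail("cluster", e))
    asg <- dplyr::bind_rows(lapply(cluster_results, function(x) tidy(x$clusters)))
    stage_msg("cluster", sum(!is.na(asg$cluster_id)), " glands in clusters")
    readr::write_tsv(asg, file.path(out_dir, "clusters.tsv"), progress = FALSE)
    results$clusters <- cluster_results
  }

  if ("timing" %in% config$stages && !is.null(cluster_results)) {
    timing <- tryCatch({
      rows <- list()
      for (subj in names(cluster_results)) {
        cl <- cluster_results[[subj]]$clusters
        mm <- cluster_results[[subj]]$matrix
        age <- clinical$age[clinical$subject_id == subj]
        for (i in seq_len(nrow(cl$clusters))) {
          members <- cl$clusters$members[[i]]
          counts <- sharing_counts(classify_sharing(mm, members))
          est <- time_expansion(age, counts[["mb_pub"]], counts[["mb_ps"]],
                                counts[["mb_priv"]])
          rows[[length(rows) + 1]] <- dplyr::mutate(
            est, subject_id = subj, cluster_id = cl$clusters$cluster_id[i],
            seed = config$seed)
        }
      }
      dplyr::bind_rows(rows)
    }, error = function(e) stage_fail("timing", e))
    stage_msg("timing", nrow(timing), " expansion timing estimate(s)")
    readr::write_tsv(timing, file.path(out_dir, "timing.tsv"), progress = FALSE)
    results$timing <- timing
  }

  manifest <- list(
    package = "endoclone",
    version = as.character(packageVersion("endoclone")),
    seed = config$seed,
    stages = config$stages,
    inputs = as.list(if (length(inputs)) tools::md5sum(inputs) else character(0)),
    outputs = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
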