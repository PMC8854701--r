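# Readers and writers for the flat formats every stage consumes. All files
# are plain TSV (or FASTA / Newick where the field's format is standard).

MUTATION_COLS <- c("gland_id", "subject_id", "chrom", "pos", "ref", "alt",
                   "depth", "alt_reads", "blood_depth", "blood_alt_reads",
                   "context", "consequence", "gene", "pop_freq")

#' Read / write a mutation record table
#'
#' One row per somatic call in one gland. Columns: `gland_id`, `subject_id`,
#' `chrom`, `pos` (1-based), `ref`, `alt`, `depth`, `alt_reads`,
#' `blood_depth`, `blood_alt_reads`, `context` (reference-strand trinucleotide
#' centered on the site), `consequence` (one of missense, nonsense,
#' synonymous, splice, inframe_indel, frameshift, noncoding), `gene`
#' (symbol or empty) and `pop_freq` (maximum population-panel frequency).
#'
#' @param path File path.
#' @return `read_mutation_tsv()` returns a tibble of records.
#' @export
read_mutation_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         ref = readr::col_character(),
                         alt = readr::col_character(),
                         context = readr::col_character(),
                         gene = readr::col_character()
                       ))
  missing <- setdiff(MUTATION_COLS, names(x))
  if (length(missing)) {
    stop("mutation TSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x$gene[is.na(x$gene)] <- ""
  x
}

#' @param records Tibble of mutation records.
#' @rdname read_mutation_tsv
#' @export
write_mutation_tsv <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a subject clinical table
#'
#' Columns: `subject_id`, `age`, `menarche_age`, `parity`, `bmi`,
#' `pack_years`, `disease`.
#'
#' @param path File path.
#' @return Tibble of subject-level clinical covariates.
#' @export
read_clinical_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(disease = readr::col_character()))
}

#' Read a reference signature matrix
#'
#' Expects a TSV with a `class` column holding the 96 class labels (any
#' order) and one column per signature; rows are reordered to the canonical
#' class order and columns renormalized to sum to one.
#'
#' @param path File path.
#' @return 96 x K numeric matrix with class rownames.
#' @export
read_signature_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cls <- sbs96_classes()
  if (!"class" %in% names(x) || !all(cls %in% x$class)) {
    stop("signature TSV needs a `class` column covering all 96 classes",
         call. = FALSE)
  }
  m <- as.matrix(x[match(cls, x$class), setdiff(names(x), "class")])
  rownames(m) <- cls
  sweep(m, 2, colSums(m), "/")
}

#' @param sigs 96 x K signature matrix.
#' @rdname read_signature_matrix
#' @export
write_signature_matrix <- function(sigs, path) {
  out <- tibble(class = rownames(sigs))
  out <- dplyr::bind_cols(out, as_tibble(sigs))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read gene models from a CDS FASTA and a coordinates TSV
#'
#' The FASTA holds, per gene, the coding sequence with one additional
#' flanking base on each side (needed for trinucleotide contexts at the CDS
#' edges). The coordinates TSV (columns `gene`, `chrom`, `start`, `end`) is
#' optional metadata carried through.
#'
#' @param fasta_path CDS FASTA path (headers are gene symbols).
#' @param coords_path Optional coordinates TSV.
#' @return Named list of `gene_model` objects (see
#'   [count_site_opportunities()]).
#' @export
read_gene_models <- function(fasta_path, coords_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  coords <- if (!is.null(coords_path)) {
    readr::read_tsv(coords_path, show_col_types = FALSE, progress = FALSE)
  }
  models <- lapply(seq_along(seqs), function(i) {
    gene <- names(seqs)[i]
    m <- count_site_opportunities(as.character(seqs[[i]]), gene = gene)
    if (!is.null(coords) && gene %in% coords$gene) {
      m$coords <- coords[coords$gene == gene, , drop = FALSE]
    }
    m
  })
  setNames(models, names(seqs))
}

#' Read somatic calls from a VCF
#'
#' Thin wrapper over `vcfR` that extracts per-sample `AD`/`DP` fields for a
#' gland and its matched blood sample and emits the same record tibble as
#' [read_mutation_tsv()]. Context, consequence, gene and population frequency
#' are taken from INFO keys `CTX`, `CSQ`, `GENE` and `PF` when present,
#' otherwise left unannotated.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param gland_sample,blood_sample Sample column names.
#' @param gland_id,subject_id Identifiers for the emitted records.
#' @return Tibble of mutation records.
#' @export
read_mutation_vcf <- function(path, gland_sample, blood_sample,
                              gland_id = gland_sample,
                              subject_id = gland_sample) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the `vcfR` package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  alt_of <- function(sample) {
    as.integer(vapply(strsplit(ad[, sample], ","), function(p) {
      if (length(p) >= 2) p[2] else "0"
    }, character(1)))
  }
  info_key <- function(key) {
    val <- vcfR::extract.info(v, key)
    if (all(is.na(val))) NULL else val
  }
  ctx <- info_key("CTX")
  csq <- info_key("CSQ")
  gene <- info_key("GENE")
  pf <- info_key("PF")
  tibble(
    gland_id = gland_id,
    subject_id = subject_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    depth = as.integer(dp[, gland_sample]),
    alt_reads = alt_of(gland_sample),
    blood_depth = as.integer(dp[, blood_sample]),
    blood_alt_reads = alt_of(blood_sample),
    context = if (is.null(ctx)) NA_character_ else ctx,
    consequence = if (is.null(csq)) "noncoding" else csq,
    gene = if (is.null(gene)) "" else gene,
    pop_freq = if (is.null(pf)) 0 else as.numeric(pf)
  )
}
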