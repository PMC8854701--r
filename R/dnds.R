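# Trinucleotide-context Poisson dN/dS. Counts of missense / nonsense /
# synonymous SNVs in context class i are modeled as
#   n_i^m ~ Poisson(t * r_i * L_i^m * omega_m)
#   n_i^n ~ Poisson(t * r_i * L_i^n * omega_n)
#   n_i^s ~ Poisson(t * r_i * L_i^s)
# where L_i^j are site opportunities enumerated from the CDS, r_i are
# relative context rates estimated from a large noncoding SNV catalog, and
# the baseline rate t is calibrated so total expected = total observed.

#' Enumerate site opportunities for a coding sequence
#'
#' Every position of the CDS admits three single-base substitutions; each is
#' translated and classified as missense, nonsense (introducing a stop) or
#' synonymous, and tallied into its pyrimidine-normalized 96 context class.
#' A change that removes the reference amino acid's identity counts as
#' missense (stop-loss changes are counted as missense under this
#' convention). The sequence must carry one flanking base on each side so
#' edge positions have full trinucleotide contexts, and must not contain
#' internal stop codons (supply the CDS without the terminal stop).
#'
#' @param cds_with_flanks Character scalar: flank + CDS + flank; CDS length
#'   divisible by 3, ACGT only.
#' @param gene Gene symbol carried in the result.
#' @return A `gene_model`: list with `gene`, `cds_length` and `L`, a 96 x 3
#'   matrix of opportunity counts (columns `m`, `n`, `s`), satisfying
#'   `sum(L) == 3 * cds_length`.
#' @export
#' @examples
#' m <- count_site_opportunities("AATGC", gene = "toy")  # single Met codon
#' colSums(m$L)
count_site_opportunities <- function(cds_with_flanks, gene = "") {
  s <- toupper(cds_with_flanks)
  if (!grepl("^[ACGT]+$", s)) stop("ambiguous or non-ACGT base in sequence", call. = FALSE)
  chars <- strsplit(s, NULL)[[1]]
  L_cds <- length(chars) - 2
  if (L_cds < 3 || L_cds %% 3 != 0) {
    stop("CDS length (without flanks) must be a positive multiple of 3", call. = FALSE)
  }
  cds <- chars[2:(L_cds + 1)]
  code <- Biostrings::GENETIC_CODE
  codon_mat <- matrix(cds, nrow = 3)
  codons <- apply(codon_mat, 2, paste, collapse = "")
  ref_aa <- unname(code[codons])
  if (any(ref_aa == "*")) stop("internal stop codon in CDS", call. = FALSE)

  pos <- rep(seq_len(L_cds), each = 3)
  ref <- cds[pos]
  alt <- unlist(lapply(cds, function(b) setdiff(BASES, b)), use.names = FALSE)
  cpos <- (pos - 1L) %% 3L + 1L
  cidx <- (pos - 1L) %/% 3L + 1L
  c1 <- codon_mat[1, cidx]; c2 <- codon_mat[2, cidx]; c3 <- codon_mat[3, cidx]
  alt_codon <- paste0(ifelse(cpos == 1, alt, c1),
                      ifelse(cpos == 2, alt, c2),
                      ifelse(cpos == 3, alt, c3))
  alt_aa <- unname(code[alt_codon])
  cons <- ifelse(alt_aa == ref_aa[cidx], "s",
                 ifelse(alt_aa == "*", "n", "m"))
  context <- paste0(chars[pos], ref, chars[pos + 2])
  cls <- classify_sbs96(ref, alt, context)
  L <- matrix(0L, 96, 3, dimnames = list(sbs96_classes(), c("m", "n", "s")))
  tab <- table(factor(cls, levels = sbs96_classes()),
               factor(cons, levels = c("m", "n", "s")))
  L[, ] <- as.integer(tab)
  structure(list(gene = gene, cds_length = L_cds, L = L, sequence = s),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$gene, "- CDS", x$cds_length, "bp; opportunities",
    paste(sprintf("%s=%d", colnames(x$L), colSums(x$L)), collapse = ", "), "\n")
  invisible(x)
}

sum_opportunities <- function(models) {
  Reduce(`+`, lapply(models, function(m) m$L))
}

#' Estimate relative context rates and the baseline rate
#'
#' Relative rates `r_i` are proportional to noncoding catalog counts divided
#' by the genomic context opportunities, normalized to mean one (the overall
#' scale is absorbed by `t`). The baseline per-site rate `t` is calibrated so
#' that the total expected count over all context classes and consequence
#' types in the target gene models equals the observed total:
#' `t = observed_total / sum_i sum_j r_i * L_i^j`.
#'
#' @param noncoding_counts 96-vector of noncoding SNV counts (canonical
#'   class order).
#' @param context_opportunities 96-vector of available genomic trinucleotide
#'   sites per class (uniform if `NULL`).
#' @param models Named list of `gene_model`s defining the target space.
#' @param observed_total Total observed coding SNV count used for
#'   calibration.
#' @return A `context_rates` list: `r` (named 96-vector, mean 1) and `t`.
#' @export
estimate_context_rates <- function(noncoding_counts,
                                   context_opportunities = NULL,
                                   models, observed_total) {
  x <- as.numeric(noncoding_counts)
  stopifnot(length(x) == 96)
  if (all(x == 0)) stop("noncoding catalog has no counts", call. = FALSE)
  opp <- if (is.null(context_opportunities)) rep(1, 96) else as.numeric(context_opportunities)
  if (any(opp <= 0 & x > 0)) {
    stop("positive counts require positive context opportunities", call. = FALSE)
  }
  r <- ifelse(opp > 0, x / opp, 0)
  r <- r / mean(r)
  L <- sum_opportunities(models)
  denom <- sum(r * rowSums(L))
  t <- observed_total / denom
  structure(list(r = setNames(r, sbs96_classes()), t = t),
            class = "context_rates")
}

# Expected counts (m, n, s) for a set of gene models under given rates.
expected_counts <- function(models, rates) {
  L <- sum_opportunities(models)
  colSums(L * rates$r) * rates$t
}

poisson_ll <- function(n, lambda) {
  sum(ifelse(n > 0, n * log(lambda), 0) - lambda)
}

#' Estimate the dN/dS ratio from observed and expected counts
#'
#' Under the shared-scale Poisson model (`n_obs ~ Poisson(s * omega * E_obs)`,
#' `n_syn ~ Poisson(s * E_syn)`) the maximum-likelihood dN/dS ratio is the
#' ratio of ratios `(n_obs/E_obs) / (n_syn/E_syn)`. The 95% CI is Wald on
#' `log(omega)` with variance `1/n_obs + 1/n_syn`, replaced by the profile
#' likelihood interval when either count is below 5. The p-value is the
#' likelihood-ratio test of `omega = 1` (chi-squared, 1 df).
#'
#' @param n_obs,e_obs Observed and expected counts of the tested class
#'   (missense or nonsense).
#' @param n_syn,e_syn Observed and expected synonymous counts.
#' @return One-row tibble: `omega`, `ci_low`, `ci_high`, `p_value`, `dn`,
#'   `ds`, `n_obs`, `n_syn`. When `n_syn = 0` the ratio is undefined: `dn`
#'   and `ds` are still reported and `omega` is `NA`.
#' @export
estimate_omega <- function(n_obs, e_obs, n_syn, e_syn) {
  stopifnot(e_obs > 0, e_syn > 0, n_obs >= 0, n_syn >= 0)
  dn <- n_obs / e_obs
  ds <- n_syn / e_syn
  base <- tibble(omega = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, dn = dn, ds = ds,
                 n_obs = n_obs, n_syn = n_syn)
  if (n_syn == 0) return(base)
  omega <- dn / ds

  # profile log-likelihood in omega (scale maximized out analytically)
  pll <- function(w) {
    s <- (n_obs + n_syn) / (w * e_obs + e_syn)
    poisson_ll(n_obs, s * w * e_obs) + poisson_ll(n_syn, s * e_syn)
  }
  ll_hat <- poisson_ll(n_obs, max(n_obs, 1e-12)) + poisson_ll(n_syn, n_syn)
  stat <- 2 * (ll_hat - pll(1))
  p <- pchisq(max(stat, 0), df = 1, lower.tail = FALSE)

  if (n_obs >= 5 && n_syn >= 5) {
    se <- sqrt(1 / n_obs + 1 / n_syn)
    lo <- exp(log(omega) - 1.96 * se)
    hi <- exp(log(omega) + 1.96 * se)
  } else {
    crit <- ll_hat - qchisq(0.95, 1) / 2
    f <- function(lw) pll(exp(lw)) - crit
    lw_hat <- log(max(omega, 1e-12))
    lo <- if (n_obs == 0) 0 else {
      exp(uniroot(f, c(lw_hat - 30, lw_hat), tol = 1e-9)$root)
    }
    hi <- exp(uniroot(f, c(lw_hat, lw_hat + 30), tol = 1e-9)$root)
  }
  tibble(omega = omega, ci_low = lo, ci_high = hi, p_value = p,
         dn = dn, ds = ds, n_obs = n_obs, n_syn = n_syn)
}

count_coding_snvs <- function(records, genes, maf_min = 0.25) {
  keep <- high_maf_snvs(records, maf_min)
  keep <- keep[keep$gene %in% genes &
                 keep$consequence %in% c("missense", "nonsense", "synonymous"), ,
               drop = FALSE]
  out <- tidyr::pivot_wider(
    dplyr::count(keep, .data$gene, .data$consequence),
    names_from = "consequence", values_from = "n", values_fill = 0L
  )
  for (col in c("missense", "nonsense", "synonymous")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out
}

#' Gene-set dN/dS
#'
#' Pools observed and expected counts over the member genes and estimates
#' separate missense and nonsense dN/dS ratios against the pooled synonymous
#' counts, with the implied driver fractions.
#'
#' @param counts Tibble of per-gene observed counts with columns `gene`,
#'   `missense`, `nonsense`, `synonymous` (e.g. from
#'   [simulate_selection_catalog()] or built from records).
#' @param models Named list of `gene_model`s.
#' @param rates `context_rates` from [estimate_context_rates()].
#' @param genes Member genes (default: all genes in `models`).
#' @param set_name Label for the gene set.
#' @return A `dnds_fit` tibble with one row per tested class (`missense`,
#'   `nonsense`): `omega`, `ci_low`, `ci_high`, `p_value`,
#'   `driver_fraction`, observed/expected counts.
#' @export
gene_set_dnds <- function(counts, models, rates, genes = names(models),
                          set_name = "set") {
  stopifnot(length(genes) > 0)
  models <- models[intersect(genes, names(models))]
  if (!length(models)) stop("no gene models for the requested set", call. = FALSE)
  E <- expected_counts(models, rates)
  if (E[["s"]] <= 0) stop("gene set has no synonymous site opportunity", call. = FALSE)
  cc <- counts[counts$gene %in% genes, , drop = FALSE]
  n_m <- sum(cc$missense); n_n <- sum(cc$nonsense); n_s <- sum(cc$synonymous)
  res <- dplyr::bind_rows(
    dplyr::mutate(estimate_omega(n_m, E[["m"]], n_s, E[["s"]]), class = "missense"),
    dplyr::mutate(estimate_omega(n_n, E[["n"]], n_s, E[["s"]]), class = "nonsense")
  )
  res <- dplyr::mutate(
    res,
    set = set_name,
    e_obs = c(E[["m"]], E[["n"]]), e_syn = E[["s"]],
    driver_fraction = ifelse(is.na(.data$omega) | .data$omega <= 0,
                             NA_real_, pmax(0, (.data$omega - 1) / .data$omega))
  )
  res <- dplyr::relocate(res, "set", "class", "omega", "ci_low", "ci_high",
                         "p_value", "driver_fraction")
  class(res) <- c("dnds_fit", class(res))
  res
}

#' Per-gene selection tests
#'
#' Tests individual genes for an excess of missense or nonsense
#' substitutions over the context-rate expectation. Only genes with at least
#' `min_snvs` high-MAF coding SNVs are considered, and a class is tested
#' only when its observed count exceeds its expectation. P-values come from
#' the likelihood-ratio test in [estimate_omega()]; Benjamini-Hochberg
#' adjustment is applied within each class across tested genes, with
#' significance at `fdr < fdr_q`.
#'
#' @param counts Per-gene observed counts (`gene`, `missense`, `nonsense`,
#'   `synonymous`).
#' @param models Named list of `gene_model`s.
#' @param rates `context_rates`.
#' @param min_snvs Minimum total coding SNVs for a gene to be considered.
#' @param fdr_q FDR significance threshold.
#' @return A `dnds_fit` tibble, one row per tested gene x class, with `dn`,
#'   `ds`, `omega`, `p_value`, `fdr`, `significant`.
#' @export
per_gene_selection <- function(counts, models, rates, min_snvs = 5,
                               fdr_q = 0.1) {
  counts <- as_tibble(counts)
  counts$total <- counts$missense + counts$nonsense + counts$synonymous
  eligible <- counts[counts$total >= min_snvs & counts$gene %in% names(models), ,
                     drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(eligible))) {
    g <- eligible$gene[i]
    E <- expected_counts(models[g], rates)
    for (cl in c("missense", "nonsense")) {
      n_obs <- eligible[[cl]][i]
      e_obs <- E[[substr(cl, 1, 1)]]
      if (e_obs <= 0 || n_obs <= e_obs) next
      fit <- estimate_omega(n_obs, e_obs, eligible$synonymous[i], E[["s"]])
      rows[[length(rows) + 1]] <- dplyr::mutate(fit, gene = g, class = cl)
    }
  }
  if (!length(rows)) {
    return(structure(tibble(gene = character(), class = character()),
                     class = c("dnds_fit", class(tibble()))))
  }
  res <- dplyr::bind_rows(rows)
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$class),
    fdr = p.adjust(.data$p_value, method = "BH")
  )
  res <- dplyr::ungroup(dplyr::mutate(res, significant = !is.na(.data$fdr) & .data$fdr < fdr_q))
  res <- dplyr::relocate(res, "gene", "class", "omega", "dn", "ds",
                         "p_value", "fdr", "significant")
  class(res) <- c("dnds_fit", class(res))
  res
}

#' Driver fraction implied by a dN/dS ratio
#'
#' The fraction of observed nonsynonymous mutations that are genuine
#' drivers: `f = (omega - 1) / omega`, floored at zero.
#'
#' @param omega dN/dS ratio(s), strictly positive.
#' @return Numeric vector of driver fractions in \[0, 1).
#' @export
#' @examples
#' driver_fraction(14.5)  # 0.931
driver_fraction <- function(omega) {
  if (any(is.na(omega)) || any(omega <= 0)) {
    stop("`omega` must be positive", call. = FALSE)
  }
  pmax(0, (omega - 1) / omega)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wrapper over
#' `p.adjust(..., method = "BH")`).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' @exportS3Method generics::glance
glance.dnds_fit <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_significant = if ("significant" %in% names(x)) sum(x$significant) else NA_integer_,
         min_p = suppressWarnings(min(x$p_value, na.rm = TRUE)))
}
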