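# Per-subject mutation burden, 96-class spectra and covariate association.

high_maf_snvs <- function(records, maf_min = 0.25) {
  records <- as_tibble(records)
  snv <- nchar(records$ref) == 1 & nchar(records$alt) == 1 &
    records$ref %in% BASES & records$alt %in% BASES
  maf <- ifelse(records$depth > 0, records$alt_reads / records$depth, 0)
  records[snv & maf >= maf_min, , drop = FALSE]
}

#' Per-subject mutation burden
#'
#' The burden for a subject pools counts and callable bases over that
#' subject's glands: `b = sum_j n_j * 1e6 / sum_j l_j`, where `n_j` is the
#' number of high-MAF somatic SNVs and `l_j` the number of target bases
#' covered by at least 20 reads in gland `j`. The burden is therefore
#' invariant to how mutations are split among glands. Burdens are also
#' broken out by the six pyrimidine substitutions and for C>T transitions at
#' CpG motifs (classes `N[C>T]G`).
#'
#' @param records Mutation record tibble (may span subjects).
#' @param glands Gland tibble with `gland_id`, `subject_id` and
#'   `callable_bases` columns.
#' @param maf_min High-MAF threshold (default 0.25).
#' @return Tibble, one row per subject: `burden` (per Mbp), `burden_<sub>`
#'   for the six substitutions, `cpg_ct_burden`, `n_snvs`, `callable_bases`.
#' @export
mutation_burden <- function(records, glands, maf_min = 0.25) {
  glands <- as_tibble(glands)
  if (any(is.na(glands$callable_bases)) || any(glands$callable_bases <= 0)) {
    stop("every gland needs `callable_bases` > 0", call. = FALSE)
  }
  keep <- high_maf_snvs(records, maf_min)
  keep$class <- classify_sbs96(keep$ref, keep$alt, keep$context)
  keep$sub <- sub(".*\\[(.>.)\\].*", "\\1", keep$class)
  keep$cpg_ct <- !is.na(keep$class) &
    keep$sub == "C>T" & substr(keep$class, 7, 7) == "G"

  denom <- dplyr::summarise(dplyr::group_by(glands, .data$subject_id),
                            callable_bases = sum(.data$callable_bases),
                            .groups = "drop")
  counts <- dplyr::summarise(
    dplyr::group_by(keep, .data$subject_id),
    n_snvs = dplyr::n(),
    cpg_ct = sum(.data$cpg_ct),
    !!!setNames(
      lapply(PYRIMIDINE_SUBS, function(s) rlang::quo(sum(.data$sub == !!s, na.rm = TRUE))),
      paste0("n_", sub(">", "", PYRIMIDINE_SUBS))
    ),
    .groups = "drop"
  )
  out <- dplyr::left_join(denom, counts, by = "subject_id")
  out <- dplyr::mutate(out, dplyr::across(dplyr::starts_with("n_"), ~ tidyr::replace_na(.x, 0L)),
                       cpg_ct = tidyr::replace_na(.data$cpg_ct, 0L))
  scale <- 1e6 / out$callable_bases
  out$burden <- out$n_snvs * scale
  for (s in PYRIMIDINE_SUBS) {
    out[[paste0("burden_", sub(">", "", s))]] <- out[[paste0("n_", sub(">", "", s))]] * scale
  }
  out$cpg_ct_burden <- out$cpg_ct * scale
  dplyr::relocate(out, "subject_id", "burden")
}

#' 96-class mutation spectrum
#'
#' Tallies SNVs into the 96 substitution classes; purine-reference SNVs are
#' reverse-complemented to the pyrimidine strand first. Records whose
#' context is not a valid ACGT trinucleotide centered on the reference base
#' are skipped with a warning.
#'
#' @param records Mutation record tibble (SNVs; other rows are ignored).
#' @return An `sbs_spectrum`: a tibble with `class` and `count` columns in
#'   canonical class order, with the number of skipped records in attribute
#'   `n_skipped`.
#' @export
spectrum_96 <- function(records) {
  records <- as_tibble(records)
  snv <- nchar(records$ref) == 1 & nchar(records$alt) == 1 &
    records$ref %in% BASES & records$alt %in% BASES
  records <- records[snv, , drop = FALSE]
  cls <- classify_sbs96(records$ref, records$alt, records$context)
  n_skipped <- sum(is.na(cls))
  if (n_skipped > 0) {
    warning(n_skipped, " SNV record(s) had invalid contexts and were skipped")
  }
  counts <- table(factor(cls[!is.na(cls)], levels = sbs96_classes()))
  out <- tibble(class = sbs96_classes(), count = as.integer(counts))
  structure(out, class = c("sbs_spectrum", class(out)), n_skipped = n_skipped)
}

#' Association between mutation burden and a clinical covariate
#'
#' Unadjusted: Pearson correlation with a two-tailed test, plus the ordinary
#' least-squares slope with its 95% CI. Age-adjusted: both variables are
#' regressed on age and the partial correlation is computed between the
#' residuals (the adjusted slope is the coefficient of the covariate in a
#' burden ~ covariate + age regression; both are returned).
#'
#' @param data Tibble with one row per subject.
#' @param response,covariate Column names (strings) of the response (burden)
#'   and covariate.
#' @param adjust_age If `TRUE`, adjust both variables for the `age` column.
#' @return One-row tibble: `r`, `p_value`, `slope`, `slope_low`, `slope_high`,
#'   `n`, `adjusted`.
#' @export
covariate_association <- function(data, response, covariate,
                                  adjust_age = FALSE) {
  data <- as_tibble(data)
  y <- data[[response]]
  x <- data[[covariate]]
  ok <- stats::complete.cases(x, y, if (adjust_age) data$age else x)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete subjects", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in response or covariate", call. = FALSE)
  }
  if (adjust_age) {
    age <- data$age[ok]
    yr <- residuals(lm(y ~ age))
    xr <- residuals(lm(x ~ age))
    if (var(xr) < 1e-10 * max(var(x), 1) || var(yr) < 1e-10 * max(var(y), 1)) {
      stop("covariate is collinear with age", call. = FALSE)
    }
    ct <- cor.test(xr, yr)
    fit <- lm(y ~ x + age)
    ci <- confint(fit)["x", ]
    slope <- coef(fit)[["x"]]
  } else {
    ct <- cor.test(x, y)
    fit <- lm(y ~ x)
    ci <- confint(fit)["x", ]
    slope <- coef(fit)[["x"]]
  }
  tibble(r = unname(ct$estimate), p_value = ct$p.value, slope = slope,
         slope_low = ci[[1]], slope_high = ci[[2]], n = length(x),
         adjusted = adjust_age)
}

#' Default driver-gene panel
#'
#' The nine cancer driver genes shared between the Cancer Gene Census and
#' the pan-gynecologic cancer-associated gene list.
#' @export
DRIVER_GENES <- c("ARID1A", "CTNNB1", "FBXW7", "KRAS", "PIK3CA",
                  "PIK3R1", "PPP2R1A", "PTEN", "TP53")

#' Per-subject driver mutation burden
#'
#' Mean number of nonsilent high-MAF mutations (non-synonymous SNVs and
#' indels) in the driver-gene panel per gland, for each subject.
#'
#' @param records Mutation record tibble.
#' @param glands Gland tibble (`gland_id`, `subject_id`); every gland counts
#'   in the denominator whether or not it carries driver mutations.
#' @param driver_genes Character vector of gene symbols.
#' @param maf_min High-MAF threshold.
#' @return Tibble with `subject_id`, `n_driver`, `n_glands`,
#'   `driver_burden` (= n_driver / n_glands).
#' @export
driver_burden <- function(records, glands, driver_genes = DRIVER_GENES,
                          maf_min = 0.25) {
  glands <- as_tibble(glands)
  if (nrow(glands) == 0) stop("empty gland list", call. = FALSE)
  records <- as_tibble(records)
  maf <- ifelse(records$depth > 0, records$alt_reads / records$depth, 0)
  nonsilent <- c("missense", "nonsense", "splice", "inframe_indel", "frameshift")
  hit <- records$gene %in% driver_genes &
    records$consequence %in% nonsilent & maf >= maf_min
  counts <- dplyr::count(records[hit, , drop = FALSE], .data$subject_id,
                         name = "n_driver")
  denom <- dplyr::count(glands, .data$subject_id, name = "n_glands")
  out <- dplyr::left_join(denom, counts, by = "subject_id")
  out$n_driver <- tidyr::replace_na(out$n_driver, 0L)
  dplyr::mutate(out, driver_burden = .data$n_driver / .data$n_glands)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact two-sided rank-sum p-value for small samples (both groups <= 50 and
#' no ties), the normal approximation with continuity correction otherwise.
#' If every value across the two groups is tied the test is uninformative
#' and p = 1 by convention.
#'
#' @param values_a,values_b Numeric vectors.
#' @return Two-sided p-value.
#' @export
group_difference_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(unique(c(values_a, values_b))) == 1) return(1)
  exact <- length(values_a) <= 50 && length(values_b) <= 50
  suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE)$p.value
  )
}
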