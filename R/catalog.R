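# Somatic-call catalog: record-level filtering, MAF classification and
# gland-level QC. Records are plain tibbles, one row per somatic call in one
# gland, with the columns documented in `read_mutation_tsv()`.

#' Classify mutant allele frequencies into the trimodal categories
#'
#' The MAF distribution of somatic mutations in monoclonal glands is
#' trimodal: subclonal mutations (MAF < 0.25), clonal heterozygous mutations
#' (MAF >= 0.25), and clonal mutations with allelic imbalance such as loss of
#' the wild-type allele (MAF >= 0.75).
#'
#' @param maf Numeric vector of mutant allele frequencies in \[0, 1\].
#' @return Factor with levels `subclonal`, `clonal`, `clonal_imbalanced`.
#' @export
#' @examples
#' classify_maf(c(0.1, 0.25, 0.8))
classify_maf <- function(maf) {
  if (any(is.na(maf)) || any(maf < 0 | maf > 1)) {
    stop("`maf` must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(maf < 0.25, "subclonal",
                ifelse(maf >= 0.75, "clonal_imbalanced", "clonal"))
  factor(out, levels = c("subclonal", "clonal", "clonal_imbalanced"))
}

# Fixed criterion order for rejection attribution, mirroring the printed
# (i)-(vi) call-filter list: variant quality, population frequency, depth,
# mutant-read support, MAF, matched-blood MAF.
FILTER_CRITERIA <- c("no_coverage", "quality", "pop_freq", "depth",
                     "alt_reads", "maf", "blood_maf")

#' Filter somatic calls
#'
#' Applies the high-confidence somatic filters to a record tibble. In `wgs`
#' mode the full criterion list is active: variant quality pass, population
#' frequency < 0.001, depth >= 20, mutant-supporting reads >= 8, MAF >= 0.25,
#' and matched-blood MAF <= 0.05. In `target` mode only the quality flag and
#' the population-frequency filter are applied (depth and support are handled
#' by the upstream caller for targeted panels). Rejected records are
#' attributed to the first failing criterion in that fixed order; records
#' with zero depth are rejected as `no_coverage`.
#'
#' @param records Tibble of mutation records (see `read_mutation_tsv()`);
#'   an optional logical `quality_pass` column models the caller's empirical
#'   variant score exceeding -10*log10(0.05) = 13.0103 (missing column means
#'   all pass).
#' @param mode `"wgs"` or `"target"`.
#' @return An object of class `somatic_filter`: a list with `kept` (tibble of
#'   passing records), `rejected` (tibble with a `reject_reason` column) and
#'   `tally` (tibble of per-criterion rejection counts). `tidy()` returns the
#'   tally; `glance()` the totals.
#' @export
filter_somatic_calls <- function(records, mode = c("wgs", "target")) {
  mode <- match.arg(mode)
  records <- as_tibble(records)
  n <- nrow(records)
  qp <- if ("quality_pass" %in% names(records)) records$quality_pass else rep(TRUE, n)
  qp[is.na(qp)] <- TRUE
  depth <- records$depth
  maf <- ifelse(depth > 0, records$alt_reads / depth, NA_real_)
  blood_maf <- ifelse(records$blood_depth > 0,
                      records$blood_alt_reads / records$blood_depth, 0)

  fail <- rep(NA_character_, n)
  mark <- function(fail, cond, reason) ifelse(is.na(fail) & cond, reason, fail)
  fail <- mark(fail, depth == 0, "no_coverage")
  fail <- mark(fail, !qp, "quality")
  fail <- mark(fail, records$pop_freq >= 0.001, "pop_freq")
  if (mode == "wgs") {
    fail <- mark(fail, depth < 20, "depth")
    fail <- mark(fail, records$alt_reads < 8, "alt_reads")
    fail <- mark(fail, maf < 0.25, "maf")
    fail <- mark(fail, blood_maf > 0.05, "blood_maf")
  }

  kept <- records[is.na(fail), , drop = FALSE]
  rejected <- records[!is.na(fail), , drop = FALSE]
  rejected$reject_reason <- fail[!is.na(fail)]
  tally <- tibble(
    criterion = FILTER_CRITERIA,
    n_rejected = vapply(FILTER_CRITERIA, function(cr) {
      sum(fail == cr, na.rm = TRUE)
    }, integer(1))
  )
  structure(
    list(kept = kept, rejected = rejected, tally = tally, mode = mode),
    class = "somatic_filter"
  )
}

#' @export
print.somatic_filter <- function(x, ...) {
  cat("<somatic_filter> mode =", x$mode, "\n")
  cat("  kept:", nrow(x$kept), " rejected:", nrow(x$rejected), "\n")
  drop <- x$tally[x$tally$n_rejected > 0, ]
  if (nrow(drop)) {
    for (i in seq_len(nrow(drop))) {
      cat("   ", drop$criterion[i], ":", drop$n_rejected[i], "\n")
    }
  }
  invisible(x)
}

#' Gland-level quality control
#'
#' A gland passes QC when more than 70% of the target bases are covered by
#' at least 20 reads.
#'
#' @param glands Tibble with a `coverage20_fraction` column (fraction of the
#'   target covered at >= 20 reads).
#' @param min_fraction Strict lower bound on the covered fraction.
#' @return The input tibble with a logical `qc_pass` column.
#' @export
gland_qc <- function(glands, min_fraction = 0.70) {
  glands <- as_tibble(glands)
  cov <- glands$coverage20_fraction
  if (is.null(cov) || any(is.na(cov))) {
    stop("`coverage20_fraction` is required for every gland", call. = FALSE)
  }
  dplyr::mutate(glands, qc_pass = cov > min_fraction)
}

#' Exact binomial test for allelic imbalance
#'
#' Two-sided exact binomial test of the mutant-read count against a null
#' heterozygous allele fraction, used to call allelic imbalance favoring the
#' mutant allele (MAF >= 0.8, P < 1e-5).
#'
#' @param alt_reads,depth Mutant-supporting and total read counts
#'   (vectorized).
#' @param p0 Null allele fraction, default 0.5.
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' binomial_imbalance_test(20, 20)  # ~1.9e-6
binomial_imbalance_test <- function(alt_reads, depth, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie in (0, 1)", call. = FALSE)
  stopifnot(all(depth >= 1), all(alt_reads >= 0), all(alt_reads <= depth))
  mapply(function(a, d) binom.test(a, d, p = p0)$p.value, alt_reads, depth)
}

#' Cumulative number of menstrual cycles (CNMC)
#'
#' CNMC is the clock covariate for hormone-cycle-driven mutation accrual:
#' cycles elapsed between menarche and sampling, minus cycles suppressed by
#' each pregnancy. The formula is an explicit, configurable modeling
#' assumption of this package; both parameters are exposed.
#'
#' @param clinical Tibble with `age`, `menarche_age` and `parity` columns.
#' @param cycles_per_year Menstrual cycles per year (default 13).
#' @param cycles_lost_per_parity Cycles suppressed per pregnancy (default 15).
#' @return The input tibble with a `cnmc` column (floored at zero).
#' @export
compute_cnmc <- function(clinical, cycles_per_year = 13,
                         cycles_lost_per_parity = 15) {
  clinical <- as_tibble(clinical)
  age <- clinical$age
  men <- clinical$menarche_age
  parity <- clinical$parity
  if (any(is.na(age)) || any(is.na(men))) {
    stop("`age` and `menarche_age` are required", call. = FALSE)
  }
  if (any(men > age)) {
    stop("`menarche_age` exceeds `age` for some subjects", call. = FALSE)
  }
  parity[is.na(parity)] <- 0
  dplyr::mutate(
    clinical,
    cnmc = pmax(0, cycles_per_year * (age - men) - cycles_lost_per_parity * parity)
  )
}

#' @exportS3Method generics::tidy
tidy.somatic_filter <- function(x, ...) x$tally

#' @exportS3Method generics::glance
glance.somatic_filter <- function(x, ...) {
  tibble(mode = x$mode, n_input = nrow(x$kept) + nrow(x$rejected),
         n_kept = nrow(x$kept), n_rejected = nrow(x$rejected))
}
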