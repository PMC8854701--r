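# Allelic-imbalance normalization and a simplified arm-level CN-LOH segment
# caller. The degree of allelic imbalance at a germline heterozygous site is
# the absolute log odds ratio of variant-allele read counts between the
# gland and its matched blood. This caller is deliberately simple tooling
# for synthetic signals: the cellular fraction rho of an event is an input
# carried through to timing, not estimated here.

#' Normalize an allelic-imbalance signal
#'
#' Subtracts the genome-wide mean |log odds ratio| (computed over
#' heterozygous sites outside any excluded copy-number-altered region) so
#' the baseline is zero, then computes a centered moving average over
#' `window` heterozygous SNVs within each chromosome (windows truncated at
#' chromosome ends).
#'
#' @param signal Tibble with `chrom`, `pos`, `logor_abs` (>= 0), sorted by
#'   position within chromosome.
#' @param excluded_regions Optional tibble `chrom`, `start`, `end` of
#'   regions excluded from the baseline mean.
#' @param window Moving-average window in sites (default 100).
#' @return The input tibble with `excluded`, `normalized` and `smooth`
#'   columns.
#' @export
normalize_imbalance <- function(signal, excluded_regions = NULL,
                                window = 100) {
  signal <- as_tibble(signal)
  stopifnot(all(signal$logor_abs >= 0))
  excl <- rep(FALSE, nrow(signal))
  if (!is.null(excluded_regions) && nrow(excluded_regions)) {
    for (i in seq_len(nrow(excluded_regions))) {
      excl <- excl | (signal$chrom == excluded_regions$chrom[i] &
                        signal$pos >= excluded_regions$start[i] &
                        signal$pos <= excluded_regions$end[i])
    }
  }
  if (all(excl)) stop("all heterozygous sites fall in excluded regions", call. = FALSE)
  baseline <- mean(signal$logor_abs[!excl])
  signal$excluded <- excl
  signal$normalized <- signal$logor_abs - baseline
  signal <- dplyr::arrange(signal, .data$chrom, .data$pos)
  signal <- dplyr::mutate(
    dplyr::group_by(signal, .data$chrom),
    smooth = zoo::rollapply(.data$normalized, window, mean,
                            partial = TRUE, align = "center")
  )
  dplyr::ungroup(signal)
}

#' Call CN-LOH segments from a smoothed imbalance signal
#'
#' Maximal runs of at least `min_sites` consecutive heterozygous sites whose
#' moving-average imbalance exceeds `threshold` become segments. The
#' cellular fraction and major:minor annotation are attached from the
#' caller's configuration (they are inputs, not estimates).
#'
#' @param signal Output of [normalize_imbalance()].
#' @param threshold Smoothed-signal threshold (default 0.2).
#' @param min_sites Minimum run length in sites (default 100).
#' @param rho Cellular fraction annotation in (0, 1\] (default 1).
#' @param copy_annotation Major:minor copy annotation (default `"2:0"`).
#' @return Tibble of segments: `chrom`, `start`, `end`, `n_sites`, `rho`,
#'   `copy_annotation`.
#' @export
call_segments <- function(signal, threshold = 0.2, min_sites = 100,
                          rho = 1, copy_annotation = "2:0") {
  stopifnot(rho > 0, rho <= 1)
  segs <- list()
  for (chr in unique(signal$chrom)) {
    s <- signal[signal$chrom == chr, , drop = FALSE]
    above <- s$smooth > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= min_sites)
    for (h in hit) {
      segs[[length(segs) + 1]] <- tibble(
        chrom = chr,
        start = s$pos[starts[h]], end = s$pos[ends[h]],
        n_sites = r$lengths[h], rho = rho,
        copy_annotation = copy_annotation
      )
    }
  }
  if (!length(segs)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_sites = integer(), rho = numeric(),
                  copy_annotation = character()))
  }
  dplyr::bind_rows(segs)
}
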