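# Trinucleotide-context machinery shared by spectra, signatures, the
# site-opportunity counter and the simulator. Contexts are carried on the
# reference strand and collapsed to the pyrimidine strand only here.

BASES <- c("A", "C", "G", "T")
PYRIMIDINE_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 single-base-substitution classes
#'
#' Class labels follow the conventional `5'[ref>alt]3'` notation on the
#' pyrimidine strand, ordered by substitution (C>A, C>G, C>T, T>A, T>C, T>G)
#' and then lexicographically by the 5' and 3' flanking bases, e.g.
#' `A[C>A]A`, `A[C>A]C`, ...
#'
#' @return Character vector of the 96 class labels, in canonical order.
#' @export
#' @examples
#' head(sbs96_classes())
sbs96_classes <- function() {
  unlist(lapply(PYRIMIDINE_SUBS, function(sub) {
    ref <- substr(sub, 1, 1)
    alt <- substr(sub, 3, 3)
    as.vector(t(outer(BASES, BASES, function(f5, f3) {
      paste0(f5, "[", ref, ">", alt, "]", f3)
    })))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}

complement <- function(x) chartr("ACGT", "TGCA", x)

#' Classify single-base substitutions into the 96 classes
#'
#' Substitutions with a purine reference base are reverse-complemented to
#' the pyrimidine strand (the flanking bases are swapped and complemented)
#' before classification.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param context Trinucleotide context on the reference strand; the middle
#'   base must equal `ref`.
#' @return Character vector of class labels such as `"T[C>T]T"`; `NA` for
#'   records that are not single-base substitutions with an ACGT context.
#' @export
#' @examples
#' classify_sbs96("G", "A", "AGA")  # -> "T[C>T]T"
classify_sbs96 <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context) &
    ref %in% BASES & alt %in% BASES & ref != alt &
    nchar(context) == 3 & substr(context, 2, 2) == ref &
    grepl("^[ACGT]{3}$", context)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  purine <- r %in% c("A", "G")
  r[purine] <- complement(r[purine])
  a[purine] <- complement(a[purine])
  ctx[purine] <- revcomp(ctx[purine])
  out[ok] <- paste0(
    substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3)
  )
  out
}

# Split a 96-class label into flank5, ref, alt, flank3.
parse_sbs96 <- function(class) {
  list(
    f5  = substr(class, 1, 1),
    ref = substr(class, 3, 3),
    alt = substr(class, 5, 5),
    f3  = substr(class, 7, 7)
  )
}
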