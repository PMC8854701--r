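# Signature exposure fitting: constrained maximum likelihood on the
# exposure simplex (multiplicative EM updates) with multinomial-bootstrap
# percentile intervals and the 0.01 lower-bound significance rule.

#' Names of the default candidate signature set
#'
#' The eleven COSMIC v3 SBS signatures active in at least 10% of samples of
#' any of the three gynecologic cancers; used as the default candidate set
#' when fitting real reference matrices.
#' @export
CANDIDATE_SIGNATURES <- c("SBS1", "SBS2", "SBS3", "SBS5", "SBS10a", "SBS10b",
                          "SBS13", "SBS15", "SBS18", "SBS40", "SBS44")

em_exposures <- function(x, sigs, start = NULL, tol = 1e-8, max_iter = 10000) {
  K <- ncol(sigs)
  N <- sum(x)
  e <- unname(if (is.null(start)) rep(1 / K, K) else start)
  ll_of <- function(e) {
    p <- pmax(drop(sigs %*% e), 1e-300)
    sum(x[x > 0] * log(p[x > 0]))
  }
  ll <- ll_of(e)
  for (iter in seq_len(max_iter)) {
    p <- pmax(drop(sigs %*% e), 1e-300)
    # responsibility-weighted counts per signature (classes with zero counts
    # contribute nothing)
    ratio <- ifelse(x > 0, x / p, 0)
    w <- colSums(ratio * sigs * rep(e, each = nrow(sigs)))
    e_new <- w / N
    e_new <- e_new / sum(e_new)
    ll_new <- ll_of(e_new)
    if (is.finite(ll_new) && abs(ll_new - ll) < tol) {
      e <- e_new; ll <- ll_new
      return(list(exposures = e, loglik = ll, iterations = iter,
                  converged = TRUE))
    }
    e <- e_new; ll <- ll_new
  }
  list(exposures = e, loglik = ll, iterations = max_iter, converged = FALSE)
}

#' Fit signature exposures to a 96-class spectrum
#'
#' Point estimates maximize the multinomial likelihood of the observed
#' spectrum under the mixture `sum_k e_k * sig_k`, subject to the exposures
#' lying on the simplex (EM-style multiplicative updates; monotone in the
#' log-likelihood). Uncertainty comes from a multinomial bootstrap of the
#' spectrum: the 90% percentile interval per signature. A signature is
#' flagged significant when the interval's lower limit exceeds
#' `significance_threshold` (default 0.01), mirroring the lower-bound rule
#' used with posterior intervals.
#'
#' @param spectrum An `sbs_spectrum` (or tibble with `class`, `count`).
#' @param sigs 96 x K signature probability matrix (columns sum to 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param level Interval level (default 0.90).
#' @param significance_threshold Lower-bound exposure threshold.
#' @param seed Optional integer seed for the bootstrap.
#' @return An `exposure_fit` object; `tidy()` gives one row per signature
#'   (`exposure`, `interval_low`, `interval_high`, `significant`),
#'   `glance()` the fit summary.
#' @export
fit_exposures <- function(spectrum, sigs, n_boot = 1000, level = 0.90,
                          significance_threshold = 0.01, seed = NULL) {
  x <- spectrum$count[match(rownames(sigs), spectrum$class)]
  stopifnot(!any(is.na(x)))
  if (sum(x) < 1) stop("spectrum must contain at least one mutation", call. = FALSE)
  if (anyDuplicated(t(sigs))) {
    warning("signature matrix has duplicate columns; exposures for them are not identifiable")
  }
  fit <- em_exposures(x, sigs)
  if (!is.null(seed)) set.seed(seed)
  N <- sum(x)
  boots <- matrix(NA_real_, n_boot, ncol(sigs))
  if (n_boot > 0) {
    draws <- rmultinom(n_boot, N, x / N)
    for (b in seq_len(n_boot)) {
      boots[b, ] <- em_exposures(draws[, b], sigs, start = fit$exposures,
                                 tol = 1e-6)$exposures
    }
  }
  alpha <- (1 - level) / 2
  lo <- if (n_boot > 0) apply(boots, 2, stats::quantile, alpha) else fit$exposures
  hi <- if (n_boot > 0) apply(boots, 2, stats::quantile, 1 - alpha) else fit$exposures
  res <- tibble(
    signature = colnames(sigs),
    exposure = unname(fit$exposures),
    interval_low = pmin(lo, fit$exposures),
    interval_high = pmax(hi, fit$exposures),
    significant = pmin(lo, fit$exposures) > significance_threshold
  )
  structure(
    list(exposures = res, loglik = fit$loglik, n_mutations = N,
         n_boot = n_boot, level = level, iterations = fit$iterations,
         converged = fit$converged,
         threshold = significance_threshold),
    class = "exposure_fit"
  )
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("<exposure_fit>", x$n_mutations, "mutations,",
      nrow(x$exposures), "signatures, log-likelihood",
      format(x$loglik, digits = 6), "\n")
  print(x$exposures)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.exposure_fit <- function(x, ...) x$exposures

#' @exportS3Method generics::glance
glance.exposure_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_mutations = x$n_mutations,
         n_signatures = nrow(x$exposures), n_boot = x$n_boot,
         iterations = x$iterations, converged = x$converged,
         n_significant = sum(x$exposures$significant))
}
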