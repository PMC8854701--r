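# Chronological timing of clonal expansions and copy-neutral LOH events.
#
# Under a constant per-lineage mutation rate between birth and sampling, the
# age of the most recent clonal expansion of a clone cluster is the sampling
# age scaled by the proportion of public mutations:
#   T_CE = Age * MB_pub / (MB_pub + MB_ps + MB_priv).
# A CN-LOH inside the cluster's history is timed from the public SNVs in the
# affected region: mutations predating the event are homozygous in affected
# cells (expected allele fraction rho), later ones heterozygous on one of
# the duplicated copies (rho / 2). SNVs on the lost allele disappeared, so
# the pre-event count is doubled before forming
#   T_CNLOH = T_CE * MB_pre / (MB_pre + MB_post).

#' Time the most recent clonal expansion
#'
#' Point estimate `T_CE = age * p` with `p = mb_pub / m`,
#' `m = mb_pub + mb_ps + mb_priv`; 95% CI from the normal approximation for
#' the proportion, `age * (p +/- 1.96 * sqrt(p (1 - p) / m))`, clipped to
#' `[0, age]`.
#'
#' @param age Age at sampling in years.
#' @param mb_pub,mb_ps,mb_priv Counts of public, partially shared and
#'   private mutations in the cluster (outside copy-number-altered regions).
#' @return A `timing_estimate` tibble row: `event`, `estimate`, `ci_low`,
#'   `ci_high`, `m`, `p`, `age`.
#' @export
#' @examples
#' time_expansion(50, 50, 25, 25)  # 25 years, CI half-width 4.9
time_expansion <- function(age, mb_pub, mb_ps, mb_priv) {
  stopifnot(age > 0, mb_pub >= 0, mb_ps >= 0, mb_priv >= 0)
  m <- mb_pub + mb_ps + mb_priv
  if (m < 1) stop("cluster has no mutations to time", call. = FALSE)
  p <- mb_pub / m
  half <- 1.96 * sqrt(p * (1 - p) / m)
  out <- tibble(
    event = "expansion",
    estimate = age * p,
    ci_low = max(0, age * (p - half)),
    ci_high = min(age, age * (p + half)),
    m = m, p = p, age = age
  )
  structure(out, class = c("timing_estimate", class(out)))
}

#' Pre/post CN-LOH assignment weights for public SNVs
#'
#' For each public SNV in the affected region, computes the joint
#' probability across glands of the observed mutant read counts given that
#' the SNV predates the event (per-read success probability `rho_i`) or
#' postdates it (`rho_i / 2`), and normalizes the two into weights. All
#' products are accumulated in log space; the binomial coefficient cancels
#' in the ratio and is omitted.
#'
#' @param reads Tibble with `site`, `gland_id`, `depth`, `alt_reads` for the
#'   public SNVs in the CN-LOH region across the cluster's glands.
#' @param rho Named numeric vector of per-gland cellular fractions in
#'   (0, 1].
#' @return Tibble: `site`, `w_pre`, `w_post` (`w_pre + w_post = 1`).
#' @export
snv_cnloh_weights <- function(reads, rho) {
  reads <- as_tibble(reads)
  stopifnot(all(reads$gland_id %in% names(rho)))
  r <- rho[reads$gland_id]
  if (any(r <= 0) || any(r > 1)) stop("rho must lie in (0, 1]", call. = FALSE)
  dmut <- reads$alt_reads
  dref <- reads$depth - reads$alt_reads
  stopifnot(all(dref >= 0), all(dmut >= 0))
  lterm <- function(p) {
    # dmut * log(p) + dref * log(1 - p), with 0 * log(0) = 0
    lp <- ifelse(dmut > 0, dmut * log(p), 0)
    lq <- ifelse(dref > 0, dref * log1p(-p), 0)
    lp + lq
  }
  per_site <- tibble(site = reads$site,
                     pre = lterm(r), post = lterm(r / 2))
  agg <- dplyr::summarise(dplyr::group_by(per_site, .data$site),
                          lpre = sum(.data$pre), lpost = sum(.data$post),
                          .groups = "drop")
  mx <- pmax(agg$lpre, agg$lpost)
  wpre <- exp(agg$lpre - mx)
  wpost <- exp(agg$lpost - mx)
  tot <- wpre + wpost
  tibble(site = agg$site, w_pre = wpre / tot, w_post = wpost / tot)
}

#' Time a CN-LOH event by resampling SNV assignments
#'
#' Propagates the uncertainty of assigning each public regional SNV to
#' before or after the event: in each of `n_iter` iterations every SNV is
#' assigned pre/post by a Bernoulli draw on its `w_pre`, the pre count is
#' doubled (`MB_pre = 2 * n_pre`, `MB_post = n_post`), and
#' `T = T_CE * MB_pre / (MB_pre + MB_post)` is computed together with its
#' 95% limits from the product-variance identity
#' `V(XY) = V(X) V(Y) + E(X)^2 V(Y) + E(Y)^2 V(X)` (X = public proportion
#' behind `T_CE`, Y = pre proportion, both with binomial variances
#' `p(1-p)/m`). The estimate and CI are the means over iterations.
#'
#' @param t_ce A `timing_estimate` from [time_expansion()] (uses `estimate`,
#'   `age`, `p`, `m`).
#' @param weights Tibble from [snv_cnloh_weights()].
#' @param n_iter Number of resampling iterations (default 10000).
#' @param seed Optional integer seed; identical inputs + seed give identical
#'   results.
#' @return A `timing_estimate` row with `event = "cnloh"`.
#' @export
time_cnloh <- function(t_ce, weights, n_iter = 10000, seed = NULL) {
  stopifnot(nrow(t_ce) == 1, nrow(weights) >= 1)
  if (any(weights$w_pre + weights$w_post == 0)) {
    stop("degenerate all-zero weights", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  l <- nrow(weights)
  X <- t_ce$p
  VX <- t_ce$p * (1 - t_ce$p) / t_ce$m
  draws <- matrix(runif(n_iter * l), n_iter, l)
  pre <- sweep(draws, 2, weights$w_pre, `<`)
  n_pre <- rowSums(pre)
  mb_pre <- 2 * n_pre
  mb_post <- l - n_pre
  m2 <- mb_pre + mb_post
  Y <- mb_pre / m2
  VY <- Y * (1 - Y) / m2
  T_iter <- t_ce$age * X * Y
  VXY <- variance_product(X, VX, Y, VY)
  half <- 1.96 * t_ce$age * sqrt(VXY)
  est <- mean(T_iter)
  out <- tibble(
    event = "cnloh",
    estimate = est,
    ci_low = max(0, mean(T_iter - half)),
    ci_high = min(t_ce$estimate, mean(T_iter + half)),
    m = l, p = mean(Y), age = t_ce$age
  )
  structure(out, class = c("timing_estimate", class(out)))
}

#' Variance of a product of independent variables
#'
#' `V(XY) = V(X) V(Y) + E(X)^2 V(Y) + E(Y)^2 V(X)`.
#'
#' @param ex,vx Mean and variance of X.
#' @param ey,vy Mean and variance of Y.
#' @return The product variance (vectorized).
#' @export
#' @examples
#' variance_product(2, 1, 3, 4)  # 29
variance_product <- function(ex, vx, ey, vy) {
  if (any(vx < 0) || any(vy < 0)) stop("variances must be >= 0", call. = FALSE)
  vx * vy + ex^2 * vy + ey^2 * vx
}
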