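# Fixture builders and independent oracles shared across the suite.

# A mutation record tibble with sensible defaults; any field overridable.
make_records <- function(n = 1, ...) {
  defaults <- list(
    gland_id = "g1", subject_id = "s1", chrom = "chr1",
    pos = seq_len(n) * 100L, ref = "C", alt = "T",
    depth = 40L, alt_reads = 20L, blood_depth = 40L, blood_alt_reads = 0L,
    context = "ACA", consequence = "noncoding", gene = "", pop_freq = 0
  )
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(lapply(args, rep_len, n))
}

make_glands <- function(gland_ids = "g1", subject_id = "s1",
                        callable_bases = 1e6, coverage20_fraction = 0.95) {
  tibble::tibble(
    gland_id = gland_ids, subject_id = subject_id,
    grid_id = as.character(seq_along(gland_ids)),
    grid_row = 1L, grid_col = seq_along(gland_ids),
    callable_bases = callable_bases,
    coverage20_fraction = coverage20_fraction
  )
}

# Exact two-sided binomial p by tail enumeration: sum of P(X = k) over all k
# whose probability does not exceed that of the observed count.
binom_twosided_oracle <- function(alt, depth, p0 = 0.5) {
  probs <- stats::dbinom(0:depth, depth, p0)
  sum(probs[probs <= probs[alt + 1] * (1 + 1e-7)])
}

# Exhaustive small-parsimony oracle: minimum number of changes over all
# labelings of the internal nodes, summed across binary characters.
fitch_oracle <- function(tree, profiles) {
  edges <- tree$edge
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(as.vector(edges)))
  internal <- internal[internal > n_tip]
  tip_idx <- match(tree$tip.label, rownames(profiles))
  total <- 0L
  for (ch in seq_len(ncol(profiles))) {
    tip_states <- profiles[tip_idx, ch]
    best <- Inf
    for (mask in 0:(2^length(internal) - 1)) {
      lab <- integer(max(internal))
      lab[seq_len(n_tip)] <- tip_states
      lab[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1), 1L)
      changes <- sum(lab[edges[, 1]] != lab[edges[, 2]])
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# Brute-force two-parameter Poisson MLE for (scale, omega) by iterative grid
# refinement; independent of the closed-form ratio estimator.
grid_mle_omega <- function(n_obs, e_obs, n_syn, e_syn) {
  ll <- function(s, w) {
    lam1 <- s * w * e_obs
    lam2 <- s * e_syn
    (if (n_obs > 0) n_obs * log(lam1) else 0) - lam1 +
      (if (n_syn > 0) n_syn * log(lam2) else 0) - lam2
  }
  s_rng <- c(1e-3, 50)
  w_rng <- c(1e-3, 200)
  for (step in 1:12) {
    s_grid <- exp(seq(log(s_rng[1]), log(s_rng[2]), length.out = 41))
    w_grid <- exp(seq(log(w_rng[1]), log(w_rng[2]), length.out = 41))
    vals <- outer(s_grid, w_grid, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    s_best <- s_grid[best[1]]; w_best <- w_grid[best[2]]
    # shrink each range to +/- two grid cells around the maximum
    s_step <- (s_rng[2] / s_rng[1])^(1 / 40)
    w_step <- (w_rng[2] / w_rng[1])^(1 / 40)
    s_rng <- c(s_best / s_step^2, s_best * s_step^2)
    w_rng <- c(w_best / w_step^2, w_best * w_step^2)
  }
  list(scale = s_best, omega = w_best)
}

# Shared small gene-model set and context rates for dN/dS tests (built once
# per test run; deterministic).
dnds_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      models <- simulate_gene_models(20, cds_length = 1200, seed = 101)
      catalog <- simulate_noncoding_catalog(c(0.3, 0.5, 0.2),
                                            n_snvs = 5e5, seed = 102)
      rates <- estimate_context_rates(catalog, NULL, models,
                                      observed_total = 900)
      cache <<- list(models = models, catalog = catalog, rates = rates)
    }
    cache
  }
})
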