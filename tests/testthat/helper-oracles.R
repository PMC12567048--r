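# Independent brute-force oracles used across the suite. Each is written
# from the definition, not from the package implementation.

# Extrema of the running sum by explicit walk over the ranked list. Returns
# the positive and negative deviations separately so the caller can check the
# signed extremum without depending on a tie-break rule: when the two
# magnitudes (near-)tie, either sign is an admissible "maximum deviation".
brute_force_es_extrema <- function(genes, scores, gene_set, weight_p) {
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  w <- abs(scores)^weight_p
  denom_hit <- sum(w[hit])
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) w[i] / denom_hit else -1 / (n - nh)
    running[i] <- acc
  }
  list(hi = max(running), lo = min(running, 0))
}

# Signed maximum deviation with positive preference on magnitude ties.
brute_force_es <- function(genes, scores, gene_set, weight_p) {
  ex <- brute_force_es_extrema(genes, scores, gene_set, weight_p)
  if (ex$hi >= -ex$lo) ex$hi else ex$lo
}

# TRUE when an observed ES agrees with the brute-force extrema: the magnitude
# must match one extremum exactly, and the sign must match unless the two
# extrema tie in magnitude to within tol (where the sign is definitionally
# ambiguous under floating-point accumulation).
es_agrees <- function(got, ex, tol = 1e-9) {
  if (ex$hi - (-ex$lo) > tol) return(isTRUE(all.equal(got, ex$hi, tolerance = 1e-12)))
  if ((-ex$lo) - ex$hi > tol) return(isTRUE(all.equal(got, ex$lo, tolerance = 1e-12)))
  isTRUE(all.equal(got, ex$hi, tolerance = 1e-9)) ||
    isTRUE(all.equal(got, ex$lo, tolerance = 1e-9))
}

# All-pairs closed-interval overlap + threshold deletion oracle.
brute_force_deletion <- function(segments, locus, threshold) {
  deleted <- FALSE
  support <- NA_real_
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    if (seg$chromosome == locus$chromosome &&
        seg$start <= locus$end && seg$end >= locus$start &&
        seg$segment_mean <= threshold) {
      deleted <- TRUE
      if (is.na(support) || seg$segment_mean < support) support <- seg$segment_mean
    }
  }
  list(deleted = deleted, support = support)
}

# Benjamini-Hochberg step-up from the definition.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# One-sided (enrichment) Fisher p as an explicit hypergeometric tail sum:
# P(X >= a) where X ~ Hypergeom(n_set in universe, draws = n_hit).
hypergeom_tail <- function(a, n_set, n_universe, n_hit) {
  ks <- a:min(n_set, n_hit)
  sum(dhyper(ks, n_set, n_universe - n_set, n_hit))
}

# Two-group log-rank chi-square tabulated by hand over event times.
hand_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Exact central 99% binomial interval for an observed count.
binom_interval_99 <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}

# Tiny two-cohort synthetic pair used by several pipeline-level tests.
make_cohort_pair <- function(n_a = 60, n_b = 40, seed = 11, ...) {
  list(
    a = generate_cohort(cohort_spec(n_a, "TCGA", seed = seed, ...)),
    b = generate_cohort(cohort_spec(n_b, "SL", n_background_genes = 110,
                                    seed = seed + 1, ...))
  )
}
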