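# shared fixtures: small scenarios built in code

# default scenario with few replicates, for fast pipeline runs
small_scenario <- function(n_replicates = 4, seed = 1L) {
  default_scenario(n_replicates = n_replicates, rng_seed = seed)
}

# deterministic scenario: all flux SDs zero, gentle uniform means, so the
# generator -> flux pipeline round trip is exact and warning-free
flat_scenario <- function(light_mean = 5, dark_mean = -1, n_replicates = 5) {
  sc <- default_scenario(n_replicates = n_replicates)
  sc$flux_params$mean <- ifelse(sc$flux_params$phase == "light", light_mean, dark_mean)
  sc$flux_params$sd <- 0
  sc$blank_drift$sd <- 0
  sc$conversion_factors$sd <- 0   # effective and nominal s coincide
  sc
}

# independent antichain enumerator: counts families of pairwise-incomparable
# nonempty subsets of a k-set (equivalently, the hierarchical model count).
# Brute force over all subset families; different route than the package's
# downward-closure check.
count_antichains <- function(k) {
  n_terms <- 2^k - 1
  subsets <- 1:n_terms
  comparable <- outer(subsets, subsets, function(a, b) {
    bitwAnd(a, b) == a | bitwAnd(a, b) == b
  })
  diag(comparable) <- FALSE
  total <- 0L
  for (fam in 0:(2^n_terms - 1)) {
    members <- which(bitwAnd(fam, bitwShiftL(1L, subsets - 1L)) != 0L)
    if (length(members) <= 1L || !any(comparable[members, members])) {
      total <- total + 1L
    }
  }
  total
}

# brute-force shortest-interval scan (O(n^2) over sorted samples)
hpd_bruteforce <- function(samples, level = 0.95) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(level * n)
  best <- c(s[1], s[m])
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1] - 1e-15) {
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}
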