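# Shared small fixtures, built in code.

# Small cohort bundle reused across tests (site effects on, default SNR).
small_bundle <- function(seed = 42, n_regions = 20, n_hc = 90,
                         n_patients = 80, ...) {
  generate_cohort(n_hc = n_hc, n_patients = n_patients,
                  n_regions = n_regions, n_sites = 3, k_pos = 2, k_neg = 2,
                  n_subtypes = 4, noise_sd = 0.5, seed = seed, ...)
}

# Deterministic non-negative low-rank matrix W0 %*% F0 (+ optional noise).
planted_nonneg <- function(n = 60, r = 30, k = 2, noise = 0, seed = 1) {
  set.seed(seed)
  W0 <- matrix(rgamma(n * k, shape = 2, rate = 1), n, k)
  F0 <- matrix(rgamma(k * r, shape = 2, rate = 2), k, r)
  X <- W0 %*% F0
  if (noise > 0) X <- pmax(X + matrix(rnorm(n * r, 0, noise), n, r), 0)
  list(X = X, W0 = W0, F0 = F0)
}

# Brute-force best bijection between factor sets by total correlation.
brute_force_match <- function(f_a, f_b) {
  k <- nrow(f_a)
  perms <- combinat_perms(k)
  cmat <- cor(t(f_a), t(f_b))
  scores <- vapply(perms, function(p) sum(cmat[cbind(seq_len(k), p)]),
                   numeric(1))
  perms[[which.max(scores)]]
}

combinat_perms <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- combinat_perms(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Connected components of a non-negative adjacency matrix (simple BFS).
n_components <- function(w) {
  n <- nrow(w)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    comps <- comps + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(w[v, ] > 0 & !seen))
    }
  }
  comps
}
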