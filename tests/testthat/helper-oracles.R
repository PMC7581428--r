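# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check.

# exhaustive hypergeometric upper tail by enumeration (N small)
hyper_upper_oracle <- function(k, K, n, N) {
  js <- max(0, K + n - N):min(K, n)
  probs <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(probs[js >= k])
}

# exact two-sample permutation p for the mean difference (all splits)
perm_ttest_oracle <- function(a, b) {
  pool <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pool), n_a)
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(idx, 2, function(i) {
    abs(mean(pool[i]) - mean(pool[-i]))
  })
  mean(diffs >= obs - 1e-12)
}

# brute-force expansion index: expectation of positive CAG change under the
# height-normalized distribution over {modal + expansion peaks}
expansion_oracle <- function(repeat_units, height) {
  modal <- repeat_units[height == max(height)]
  modal <- min(modal)
  keep <- repeat_units >= modal
  ru <- repeat_units[keep]; h <- height[keep]
  w <- h / sum(h)
  sum(w * (ru - modal))
}

# exhaustive relative-impact permutation p over all subsets of the universe
perm_exhaustive_oracle <- function(reduced, set_idx) {
  k <- length(set_idx)
  obs <- sum(reduced[set_idx])
  subsets <- utils::combn(length(reduced), k)
  stats <- apply(subsets, 2, function(i) sum(reduced[i]))
  mean(stats >= obs)
}

# random peak trace generator for property tests
random_trace <- function(id, n_peaks = sample(1:12, 1)) {
  lens <- sort(sample(90:130, n_peaks))
  h <- stats::runif(n_peaks, 0.1, 100)
  peak_trace(id, lens, h)
}

# small count world shared by expression tests
make_sim <- function(seed, n_genes = 500, dispersion = 0.1, ...) {
  simulate_count_matrix(
    n_genes = n_genes,
    group_sizes = c(WT_WT = 8, Q111_WT = 8, WT_KO = 8, Q111_KO = 8),
    dispersion = dispersion, seed = seed, ...)
}
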