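# Independent brute-force oracles the fast implementations are checked
# against.

# P(at least one event) over independent Bernoulli(p_i), by enumerating all
# 2^n joint outcomes and summing the probability of those with >= 1 event.
brute_force_at_least_one <- function(p) {
  n <- length(p)
  if (n == 0L) return(0)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    fired <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    if (!any(fired)) next
    total <- total + prod(ifelse(fired, p, 1 - p))
  }
  total
}

# Mann-Whitney AUC by explicit all-pairs counting, ties worth 1/2.
brute_force_auc <- function(labels, probabilities) {
  pos <- probabilities[labels == 1]
  neg <- probabilities[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
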