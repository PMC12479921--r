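# Independent brute-force oracles used to check the package's statistics.

# Exact two-sided rank-sum p by enumeration of all rank assignments:
# probability, over all choose(n1+n2, n1) splits, of a group-1 rank sum at
# least as far from its null mean as observed.
oracle_rank_sum_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  r <- rank(vals)
  mu <- n1 * (n1 + length(y) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  splits <- utils::combn(length(vals), n1)
  sums <- apply(splits, 2, function(idx) sum(r[idx]))
  mean(abs(sums - mu) >= obs - 1e-12)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  mu <- n * (n + 1) / 4
  obs <- abs(sum(r[d > 0]) - mu)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- signs %*% r
  mean(abs(sums - mu) >= obs - 1e-12)
}

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    adj[o[k]] <- min(1, running)
  }
  adj
}

# Tiny builder for repertoire samples from a named count vector.
make_repertoire <- function(counts, sample_id = "s", donor_id = "d",
                            timepoint = "ex_vivo", input_cell_count = NULL) {
  repertoire_sample(sample_id, donor_id, timepoint,
                    data.frame(cdr3b_aa = names(counts),
                               count = as.numeric(counts),
                               stringsAsFactors = FALSE),
                    input_cell_count = input_cell_count)
}

# Frequencies (summing to 1) from a named weight vector.
freqs <- function(w) w / sum(w)

# Unique valid amino-acid identifiers for bulk fixtures.
random_names <- function(n) {
  stopifnot(n <= 26^4)
  combos <- expand.grid(L1 = LETTERS, L2 = LETTERS, L3 = LETTERS,
                        L4 = LETTERS, stringsAsFactors = FALSE)
  keep <- c("A","C","D","E","F","G","H","I","K","L")
  combos <- combos[combos$L1 %in% keep & combos$L2 %in% keep &
                   combos$L3 %in% keep & combos$L4 %in% keep, ]
  paste0("CASS", combos$L1, combos$L2, combos$L3, combos$L4)[seq_len(n)]
}
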