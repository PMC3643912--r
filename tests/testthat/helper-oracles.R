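# Independent oracles used across the suite. These never call package code.

# Audic-Claverie tails via the negative-binomial identity:
# sum_{k<=y} P(k|x) = pnbinom(y, size = x+1, prob = n1/(n1+n2))
nb_oracle_pvalue <- function(x, y, n1, n2) {
  pr <- n1 / (n1 + n2)
  f <- exp(stats::pnbinom(y, size = x + 1, prob = pr, log.p = TRUE))
  s <- if (y == 0) 1 else
    exp(stats::pnbinom(y - 1, size = x + 1, prob = pr, log.p = TRUE,
                       lower.tail = FALSE))
  min(1, 2 * min(f, s))
}

# direct term-by-term summation of the conditional distribution using the
# recurrence t(k+1) = t(k) * (n2/n1) * (x+k+1) / ((1+n2/n1)*(k+1));
# valid in double precision for the moderate counts used in tests
brute_ac_tails <- function(x, n1, n2, k_max) {
  r <- n2 / n1
  t <- numeric(k_max + 1)
  t[1] <- (1 + r)^(-(x + 1))
  for (k in seq_len(k_max))
    t[k + 1] <- t[k] * r * (x + k) / ((1 + r) * k)
  list(lower = cumsum(t), upper = rev(cumsum(rev(t))), pmf = t)
}

brute_ac_pvalue <- function(x, y, n1, n2, k_max = NULL) {
  if (is.null(k_max)) k_max <- max(2000, 4 * ceiling((x + 1) * n2 / n1) + y)
  tails <- brute_ac_tails(x, n1, n2, k_max)
  min(1, 2 * min(tails$lower[y + 1], tails$upper[y + 1]))
}

# quadratic-time transcription of the Benjamini-Hochberg step-up definition:
# sort ascending, q_(i) = min_{j >= i} p_(j) * m / j capped at 1, map back
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q <- numeric(m)
  q[ord] <- qs
  q
}

# small planted dataset shared by several files
tiny_dataset <- function(n_genes = 400, seed = 11, ...) {
  generate_dataset(simulation_config(n_genes = n_genes, seed = seed, ...))
}
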