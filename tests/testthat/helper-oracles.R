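# Independent oracles used across test files.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
# U is the count of (x, y) pairs with x > y; the two-sided p doubles the
# smaller tail of the enumerated null distribution, capped at 1.
enum_rank_sum_p <- function(x, y) {
  pool <- c(x, y)
  m <- length(x)
  u_of <- function(ix) {
    xs <- pool[ix]; ys <- pool[-ix]
    sum(outer(xs, ys, ">"))
  }
  us <- combn(length(pool), m, u_of)
  u_obs <- sum(outer(x, y, ">"))
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins; tables as or less probable than the observed
# one contribute (with the conventional 1e-7 relative tolerance).
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0, r1 + c1 - n); a_max <- min(r1, c1)
  prob <- function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  p_obs <- prob(tab[1, 1])
  ps <- vapply(a_min:a_max, prob, numeric(1))
  min(1, sum(ps[ps <= p_obs * (1 + 1e-7)]))
}

# Step-up Benjamini-Hochberg by definition.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
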