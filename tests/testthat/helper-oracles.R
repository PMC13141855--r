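# Independent statistical oracles, implemented from first principles so they
# share no code with the package paths they check.

# two-sided Fisher exact p from the hypergeometric probability mass
# definition (choose(), not dhyper): sum of all table probabilities not
# exceeding the observed one, margins fixed
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  xs <- max(0, k - n):min(k, m)
  pmf <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- pmf[xs == a]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# exhaustive-permutation two-sided Mann-Whitney p (tie-free data):
# enumerate every assignment of the pooled ranks to group 1
perm_oracle <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), n1)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mn <- n1 * length(b)
  p <- if (u_obs > mn / 2) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}
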