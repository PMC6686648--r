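# Independent reference implementations used to cross-check the package.

# Exhaustive two-sided Fisher p by enumerating all tables with the observed
# margins and summing hypergeometric point probabilities <= the observed one.
fisher_enumerate <- function(t) {
  a <- t[1, 1]; r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
  n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  pt <- function(x) dhyper(x, r1, r2, c1)
  p_obs <- pt(a)
  sum(vapply(lo:hi, pt, numeric(1))[vapply(lo:hi, pt, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# Naive nested-loop k-mer recount (observed orientation).
recount_kmers_naive <- function(reads, k) {
  out <- character(0)
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in 1:(nchar(r) - k + 1)) {
      km <- substr(r, i, i + k - 1)
      if (!grepl("N", km, fixed = TRUE)) out <- c(out, km)
    }
  }
  table(out)
}

# Sort-based Benjamini-Hochberg, written independently of stats::p.adjust.
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Median-of-ratios size factors as a direct one-liner.
size_factors_by_hand <- function(m) {
  geo <- exp(rowMeans(log(m)))
  f <- apply(m, 2, function(col) median(col / geo))
  f / exp(mean(log(f)))
}

# Direct NB log-likelihood maximization over coefficients (numerical
# optimizer oracle for the IRLS fit).
nb_loglik_optim <- function(y, X, alpha, sf) {
  nll <- function(beta) {
    mu <- exp(drop(X %*% beta) + log(sf))
    -sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  -fit$value
}

# A random micro read set plus (k, c) for assembler/oracle comparisons.
random_micro_readset <- function() {
  n_reads <- sample(2:6, 1)
  reads <- vapply(seq_len(n_reads), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(15:50, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  k <- sample(c(5L, 7L, 9L), 1)
  c <- sample(1:2, 1)
  list(reads = reads, k = k, c = c)
}
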