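# Independent brute-force oracle for the two-sided Fisher exact test:
# enumerate every 2x2 table with the observed margins, compute each table's
# hypergeometric probability from factorials, and sum the probabilities of
# all tables no more likely than the observed one.
fisher_p_enumerated <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  log_prob <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  probs <- vapply(lo:hi, function(x) exp(log_prob(x)), double(1))
  p_obs <- exp(log_prob(a))
  # tolerance mirrors the conventional relative-error guard for ties
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# every (a, b, c, d) composition with total n, as a matrix of rows
all_tables_with_total <- function(n) {
  grid <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
  grid <- grid[grid$a + grid$b + grid$c <= n, ]
  grid$d <- n - grid$a - grid$b - grid$c
  as.matrix(grid)
}
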