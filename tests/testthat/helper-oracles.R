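# independent oracles used by several test files

# brute-force posterior: enumerate every read-assignment sequence of length n
# under the per-read weights of each genotype, accumulate sequence weights by
# their parent-1 read count, then apply priors
enumerate_posterior <- function(n1, n, E1, E2,
                                priors = c(0.25, 0.25, 0.5)) {
  stopifnot(n >= 1, n <= 16)
  seqs <- as.matrix(expand.grid(rep(list(0:1), n)))  # 1 = parent-1 read
  k <- rowSums(seqs)
  weights <- list(c(E2, 1 - E1),                      # P1P1: (p2read, p1read)
                  c(1 - E2, E1),                      # P2P2
                  c((1 + E1 - E2) / 2, (1 - E1 + E2) / 2))  # P1P2
  lik <- vapply(weights, function(w) {
    per_seq <- apply(seqs, 1, function(s) prod(w[s + 1]))
    sum(per_seq[k == n1])
  }, numeric(1))
  post <- lik * priors
  post / sum(post)
}

# exhaustive best order over <= 8 bins minimizing the sum of adjacent r
exhaustive_order <- function(rmat) {
  k <- nrow(rmat)
  stopifnot(k <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(k))) {
    cost <- sum(rmat[cbind(p[-k], p[-1])])
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- p }
  }
  list(order = best, cost = best_cost)
}

# grid-search ML recombination fraction for two F2 loci
grid_rf <- function(g1, g2, grid = seq(0, 0.5, by = 1e-4)) {
  ok <- !is.na(g1) & !is.na(g2)
  a <- match(g1[ok], c("A", "H", "B")) - 1L
  b <- match(g2[ok], c("A", "H", "B")) - 1L
  xlog <- function(k, p) if (k == 0) 0 else k * log(p)
  ll <- vapply(grid, function(r) {
    fpar <- ((1 - r) / 2)^2; frec <- (r / 2)^2
    fmix <- r * (1 - r) / 2; fdh <- ((1 - r)^2 + r^2) / 2
    xlog(sum(a == 0 & b == 0) + sum(a == 2 & b == 2), fpar) +
      xlog(sum(a == 0 & b == 2) + sum(a == 2 & b == 0), frec) +
      xlog(sum(abs(a - b) == 1), fmix) +
      xlog(sum(a == 1 & b == 1), fdh)
  }, numeric(1))
  grid[which.max(ll)]
}
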