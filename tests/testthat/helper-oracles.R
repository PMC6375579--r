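# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# O(n^2) Kendall tau-b by direct concordant/discordant pair counting.
tau_brute <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# Monte-Carlo permutation rank-sum p-value (two-sided, distance from the
# null expectation), independent of group_contrast().
perm_ranksum_p <- function(x, y, B = 1e5) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  Wb <- vapply(seq_len(B), function(i) sum(r[sample.int(n, n1)]), numeric(1))
  mean(abs(Wb - mu) >= abs(W - mu) - 1e-9)
}

# Exact hypergeometric upper tail by direct combinatorial summation.
hyper_tail_exact <- function(k, K, N, h) {
  kk <- k:min(K, h)
  sum(choose(K, kk) * choose(N - K, h - kk)) / choose(N, h)
}

# Random tree fixture independent of the package generator.
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = sprintf("t%02d", sample(n)))
  tr$edge.length <- round(tr$edge.length, 4)
  tr
}

# Brute-force minimal Fitch changes for one column by enumerating all
# internal-node state assignments of a (small) rooted binary tree.
brute_column_score <- function(tree, states) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  internal <- nt + seq_len(nn)
  best <- Inf
  grid <- expand.grid(rep(list(c(0L, 1L)), nn))
  for (g in seq_len(nrow(grid))) {
    assign_full <- c(states, as.integer(grid[g, ]))
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- assign_full[tree$edge[e, 1]]
      c_ <- assign_full[tree$edge[e, 2]]
      if (!is.na(c_) && !is.na(p) && p != c_) cost <- cost + 1
    }
    best <- min(best, cost)
  }
  best
}

# Shared small simulated dataset reused by several tests (built once).
shared_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- sim_config(n_species = 12, n_orthogroups = 30,
                        module_spec = list(mod1 = sprintf("g%03d", 1:4)),
                        sigma_shared = 0.5, sigma_noise = 0.1,
                        dropout_prob = 0.1, seed = 101)
      val <<- simulate_orthogroups(cfg)
    }
    val
  }
})
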