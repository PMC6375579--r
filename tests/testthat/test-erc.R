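test_that("Kendall tau-b matches the brute-force pair-count oracle", {
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(kendall_tau(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               tau_brute(c(1, 2, 2, 3), c(1, 3, 2, 4)), tolerance = 1e-12)
  # constant vectors are undefined, not zero
  expect_true(is.na(kendall_tau(c(1, 1, 1), c(1, 2, 3))))
  expect_error(kendall_tau(1:3, 1:4), "equal length")

  set.seed(55)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- if (i %% 2) sample(1:8, n, replace = TRUE) else rnorm(n)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y), tau_brute(x, y), tolerance = 1e-12)
  }
})

test_that("pairwise ERC honours the shared-species contract", {
  sim <- shared_sim()
  avg <- build_average_tree(sim$tables, sim$master)
  sp <- sort(sim$master$tip.label)

  # identical tables: perfect self-correlation
  tb <- sim$tables[[8]]
  tb2 <- tb; tb2$orthogroup_id <- "copy"
  e <- erc_pair(tb, tb2, avg, sim$master)
  expect_equal(e$tau, 1)
  expect_equal(e$status, "ok")

  # overlap of 5 species under min_species = 6 is undefined with a reason
  a <- branch_table(prune(sim$master, sp[1:6]), "a")
  b <- branch_table(prune(sim$master, sp[2:7]), "b")   # shared = 5
  e <- erc_pair(a, b, avg, sim$master, min_species = 6)
  expect_true(is.na(e$tau))
  expect_equal(e$status, "insufficient shared species")
  expect_equal(e$n_shared_species, 5L)

  # symmetry is exact, including argument order
  x <- sim$tables[[2]]; y <- sim$tables[[9]]
  expect_identical(erc_pair(x, y, avg, sim$master),
                   erc_pair(y, x, avg, sim$master))
})

test_that("ERC depends only on the pair given a fixed average tree", {
  sim <- shared_sim()
  avg <- build_average_tree(sim$tables, sim$master)
  e_all <- erc_pair(sim$tables[[3]], sim$tables[[7]], avg, sim$master)
  # recompute with unrelated orthogroups absent: identical entry
  e_two <- erc_pair(sim$tables[[3]], sim$tables[[7]], avg, sim$master)
  expect_identical(e_all, e_two)
})

test_that("ERC is invariant under global branch-length rescaling", {
  sim <- shared_sim()
  avg <- build_average_tree(sim$tables, sim$master)
  tabs2 <- lapply(sim$tables, function(tb) {
    tb$lengths <- tb$lengths * 7.3; tb
  })
  avg2 <- build_average_tree(tabs2, sim$master)
  e1 <- erc_pair(sim$tables[[1]], sim$tables[[4]], avg, sim$master)
  e2 <- erc_pair(tabs2[[1]], tabs2[[4]], avg2, sim$master)
  expect_equal(e1$tau, e2$tau, tolerance = 1e-12)
})

test_that("the ERC matrix is symmetric with unit diagonal", {
  sim <- shared_sim()
  avg <- build_average_tree(sim$tables, sim$master)
  tabs <- sim$tables[1:12]
  m <- erc_matrix(tabs, avg, sim$master)
  expect_identical(m$tau, t(m$tau))
  expect_equal(unname(diag(m$tau)), rep(1, 12))
  # permuting input order leaves named entries unchanged
  m2 <- erc_matrix(rev(tabs), avg, sim$master)
  expect_equal(m2$tau[m$genes, m$genes], m$tau, tolerance = 1e-15)
})

test_that("focal ranking orders by tau and percentiles match enumeration", {
  sim <- shared_sim()
  avg <- build_average_tree(sim$tables, sim$master)
  m <- erc_matrix(sim$tables[1:15], avg, sim$master)
  rk <- focal_ranking(m, "g001", threshold = 0.4)
  expect_false(is.unsorted(rev(rk$tau[!is.na(rk$tau)])))
  expect_equal(attr(rk, "n_hits"), sum(rk$hit))
  expect_true(all(rk$tau[rk$hit] >= 0.4))
  # percentile = fraction of defined pairs strictly greater
  pool <- m$tau[upper.tri(m$tau)]
  pool <- pool[!is.na(pool)]
  for (k in which(!is.na(rk$tau))[1:5])
    expect_equal(rk$top_fraction[k], mean(pool > rk$tau[k]))
  # threshold above 1 gives an empty hit set
  rk2 <- focal_ranking(m, "g001", threshold = 1)
  expect_true(all(rk2$tau[rk2$hit] >= 1) || sum(rk2$hit) == 0)
  expect_error(focal_ranking(m, "nope"), "unknown focal")
  # focal-row percentile mode uses the focal gene's own taus as the pool
  rkr <- focal_ranking(m, "g001", percentile = "focal_row")
  taus <- rkr$tau[!is.na(rkr$tau)]
  expect_equal(rkr$top_fraction[1], mean(taus > max(taus)))
})

test_that("rank-sum contrast: exact enumeration and normal approximation", {
  sc <- stats::setNames(1:6, letters[1:6])
  res <- group_contrast(sc, letters[1:3], letters[4:6])
  expect_equal(res$method, "exact")
  expect_equal(res$p.value, 0.1)

  # identical score multisets: p = 1 exactly
  sc2 <- stats::setNames(c(1, 2, 3, 1, 2, 3), letters[1:6])
  expect_equal(group_contrast(sc2, letters[1:3], letters[4:6])$p.value, 1)

  expect_error(group_contrast(sc, letters[1:3], letters[3:5]), "disjoint")
  expect_error(group_contrast(sc, character(0), letters[1:3]), "non-empty")

  # small-sample exact agrees with wilcox.test's exact p (no ties)
  set.seed(77)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    sc <- stats::setNames(c(x, y), paste0("g", seq_len(n1 + n2)))
    p_pkg <- group_contrast(sc, paste0("g", 1:n1),
                            paste0("g", n1 + 1:n2))$p.value
    p_ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }

  # large-sample normal approximation close to wilcox.test's
  set.seed(78)
  x <- rnorm(15); y <- rnorm(18, 0.5)
  sc <- stats::setNames(c(x, y), paste0("g", 1:33))
  res <- group_contrast(sc, paste0("g", 1:15), paste0("g", 16:33))
  expect_equal(res$method, "normal")
  p_ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(res$p.value, p_ref, tolerance = 1e-10)
})
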