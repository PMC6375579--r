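make_table <- function(master, keep, scale = 1, id = "g") {
  tb <- branch_table(prune(master, keep), id)
  tb$lengths <- tb$lengths * scale
  tb
}

test_that("orthogroup filter keeps >= min_species and preserves order", {
  master <- simulate_species_tree(22, seed = 4)
  sizes <- c(5, 6, 22)
  tabs <- lapply(seq_along(sizes), function(i)
    make_table(master, sort(master$tip.label)[seq_len(sizes[i])],
               id = paste0("g", i)))
  kept <- filter_orthogroups(tabs, 6)
  expect_equal(vapply(kept, `[[`, character(1), "orthogroup_id"),
               c("g2", "g3"))
  # min_species = 2 is the identity
  expect_equal(length(filter_orthogroups(tabs, 2)), 3L)
  expect_error(filter_orthogroups(tabs, 1), "min_species")

  # recount against a brute-force filter on random sizes
  set.seed(9)
  sizes <- sample(2:22, 200, replace = TRUE)
  tabs <- lapply(seq_along(sizes), function(i)
    structure(list(orthogroup_id = paste0("r", i),
                   species = sprintf("s%02d", seq_len(sizes[i])),
                   lengths = numeric(0)), class = "branch_table"))
  for (ms in c(2, 6, 15)) {
    kept <- filter_orthogroups(tabs, ms)
    expect_equal(length(kept), sum(sizes >= ms))
  }
})

test_that("average tree equals per-branch means over one-to-one contributors", {
  master <- simulate_species_tree(8, seed = 11)
  all_sp <- sort(master$tip.label)

  # all orthogroups on the full species set: plain arithmetic mean
  tabs <- lapply(1:4, function(i) make_table(master, all_sp, scale = i,
                                             id = paste0("g", i)))
  avg <- build_average_tree(tabs, master)
  ref <- branch_table(master, "m")$lengths
  expect_equal(avg$mean[names(ref)], ref * mean(1:4), tolerance = 1e-12)
  expect_true(all(avg$count == 4))

  # single orthogroup: average equals its table
  avg1 <- build_average_tree(tabs[1], master)
  expect_equal(avg1$mean[names(ref)], ref, tolerance = 1e-12)

  # mixed subsets: brute-force per-edge average over path-length-1 edges
  set.seed(12)
  keeps <- lapply(1:6, function(i) sort(sample(all_sp, sample(4:8, 1))))
  tabs <- lapply(seq_along(keeps), function(i)
    make_table(master, keeps[[i]], scale = runif(1, 0.5, 2),
               id = paste0("g", i)))
  avg <- build_average_tree(tabs, master)
  for (mid in avg$master_ids) {
    vals <- c()
    for (i in seq_along(tabs)) {
      sub_ids <- branch_ids(prune(master, keeps[[i]]))
      hit <- vapply(sub_ids, function(sid) {
        path <- map_to_master(sid, master, keeps[[i]])
        length(path) == 1L && path == mid
      }, logical(1))
      if (any(hit)) vals <- c(vals, unname(tabs[[i]]$lengths[sub_ids[hit]]))
    }
    expect_equal(unname(avg$mean[mid]),
                 if (length(vals)) mean(vals) else 0, tolerance = 1e-10)
    expect_equal(unname(avg$count[mid]), length(vals))
  }
})

test_that("expected lengths are additive along master-edge paths", {
  master <- simulate_species_tree(8, seed = 13)
  all_sp <- sort(master$tip.label)
  tabs <- lapply(1:3, function(i) make_table(master, all_sp, scale = i,
                                             id = paste0("g", i)))
  avg <- build_average_tree(tabs, master)
  # full set: expected = the means themselves
  exp_full <- expected_lengths(avg, master, all_sp)
  expect_equal(exp_full[avg$master_ids], avg$mean[avg$master_ids])
  # subset: each expected length is the path sum of means
  keep <- all_sp[1:5]
  exp_sub <- expected_lengths(avg, master, keep)
  for (sid in names(exp_sub))
    expect_equal(unname(exp_sub[sid]),
                 sum(avg$mean[map_to_master(sid, master, keep)]),
                 tolerance = 1e-12)
  # total expected equals total mean over covered edges
  covered <- unique(unlist(lapply(names(exp_sub), map_to_master,
                                  master = master, keep = keep)))
  expect_equal(sum(exp_sub), sum(avg$mean[covered]), tolerance = 1e-12)
})

test_that("RER regression is through-origin OLS with the stated sign", {
  tb <- structure(list(orthogroup_id = "g", species = c("A", "B"),
                       lengths = c(x = 2, y = 4)), class = "branch_table")
  # proportional gene: slope recovered exactly, residuals zero
  r <- compute_rer(tb, c(x = 1, y = 2))
  expect_equal(r$rate, 2)
  expect_equal(unname(r$residual), c(0, 0))

  # closed-form two-point case: a=(1,1), b=(0,2) -> r=1, residuals (-1,+1)
  tb$lengths <- c(x = 0, y = 2)
  r <- compute_rer(tb, c(x = 1, y = 1))
  expect_equal(r$rate, 1)
  expect_equal(unname(r$residual), c(-1, 1))

  # faster-than-expected branch gets a positive residual
  expect_gt(r$residual[["y"]], 0)

  # expected-length floor drops branches
  tb$lengths <- c(x = 1, y = 2, z = 5)[1:2]
  expect_error(compute_rer(tb, c(x = 1, y = 1e-12)), "fewer than 2")
})

test_that("residuals are orthogonal to expected lengths (normal equation)", {
  set.seed(21)
  for (i in 1:500) {
    n <- sample(5:40, 1)
    a <- runif(n, 0.01, 2)
    b <- runif(n, 0, 3)
    ids <- sprintf("b%02d", seq_len(n))
    tb <- structure(list(orthogroup_id = "g", species = "x",
                         lengths = stats::setNames(b, ids)),
                    class = "branch_table")
    r <- compute_rer(tb, stats::setNames(a, ids))
    expect_lt(abs(sum(r$expected * r$residual)), 1e-10)
  }
})

test_that("rescaling a gene scales its rate and residuals linearly", {
  master <- simulate_species_tree(10, seed = 31)
  sim <- shared_sim()
  tb <- sim$tables[[5]]
  avg <- build_average_tree(sim$tables, sim$master)
  e <- expected_lengths(avg, sim$master, tb$species)
  r1 <- compute_rer(tb, e)
  tb2 <- tb; tb2$lengths <- tb$lengths * 3
  r2 <- compute_rer(tb2, e)
  expect_equal(r2$rate, 3 * r1$rate, tolerance = 1e-12)
  expect_equal(r2$residual, 3 * r1$residual, tolerance = 1e-10)
})

test_that("zero-noise simulation yields identically zero RERs", {
  cfg <- sim_config(n_species = 10, n_orthogroups = 15, sigma_shared = 0,
                    sigma_noise = 0, dropout_prob = 0, seed = 41)
  sim <- simulate_orthogroups(cfg)
  avg <- build_average_tree(sim$tables, sim$master)
  for (tb in sim$tables) {
    r <- compute_rer(tb, expected_lengths(avg, sim$master, tb$species))
    expect_lt(max(abs(r$residual)), 1e-10)
  }
})
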