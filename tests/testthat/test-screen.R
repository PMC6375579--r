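test_that("migration classes follow the 25/75 boundaries", {
  expect_equal(as.character(classify_migration(c(0.10, 0.50, 1.00))),
               c("no_migration", "delayed", "completed"))
  # half-open boundaries, top class closed at 1
  expect_equal(as.character(classify_migration(c(0, 0.25, 0.75))),
               c("no_migration", "delayed", "completed"))
  expect_error(classify_migration(1.2), "0, 1")
})

test_that("class fractions and disassociation rates equal brute recounts", {
  rec <- data.frame(genotype = "g",
                    migration_fraction = c(0.9, 0.9),
                    disassociated = FALSE)
  expect_equal(class_fractions(rec, "g")$fractions[["completed"]], 1)
  rec2 <- data.frame(genotype = "g", migration_fraction = c(0.1, 0.5),
                     disassociated = c(TRUE, FALSE))
  cf <- class_fractions(rec2, "g")
  expect_equal(unname(cf$fractions), c(0.5, 0.5, 0))
  expect_equal(disassociation_rate(rec2, "g")$rate, 0.5)
  expect_error(class_fractions(rec2, "absent"), "no records")

  set.seed(31)
  rec <- data.frame(genotype = sample(letters[1:5], 2000, TRUE),
                    migration_fraction = runif(2000),
                    disassociated = runif(2000) < 0.3)
  for (g in letters[1:5]) {
    sub <- rec[rec$genotype == g, ]
    f <- sub$migration_fraction
    brute <- c(mean(f < 0.25), mean(f >= 0.25 & f < 0.75), mean(f >= 0.75))
    cf <- class_fractions(rec, g)
    expect_equal(unname(cf$fractions), brute, tolerance = 1e-12)
    expect_equal(sum(cf$fractions), 1, tolerance = 1e-12)
    expect_equal(disassociation_rate(rec, g)$rate, mean(sub$disassociated))
  }
})

test_that("junctional intensity normalizes BC peaks by same-chamber NC peaks", {
  prof <- function(id, ch, cls, peak)
    data.frame(profile_id = id, chamber = ch, class = cls,
               position = 1:5, intensity = c(1, 2, peak, 2, 1))
  p <- rbind(prof("b1", 1, "BC", 100), prof("n1", 1, "NC", 50))
  out <- contact_intensity(p)
  expect_equal(out$normalized, 2)
  # BC identical to NC: ratio 1
  p2 <- rbind(prof("b1", 1, "BC", 50), prof("n1", 1, "NC", 50))
  expect_equal(contact_intensity(p2)$normalized, 1)
  zero_nc <- rbind(prof("b1", 1, "BC", 10),
                   data.frame(profile_id = "n1", chamber = 1, class = "NC",
                              position = 1:5, intensity = rep(0, 5)))
  expect_error(contact_intensity(zero_nc), "zero NC reference")

  # batch equals per-chamber brute-force recompute (mean and median)
  set.seed(41)
  rows <- list()
  for (ch in 1:6) {
    for (b in 1:3) rows[[length(rows) + 1]] <-
        prof(paste0("b", ch, "_", b), ch, "BC", runif(1, 10, 100))
    for (k in 1:3) rows[[length(rows) + 1]] <-
        prof(paste0("n", ch, "_", k), ch, "NC", runif(1, 10, 100))
  }
  p <- do.call(rbind, rows)
  for (aggr in c("mean", "median")) {
    out <- contact_intensity(p, aggregate = aggr)
    f <- get(aggr)
    for (i in seq_len(nrow(out))) {
      sub <- p[p$chamber == out$chamber[i], ]
      ncp <- tapply(sub$intensity[sub$class == "NC"],
                    sub$profile_id[sub$class == "NC"], max)
      bcp <- max(sub$intensity[sub$profile_id == out$profile_id[i]])
      expect_equal(out$normalized[i], bcp / f(ncp), tolerance = 1e-12)
    }
  }
})

test_that("protrusion sectors partition the 45-degree histogram", {
  s <- protrusion_sectors(c(0, 90, 180))
  expect_equal(unname(s$sectors), c(1, 1, 1))
  expect_equal(names(which(protrusion_sectors(0)$sectors == 1)), "front")
  expect_equal(names(which(protrusion_sectors(90)$sectors == 1)), "middle")
  expect_equal(names(which(protrusion_sectors(180)$sectors == 1)), "rear")
  # boundary angles go to the clockwise-starting sector
  expect_equal(names(which(protrusion_sectors(45)$sectors == 1)), "middle")
  expect_equal(names(which(protrusion_sectors(135)$sectors == 1)), "rear")
  expect_equal(names(which(protrusion_sectors(225)$sectors == 1)), "middle")
  expect_equal(names(which(protrusion_sectors(315)$sectors == 1)), "front")
  expect_error(protrusion_sectors(360), "0, 360")

  set.seed(51)
  ang <- runif(10000, 0, 360) %% 360
  s <- protrusion_sectors(ang)
  expect_equal(sum(s$histogram), 10000)
  expect_equal(sum(s$sectors), 10000)
  brute_front <- sum(ang >= 315 | ang < 45)
  brute_rear <- sum(ang >= 135 & ang < 225)
  expect_equal(unname(s$sectors["front"]), brute_front)
  expect_equal(unname(s$sectors["rear"]), brute_rear)
  expect_equal(unname(s$sectors["middle"]), 10000 - brute_front - brute_rear)
  # sector counts are partial sums of the histogram
  expect_equal(unname(s$sectors["rear"]),
               unname(s$histogram[4] + s$histogram[5]))
})

test_that("enrichment test matches the exact hypergeometric tail", {
  U <- paste0("g", 1:20)
  # term = universe: no enrichment possible
  res <- enrichment_test(paste0("g", 1:5), U, list(all = U))
  expect_equal(res$p, 1)
  expect_equal(res$fold, 1)
  # empty overlap: fold 0
  res <- enrichment_test(paste0("g", 1:5), U, list(t = paste0("g", 6:9)))
  expect_equal(res$fold, 0)
  expect_error(enrichment_test("zz", U, list(t = U[1:3])), "outside")

  # factorial-exact oracle on small universes
  set.seed(61)
  for (i in 1:50) {
    N <- sample(8:30, 1)
    U <- paste0("g", seq_len(N))
    hits <- sample(U, sample(2:(N - 2), 1))
    terms <- lapply(1:4, function(j) sample(U, sample(2:N, 1)))
    names(terms) <- paste0("t", 1:4)
    res <- enrichment_test(hits, U, terms)
    for (r in seq_len(nrow(res))) {
      tg <- terms[[res$term[r]]]
      k <- length(intersect(tg, hits))
      expect_equal(res$p[r],
                   hyper_tail_exact(k, length(tg), N, length(hits)),
                   tolerance = 1e-10)
    }
    # BH q-values are monotone when traversing p in increasing order
    expect_false(is.unsorted(res$q))
  }
})
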