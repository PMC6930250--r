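test_that("coverage profile places reads and conserves mass", {
  g <- tiny_genome()  # tA [10,40) heavy
  seq20 <- substr(g$sequence, 11, 30)  # covers [10,30)
  cat <- build_catalog(seq20, g)
  norm <- matrix(5, nrow = 1, ncol = 2,
                 dimnames = list(seq20, c("L1", "L2")))
  prof <- coverage_profile(cat, norm, g, "tA", samples = "L1", flank = 5)
  expect_equal(nrow(prof), 30 + 10)
  expect_equal(prof$value[prof$position %in% 0:19], rep(5, 20))
  expect_true(all(prof$value[prof$position >= 20] == 0))
  # mass conservation: sum(profile) = sum(count x overlap length)
  expect_equal(sum(prof$value), 5 * 20)
  empty <- coverage_profile(cat, norm * 0, g, "tA", samples = "L1")
  expect_true(all(empty$value == 0))
  expect_error(coverage_profile(cat, norm, g, "nope", "L1"),
               "unknown feature")
})

test_that("end classification respects tolerance and orientation", {
  f <- list(start = 100, end = 170, strand = "heavy")
  expect_equal(classify_end(150, 170, f), "three_prime")
  expect_equal(classify_end(100, 120, f), "five_prime")
  expect_equal(classify_end(100, 170, f), "full_length")
  expect_equal(classify_end(120, 140, f), "internal")
  expect_equal(classify_end(152, 170, f, tau = 2), "three_prime")
  # orientation consistency: the same fragment on a light-strand feature
  fl <- list(start = 100, end = 170, strand = "light")
  expect_equal(classify_end(100, 120, fl), "three_prime")
  expect_equal(classify_end(150, 170, fl), "five_prime")
  expect_error(classify_end(10, 20, f), "overlap")
})

test_that("planted end classes are recovered exactly at jitter <= tau", {
  g <- make_toy_genome(seed = 8)
  trnas <- g$features$id[g$features$type == "tRNA"]
  frags <- list(
    planted_fragment(trnas[1], "three_prime", end_jitter = 2),
    planted_fragment(trnas[2], "five_prime", end_jitter = 2),
    planted_fragment(trnas[3], "internal", end_jitter = 2))
  truth <- plant_fragments(g, frags, seed = 2, stages = "WS36")
  vars <- unique(truth[, c("variant_id", "sequence", "parent",
                           "end_class")])
  cat <- build_catalog(vars$sequence, g)
  for (i in seq_len(nrow(vars))) {
    f <- g$features[g$features$id == vars$parent[i], ]
    row <- cat[cat$seq_id == vars$sequence[i], ]
    got <- classify_end(row$start, row$end, f, tau = 2)
    expect_equal(got, vars$end_class[i], label = vars$variant_id[i])
  }
})

test_that("k-means clustering recovers separated patterns deterministically", {
  set.seed(12)
  centers <- rbind(c(4, 4, -4, -4), c(-4, 4, 4, -4), c(0, -4, 0, 4))
  x <- centers[rep(1:3, each = 10), ] + matrix(rnorm(120, sd = 0.3),
                                               nrow = 30)
  rownames(x) <- paste0("s", 1:30)
  cm <- cluster_expression(x, k = 3, seed = 3)
  truthlab <- rep(1:3, each = 10)
  # perfect recovery: each true group lands in exactly one cluster
  tab <- table(truthlab, cm$assignments)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  cm2 <- cluster_expression(x, k = 3, seed = 3)
  expect_identical(cm$assignments, cm2$assignments)
  # k = rows -> each row its own cluster with zero WCSS
  sub <- x[1:5, ]
  cm5 <- cluster_expression(sub, k = 5, seed = 1)
  expect_equal(cm5$tot_withinss, 0)
  expect_error(cluster_expression(sub, k = 6), "exceeds")
  xm <- x; xm[1, 1] <- NA
  expect_message(cluster_expression(xm, k = 3, seed = 1), "imputed")
})

test_that("conserved core matches the brute-force common-substring oracle", {
  expect_equal(find_conserved_core("ACGTACGT")$core, "ACGTACGT")
  seqs <- c("AAGTCCCGGCTGGCGAATTT", "GTCCCGGCTGGCGAATAC",
            "TAGTCCCGGCTGGCGAAT")
  pc <- find_conserved_core(seqs)
  oracle <- lcs_oracle(seqs)
  expect_equal(pc$core_length, nchar(oracle[1]))
  expect_true(pc$core %in% oracle)
  expect_equal(pc$probe, revcomp(pc$core))
  disjoint <- c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC")
  d <- find_conserved_core(disjoint)
  expect_equal(d$core_length, 0)
  expect_true(d$degenerate)
  set.seed(44)
  for (i in 1:40) {
    trip <- vapply(1:3, function(j)
      paste(sample(c("A", "C", "G", "T"), sample(8:16, 1),
                   replace = TRUE), collapse = ""), character(1))
    pc <- find_conserved_core(trip)
    oracle <- lcs_oracle(trip)
    expect_equal(pc$core_length, max(0, nchar(oracle[1])))
    if (pc$core_length > 0) expect_true(pc$core %in% oracle)
  }
})

test_that("mitosRNA fraction is a normalized-count ratio", {
  norm <- matrix(c(10, 30, 20, 40), nrow = 2,
                 dimnames = list(c("a", "b"), c("L1", "L2")))
  expect_equal(mitos_fraction(norm, c(TRUE, TRUE), "L1"), 1)
  expect_equal(mitos_fraction(norm, c(FALSE, FALSE), "L1"), 0)
  expect_equal(mitos_fraction(norm, c(TRUE, FALSE), c("L1", "L2")),
               (10 + 20) / 100)
  expect_error(mitos_fraction(norm * 0, c(TRUE, FALSE), "L1"), "zero")
})

test_that("trait correlation reproduces the Pearson t-test formula", {
  traits <- data.frame(stage = c("D2", "WS36", "WS40", "WS42"),
                       lt50 = c(100, 80, 12, 1),
                       mr = c(1, 3, 5, 7))
  fr <- c(D2 = 0.1, WS36 = 0.3, WS40 = 0.5, WS42 = 0.7)
  fr2 <- c(D2 = 0.31, WS36 = 0.22, WS40 = 0.17, WS42 = 0.02)
  ct <- trait_correlation(fr2, traits, "lt50")
  r <- cor(fr2, traits$lt50)
  tstat <- r * sqrt(2) / sqrt(1 - r^2)
  expect_equal(ct$r, r)
  expect_equal(ct$p, 2 * pt(-abs(tstat), df = 2))
  # perfectly linear relationships
  expect_equal(trait_correlation(fr, traits, "mr")$r, 1)
  down <- c(D2 = 4, WS36 = 3, WS40 = 2, WS42 = 1)
  expect_equal(trait_correlation(down, traits, "mr")$r, -1)
  expect_error(trait_correlation(fr[1:2], traits, "mr"), ">= 3")
  expect_warning(
    trait_correlation(c(D2 = 1, WS36 = 1, WS40 = 1), traits, "mr"),
    "zero variance")
})
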