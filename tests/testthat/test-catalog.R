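test_that("exact alignment finds identity, strand and wrapped hits", {
  g <- tiny_genome()
  s <- substr(g$sequence, 1, 20)
  h <- exact_align(s, g)
  expect_true(any(h$start == 0 & h$end == 20 & h$strand == "heavy"))
  hl <- exact_align(revcomp(substr(g$sequence, 51, 70)), g)
  expect_true(any(hl$start == 50 & hl$end == 70 & hl$strand == "light"))
  # wrap around the origin
  sw <- paste0(substr(g$sequence, 111, 120), substr(g$sequence, 1, 8))
  hw <- exact_align(sw, g)
  expect_true(any(hw$start == 110 & hw$end == 128 & hw$wraps_origin))
  # strand symmetry: reverse-complementing swaps strands, keeps intervals
  h2 <- exact_align(revcomp(s), g)
  expect_equal(h2$start, h$start)
  expect_equal(h2$strand,
               ifelse(h$strand == "heavy", "light", "heavy"))
})

test_that("alignment agrees with the naive doubled-string oracle", {
  set.seed(17)
  for (i in 1:15) {
    L <- sample(80:400, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    g <- genome_annotation(seq, data.frame(
      id = "f1", type = "tRNA", start = 0L, end = 40L,
      strand = "heavy", name = "f1"))
    for (j in 1:4) {
      m <- sample(10:20, 1)
      st <- sample(0:(L - 1), 1)
      q <- substr(paste0(seq, seq), st + 1, st + m)
      if (sample(c(TRUE, FALSE), 1)) q <- revcomp(q)
      expect_equal(exact_align(q, g)[, c("start", "end", "strand")],
                   naive_align_oracle(q, g),
                   ignore_attr = TRUE)
    }
  }
})

test_that("circularity: rotations shift hit coordinates consistently", {
  g <- tiny_genome()
  rot <- 37L
  L <- genome_length(g)
  rseq <- paste0(substr(g$sequence, rot + 1, L),
                 substr(g$sequence, 1, rot))
  gr <- genome_annotation(rseq, g$features[1, , drop = FALSE])
  q <- substr(g$sequence, 61, 78)
  h1 <- exact_align(q, g)
  h2 <- exact_align(q, gr)
  expect_equal(sort((h1$start - rot) %% L), sort(h2$start %% L))
  expect_equal(nrow(h1), nrow(h2))
})

test_that("hit annotation classifies overlap and extensions", {
  g <- tiny_genome()  # tA [10,40), tB [40,70) heavy; m1 [80,115) light
  inside <- annotate_hit(list(start = 15, end = 35, strand = "heavy"), g)
  expect_equal(inside$overlap_class, "single_feature")
  expect_equal(inside$features, "tA")
  expect_equal(c(inside$upstream_extension, inside$downstream_extension),
               c(0L, 0L))
  # 2 nt upstream of a tRNA, extending into it
  up2 <- annotate_hit(list(start = 8, end = 28, strand = "heavy"), g)
  expect_equal(up2$overlap_class, "overlapping_features")
  expect_equal(up2$upstream_extension, 2L)
  expect_equal(up2$features, c("intergenic", "tA"))
  # spanning the junction of two adjacent tRNAs
  span <- annotate_hit(list(start = 30, end = 50, strand = "heavy"), g)
  expect_equal(span$overlap_class, "overlapping_features")
  expect_equal(span$features, c("tA", "tB"))
  # intergenic only
  inter <- annotate_hit(list(start = 70, end = 80, strand = "heavy"), g)
  expect_equal(inter$overlap_class, "intergenic")
})

test_that("annotation agrees with a per-base membership oracle", {
  g <- tiny_genome()
  mem <- base_membership(g)
  L <- genome_length(g)
  set.seed(23)
  for (i in 1:60) {
    st <- sample(0:(L - 1), 1)
    len <- sample(15:25, 1)
    ann <- annotate_hit(list(start = st, end = st + len,
                             strand = "heavy"), g)
    bases <- (seq(st, st + len - 1) %% L) + 1
    expected <- unique(unlist(mem[bases]))
    got <- setdiff(ann$features, "intergenic")
    expect_setequal(got, expected)
    covered <- vapply(mem[bases], function(x) length(x) > 0, logical(1))
    if (length(expected) == 0) {
      expect_equal(ann$overlap_class, "intergenic")
    } else if (length(expected) == 1 && all(covered)) {
      expect_equal(ann$overlap_class, "single_feature")
    } else {
      expect_equal(ann$overlap_class, "overlapping_features")
    }
  }
})

test_that("catalog flags mitochondrial vs decoy sequences", {
  g <- make_toy_genome(seed = 3)
  trna <- g$features$id[g$features$type == "tRNA"][1]
  truth <- plant_fragments(
    g, list(planted_fragment(trna, "three_prime")), seed = 1)
  seqs <- unique(truth$sequence)
  cat1 <- build_catalog(seqs, g)
  expect_true(all(cat1$mito))
  expect_equal(nrow(cat1), length(seqs))
  decoy <- make_decoy(seed = 5)
  dseqs <- substring(decoy, c(1, 101, 201), c(20, 120, 220))
  cat2 <- build_catalog(dseqs, g)
  expect_false(any(cat2$mito))
})

test_that("catalog summary conserves counts and renders percentages", {
  cat <- table1_de_catalog()
  s <- summarize_catalog(cat)
  expect_equal(s$total, 208)
  expect_equal(sum(s$by_category$n), s$total)
  pick <- function(strand, cls)
    s$by_category$pct[s$by_category$strand == strand &
                        s$by_category$overlap_class == cls]
  expect_equal(pick("heavy", "single_feature"), 67.3)
  expect_equal(pick("light", "single_feature"), 25.0)
  expect_equal(s$by_type$n[s$by_type$type == "tRNA"], 80L)
  expect_equal(s$by_type$share_pct[s$by_type$type == "tRNA"], 38.5)
  empty <- summarize_catalog(cat, subset = integer(0))
  expect_true(empty$empty)
  expect_true(all(empty$by_category$pct == 0))
})

test_that("feature enrichment matches the exact binomial tail sum", {
  g <- tiny_genome()
  # all 50 sequences in tRNAs; genome tRNA fraction is 60/120
  cat <- data.frame(mito = TRUE, strand = "heavy",
                    overlap_class = "single_feature",
                    feature_types = "tRNA")[rep(1, 50), ]
  s <- summarize_catalog(cat)
  enr <- feature_enrichment(s, g)
  row <- enr[enr$type == "tRNA", ]
  gp <- row$genome_frac
  expect_equal(gp, 60 / 120)
  dens <- dbinom(0:50, 50, gp)
  oracle <- sum(dens[dens <= dbinom(50, 50, gp) * (1 + 1e-7)])
  expect_equal(row$p, oracle, tolerance = 1e-10)
  expect_gt(row$ratio, 1.9)
  expect_error(feature_enrichment(summarize_catalog(cat, integer(0)), g),
               "empty")
})
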