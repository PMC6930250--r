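# exhaustive re-derivation of the adapter-trim contract: leftmost i where
# an adapter prefix of length >= min_overlap matches exactly
trim_oracle <- function(read, adapter, min_overlap) {
  n <- nchar(read)
  la <- nchar(adapter)
  for (i in seq_len(n)) {
    k <- min(la, n - i + 1)
    if (k < min_overlap) next
    if (substr(read, i, i + k - 1) == substr(adapter, 1, k)) {
      return(substr(read, 1, i - 1))
    }
  }
  read
}

test_that("adapter trimming matches the substring-search oracle", {
  expect_equal(trim_adapter("ACGTACGTTCGTATGCC", "TCGTATGCC", 6),
               "ACGTACGT")
  expect_equal(trim_adapter("ACGTACGT", "TCGTATGCC", 6), "ACGTACGT")
  expect_equal(trim_adapter("TCGTATGCC", "TCGTATGCC", 6), "")
  set.seed(71)
  adapter <- "TGGAATTCTCGG"
  for (i in 1:200) {
    insert <- paste(sample(c("A", "C", "G", "T"),
                           sample(5:30, 1), replace = TRUE),
                    collapse = "")
    read <- substr(paste0(insert, adapter), 1, sample(10:40, 1))
    expect_identical(trim_adapter(read, adapter, 6),
                     trim_oracle(read, adapter, 6))
  }
})

test_that("size selection keeps the 15-27 nt window inclusively", {
  seqs <- strrep("A", c(14, 15, 27, 28))
  expect_identical(size_select(seqs), strrep("A", c(15, 27)))
  expect_identical(size_select(character(0)), character(0))
  inside <- strrep("C", c(15, 20, 27))
  expect_identical(size_select(inside), inside)
})

test_that("collapsing counts unique sequences and preserves totals", {
  libs <- list(L1 = c(rep("AAAAAAAAAAAAAAA", 3), "CCCCCCCCCCCCCCC"),
               L2 = c(rep("AAAAAAAAAAAAAAA", 3), "CCCCCCCCCCCCCCC"))
  m <- collapse_reads(libs)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m["AAAAAAAAAAAAAAA", ]), c(3L, 3L))
  expect_identical(m[, 1], m[, 2])
  expect_equal(unname(colSums(m)),
               unname(vapply(libs, length, integer(1))))
})

test_that("low-abundance filtering uses >= min_total across libraries", {
  m <- matrix(c(4, 5, 5, 5, 6, 5), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("L1", "L2")))
  expect_identical(rownames(filter_low_abundance(m, 10)), c("b", "c"))
  expect_identical(filter_low_abundance(m, 0), m)
})

test_that("size factors follow median-of-ratios and its invariances", {
  m <- matrix(c(10, 20, 5, 80, 100,
                20, 40, 10, 160, 200,
                30, 60, 15, 240, 300), nrow = 5,
              dimnames = list(paste0("s", 1:5), c("A", "B", "C")))
  sf <- size_factors(m)
  expect_equal(unname(sf), unname(mor_oracle(m)))
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  # identical libraries -> all factors 1
  ident <- cbind(A = c(3, 9, 27), B = c(3, 9, 27))
  expect_equal(unname(size_factors(ident)), c(1, 1))
  # normalization undoes pure depth scaling
  norm <- normalize_counts(m)
  expect_equal(unname(norm[, "A"]), unname(norm[, "B"]))
  # no row positive everywhere -> fallback with warning
  z <- matrix(c(5, 0, 0, 7), nrow = 2,
              dimnames = list(c("a", "b"), c("A", "B")))
  expect_warning(size_factors(z), "falling back")
})

test_that("size factors agree with the DESeq2 estimator", {
  set.seed(21)
  m <- matrix(rnbinom(60, mu = 50, size = 5) + 1, nrow = 12,
              dimnames = list(paste0("s", 1:12), paste0("L", 1:5)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("full preprocessing recounts reads and drops ambiguous bases", {
  adapter <- "TGGAATTCTCGG"
  set.seed(5)
  mk <- function(n, seqs) sample(seqs, n, replace = TRUE)
  pool <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
          collapse = ""), character(1))
  libs <- list(L1 = paste0(mk(120, pool), adapter),
               L2 = paste0(mk(80, pool), adapter))
  pp <- preprocess_libraries(libs, adapter, min_total = 10)
  expect_equal(unname(pp$retained_reads), c(120L, 80L))
  expect_equal(unname(colSums(pp$raw)), c(120L, 80L))
  expect_true(all(rownames(pp$raw) %in% pool))
  # FASTQ round trip drops N-containing reads with a message
  fq <- withr::local_tempfile(fileext = ".fastq")
  rs <- Biostrings::DNAStringSet(c(pool[1], gsub("^.", "N", pool[2])))
  names(rs) <- c("r1", "r2")
  Biostrings::writeXStringSet(rs, fq, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", Biostrings::width(rs))))
  expect_message(reads <- read_library(fq), "ambiguous")
  expect_identical(reads, pool[1])
})
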