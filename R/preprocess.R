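#' Trim a 3' adapter from reads
#'
#' Removes everything from the leftmost position where a prefix of the
#' adapter, at least `min_overlap` nt long, matches the read exactly.
#' An internal match must contain the full adapter; a match running into
#' the read's 3' end may be a shorter adapter prefix, down to
#' `min_overlap` nt. Matching is exact (no mismatches), consistent with
#' the downstream 100%-identity alignment regime. Reads without a match
#' are returned unchanged.
#'
#' @param reads Character vector of reads.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum matched adapter prefix length (>= 1).
#' @return Character vector of trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  stopifnot(min_overlap >= 1L, nchar(adapter) >= 1L)
  la <- nchar(adapter)
  k0 <- min(min_overlap, la)
  seed <- substr(adapter, 1L, k0)
  vapply(reads, function(r) {
    n <- nchar(r)
    occ <- gregexpr(seed, r, fixed = TRUE)[[1]]
    if (occ[1] == -1L) return(r)
    for (i in occ) {
      k <- min(la, n - i + 1L)
      if (k < min_overlap) next
      if (substr(r, i, i + k - 1L) == substr(adapter, 1L, k)) {
        return(substr(r, 1L, i - 1L))
      }
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

#' Size-select sequences
#'
#' Retains sequences with length in `[min_len, max_len]` inclusive;
#' 15-27 nt is the small-RNA window used throughout.
#'
#' @param seqs Character vector.
#' @param min_len,max_len Inclusive length bounds.
#' @return The retained subset.
#' @export
size_select <- function(seqs, min_len = 15L, max_len = 27L) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  n <- nchar(seqs)
  seqs[n >= min_len & n <= max_len]
}

#' Collapse libraries of reads into a unique-sequence count matrix
#'
#' @param libraries Named list of character vectors (trimmed,
#'   size-selected reads per library).
#' @return Integer matrix, rows = distinct sequences (lexicographic),
#'   columns = libraries; each column sums to the library's read count.
#' @export
collapse_reads <- function(libraries) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  all_seqs <- sort(unique(unlist(libraries, use.names = FALSE)))
  m <- matrix(0L, nrow = length(all_seqs), ncol = length(libraries),
              dimnames = list(all_seqs, names(libraries)))
  for (j in seq_along(libraries)) {
    tab <- table(factor(libraries[[j]], levels = all_seqs))
    m[, j] <- as.integer(tab)
  }
  m
}

#' Filter low-abundance sequences
#'
#' Keeps rows whose total raw count across all libraries is at least
#' `min_total`.
#'
#' @param counts Count matrix.
#' @param min_total Minimum total raw count (default 10).
#' @return The filtered matrix.
#' @export
filter_low_abundance <- function(counts, min_total = 10L) {
  stopifnot(min_total >= 0L)
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' The DESeq-style estimator: for rows positive in every library, the
#' per-library median of the ratio count / row geometric mean. If no row
#' is positive in all libraries the estimator falls back to column-total
#' scaling (factors proportional to library totals, geometric mean 1),
#' with a warning.
#'
#' @param counts Raw count matrix (rows = sequences, cols = libraries).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  logc <- log(counts)
  ok <- apply(is.finite(logc), 1L, all)
  if (!any(ok)) {
    warning("no sequence detected in every library; ",
            "falling back to column-total size factors")
    tot <- colSums(counts)
    if (any(tot == 0)) stop("library with zero total count")
    return(tot / exp(mean(log(tot))))
  }
  loggeo <- rowMeans(logc[ok, , drop = FALSE])
  sf <- apply(logc[ok, , drop = FALSE], 2L, function(lc)
    exp(stats::median(lc - loggeo)))
  sf
}

#' Normalize a count matrix by size factors
#'
#' @param counts Raw count matrix.
#' @param sf Size factors from [size_factors()]; computed if missing.
#' @return Matrix of normalized counts `raw / factor`, with the factors
#'   attached as attribute `"size_factors"`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  stopifnot(all(sf > 0), length(sf) == ncol(counts))
  out <- sweep(counts, 2L, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

#' Read one small-RNA library from FASTQ or FASTA
#'
#' Reads containing characters outside `{A,C,G,T}` (e.g. `N`) are
#' dropped, with a message reporting how many.
#'
#' @param path File path; format inferred from the extension
#'   (`.fastq/.fq` vs `.fasta/.fa/.fna`).
#' @return Character vector of reads.
#' @export
read_library <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  reads <- as.character(Biostrings::readDNAStringSet(path, format = fmt))
  keep <- is_dna(reads)
  if (any(!keep)) {
    message(sum(!keep), " read(s) with ambiguous bases dropped from ",
            basename(path))
  }
  unname(reads[keep])
}

#' Preprocess raw libraries into a normalized count matrix
#'
#' Fixed pipeline order: adapter trim, size selection, collapse to
#' unique sequences, low-abundance filter, median-of-ratios
#' normalization.
#'
#' @param files Named character vector of library file paths (names =
#'   library ids), or a named list of in-memory read vectors.
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum adapter overlap for trimming.
#' @param min_len,max_len Size-selection bounds.
#' @param min_total Low-abundance threshold (total raw count).
#' @return List with `raw` (filtered raw counts), `normalized`,
#'   `size_factors` and `retained_reads` per library.
#' @export
preprocess_libraries <- function(files, adapter, min_overlap = 6L,
                                 min_len = 15L, max_len = 27L,
                                 min_total = 10L) {
  libs <- if (is.list(files)) files else
    stats::setNames(lapply(files, read_library), names(files))
  trimmed <- lapply(libs, trim_adapter, adapter = adapter,
                    min_overlap = min_overlap)
  selected <- lapply(trimmed, size_select, min_len = min_len,
                     max_len = max_len)
  raw <- collapse_reads(selected)
  raw <- filter_low_abundance(raw, min_total = min_total)
  if (nrow(raw) == 0L) stop("no sequences survive the low-abundance filter")
  sf <- size_factors(raw)
  list(raw = raw, normalized = normalize_counts(raw, sf),
       size_factors = sf,
       retained_reads = vapply(selected, length, integer(1)))
}
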