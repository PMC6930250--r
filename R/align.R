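#' Exact alignment of a sequence to a circular genome, both strands
#'
#' Finds every position where the query matches the heavy strand with
#' 100% identity, and every position where it matches the light strand
#' (i.e. the query equals the reverse complement of a heavy-strand
#' interval). On a circular genome, matches wrapping the origin are
#' found by scanning the genome extended with its first
#' `length(query) - 1` bases. Coordinates are 0-based half-open on the
#' heavy strand; a wrapped hit keeps `start` in `[0, L)` with
#' `end = start + nchar(seq) > L`.
#'
#' @param seq Query sequence over `{A,C,G,T}`.
#' @param genome A [genome_annotation()].
#' @return `data.frame` with columns `start`, `end`, `strand`
#'   (`"heavy"`/`"light"`), `wraps_origin`; zero rows if no match.
#'   Ordered by `start`, heavy before light on ties.
#' @export
exact_align <- function(seq, genome) {
  stopifnot(is_dna(seq))
  L <- genome_length(genome)
  m <- nchar(seq)
  if (m > L) stop("query longer than genome")
  subject <- if (genome$circular && m > 1L) {
    paste0(genome$sequence, substr(genome$sequence, 1L, m - 1L))
  } else genome$sequence
  subj <- Biostrings::DNAString(subject)
  find <- function(pat) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj)
    s0 <- Biostrings::start(hits) - 1L
    s0[s0 < L]  # starts >= L duplicate a wrapped hit already reported
  }
  heavy <- find(seq)
  light <- find(revcomp(seq))
  out <- data.frame(
    start = c(heavy, light),
    end = c(heavy, light) + m,
    strand = rep(c("heavy", "light"), c(length(heavy), length(light))),
    stringsAsFactors = FALSE)
  out$wraps_origin <- out$end > L
  out[order(out$start, match(out$strand, c("heavy", "light"))), ,
      drop = FALSE]
}

# split a (possibly wrapped) 0-based half-open interval into linear pieces
.circ_pieces <- function(start, end, L) {
  if (end <= L) return(list(c(start, end)))
  list(c(start, L), c(0L, end - L))
}

# total overlap length between a hit interval and a feature interval on
# the circle, plus the hit-local offset interval of the feature
.hit_feature_overlap <- function(hs, he, fs, fe, L) {
  # project the feature onto the hit's local frame [0, he - hs)
  len <- he - hs
  best <- NULL
  for (fp in .circ_pieces(fs, fe, L)) {
    # candidate placements of the feature piece relative to hs (the hit
    # may wrap, so consider the piece shifted by 0 and +L)
    for (shift in c(0L, L)) {
      a <- fp[1] + shift - hs
      b <- fp[2] + shift - hs
      lo <- max(a, 0L)
      hi <- min(b, len)
      if (hi > lo) {
        piece <- c(lo, hi)
        best <- if (is.null(best)) list(piece) else c(best, list(piece))
      }
    }
  }
  if (is.null(best)) return(NULL)
  mat <- do.call(rbind, best)
  c(min(mat[, 1]), max(mat[, 2]))
}

#' Annotate an alignment hit by feature overlap
#'
#' Computes which annotated features the hit overlaps (half-open
#' interval intersection, modulo the genome length), assigns the overlap
#' class and measures the extensions beyond the first/last overlapped
#' feature. A hit entirely contained in one feature is
#' `single_feature`; any extension beyond the feature, or overlap of
#' two or more features, makes it `overlapping_features` (an extension
#' into intergenic sequence counts intergenic as a second "feature");
#' a hit touching no feature is `intergenic`.
#'
#' @param hit One-row `data.frame` (or list) with `start`, `end`,
#'   `strand` as returned by [exact_align()].
#' @param genome A [genome_annotation()].
#' @return List of class `mitos_annotation`: `start`, `end`, `strand`,
#'   `overlap_class`, `features` (ids ordered along the hit),
#'   `feature_types`, `upstream_extension`, `downstream_extension`.
#' @export
annotate_hit <- function(hit, genome) {
  L <- genome_length(genome)
  hs <- hit$start %% L
  he <- hs + (hit$end - hit$start)
  len <- he - hs
  f <- genome$features
  ov <- lapply(seq_len(nrow(f)), function(i)
    .hit_feature_overlap(hs, he, f$start[i], f$end[i], L))
  idx <- which(!vapply(ov, is.null, logical(1)))
  if (length(idx) == 0L) {
    ann <- list(start = hs, end = he, strand = hit$strand,
                overlap_class = "intergenic", features = "intergenic",
                feature_types = "intergenic",
                upstream_extension = 0L, downstream_extension = 0L)
    class(ann) <- "mitos_annotation"
    return(ann)
  }
  starts <- vapply(ov[idx], `[`, numeric(1), 1L)
  ends <- vapply(ov[idx], `[`, numeric(1), 2L)
  ord <- order(starts, ends)
  idx <- idx[ord]
  up <- as.integer(min(starts))
  down <- as.integer(len - max(ends))
  feats <- f$id[idx]
  types <- f$type[idx]
  if (length(idx) == 1L && up == 0L && down == 0L) {
    cls <- "single_feature"
  } else {
    cls <- "overlapping_features"
    if (up > 0L || down > 0L) {
      feats <- c(if (up > 0L) "intergenic", feats,
                 if (down > 0L) "intergenic")
      types <- c(if (up > 0L) "intergenic", types,
                 if (down > 0L) "intergenic")
    }
  }
  ann <- list(start = hs, end = he, strand = hit$strand,
              overlap_class = cls, features = feats,
              feature_types = types,
              upstream_extension = up, downstream_extension = down)
  class(ann) <- "mitos_annotation"
  ann
}
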