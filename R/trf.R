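#' Per-base coverage profile of a feature
#'
#' For every base of the feature window (the feature plus `flank` nt on
#' each side, indexed 5'->3' in the feature's own orientation), sums the
#' normalized counts of all cataloged sequences covering that base in
#' the selected samples.
#'
#' @param catalog Catalog from [build_catalog()].
#' @param norm Normalized count matrix (rows = sequences).
#' @param genome A [genome_annotation()].
#' @param feature_id Feature to profile.
#' @param samples Library ids (columns of `norm`) to sum over.
#' @param flank Flanking nt on each side of the feature (default 5),
#'   so upstream extensions are visible.
#' @return `data.frame` with `position` (0 = feature 5' end; negative =
#'   upstream flank) and `value`.
#' @export
coverage_profile <- function(catalog, norm, genome, feature_id, samples,
                             flank = 5L) {
  f <- genome$features[genome$features$id == feature_id, ]
  if (nrow(f) != 1L) stop("unknown feature id: ", feature_id)
  L <- genome_length(genome)
  flen <- f$end - f$start
  wlen <- flen + 2L * flank
  ws <- (f$start - flank) %% L  # heavy-strand window start
  prof <- numeric(wlen)
  cat_m <- catalog[catalog$mito %in% TRUE, , drop = FALSE]
  for (i in seq_len(nrow(cat_m))) {
    w <- sum(norm[cat_m$seq_id[i], samples])
    if (w == 0) next
    ov <- .hit_feature_overlap(ws, ws + wlen, cat_m$start[i],
                               cat_m$end[i], L)
    if (is.null(ov)) next
    idx <- (ov[1] + 1L):ov[2]
    prof[idx] <- prof[idx] + w
  }
  if (f$strand == "light") prof <- rev(prof)
  data.frame(position = seq(-flank, flen + flank - 1L), value = prof)
}

#' Classify the end type of a fragment relative to its parent feature
#'
#' In the feature's own 5'->3' orientation: a hit whose 5' end is within
#' `tau` nt of the feature 5' end, while its 3' end falls short of the
#' feature 3' end by more than `tau`, is `five_prime`; symmetrically for
#' `three_prime`; both ends within `tau` is `full_length`; neither is
#' `internal`. Light-strand features have their coordinates flipped.
#'
#' @param start,end Hit coordinates (0-based half-open, heavy strand),
#'   vectorized.
#' @param feature One row of `genome$features` (or a list with `start`,
#'   `end`, `strand`).
#' @param tau End tolerance in nt (default 2).
#' @return Character vector of classes.
#' @export
classify_end <- function(start, end, feature, tau = 2L) {
  if (any(pmin(end, feature$end) <= pmax(start, feature$start))) {
    stop("hit does not overlap the feature")
  }
  if (feature$strand == "heavy") {
    d5 <- abs(start - feature$start)
    d3 <- abs(end - feature$end)
  } else {
    d5 <- abs(end - feature$end)
    d3 <- abs(start - feature$start)
  }
  ifelse(d5 <= tau & d3 <= tau, "full_length",
         ifelse(d5 <= tau & d3 > tau, "five_prime",
                ifelse(d3 <= tau & d5 > tau, "three_prime", "internal")))
}

#' k-means clustering of expression patterns
#'
#' Lloyd's algorithm with multiple random restarts on Euclidean
#' distance, deterministic for a given seed. Missing values are imputed
#' as 0 with a message.
#'
#' @param x Numeric matrix, rows = sequences, columns = samples
#'   (typically relative-log2FC heatmap rows).
#' @param k Number of clusters (default 3, the number of broad
#'   anoxia/recovery expression patterns).
#' @param seed Integer seed.
#' @param restarts Number of random restarts (default 20).
#' @return List of class `cluster_model`: `k`, `assignments` (named),
#'   `centers`, `withinss`, `tot_withinss`.
#' @export
cluster_expression <- function(x, k = 3L, seed = 1L, restarts = 20L) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of rows")
  if (anyNA(x)) {
    message(sum(is.na(x)), " missing value(s) imputed as 0 for clustering")
    x[is.na(x)] <- 0
  }
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = restarts,
                  algorithm = "Lloyd", iter.max = 200L))
  structure(list(k = k, assignments = stats::setNames(km$cluster,
                                                      rownames(x)),
                 centers = km$centers, withinss = km$withinss,
                 tot_withinss = km$tot.withinss),
            class = "cluster_model")
}

#' Longest substring common to a set of sequences
#'
#' Finds the maximal substring shared by every sequence (the conserved
#' core of a fragment family) and its reverse complement (the antisense
#' probe that would capture every member). Ties are broken by the
#' leftmost occurrence in the first sequence. Disjoint sequences yield a
#' length-0 core, flagged.
#'
#' @param seqs Character vector of sequences (>= 1).
#' @return List of class `probe_core`: `core`, `core_length`, `probe`
#'   (reverse complement of the core), `degenerate` flag.
#' @export
find_conserved_core <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  first <- seqs[1]
  others <- seqs[-1]
  n <- nchar(first)
  maxlen <- min(nchar(seqs))
  core <- ""
  found <- FALSE
  for (len in seq(maxlen, 1L)) {
    for (s in seq_len(n - len + 1L)) {
      cand <- substr(first, s, s + len - 1L)
      if (all(vapply(others, function(o) grepl(cand, o, fixed = TRUE),
                     logical(1)))) {
        core <- cand
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  structure(list(core = core, core_length = nchar(core),
                 probe = if (nchar(core) > 0) revcomp(core) else "",
                 degenerate = nchar(core) == 0L),
            class = "probe_core")
}

#' @export
print.probe_core <- function(x, ...) {
  cat(sprintf("conserved core (%d nt): 5'-%s-3'\nantisense probe: 5'-%s-3'\n",
              x$core_length, x$core, x$probe))
  invisible(x)
}

#' Fraction of expression attributable to mitosRNAs
#'
#' Sum of normalized counts of mitochondria-derived sequences divided by
#' the sum over all sequences, within a set of samples.
#'
#' @param norm Normalized count matrix.
#' @param mito Logical vector over rows of `norm` (mitosRNA flag).
#' @param samples Library ids (columns) of the group.
#' @return Scalar fraction in `[0, 1]`.
#' @export
mitos_fraction <- function(norm, mito, samples) {
  stopifnot(length(mito) == nrow(norm), length(samples) >= 1L)
  denom <- sum(norm[, samples])
  if (denom == 0) stop("zero total expression in the selected samples")
  sum(norm[mito, samples, drop = FALSE]) / denom
}

#' Correlate per-stage mitosRNA fraction with a stage trait
#'
#' Pearson correlation with the two-sided p-value from the t transform
#' on n - 2 degrees of freedom, e.g. against anoxia LT50 or metabolic
#' rate.
#'
#' @param fractions Named numeric vector of mitosRNA fractions (names =
#'   stages).
#' @param traits `data.frame` with a `stage` column plus trait columns.
#' @param trait Name of the trait column.
#' @return List: `r`, `p`, `n`. Zero variance yields `NA` with a
#'   warning.
#' @export
trait_correlation <- function(fractions, traits, trait) {
  stopifnot(trait %in% names(traits), "stage" %in% names(traits))
  y <- traits[[trait]][match(names(fractions), traits$stage)]
  ok <- !is.na(fractions) & !is.na(y)
  if (sum(ok) < 3L) stop("need >= 3 stages with both values")
  x <- fractions[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
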