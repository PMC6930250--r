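#' Build the mitosRNA catalog for a set of unique sequences
#'
#' Aligns every sequence to the mitochondrial genome with 100% identity
#' on both strands. A sequence is a mitosRNA iff it has at least one
#' hit. Multi-mapping sequences carry all hits, but summaries count each
#' sequence once via its primary hit (lowest heavy-strand start, heavy
#' strand preferred on ties).
#'
#' @param seqs Character vector of unique sequences, or a count matrix
#'   whose row names are sequences.
#' @param genome A [genome_annotation()].
#' @param per_locus If `TRUE`, return one row per hit instead of one row
#'   per sequence (primary hit).
#' @return `data.frame` with one row per sequence (or hit): `seq_id`,
#'   `mito`, `n_hits`, `start`, `end`, `strand`, `wraps_origin`,
#'   `overlap_class`, `features` and `feature_types` (comma-collapsed),
#'   `upstream_extension`, `downstream_extension`. Non-mito rows have
#'   `NA` annotation fields.
#' @export
build_catalog <- function(seqs, genome, per_locus = FALSE) {
  if (is.matrix(seqs)) seqs <- rownames(seqs)
  stopifnot(is.character(seqs))
  rows <- lapply(seqs, function(s) {
    hits <- exact_align(s, genome)
    if (nrow(hits) == 0L) {
      return(data.frame(seq_id = s, mito = FALSE, n_hits = 0L,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_, wraps_origin = NA,
                        overlap_class = NA_character_,
                        features = NA_character_,
                        feature_types = NA_character_,
                        upstream_extension = NA_integer_,
                        downstream_extension = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    use <- if (per_locus) seq_len(nrow(hits)) else 1L  # hits are ordered
    do.call(rbind, lapply(use, function(i) {
      ann <- annotate_hit(hits[i, ], genome)
      data.frame(seq_id = s, mito = TRUE, n_hits = nrow(hits),
                 start = ann$start, end = ann$end, strand = ann$strand,
                 wraps_origin = hits$wraps_origin[i],
                 overlap_class = ann$overlap_class,
                 features = paste(ann$features, collapse = ","),
                 feature_types = paste(ann$feature_types, collapse = ","),
                 upstream_extension = ann$upstream_extension,
                 downstream_extension = ann$downstream_extension,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a catalog in the strand-by-overlap-class layout
#'
#' Counts and one-decimal percentages per strand x overlap class, and
#' per feature-type column. Single-feature rows contribute their one
#' feature's type; overlapping rows contribute each overlapped type
#' once; intergenic-only rows count in the `intergenic` column.
#'
#' @param catalog Catalog `data.frame` from [build_catalog()] (or any
#'   data frame with `strand`, `overlap_class`, `feature_types`
#'   columns); non-mito rows are ignored.
#' @param subset Optional logical or integer index selecting the rows to
#'   summarize (e.g. the differentially expressed subset).
#' @return List of class `catalog_summary`: `total`, `by_category`
#'   (strand, overlap_class, n, pct), `by_type` (type, n, share_pct),
#'   `empty` flag (percentages reported as 0.0 when the subset is
#'   empty).
#' @export
summarize_catalog <- function(catalog, subset = NULL) {
  if (!is.null(subset)) catalog <- catalog[subset, , drop = FALSE]
  if ("mito" %in% names(catalog)) {
    catalog <- catalog[catalog$mito %in% TRUE, , drop = FALSE]
  }
  total <- nrow(catalog)
  grid <- expand.grid(strand = c("heavy", "light"),
                      overlap_class = c("single_feature",
                                        "overlapping_features",
                                        "intergenic"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(s, oc)
    sum(catalog$strand == s & catalog$overlap_class == oc),
    grid$strand, grid$overlap_class)
  grid$pct <- if (total > 0) round(100 * grid$n / total, 1) else 0.0
  types <- c(FEATURE_TYPES, "intergenic")
  tl <- strsplit(catalog$feature_types, ",", fixed = TRUE)
  ntype <- vapply(types, function(ty)
    sum(vapply(tl, function(x) ty %in% x, logical(1))), integer(1))
  by_type <- data.frame(type = types, n = ntype,
                        share_pct = if (total > 0)
                          round(100 * ntype / total, 1) else 0.0,
                        stringsAsFactors = FALSE)
  structure(list(total = total, by_category = grid, by_type = by_type,
                 empty = total == 0L),
            class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("catalog_summary:", x$total, "mitosRNAs\n")
  print(x$by_category, row.names = FALSE)
  cat("feature types:\n")
  print(x$by_type, row.names = FALSE)
  invisible(x)
}

#' Feature-type enrichment against genome composition
#'
#' Compares the fraction of cataloged sequences annotating to each
#' feature type with the fraction of the genome covered by that type
#' (bases in at least one feature of the type / genome length), via a
#' two-sided exact binomial test per type with Benjamini-Hochberg
#' correction across types.
#'
#' @param summary A `catalog_summary` (from [summarize_catalog()]).
#' @param genome A [genome_annotation()].
#' @return `data.frame`: `type`, `observed`, `observed_frac`,
#'   `genome_frac`, `ratio`, `p`, `padj`.
#' @export
feature_enrichment <- function(summary, genome) {
  stopifnot(inherits(summary, "catalog_summary"))
  if (summary$empty) stop("cannot compute enrichment for an empty subset")
  L <- genome_length(genome)
  covered <- function(type) {
    f <- genome$features[genome$features$type == type, , drop = FALSE]
    if (nrow(f) == 0L) return(0L)
    pos <- logical(L)
    for (i in seq_len(nrow(f))) {
      for (p in .circ_pieces(f$start[i], f$end[i], L)) {
        pos[(p[1] + 1L):p[2]] <- TRUE
      }
    }
    sum(pos)
  }
  base_cov <- vapply(FEATURE_TYPES, covered, integer(1))
  any_cov <- {
    pos <- logical(L)
    for (i in seq_len(nrow(genome$features))) {
      for (p in .circ_pieces(genome$features$start[i],
                             genome$features$end[i], L)) {
        pos[(p[1] + 1L):p[2]] <- TRUE
      }
    }
    pos
  }
  gfrac <- c(base_cov, intergenic = sum(!any_cov)) / L
  bt <- summary$by_type
  n <- summary$total
  res <- data.frame(type = bt$type, observed = bt$n,
                    observed_frac = bt$n / n,
                    genome_frac = as.numeric(gfrac[bt$type]),
                    stringsAsFactors = FALSE)
  res$ratio <- ifelse(res$genome_frac > 0,
                      res$observed_frac / res$genome_frac, NA_real_)
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    gp <- res$genome_frac[i]
    if (gp <= 0 || gp >= 1) return(NA_real_)
    stats::binom.test(res$observed[i], n, p = gp,
                      alternative = "two.sided")$p.value
  }, numeric(1))
  res$padj <- bh_adjust(res$p)
  res
}
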