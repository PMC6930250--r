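#' Circular mitochondrial genome with typed, stranded features
#'
#' Container for a heavy-strand reference sequence plus its feature
#' annotation. The heavy strand is the forward strand of the reference
#' FASTA; the light strand is its reverse complement. Coordinates are
#' 0-based half-open internally; features spanning the origin of the
#' circle are stored wrapped, with `end > nchar(sequence)`, and
#' interpreted modulo the genome length.
#'
#' @param sequence Single heavy-strand DNA string over `{A,C,G,T}`.
#' @param features `data.frame` with columns `id`, `type` (one of
#'   `tRNA`, `rRNA`, `mRNA`, `D-loop`, `origin`), `start`, `end`
#'   (0-based half-open), `strand` (`"heavy"` or `"light"`), `name`.
#' @param circular Logical; treat the sequence as circular (default).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(sequence, features, circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is_dna(sequence)) {
    stop("genome sequence must contain only A, C, G, T")
  }
  L <- nchar(sequence)
  req <- c("id", "type", "start", "end", "strand", "name")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  features <- as.data.frame(features)[, req]
  if (anyDuplicated(features$id)) stop("duplicate feature ids")
  if (!all(features$type %in% FEATURE_TYPES)) {
    stop("feature types must be one of: ", paste(FEATURE_TYPES, collapse = ", "))
  }
  if (!all(features$strand %in% c("heavy", "light"))) {
    stop("feature strand must be 'heavy' or 'light'")
  }
  bad <- features$start < 0 | features$start >= L | features$end <= features$start
  if (any(bad)) stop("feature coordinates out of range: ",
                     paste(features$id[bad], collapse = ", "))
  if (!circular && any(features$end > L)) {
    stop("wrapped features require a circular genome")
  }
  structure(
    list(sequence = sequence, features = features, circular = circular),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d nt (%s), %d features\n",
              nchar(x$sequence), if (x$circular) "circular" else "linear",
              nrow(x$features)))
  print(table(x$features$type))
  invisible(x)
}

#' @rdname genome_annotation
#' @param genome A `genome_annotation`.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

# substring of the heavy strand, 0-based half-open, wrapping the origin
genome_substr <- function(genome, start, end) {
  L <- genome_length(genome)
  stopifnot(end > start)
  if (end <= L) return(substr(genome$sequence, start + 1L, end))
  if (!genome$circular) stop("interval beyond a linear genome")
  paste0(substr(genome$sequence, start + 1L, L),
         substr(genome$sequence, 1L, end - L))
}

# heavy-strand sequence of a feature in its own 5'->3' orientation
feature_sequence <- function(genome, feature_id) {
  f <- genome$features[genome$features$id == feature_id, ]
  if (nrow(f) != 1L) stop("unknown feature id: ", feature_id)
  s <- genome_substr(genome, f$start, f$end)
  if (f$strand == "light") revcomp(s) else s
}

#' Write a genome and its annotation to FASTA + GFF3
#'
#' GFF3 uses 1-based closed coordinates; the conversion from the internal
#' 0-based half-open convention happens here. Heavy strand maps to `+`,
#' light to `-`.
#'
#' @param genome A `genome_annotation`.
#' @param fasta_path,gff_path Output file paths.
#' @param seqname Sequence name used in both files.
#' @return Invisibly, a list of the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff_path, seqname = "chrM") {
  seq <- Biostrings::DNAStringSet(genome$sequence)
  names(seq) <- seqname
  Biostrings::writeXStringSet(seq, fasta_path)
  f <- genome$features
  L <- genome_length(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = ifelse(f$strand == "heavy", "+", "-")
  )
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$ID <- f$id
  S4Vectors::mcols(gr)$Name <- f$name
  GenomeInfoDb_ok <- requireNamespace("GenomeInfoDb", quietly = TRUE)
  if (GenomeInfoDb_ok) {
    # record circularity so round-trips keep the convention
    sl <- max(L, max(f$end))
    GenomeInfoDb::seqlengths(gr) <- sl
    GenomeInfoDb::isCircular(gr) <- genome$circular
  }
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(list(fasta = fasta_path, gff = gff_path))
}

#' Read a genome and its annotation from FASTA + GFF3
#'
#' @param fasta_path,gff_path Input file paths.
#' @param circular Logical; whether the genome is circular.
#' @return A `genome_annotation`.
#' @export
read_genome <- function(fasta_path, gff_path, circular = TRUE) {
  seq <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seq) < 1L) stop("empty genome FASTA: ", fasta_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    paste0("feat", seq_along(gr))
  nm <- if ("Name" %in% names(mc)) as.character(mc$Name) else ids
  features <- data.frame(
    id = ids,
    type = as.character(mc$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                    "light", "heavy"),
    name = nm,
    stringsAsFactors = FALSE
  )
  genome_annotation(as.character(seq[[1]]), features, circular = circular)
}
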