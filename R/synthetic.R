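#' Feature specification for toy genome construction
#'
#' Describes one class of features to place on the toy mitochondrial
#' genome: how many, how long, and what fraction fall on the light
#' strand.
#'
#' @param type One of `tRNA`, `rRNA`, `mRNA`, `D-loop`, `origin`.
#' @param count Number of features of this class (>= 0).
#' @param length_range Integer length interval in nt; tRNA-class toy
#'   features must be at least 30 nt so that 15-27 nt fragments with end
#'   jitter fit inside them.
#' @param light_frac Fraction of the features placed on the light strand.
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(type, count, length_range, light_frac = 0) {
  stopifnot(type %in% FEATURE_TYPES, count >= 0,
            length(length_range) == 2L, all(length_range >= 1),
            length_range[1] <= length_range[2],
            light_frac >= 0, light_frac <= 1)
  if (type == "tRNA" && length_range[1] < 30) {
    stop("toy tRNA features must be >= 30 nt")
  }
  structure(list(type = type, count = as.integer(count),
                 length_range = as.integer(length_range),
                 light_frac = light_frac),
            class = "feature_spec")
}

#' Default toy-genome composition
#'
#' A miniature version of a vertebrate mitochondrial genome: a handful of
#' tRNAs (some on the light strand, as in real mt genomes), two rRNAs,
#' a few mRNAs, one control region (D-loop) and one light-strand
#' replication origin.
#'
#' @return List of [feature_spec()]s.
#' @export
default_feature_specs <- function() {
  list(
    feature_spec("tRNA", 5, c(65, 75), light_frac = 0.2),
    feature_spec("rRNA", 2, c(120, 160)),
    feature_spec("mRNA", 3, c(180, 250)),
    feature_spec("D-loop", 1, c(100, 140)),
    feature_spec("origin", 1, c(25, 35))
  )
}

# toy tRNA names; the first is tRNA-cys, the anoxia-responsive fragment
# donor of interest
.trna_names <- c("tRNA-cys", "tRNA-ser", "tRNA-his", "tRNA-met", "tRNA-leu",
                 "tRNA-gly", "tRNA-ala", "tRNA-val")

#' Generate a toy circular mitochondrial genome
#'
#' Draws a random heavy-strand sequence and places the requested features
#' non-overlapping, separated by intergenic gaps, deterministically for a
#' given seed.
#'
#' @param seed Integer RNG seed.
#' @param length Genome length in nt.
#' @param specs List of [feature_spec()]s.
#' @return A [genome_annotation()].
#' @export
#' @examples
#' g <- make_toy_genome(seed = 1, length = 2000)
#' g
make_toy_genome <- function(seed = 1L, length = 2000L,
                            specs = default_feature_specs()) {
  set.seed(seed)
  length <- as.integer(length)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  rows <- list()
  counters <- stats::setNames(integer(length(FEATURE_TYPES)), FEATURE_TYPES)
  for (sp in specs) {
    if (sp$count == 0L) next
    lens <- sample(seq(sp$length_range[1], sp$length_range[2]),
                   sp$count, replace = TRUE)
    on_light <- stats::runif(sp$count) < sp$light_frac
    for (i in seq_len(sp$count)) {
      counters[sp$type] <- counters[sp$type] + 1L
      n <- counters[sp$type]
      nm <- if (sp$type == "tRNA" && n <= length(.trna_names))
        .trna_names[n] else paste0(sp$type, "-", n)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(gsub("-", "", sp$type), n),
        type = sp$type, start = NA_integer_, end = NA_integer_,
        strand = if (on_light[i]) "light" else "heavy",
        name = nm, len = lens[i], stringsAsFactors = FALSE)
    }
  }
  feats <- do.call(rbind, rows)
  total <- sum(feats$len)
  n_gaps <- nrow(feats)  # one gap after each feature keeps >= 1 intergenic run
  slack <- length - total - n_gaps
  if (slack < 0) {
    stop("feature placement infeasible: ", total, " nt of features (+",
         n_gaps, " minimum gap nt) exceed genome length ", length)
  }
  # distribute the remaining slack over the gaps at random
  extra <- if (slack > 0) as.vector(stats::rmultinom(1, slack, rep(1, n_gaps))) else
    rep(0L, n_gaps)
  gaps <- 1L + extra
  pos <- 0L
  for (i in seq_len(nrow(feats))) {
    feats$start[i] <- pos
    feats$end[i] <- pos + feats$len[i]
    pos <- feats$end[i] + gaps[i]
  }
  feats$len <- NULL
  genome_annotation(seq, feats, circular = TRUE)
}

#' Specification of a planted tRNA fragment
#'
#' Defines one fragment family to plant into simulated libraries: its
#' parent feature, which end of the mature RNA it retains, the shared
#' core, end jitter (which generates 1-5 sequence variants), and the
#' expression model (negative-binomial mean/dispersion with per-treatment
#' log2 fold changes scaled per stage).
#'
#' @param parent Feature id in the toy genome.
#' @param end_class `"five_prime"`, `"three_prime"` or `"internal"`.
#' @param core_length Length in nt of the invariant core (default 17,
#'   the length regime of the anoxia-induced 3' tRNA-cys core).
#' @param end_jitter Maximum nt of end variation; produces
#'   `end_jitter + 1` variants (capped at 5).
#' @param base_mean Expected normalized count at `t0`.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2);
#'   0 means Poisson.
#' @param lfc Named numeric of true log2 fold changes vs `t0`, names in
#'   `EA`, `LA`, `ER`, `LR`; missing treatments get 0.
#' @param stage_scale Named numeric multiplier on `lfc` per stage;
#'   the default emulates an anoxia response that is robust in WS36,
#'   muted in WS40, weak in WS42 and absent in dormant D2 embryos.
#' @param offset For `internal` fragments, nt from the feature 5' end to
#'   the core start (default: centered); lets several distinct internal
#'   fragments tile one feature.
#' @return A `planted_fragment` list.
#' @export
planted_fragment <- function(parent, end_class = "three_prime",
                             core_length = 17L, end_jitter = 2L,
                             base_mean = 200, dispersion = 0.1,
                             lfc = c(LA = 4),
                             stage_scale = c(D2 = 0, WS36 = 1,
                                             WS40 = 0.5, WS42 = 0.25),
                             offset = NULL) {
  stopifnot(end_class %in% c("five_prime", "three_prime", "internal"),
            core_length >= 1, end_jitter >= 0, base_mean >= 0,
            dispersion >= 0)
  full <- stats::setNames(rep(0, 4), c("EA", "LA", "ER", "LR"))
  full[names(lfc)] <- lfc
  structure(list(parent = parent, end_class = end_class,
                 core_length = as.integer(core_length),
                 end_jitter = as.integer(end_jitter),
                 base_mean = base_mean, dispersion = dispersion,
                 lfc = full, stage_scale = stage_scale,
                 offset = if (!is.null(offset)) as.integer(offset)),
            class = "planted_fragment")
}

#' Expand planted fragments into a ground-truth table
#'
#' Each fragment becomes 1-5 sequence variants differing by end jitter;
#' variants of a `three_prime` fragment all end exactly at the parent
#' feature's 3' end and therefore share the fragment's core, and
#' symmetrically for `five_prime`. The truth table carries the expected
#' normalized count of every variant in every stage x treatment cell, so
#' downstream recovery (differential expression, end class, conserved
#' core) is decidable from it alone.
#'
#' @param genome A [genome_annotation()].
#' @param fragments List of [planted_fragment()]s.
#' @param seed Integer seed (reserved; variant layout is deterministic).
#' @param stages,treatments Design labels.
#' @return `data.frame` with one row per variant x stage x treatment:
#'   `variant_id`, `fragment_id`, `parent`, `end_class`, `sequence`,
#'   `start`, `end`, `strand`, `core`, `stage`, `treatment`, `mean`,
#'   `dispersion`, `true_lfc`.
#' @export
plant_fragments <- function(genome, fragments, seed = 1L,
                            stages = STAGES, treatments = TREATMENTS) {
  set.seed(seed)
  out <- list()
  for (fi in seq_along(fragments)) {
    fr <- fragments[[fi]]
    f <- genome$features[genome$features$id == fr$parent, ]
    if (nrow(f) != 1L) stop("unknown feature id: ", fr$parent)
    flen <- f$end - f$start
    nv <- min(5L, fr$end_jitter + 1L)
    maxlen <- fr$core_length + (nv - 1L)
    if (maxlen > flen) stop("fragment does not fit inside feature ", fr$parent)
    if (fr$end_class == "internal" && !is.null(fr$offset) &&
        fr$offset + maxlen > flen) {
      stop("internal fragment offset overruns feature ", fr$parent)
    }
    if (fr$core_length < 15L || maxlen > 27L) {
      stop("planted variant lengths must stay within 15-27 nt")
    }
    vars <- lapply(seq_len(nv) - 1L, function(j) {
      # heavy-strand genome interval of variant j, per end class, in the
      # feature's own orientation
      if (fr$end_class == "three_prime") {
        if (f$strand == "heavy") {
          gs <- f$end - (fr$core_length + j); ge <- f$end
        } else {
          gs <- f$start; ge <- f$start + fr$core_length + j
        }
      } else if (fr$end_class == "five_prime") {
        if (f$strand == "heavy") {
          gs <- f$start; ge <- f$start + fr$core_length + j
        } else {
          gs <- f$end - (fr$core_length + j); ge <- f$end
        }
      } else {  # internal: fixed length, sliding start
        base_off <- if (!is.null(fr$offset)) fr$offset else
          (flen - fr$core_length) %/% 2L
        off <- base_off + j
        if (f$strand == "heavy") {
          gs <- f$start + off; ge <- gs + fr$core_length
        } else {
          ge <- f$end - off; gs <- ge - fr$core_length
        }
      }
      s <- genome_substr(genome, gs, ge)
      if (f$strand == "light") s <- revcomp(s)
      list(start = gs, end = ge, seq = s)
    })
    # the shared core in read orientation
    core <- switch(fr$end_class,
      three_prime = substr(vars[[1]]$seq,
                           nchar(vars[[1]]$seq) - fr$core_length + 1L,
                           nchar(vars[[1]]$seq)),
      five_prime = substr(vars[[1]]$seq, 1L, fr$core_length),
      internal = vars[[1]]$seq)
    grid <- expand.grid(stage = stages, treatment = treatments,
                        stringsAsFactors = FALSE)
    ss <- fr$stage_scale
    for (vi in seq_along(vars)) {
      v <- vars[[vi]]
      lfc_t <- ifelse(grid$treatment == "t0", 0,
                      fr$lfc[grid$treatment] *
                        ifelse(grid$stage %in% names(ss), ss[grid$stage], 1))
      out[[length(out) + 1L]] <- data.frame(
        variant_id = sprintf("frag%d_v%d", fi, vi),
        fragment_id = sprintf("frag%d", fi),
        parent = fr$parent, end_class = fr$end_class,
        sequence = v$seq, start = v$start, end = v$end,
        strand = f$strand, core = core,
        stage = grid$stage, treatment = grid$treatment,
        mean = fr$base_mean * 2^lfc_t,
        dispersion = fr$dispersion, true_lfc = lfc_t,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulation design
#'
#' @param stages,treatments Ordered design labels; treatments must be the
#'   five-cell anoxia/recovery design `t0, EA, LA, ER, LR`.
#' @param replicates Libraries per stage x treatment cell.
#' @param adapter 3' adapter sequence appended to every simulated read.
#' @param background Decoy (non-mitochondrial) reads per library.
#' @param read_length Fixed sequencer read length; insert + adapter is
#'   truncated to this length.
#' @param noise `"nb"` for negative-binomial sampling, `"exact"` to
#'   bypass sampling and emit `round(mean)` copies (debug mode).
#' @param depth_range Per-library depth factors are drawn uniformly from
#'   this interval, exercising size-factor normalization.
#' @param seed Integer seed.
#' @return A `sim_design` list.
#' @export
sim_design <- function(stages = STAGES, treatments = TREATMENTS,
                       replicates = 3L, adapter = "TGGAATTCTCGG",
                       background = 200L, read_length = 34L,
                       noise = c("nb", "exact"),
                       depth_range = c(0.75, 1.25), seed = 1L) {
  noise <- match.arg(noise)
  if (!identical(sort(treatments), sort(TREATMENTS))) {
    stop("treatments must be exactly: ", paste(TREATMENTS, collapse = ", "))
  }
  stopifnot(replicates >= 1, background >= 0, is_dna(adapter))
  structure(list(stages = stages, treatments = treatments,
                 replicates = as.integer(replicates), adapter = adapter,
                 background = as.integer(background),
                 read_length = as.integer(read_length), noise = noise,
                 depth_range = depth_range, seed = as.integer(seed)),
            class = "sim_design")
}

# library ids in design order
library_ids <- function(design) {
  grid <- expand.grid(rep = seq_len(design$replicates),
                      treatment = design$treatments,
                      stage = design$stages, stringsAsFactors = FALSE)
  data.frame(library = sprintf("%s_%s_r%d", grid$stage, grid$treatment,
                               grid$rep),
             stage = grid$stage, treatment = grid$treatment,
             replicate = grid$rep, stringsAsFactors = FALSE)
}

# one NB draw per (mean, alpha); alpha = 0 -> Poisson
rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate the variant count matrix for a design
#'
#' Draws raw counts for every planted variant in every library from the
#' truth table's NB model, scaled by the library's depth factor.
#'
#' @param truth Truth table from [plant_fragments()].
#' @param design A [sim_design()].
#' @return List with `counts` (variants x libraries integer matrix, row
#'   names are variant sequences), `sample_sheet` and `depth_factors`.
#' @export
simulate_counts <- function(truth, design) {
  set.seed(design$seed)
  sheet <- library_ids(design)
  depth <- stats::runif(nrow(sheet), design$depth_range[1],
                        design$depth_range[2])
  names(depth) <- sheet$library
  key <- unique(truth[, c("variant_id", "sequence")])
  counts <- matrix(0L, nrow = nrow(key), ncol = nrow(sheet),
                   dimnames = list(key$sequence, sheet$library))
  for (j in seq_len(nrow(sheet))) {
    cell <- truth[truth$stage == sheet$stage[j] &
                    truth$treatment == sheet$treatment[j], ]
    cell <- cell[match(key$variant_id, cell$variant_id), ]
    mu <- cell$mean * depth[j]
    counts[, j] <- if (design$noise == "exact") as.integer(round(mu)) else
      vapply(seq_len(nrow(cell)),
             function(i) rnb(1L, mu[i], cell$dispersion[i]), numeric(1))
  }
  list(counts = counts, sample_sheet = sheet, depth_factors = depth)
}

#' Random decoy (non-mitochondrial) contig
#'
#' @param seed Integer seed.
#' @param length Contig length in nt (default 5 kb).
#' @return Character DNA string.
#' @export
make_decoy <- function(seed = 99L, length = 5000L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Simulate small-RNA-seq libraries as FASTQ files
#'
#' Every library receives NB-sampled copies of the planted variants plus
#' uniform background reads drawn from a decoy contig; each read gets the
#' 3' adapter appended and is truncated to the design read length.
#' Output is deterministic for a fixed design seed.
#'
#' @param genome A [genome_annotation()].
#' @param truth Truth table from [plant_fragments()].
#' @param design A [sim_design()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the sample sheet (including file
#'   paths), truth-table path, genome FASTA/GFF3 paths and decoy path.
#' @export
simulate_libraries <- function(genome, truth, design, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cm <- simulate_counts(truth, design)
  decoy <- make_decoy(seed = design$seed + 7L)
  set.seed(design$seed + 13L)
  # background reads come from a fixed pool of decoy fragments, so the
  # abundant ones survive the low-abundance filter and exercise the
  # non-mitochondrial branch of the catalog
  pool_len <- sample(15:27, 25L, replace = TRUE)
  pool_pos <- vapply(pool_len, function(l)
    sample.int(nchar(decoy) - l + 1L, 1L), integer(1))
  pool <- substring(decoy, pool_pos, pool_pos + pool_len - 1L)
  sheet <- cm$sample_sheet
  sheet$file <- file.path(out_dir, paste0(sheet$library, ".fastq"))
  for (j in seq_len(nrow(sheet))) {
    inserts <- rep(rownames(cm$counts), times = cm$counts[, j])
    if (design$background > 0) {
      inserts <- c(inserts, sample(pool, design$background,
                                   replace = TRUE))
    }
    reads <- substr(paste0(inserts, design$adapter), 1L, design$read_length)
    rs <- Biostrings::DNAStringSet(reads)
    names(rs) <- sprintf("%s:%06d", sheet$library[j], seq_along(rs))
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(rs, sheet$file[j], format = "fastq",
                                qualities = qual)
  }
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gpaths <- write_genome(genome, file.path(out_dir, "mito.fasta"),
                         file.path(out_dir, "mito.gff3"))
  dset <- Biostrings::DNAStringSet(decoy)
  names(dset) <- "decoy"
  decoy_path <- file.path(out_dir, "decoy.fasta")
  Biostrings::writeXStringSet(dset, decoy_path)
  invisible(list(sample_sheet = sheet, sample_sheet_path = sheet_path,
                 truth_path = truth_path, genome_fasta = gpaths$fasta,
                 genome_gff = gpaths$gff, decoy_path = decoy_path,
                 depth_factors = cm$depth_factors))
}
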