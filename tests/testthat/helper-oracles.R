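# Independent oracles and fixtures used across the suite. Every oracle is a
# deliberately naive re-derivation, kept separate from the package's own
# code paths.

# naive O(n*m) scan of every rotation of the doubled genome, both strands
naive_align_oracle <- function(seq, genome) {
  L <- nchar(genome$sequence)
  m <- nchar(seq)
  doubled <- if (genome$circular)
    paste0(genome$sequence, substr(genome$sequence, 1, m - 1)) else
      genome$sequence
  starts <- seq_len(min(L, nchar(doubled) - m + 1))
  win <- substring(doubled, starts, starts + m - 1)
  hv <- which(win == seq) - 1L
  lt <- which(win == revcomp(seq)) - 1L
  out <- data.frame(start = c(hv, lt), end = c(hv, lt) + m,
                    strand = rep(c("heavy", "light"),
                                 c(length(hv), length(lt))))
  out[order(out$start, match(out$strand, c("heavy", "light"))), ,
      drop = FALSE]
}

# textbook BH: padj_i = min over {j : p_(j) >= p_i} of m * p_(j) / j
bh_oracle <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  srt <- sort(pv)
  adj <- vapply(pv, function(pi) {
    j <- which(srt >= pi - 1e-12)
    min(1, min(m * srt[j] / j))
  }, numeric(1))
  out <- rep(NA_real_, length(p))
  out[ok] <- adj
  out
}

all_substrings <- function(s) {
  n <- nchar(s)
  unique(unlist(lapply(seq_len(n), function(l)
    substring(s, 1:(n - l + 1), l:n))))
}

# brute-force longest common substring over a set, by set intersection
lcs_oracle <- function(seqs) {
  common <- Reduce(intersect, lapply(seqs, all_substrings))
  if (length(common) == 0) return("")
  common[nchar(common) == max(nchar(common))]
}

# hand median-of-ratios on a matrix with all-positive rows available
mor_oracle <- function(m) {
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  keep <- is.finite(geo) & geo > 0
  apply(m[keep, , drop = FALSE], 2, function(col)
    median(col / geo[keep]))
}

# per-base feature membership of the genome (circular)
base_membership <- function(genome) {
  L <- genome_length(genome)
  mem <- vector("list", L)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    idx <- (seq(f$start[i], f$end[i] - 1L) %% L) + 1L
    for (b in idx) mem[[b]] <- c(mem[[b]], f$id[i])
  }
  mem
}

# small hand-built genome: 120 nt, two adjacent tRNAs and one light mRNA
tiny_genome <- function() {
  set.seed(404)
  seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  feats <- data.frame(
    id = c("tA", "tB", "m1"),
    type = c("tRNA", "tRNA", "mRNA"),
    start = c(10L, 40L, 80L),
    end = c(40L, 70L, 115L),
    strand = c("heavy", "heavy", "light"),
    name = c("tRNA-a", "tRNA-b", "mRNA-1"))
  genome_annotation(seq, feats, circular = TRUE)
}

# catalog fixture reproducing the published DE-subset category counts:
# strand x overlap-class 140/52/15/1 with tRNA column 33/39/7/1
table1_de_catalog <- function() {
  row <- function(n, strand, cls, types)
    data.frame(seq_id = sprintf("s%s%d", substr(strand, 1, 1) , seq_len(n)),
               mito = TRUE, strand = strand, overlap_class = cls,
               feature_types = types, stringsAsFactors = FALSE)
  rbind(
    row(33, "heavy", "single_feature", "tRNA"),
    row(42, "heavy", "single_feature", "rRNA"),
    row(65, "heavy", "single_feature", "mRNA"),
    row(39, "light", "single_feature", "tRNA"),
    row(5, "light", "single_feature", "mRNA"),
    row(4, "light", "single_feature", "D-loop"),
    row(4, "light", "single_feature", "origin"),
    row(7, "heavy", "overlapping_features", "tRNA,mRNA"),
    row(8, "heavy", "overlapping_features", "rRNA,mRNA"),
    row(1, "light", "overlapping_features", "tRNA,rRNA"))
}

# full-catalog category counts: 75008 / 9031 / 3484 / 761 of 88284
table1_full_catalog <- function() {
  cat_row <- function(n, strand, cls)
    data.frame(mito = TRUE, strand = strand, overlap_class = cls,
               feature_types = if (cls == "single_feature") "mRNA" else
                 "tRNA,mRNA", stringsAsFactors = FALSE)[rep(1, n), ]
  rbind(cat_row(75008, "heavy", "single_feature"),
        cat_row(9031, "light", "single_feature"),
        cat_row(3484, "heavy", "overlapping_features"),
        cat_row(761, "light", "overlapping_features"))
}

# the parameter-recovery world: planted 3' tRNA fragments (|log2FC| = 4,
# mean 200, alpha = 0.1) among null internal fragments at the same depth
recovery_fragments <- function(genome, null_lfc = 0) {
  trnas <- genome$features$id[genome$features$type == "tRNA"]
  de <- lapply(trnas, function(id)
    planted_fragment(id, "three_prime", base_mean = 200,
                     dispersion = 0.1, lfc = c(LA = 4),
                     stage_scale = c(WS36 = 1)))
  others <- genome$features[genome$features$type %in% c("mRNA", "rRNA"), ]
  nulls <- list()
  for (i in seq_len(nrow(others))) {
    flen <- others$end[i] - others$start[i]
    for (o in seq(0L, flen - 18L, by = 20L)) {
      nulls[[length(nulls) + 1L]] <-
        planted_fragment(others$id[i], "internal", end_jitter = 0L,
                         base_mean = 200, dispersion = 0.1,
                         lfc = c(LA = null_lfc),
                         stage_scale = c(WS36 = 1), offset = o)
    }
  }
  c(de, nulls)
}
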