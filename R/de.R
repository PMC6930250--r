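#' Moment estimate of negative-binomial dispersion
#'
#' Per-sequence method-of-moments estimator on normalized counts:
#' `alpha = max(0, (pooled within-group variance - pooled mean) /
#' pooled mean^2)` under the NB parameterization
#' `variance = mu + alpha * mu^2`. Rows with all-zero counts get `NA`
#' and are excluded from testing.
#'
#' @param norm Normalized count matrix.
#' @param groups Factor (or character) of length `ncol(norm)` giving the
#'   experimental group of each library; at least one group needs >= 2
#'   replicates.
#' @return Named numeric vector of dispersions (>= 0 or `NA`).
#' @export
nb_dispersion <- function(norm, groups) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(norm))
  sizes <- table(groups)
  if (!any(sizes >= 2)) stop("need >= 2 replicates in >= 1 group")
  use <- groups %in% names(sizes)[sizes >= 2]
  x <- norm[, use, drop = FALSE]
  g <- droplevels(groups[use])
  n <- ncol(x)
  k <- nlevels(g)
  gm <- t(rowsum(t(x), g) / as.vector(table(g)))  # group means
  ss <- rowSums((x - gm[, as.integer(g), drop = FALSE])^2)
  v <- ss / (n - k)
  mu <- rowMeans(x)
  alpha <- pmax(0, (v - mu) / mu^2)
  alpha[mu == 0] <- NA_real_
  alpha
}

#' Negative-binomial Wald test for one contrast
#'
#' Per-sequence log2 fold change between two groups of normalized
#' counts, with a pseudocount, and a Wald p-value from the NB
#' delta-method standard error:
#' `SE(log2FC)^2 = (1/ln 2)^2 * sum_g (mu_g + alpha mu_g^2) / n_g /
#' (mu_g + c)^2`.
#'
#' @param norm Normalized count matrix.
#' @param group_a,group_b Column indices (or names) of the reference and
#'   treatment libraries.
#' @param alpha Per-sequence dispersion from [nb_dispersion()].
#' @param pseudocount Added to both means before the log ratio
#'   (default 0.5 normalized counts).
#' @return `data.frame`: `mean_a`, `mean_b`, `log2fc`, `se`, `stat`,
#'   `pvalue`. With < 2 replicates on either side `pvalue` is `NA` but
#'   `log2fc` is still reported.
#' @export
wald_test <- function(norm, group_a, group_b, alpha,
                      pseudocount = 0.5) {
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  c0 <- pseudocount
  lfc <- log2((mb + c0) / (ma + c0))
  va <- (ma + alpha * ma^2) / na
  vb <- (mb + alpha * mb^2) / nb
  se <- sqrt(va / (ma + c0)^2 + vb / (mb + c0)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, Inf * sign(lfc)))
  p <- 2 * stats::pnorm(-abs(stat))
  if (na < 2L || nb < 2L) p[] <- NA_real_
  p[is.na(alpha)] <- NA_real_
  data.frame(mean_a = ma, mean_b = mb, log2fc = lfc, se = se,
             stat = stat, pvalue = p, row.names = rownames(norm))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement; `NA`s are passed through
#' and do not count toward the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  stopifnot(all(pv >= 0 & pv <= 1))
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[o]))
  out[ok[o]] <- adj
  out
}

#' Per-stage differential expression across the treatment design
#'
#' For one embryonic stage, tests every non-reference treatment against
#' the reference (`t0`) with the NB Wald test, using a dispersion pooled
#' across the stage's treatment groups, and BH-adjusts p-values within
#' each contrast. `baseMean` is the mean normalized count across all of
#' the stage's samples.
#'
#' @param norm Normalized count matrix.
#' @param sheet Sample sheet `data.frame` with columns `library`,
#'   `stage`, `treatment` matching `colnames(norm)`.
#' @param stage Stage label to analyse.
#' @param reference Reference treatment (default `"t0"`).
#' @param pseudocount Pseudocount for fold changes.
#' @return Long `data.frame`: `seq_id`, `stage`, `contrast`, `baseMean`,
#'   `log2fc`, `pvalue`, `padj`.
#' @export
de_stage <- function(norm, sheet, stage, reference = "t0",
                     pseudocount = 0.5) {
  sheet <- sheet[sheet$stage == stage, , drop = FALSE]
  if (nrow(sheet) == 0L) stop("unknown stage: ", stage)
  libs <- intersect(colnames(norm), sheet$library)
  sheet <- sheet[match(libs, sheet$library), , drop = FALSE]
  x <- norm[, libs, drop = FALSE]
  alpha <- nb_dispersion(x, sheet$treatment)
  base_mean <- rowMeans(x)
  trts <- setdiff(unique(sheet$treatment), reference)
  out <- lapply(trts, function(tr) {
    wt <- wald_test(x, sheet$library[sheet$treatment == reference],
                    sheet$library[sheet$treatment == tr], alpha,
                    pseudocount)
    data.frame(seq_id = rownames(x), stage = stage,
               contrast = paste0(tr, "_vs_", reference),
               baseMean = base_mean, log2fc = wt$log2fc,
               pvalue = wt$pvalue, padj = bh_adjust(wt$pvalue),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Call differentially expressed sequences
#'
#' Applies the strict published thresholds: a sequence is flagged in a
#' stage if `baseMean > 25` and, in at least one contrast of that
#' stage, `|log2FC| > 2` with `padj < 0.01` (all inequalities strict).
#' A sequence is DE overall if flagged in at least one stage.
#'
#' @param results Long results from [de_stage()] (one or several stages
#'   row-bound together).
#' @param min_base_mean,min_abs_lfc,max_padj Thresholds (defaults 25, 2,
#'   0.01).
#' @return Named logical vector over the distinct `seq_id`s.
#' @export
call_de <- function(results, min_base_mean = 25, min_abs_lfc = 2,
                    max_padj = 0.01) {
  hit <- results$baseMean > min_base_mean &
    abs(results$log2fc) > min_abs_lfc &
    !is.na(results$padj) & results$padj < max_padj
  ids <- unique(results$seq_id)
  flags <- vapply(ids, function(s) any(hit[results$seq_id == s]),
                  logical(1))
  stats::setNames(flags, ids)
}

#' Log2 fold change relative to the row mean (heatmap values)
#'
#' `v_ij = log2((x_ij + c) / (rowmean_i + c))`, the convention used for
#' expression heatmaps: yellow above the mean, blue below.
#'
#' @param norm Normalized count matrix (may contain `NA` for missing
#'   samples, which propagate).
#' @param pseudocount Pseudocount `c` (default 0.5).
#' @return Matrix of the same shape.
#' @export
relative_log2fc_matrix <- function(norm, pseudocount = 0.5) {
  rm <- rowMeans(norm, na.rm = TRUE)
  log2(sweep(norm + pseudocount, 1L, rm + pseudocount, "/"))
}
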