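#' Pipeline configuration
#'
#' Bundles input paths and analysis parameters for [run_pipeline()].
#' All parameters default to the published analysis settings: 15-27 nt
#' size window, DE thresholds mean > 25 / |log2FC| > 2 / padj < 0.01,
#' end tolerance 2 nt, k = 3 expression clusters.
#'
#' @param sample_sheet Path to a TSV with columns `library`, `stage`,
#'   `treatment`, `file` (FASTQ/FASTA per library).
#' @param genome_fasta,genome_gff Mitochondrial reference paths.
#' @param traits Optional path to a stage-traits TSV (`stage` plus trait
#'   columns such as anoxia LT50 and metabolic rate).
#' @param out_dir Output directory.
#' @param adapter 3' adapter sequence.
#' @param min_overlap,min_len,max_len,min_total Preprocessing knobs.
#' @param min_base_mean,min_abs_lfc,max_padj DE thresholds.
#' @param tau End-class tolerance (nt).
#' @param k Number of expression clusters.
#' @param pseudocount Pseudocount for fold changes.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_sheet, genome_fasta, genome_gff,
                            out_dir, adapter, traits = NULL,
                            min_overlap = 6L, min_len = 15L,
                            max_len = 27L, min_total = 10L,
                            min_base_mean = 25, min_abs_lfc = 2,
                            max_padj = 0.01, tau = 2L, k = 3L,
                            pseudocount = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  for (p in c(sample_sheet, genome_fasta, genome_gff, traits)) {
    if (!file.exists(p)) stop_stage("config", "input file not found: ", p)
  }
  stopifnot(min_len >= 1, min_len <= max_len, min_total >= 0,
            tau >= 0, k >= 1, pseudocount >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Simulate a full synthetic input set
#'
#' Convenience wrapper over the synthetic-data module: builds the toy
#' genome, plants anoxia-responsive 3' tRNA fragments, simulates the
#' stage x treatment libraries and writes every file [run_pipeline()]
#' needs.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param design A [sim_design()].
#' @param genome Optional [genome_annotation()]; built from `seed` if
#'   missing.
#' @param fragments Optional list of [planted_fragment()]s; the default
#'   plants one anoxia-induced 3' family and one recovery-induced 5'
#'   family on the first two tRNAs.
#' @return The [simulate_libraries()] manifest (invisibly), plus the
#'   genome and truth table.
#' @export
simulate_inputs <- function(out_dir, seed = 1L,
                            design = sim_design(seed = seed),
                            genome = NULL, fragments = NULL) {
  if (is.null(genome)) genome <- make_toy_genome(seed = seed)
  if (is.null(fragments)) {
    trnas <- genome$features$id[genome$features$type == "tRNA"]
    fragments <- list(
      planted_fragment(trnas[1], "three_prime", base_mean = 200,
                       lfc = c(LA = 4)),
      planted_fragment(trnas[2], "five_prime", base_mean = 100,
                       lfc = c(ER = 3, LR = 2))
    )
  }
  truth <- plant_fragments(genome, fragments, seed = seed,
                           stages = design$stages,
                           treatments = design$treatments)
  manifest <- simulate_libraries(genome, truth, design, out_dir)
  invisible(c(manifest, list(genome = genome, truth = truth)))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full mitosRNA analysis
#'
#' Executes preprocess -> catalog -> differential expression -> fragment
#' profiling and writes every module's tables plus a JSON run summary.
#' Any stage failure aborts with a stage-tagged error and removes
#' partial outputs. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`counts`,
#'   `catalog`, `summary`, `de`, `de_flags`, `clusters`, `probe`,
#'   `fractions`, `output_files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_stage(name, conditionMessage(e)))
  }

  sheet <- stage("input", {
    s <- utils::read.delim(config$sample_sheet, stringsAsFactors = FALSE)
    req <- c("library", "stage", "treatment", "file")
    if (!all(req %in% names(s))) stop("sample sheet needs columns: ",
                                      paste(req, collapse = ", "))
    # resolve library paths relative to the sheet's directory
    rel <- !file.exists(s$file)
    s$file[rel] <- file.path(dirname(config$sample_sheet), s$file[rel])
    if (!all(file.exists(s$file))) stop("missing library file(s)")
    s
  })
  genome <- stage("input",
                  read_genome(config$genome_fasta, config$genome_gff))

  pp <- stage("preprocess", preprocess_libraries(
    stats::setNames(sheet$file, sheet$library), adapter = config$adapter,
    min_overlap = config$min_overlap, min_len = config$min_len,
    max_len = config$max_len, min_total = config$min_total))
  written <- c(written,
    .write_tsv(data.frame(sequence = rownames(pp$raw), pp$raw,
                          check.names = FALSE),
               file.path(out, "counts_raw.tsv")),
    .write_tsv(data.frame(library = names(pp$size_factors),
                          size_factor = pp$size_factors),
               file.path(out, "size_factors.tsv")))

  catalog <- stage("catalog", build_catalog(pp$normalized, genome))
  summary <- stage("catalog", summarize_catalog(catalog))
  written <- c(written,
    .write_tsv(catalog, file.path(out, "catalog.tsv")),
    .write_tsv(summary$by_category, file.path(out, "summary_categories.tsv")),
    .write_tsv(summary$by_type, file.path(out, "summary_types.tsv")))

  de <- stage("diff_expression", {
    res <- lapply(unique(sheet$stage), function(st)
      de_stage(pp$normalized, sheet, st,
               pseudocount = config$pseudocount))
    do.call(rbind, res)
  })
  de_flags <- call_de(de, config$min_base_mean, config$min_abs_lfc,
                      config$max_padj)
  written <- c(written, .write_tsv(de, file.path(out, "de_results.tsv")),
    .write_tsv(data.frame(seq_id = names(de_flags), de = de_flags),
               file.path(out, "de_flags.tsv")))

  prof <- stage("trf_profile", {
    heat <- relative_log2fc_matrix(pp$normalized, config$pseudocount)
    de_ids <- names(de_flags)[de_flags]
    clusters <- if (length(de_ids) >= config$k)
      cluster_expression(heat[de_ids, , drop = FALSE], k = config$k,
                         seed = config$seed) else NULL
    # end classes of DE mitosRNAs against their primary feature
    mito_cat <- catalog[catalog$mito & catalog$seq_id %in% de_ids &
                          catalog$overlap_class == "single_feature", ,
                        drop = FALSE]
    ends <- if (nrow(mito_cat)) do.call(rbind, lapply(
      seq_len(nrow(mito_cat)), function(i) {
        fid <- mito_cat$features[i]
        f <- genome$features[genome$features$id == fid, ]
        data.frame(seq_id = mito_cat$seq_id[i], feature = fid,
                   end_class = classify_end(mito_cat$start[i],
                                            mito_cat$end[i], f,
                                            tau = config$tau),
                   stringsAsFactors = FALSE)
      })) else data.frame(seq_id = character(0), feature = character(0),
                          end_class = character(0))
    # probe core over the 3' DE variants of the most-hit feature
    probe <- NULL
    three <- ends[ends$end_class == "three_prime", , drop = FALSE]
    if (nrow(three)) {
      top_feat <- names(sort(table(three$feature), decreasing = TRUE))[1]
      probe <- find_conserved_core(three$seq_id[three$feature == top_feat])
    }
    fractions <- vapply(unique(sheet$stage), function(st) {
      t0 <- sheet$library[sheet$stage == st & sheet$treatment == "t0"]
      mitos_fraction(pp$normalized, catalog$mito, t0)
    }, numeric(1))
    list(heat = heat, clusters = clusters, ends = ends, probe = probe,
         fractions = fractions)
  })
  written <- c(written,
    .write_tsv(prof$ends, file.path(out, "end_classes.tsv")),
    .write_tsv(data.frame(stage = names(prof$fractions),
                          mitos_fraction = prof$fractions),
               file.path(out, "mitos_fraction.tsv")))
  if (!is.null(prof$clusters)) {
    written <- c(written, .write_tsv(
      data.frame(seq_id = names(prof$clusters$assignments),
                 cluster = prof$clusters$assignments),
      file.path(out, "clusters.tsv")))
  }
  if (!is.null(prof$probe)) {
    written <- c(written, .write_tsv(
      data.frame(core = prof$probe$core,
                 core_length = prof$probe$core_length,
                 probe = prof$probe$probe),
      file.path(out, "probe_report.tsv")))
  }

  corr <- NULL
  if (!is.null(config$traits)) {
    traits <- utils::read.delim(config$traits, stringsAsFactors = FALSE)
    corr <- lapply(setdiff(names(traits), "stage"), function(tr)
      c(trait = tr, trait_correlation(prof$fractions, traits, tr)))
    written <- c(written, .write_tsv(
      do.call(rbind, lapply(corr, as.data.frame)),
      file.path(out, "trait_correlation.tsv")))
  }

  run_summary <- list(
    n_libraries = nrow(sheet),
    retained_reads = as.list(pp$retained_reads),
    n_unique_sequences = nrow(pp$raw),
    n_mitosRNA = sum(catalog$mito),
    n_de = sum(de_flags),
    parameters = config[!(names(config) %in%
                            c("sample_sheet", "genome_fasta",
                              "genome_gff", "traits", "out_dir"))],
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("mitosr")))
  sp <- file.path(out, "run_summary.json")
  jsonlite::write_json(run_summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, sp)
  ok <- TRUE
  invisible(list(counts = pp, catalog = catalog, summary = summary,
                 de = de, de_flags = de_flags, heat = prof$heat,
                 clusters = prof$clusters, ends = prof$ends,
                 probe = prof$probe, fractions = prof$fractions,
                 correlations = corr, output_files = written))
}
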