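## End-to-end orchestration: simulate a synthetic study, or run the
## discovery pipeline (parse -> enumerate -> deplete -> test -> consequence
## -> cis features) on junction counts plus annotation (and optionally a
## genome). All stage outputs are plain tables; writers emit deterministic
## TSVs and a JSON run summary.

#' Generate and (optionally) write a synthetic study
#'
#' Delegates to [generate_reference()] and [simulate_counts()]; when
#' `out_dir` is given, writes `genome.fa`, `annotation.gtf`, one
#' `SJ.<sample>.out.tab` and `junctions.<sample>.tsv` per sample,
#' `design.tsv` and `truth.tsv`.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @return list with `ref` (`synth_reference`) and `sim` (`synth_counts`).
#' @export
run_simulate <- function(config, out_dir = NULL) {
  ref <- generate_reference(config)
  sim <- simulate_counts(ref)
  if (!is.null(out_dir)) write_synthetic_dataset(ref, sim, out_dir)
  list(ref = ref, sim = sim)
}

#' Run the discovery pipeline
#'
#' Stages: junction collection (introns shorter than `min_intron` dropped),
#' A5C/A3C enumeration, cassette depletion against the annotation,
#' per-contrast psi/Fisher calling, and — when a genome is supplied —
#' consequence classification and the cis-feature class comparison. Without
#' a genome the last two stages are skipped with explicit status.
#'
#' @param counts a `junction_counts` data.frame over all samples.
#' @param design a [sample_design()].
#' @param exons exon annotation table.
#' @param genome optional `DNAStringSet`.
#' @param alpha,min_dpsi,min_reads calling thresholds (see
#'   [call_regulated()]).
#' @param nmd_rule_nt NMD boundary-rule distance.
#' @param min_intron minimum intron length (nt).
#' @param class3_size,class3_seed control-class sampling (see
#'   [build_class_sets()]).
#' @param pwm donor frequency matrix for strength scoring.
#' @param cassette_rule depletion rule (see [deplete_cassette()]).
#' @param use_fdr gate regulation on BH q-values instead of raw p.
#' @param out_dir optional output directory for stage TSVs and the summary
#'   JSON.
#' @return list of class `altss_run` with `junctions`, `events`, `results`,
#'   `consequences`, `class_report`, `summary`.
#' @export
run_discover <- function(counts, design, exons, genome = NULL,
                         alpha = 0.05, min_dpsi = 5, min_reads = 10,
                         nmd_rule_nt = 50, min_intron = 20,
                         class3_size = 100, class3_seed = 1,
                         pwm = donor_pwm_default(),
                         cassette_rule = "containment", use_fdr = FALSE,
                         out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_dpsi < 0 || min_dpsi > 100) stop("min_dpsi must lie in [0, 100]")
  counts <- as.data.frame(counts)
  counts <- counts[counts$intron_end - counts$intron_start >= min_intron, ,
                   drop = FALSE]
  counts <- validate_junction_counts(counts)
  idx <- exon_index(exons)
  junctions <- unique(counts[c("chrom", "intron_start", "intron_end",
                               "strand")])
  events <- rbind(enumerate_a5c(junctions), enumerate_a3c(junctions))
  events <- deplete_cassette(events, idx, rule = cassette_rule)
  events <- annotate_event_gene(events, idx)
  results <- call_regulated(events, counts, design, alpha = alpha,
                            min_dpsi = min_dpsi, min_reads = min_reads,
                            use_fdr = use_fdr)
  consequences <- NULL
  class_report <- NULL
  if (!is.null(genome)) {
    models <- transcript_models(exons, genome)
    consequences <- call_consequences(events, models, genome,
                                      nmd_rule_nt = nmd_rule_nt)
    class_sets <- build_class_sets(results, alpha = alpha,
                                   min_dpsi = min_dpsi,
                                   class3_size = class3_size,
                                   seed = class3_seed)
    class_report <- tryCatch(
      compare_classes(class_sets, events, genome, pwm),
      error = function(e) NULL)
  }
  summary <- c(
    list(n_junctions = nrow(junctions),
         n_candidate_a5c = sum(events$type == "A5C"),
         n_candidate_a3c = sum(events$type == "A3C"),
         n_retained = sum(events$retained)),
    summarize_calls(results),
    list(consequence_counts = if (!is.null(consequences))
           as.list(table(consequences$category)) else NULL,
         genome_stages = if (is.null(genome)) "skipped" else "run",
         thresholds = list(alpha = alpha, min_dpsi = min_dpsi,
                           min_reads = min_reads, nmd_rule_nt = nmd_rule_nt,
                           min_intron = min_intron,
                           class3_size = class3_size,
                           class3_seed = class3_seed,
                           cassette_rule = cassette_rule,
                           use_fdr = use_fdr)))
  run <- structure(list(junctions = junctions, events = events,
                        results = results, consequences = consequences,
                        class_report = class_report, summary = summary),
                   class = "altss_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Run discovery from files
#'
#' Thin wrapper reading per-sample junction files (`star` SJ.out.tab,
#' `bed12`, or the generic `tsv` dialect), a GTF/BED12 annotation, an
#' optional FASTA genome and a design TSV, then calling [run_discover()].
#'
#' @param junction_files named character vector of paths (names = sample
#'   ids; unnamed `tsv` files may carry multiple samples).
#' @param dialect `"star"`, `"bed12"` or `"tsv"`.
#' @param annotation_file annotation path.
#' @param annotation_format `"gtf"` or `"bed12"`.
#' @param genome_file optional FASTA path.
#' @param design_file design TSV (columns `sample`, `condition`; the
#'   reference condition is flagged by a third column `role` containing
#'   `reference`).
#' @param ... further arguments to [run_discover()].
#' @return an `altss_run` list.
#' @export
discover_from_files <- function(junction_files,
                                dialect = c("star", "bed12", "tsv"),
                                annotation_file,
                                annotation_format = c("gtf", "bed12"),
                                genome_file = NULL, design_file, ...) {
  dialect <- match.arg(dialect)
  exons <- read_exon_annotation(annotation_file, match.arg(annotation_format))
  design <- read_design_tsv(design_file)
  counts <- do.call(rbind, lapply(seq_along(junction_files), function(i) {
    path <- junction_files[i]
    sample <- names(junction_files)[i]
    switch(dialect,
           star = parse_star_sj(path, sample, exon_index = exon_index(exons)),
           bed12 = parse_junction_bed(path, sample),
           tsv = read_junction_tsv(path))
  }))
  genome <- if (!is.null(genome_file)) read_genome(genome_file) else NULL
  run_discover(counts, design, exons, genome = genome, ...)
}

## ---- writers -------------------------------------------------------------

#' Write a GTF annotation
#'
#' @param exons exon table (`exon` and `CDS` rows).
#' @param path output file.
#' @export
write_gtf <- function(exons, path) {
  df <- exons[order(exons$chrom, exons$transcript_id,
                    exons$type != "exon", exons$start), , drop = FALSE]
  lines <- sprintf(
    '%s\taltss\t%s\t%d\t%d\t.\t%s\t%s\tgene_id "%s"; transcript_id "%s";',
    df$chrom, df$type, df$start + 1L, df$end, df$strand,
    ifelse(df$type == "CDS", "0", "."), df$gene_id, df$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write one sample's counts as an SJ.out.tab file
#'
#' @param counts a `junction_counts` data.frame (one sample).
#' @param path output file.
#' @export
write_sj_tab <- function(counts, path) {
  stopifnot(length(unique(counts$sample)) <= 1)
  code <- ifelse(counts$strand == "+", 1L, 2L)
  lines <- sprintf("%s\t%d\t%d\t%d\t0\t1\t%d\t0\t50",
                   counts$chrom, counts$intron_start + 1L,
                   counts$intron_end, code, counts$count)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a design TSV
#'
#' Columns `sample`, `condition`, `role` (`reference` for the control
#' condition, `treatment` otherwise).
#'
#' @param path file path.
#' @return `read_design_tsv`: a [sample_design()].
#' @export
read_design_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ref <- unique(df$condition[df$role == "reference"])
  if (length(ref) != 1) stop("design must flag exactly one reference condition")
  sample_design(setNames(df$condition, df$sample), ref)
}

#' @rdname read_design_tsv
#' @param design a [sample_design()].
#' @export
write_design_tsv <- function(design, path) {
  df <- data.frame(sample = names(design$condition_of),
                   condition = unname(design$condition_of),
                   role = ifelse(design$condition_of == design$reference,
                                 "reference", "treatment"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic dataset
#'
#' @param ref a `synth_reference`.
#' @param sim a `synth_counts`.
#' @param dir output directory (created if missing).
#' @export
write_synthetic_dataset <- function(ref, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  write_gtf(ref$exons, file.path(dir, "annotation.gtf"))
  write.table(ref$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_design_tsv(sim$design, file.path(dir, "design.tsv"))
  for (s in sim$samples) {
    sc <- sim$counts[sim$counts$sample == s, , drop = FALSE]
    write_sj_tab(sc, file.path(dir, paste0("SJ.", s, ".out.tab")))
    write_junction_tsv(sc, file.path(dir, paste0("junctions.", s, ".tsv")))
  }
  invisible(dir)
}

#' Write the stage tables and run summary of a discovery run
#'
#' @param run an `altss_run`.
#' @param dir output directory (created if missing).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    if (!is.null(df)) write.table(df, file.path(dir, name), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  wt(run$events, "events.tsv")
  wt(run$results, "results.tsv")
  wt(run$consequences, "consequences.tsv")
  if (!is.null(run$class_report)) {
    wt(run$class_report$features, "class_features.tsv")
    wt(run$class_report$ecdf, "class_ecdf.tsv")
    jsonlite::write_json(run$class_report$stats,
                         file.path(dir, "class_stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  ## BED6 of extension regions for genome-browser inspection
  ev <- run$events
  if (nrow(ev)) {
    bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", ev$chrom, ev$ext_start,
                   ev$ext_end, ev$event_id, as.integer(ev$retained),
                   ev$strand)
    writeLines(bed, file.path(dir, "extensions.bed"))
  }
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
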