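#' Run the simulation stage and write all artifacts
#'
#' One-call driver behind the `simulate` subcommand: builds (or loads) a
#' reference, mutates it into a diploid genome, simulates reads, and writes
#' FASTA, FASTQ, truth VCF, high-confidence BED and the origins sidecar under
#' one output prefix, together with a JSON provenance record.
#'
#' @param out_prefix Output path prefix (directories are created).
#' @param seed Master integer seed; the mutation stage uses `seed`, the
#'   fragmentation stage `seed + 10`, and sequencing errors `seed + 11`, so
#'   stages are independently reproducible.
#' @param reference `NULL` to synthesize one, a path to a FASTA file, or a
#'   `reference` object.
#' @param synthetic_length Length of the synthetic reference when no FASTA is
#'   given.
#' @param gc_content GC content of the synthetic reference.
#' @param model A `mutation_model`.
#' @param lib A `library_model`.
#' @return Invisibly, a list with the `diploid_genome`, the `read_set` and
#'   the file paths written.
#' @export
run_simulate <- function(out_prefix, seed = 1L, reference = NULL,
                         synthetic_length = 1e6, gc_content = 0.41,
                         model = mutation_model(), lib = library_model()) {
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  ref <- if (is.null(reference))
    generate_reference(synthetic_length, gc_content, seed = seed)
  else if (inherits(reference, "reference")) reference
  else read_reference(reference)

  genome <- mutate_diploid(ref, model, seed = seed)
  rs <- simulate_reads(genome, lib, seed = as.integer(seed) + 10L)

  contigs <- stats::setNames(ref$length, ref$name)
  files <- c(
    fasta = write_reference(ref, paste0(out_prefix, ".ref.fasta")),
    write_truth(genome$truth, contigs,
                vcf_path = paste0(out_prefix, ".truth.vcf"),
                bed_path = paste0(out_prefix, ".confident.bed"))[1:2],
    write_fastq(rs, out_prefix)
  )
  prov <- provenance(list(stage = "simulate", seed = seed,
                          reference_length = ref$length,
                          gc_content = gc_content,
                          model = unclass(model), lib = unclass(lib)))
  json <- paste0(out_prefix, ".simulate.json")
  jsonlite::write_json(c(prov, list(n_truth = nrow(genome$truth),
                                    n_fragments = nrow(rs$origins))),
                       json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genome = genome, reads = rs, files = c(files, json = json)))
}

#' Evaluate a SAM/BAM of simulated reads and write the report tables
#'
#' Driver behind the `eval-alignment` subcommand: judges every primary
#' record against its encoded origin, then writes the summary, the
#' mapping-quality ROC points and the calibration histogram as TSV, plus a
#' JSON report (and optional PDF plots).
#'
#' @param bam Path to the SAM/BAM produced by an external mapper.
#' @param out_prefix Output path prefix.
#' @param tolerance Position tolerance in bp for a correct placement.
#' @param origins Optional path to an origins TSV sidecar; by default the
#'   truth is decoded from the read names.
#' @param plots Also write PDF plots.
#' @return Invisibly, a list with `judgments`, `summary`, `roc`,
#'   `calibration` and the files written.
#' @export
run_eval_alignment <- function(bam, out_prefix, tolerance = 20L,
                               origins = NULL, plots = FALSE) {
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  alns <- read_alignments(bam)
  if (!is.null(origins)) origins <- read_origins(origins)
  j <- judge_alignments(alns, tolerance = tolerance, origins = origins)
  s <- alignment_summary(j)
  roc <- mapq_roc(j)
  calib <- mapq_calibration(j)

  files <- c(
    summary = write_tsv(summary_as_df(s), paste0(out_prefix, ".summary.tsv")),
    roc = write_tsv(roc, paste0(out_prefix, ".mapq_roc.tsv")),
    calibration = write_tsv(calib, paste0(out_prefix, ".calibration.tsv")))
  prov <- provenance(list(stage = "eval-alignment", bam = bam,
                          tolerance = tolerance))
  json <- paste0(out_prefix, ".alignment.json")
  jsonlite::write_json(c(prov, list(summary = unclass(s))), json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (plots) {
    grDevices::pdf(paste0(out_prefix, ".alignment_plots.pdf"), width = 9,
                   height = 4.5)
    graphics::par(mfrow = c(1, 2))
    plot_mapq_roc(roc)
    plot_calibration(calib)
    grDevices::dev.off()
    files <- c(files, plots = paste0(out_prefix, ".alignment_plots.pdf"))
  }
  invisible(list(judgments = j, summary = s, roc = roc, calibration = calib,
                 files = c(files, json = json)))
}

summary_as_df <- function(s) {
  data.frame(metric = names(unclass(s)),
             value = unlist(unclass(s), use.names = FALSE))
}

#' Benchmark a test VCF against a truth VCF and write the report tables
#'
#' Driver behind the `eval-variants` subcommand: reads and normalizes both
#' call sets against the reference, derives the complex-region exclusions
#' from the truth set, compares within the high-confidence regions, and
#' writes counts and metrics (TSV + JSON), the variant-quality ROC, the depth
#' strata, and annotated TP/FP/FN VCFs.
#'
#' @param test_vcf,truth_vcf Paths to the test and truth VCFs.
#' @param regions_bed Path to the high-confidence BED.
#' @param ref Reference: path to FASTA, or a `reference` object.
#' @param out_prefix Output path prefix.
#' @param genotype_aware Require matching genotype for a TP.
#' @param window Complex-region exclusion window (bp).
#' @param include_filtered Keep FILTER-failed test records.
#' @param depth_edges Bin edges for the depth stratification.
#' @param plots Also write PDF plots.
#' @return Invisibly, a list with the `variant_comparison`, `metrics`, `roc`,
#'   `depth` strata and files written.
#' @export
run_eval_variants <- function(test_vcf, truth_vcf, regions_bed, ref,
                              out_prefix, genotype_aware = TRUE, window = 10L,
                              include_filtered = FALSE,
                              depth_edges = c(0, 10, 20, 30, 40, 60, 100, Inf),
                              plots = FALSE) {
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  if (!inherits(ref, "reference")) ref <- read_reference(ref)
  test <- normalize_calls(read_calls(test_vcf,
                                     include_filtered = include_filtered), ref)
  truth <- normalize_calls(read_truth_vcf(truth_vcf), ref)
  regions <- read_regions(regions_bed)
  cmp <- compare_calls(test, truth, regions, genotype_aware = genotype_aware,
                       window = window)
  m <- call_metrics(cmp)
  roc <- quality_roc(cmp)
  depth <- stratify_by_depth(cmp, depth_edges)

  counts <- data.frame(
    metric = c("tp", "fp", "fn", "tn_bases", "excluded_test", "excluded_truth",
               "precision_pct", "sensitivity_pct", "specificity_pct"),
    value = c(cmp$tp, cmp$fp, cmp$fn, cmp$tn, cmp$excluded_test,
              cmp$excluded_truth, round(100 * m$precision, 2),
              round(100 * m$sensitivity, 2), round(100 * m$specificity, 2)))
  contigs <- stats::setNames(ref$length, ref$name)
  files <- c(
    metrics = write_tsv(counts, paste0(out_prefix, ".metrics.tsv")),
    roc = write_tsv(roc, paste0(out_prefix, ".quality_roc.tsv")),
    depth = write_tsv(depth, paste0(out_prefix, ".depth_strata.tsv")),
    tp = write_truth(cmp$tp_records, contigs, paste0(out_prefix, ".tp.vcf"))[1],
    fp = write_truth(cmp$fp_records, contigs, paste0(out_prefix, ".fp.vcf"))[1],
    fn = write_truth(cmp$fn_records, contigs, paste0(out_prefix, ".fn.vcf"))[1])
  prov <- provenance(list(stage = "eval-variants", test_vcf = test_vcf,
                          truth_vcf = truth_vcf, regions = regions_bed,
                          genotype_aware = genotype_aware, window = window))
  json <- paste0(out_prefix, ".variants.json")
  jsonlite::write_json(
    c(prov, list(counts = list(tp = cmp$tp, fp = cmp$fp, fn = cmp$fn,
                               tn_bases = cmp$tn,
                               excluded_test = cmp$excluded_test,
                               excluded_truth = cmp$excluded_truth),
                 metrics = m,
                 note = paste("specificity is near-saturated when confident",
                              "regions are large; precision is usually the",
                              "more informative statistic"))),
    json, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  if (plots) {
    grDevices::pdf(paste0(out_prefix, ".variant_plots.pdf"), width = 9,
                   height = 4.5)
    graphics::par(mfrow = c(1, 2))
    plot_quality_roc(roc)
    plot_depth_precision(depth)
    grDevices::dev.off()
    files <- c(files, plots = paste0(out_prefix, ".variant_plots.pdf"))
  }
  invisible(list(comparison = cmp, metrics = m, roc = roc, depth = depth,
                 files = c(files, json = json)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# provenance block embedded in every JSON report: package version, config
# and a hash of the serialized config so reruns can be verified
provenance <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  list(tool = "varbench",
       version = as.character(utils::packageVersion("varbench")),
       config = config,
       config_md5 = unname(tools::md5sum(tmp)))
}

#' Plot helpers for the benchmark figures
#'
#' Base-graphics renderings of the four standard panels: the cumulative
#' correct-vs-incorrect mapping-quality curve, the calibration histogram of
#' incorrect reads per mapping-quality percentile bin (log-scaled counts),
#' the variant-quality TPR/FPR curve, and precision by read-depth bin.
#'
#' @param roc,calib,depth Tables from [mapq_roc()], [mapq_calibration()],
#'   [quality_roc()] and [stratify_by_depth()].
#' @param ... Passed to the underlying plot call.
#' @return `NULL`, invisibly; called for the side effect.
#' @name benchmark_plots
NULL

#' @rdname benchmark_plots
#' @export
plot_mapq_roc <- function(roc, ...) {
  graphics::plot(roc$cum_correct, roc$cum_incorrect, type = "s",
                 xlab = "correctly mapped reads (cumulative)",
                 ylab = "incorrectly mapped reads (cumulative)",
                 main = "mapping quality ROC", ...)
  invisible(NULL)
}

#' @rdname benchmark_plots
#' @export
plot_calibration <- function(calib, ...) {
  cnt <- pmax(calib$incorrect, 0.5)  # log axis cannot show zero
  graphics::barplot(cnt, log = "y",
                    names.arg = sprintf("%d-%d", calib$bin_lo, calib$bin_hi),
                    xlab = "mapping quality percentile bin",
                    ylab = "incorrect reads (log)",
                    main = "quality calibration", las = 2, ...)
  invisible(NULL)
}

#' @rdname benchmark_plots
#' @export
plot_quality_roc <- function(roc, ...) {
  graphics::plot(roc$fpr, roc$tpr, type = "b", pch = 20,
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 main = "variant quality ROC", ...)
  invisible(NULL)
}

#' @rdname benchmark_plots
#' @export
plot_depth_precision <- function(depth, ...) {
  d <- depth[!is.na(depth$lo) & !is.na(depth$precision), , drop = FALSE]
  graphics::plot(seq_len(nrow(d)), 100 * d$precision, type = "b", pch = 20,
                 xaxt = "n", xlab = "read depth bin", ylab = "precision (%)",
                 main = "precision by read depth", ...)
  graphics::axis(1, at = seq_len(nrow(d)),
                 labels = sprintf("%g-%g", d$lo, d$hi), las = 2)
  invisible(NULL)
}
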