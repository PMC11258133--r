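#' Run the full analysis pipeline from a configuration
#'
#' Executes every stage on the configured inputs — read subsampling and
#' window trimming, telomere motif profiling and calling, k-mer spectrum
#' profiling, assembly statistics, contig-end telomere scan, 100-kb binned
#' density tracks with the repeat/depth median split, the SV size filter
#' and type spectrum, the gene-by-SV intersection, and Circos track export
#' — logging each stage with its parameters and record counts, and writes
#' a machine-readable JSON report. Stage outputs are pure functions of the
#' inputs plus configuration, so reruns with the same config and seed are
#' byte-identical.
#'
#' @param config A named list or a YAML file path. Recognised input keys:
#'   `reads` (FASTQ), `assembly` (FASTA), `repeats_out`, `genes_gff3`,
#'   `snp_vcf`, `sv_vcf`, `depth_tsv`, `out_dir`; parameters under
#'   `params`: `subsample_n`, `seed`, `k`, `bin_width`, `min_contig_len`,
#'   `min_sv_size`, `telomere_motif`, `min_windows`, `min_fraction`.
#' @param quiet Suppress per-stage log messages.
#' @return The report, a `pipeline_report` list (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  p <- utils::modifyList(
    list(subsample_n = NULL, seed = 42L, k = 21L, bin_width = 1e5,
         min_contig_len = 0, min_sv_size = 50L, telomere_motif = "TTTAGGG",
         min_windows = 50L, min_fraction = 0.5),
    config$params %||% list())
  out_dir <- config$out_dir %||% stop("config$out_dir is required", call. = FALSE)

  # validate all configured inputs before any stage runs
  input_keys <- c("reads", "assembly", "repeats_out", "genes_gff3",
                  "snp_vcf", "sv_vcf", "depth_tsv")
  for (key in input_keys) {
    path <- config[[key]]
    if (!is.null(path) && !file.exists(path))
      stop(sprintf("configured input `%s` not found: %s", key, path),
           call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_stage <- function(...) if (!quiet) message("[teloscope] ", sprintf(...))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  report <- list(parameters = p)

  if (!is.null(config$reads)) {
    reads <- run_stage("read_input", read_fastq(config$reads))
    log_stage("read_input: %d records from %s", length(reads), config$reads)
    if (!is.null(p$subsample_n) && p$subsample_n < length(reads)) {
      reads <- run_stage("subsample",
                         subsample_reads(reads, n = p$subsample_n,
                                         seed = p$seed))
      log_stage("subsample: kept %d records (seed %d)", length(reads), p$seed)
    }
    windows <- run_stage("trim", trim_to_window(as.character(reads)))
    log_stage("trim: %d windows, %d reads skipped", length(windows),
              attr(windows, "n_skipped"))
    tab <- run_stage("telomere_profile", profile_sample(windows))
    call <- run_stage("telomere_call",
                      call_sample_telomere(tab, min_windows = p$min_windows,
                                           min_fraction = p$min_fraction))
    log_stage("telomere: %d telomere-like windows; call = %s",
              sum(tab$windows),
              if (call$determined) call$motif else "undetermined")
    report$telomere_call <- call[c("motif", "determined", "family", "source",
                                   "windows", "relative_abundance")]
    report$motif_table <- as.data.frame(tab)

    hist <- run_stage("kmer_count", count_kmers(reads, k = p$k))
    prof <- run_stage("kmer_profile", fit_genome_profile(hist))
    log_stage("kmer profile: len=%.0f ab=%.4f kcov=%.1f (k=%d)",
              prof$len, prof$ab, prof$kcov, prof$k)
    report$genome_profile <- unclass(prof)
  }

  bins <- NULL
  if (!is.null(config$assembly)) {
    asm <- run_stage("assembly_read", as_sequences(config$assembly))
    st <- run_stage("assembly_stats", assembly_stats(asm))
    log_stage("assembly: %d contigs, N50 %d", st$n_contigs, st$n50)
    report$assembly_stats <- unclass(st)
    ends <- run_stage("contig_ends",
                      scan_contig_ends(asm, motif = p$telomere_motif))
    log_stage("contig ends: %d telomere calls", nrow(ends))
    report$contig_end_telomeres <- ends
    cl <- setNames(as.numeric(Biostrings::width(asm)), names(asm))
    bins <- run_stage("bins", compute_bins(
      cl, depth = config$depth_tsv, repeats = config$repeats_out,
      genes = config$genes_gff3, snps = config$snp_vcf,
      svs = if (!is.null(config$sv_vcf))
        filter_and_spectrum_svs(config$sv_vcf, p$min_sv_size)$records,
      bin_width = p$bin_width, min_contig_len = p$min_contig_len))
    log_stage("bins: %d bins of width %d", nrow(bins), p$bin_width)
    if (nrow(bins) >= 2L) {
      split <- run_stage("repeat_split", repeat_split_depth_summary(bins))
      report$repeat_depth_split <- as.data.frame(split)
      report$repeat_depth_split_threshold <- attr(split, "threshold")
    }
  }
  if (!is.null(config$sv_vcf)) {
    spec <- run_stage("sv_spectrum",
                      filter_and_spectrum_svs(config$sv_vcf, p$min_sv_size))
    log_stage("SVs: %d retained (>= %d bp), %d dropped",
              nrow(spec$records), p$min_sv_size, spec$n_dropped)
    report$sv_counts <- as.list(spec$counts)
    report$sv_length_hist <- spec$length_hist
    if (!is.null(config$genes_gff3)) {
      aff <- run_stage("genes_affected",
                       genes_affected_by_sv(config$genes_gff3, spec))
      log_stage("genes with CDS affected by SV: %d", aff$n_affected)
      report$genes_affected_by_sv <- aff$n_affected
    }
  }
  if (!is.null(bins)) {
    ts <- run_stage("circos_export",
                    export_circos_tracks(bins, file.path(out_dir, "circos")))
    report$circos_ranges <- ts$ranges
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  log_stage("report written to %s", report_path)
  structure(report, path = report_path, class = c("pipeline_report", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
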