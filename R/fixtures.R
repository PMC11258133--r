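#' Write annotation fixtures for a synthetic truth set
#'
#' Serialises the planted truth of [simulate_genome()] into the standard
#' annotation formats consumed by the assembly-QC parsers: a
#' RepeatMasker-style `.out` table, a GFF3 gene annotation, SNP and SV VCFs
#' (v4.2, symbolic ALT with `SVTYPE`/`SVLEN`/`END`), and a three-column
#' per-base depth table. Files written here round-trip exactly through
#' [parse_repeatmasker_out()], [read_gff3_cds()], [read_snp_positions()] and
#' [filter_and_spectrum_svs()].
#'
#' @param truth Truth list from [simulate_genome()].
#' @param dir Output directory (created if missing).
#' @param mean_depth Constant depth written to the depth track (default 30).
#' @return Named list of file paths (`repeats_out`, `genes_gff3`,
#'   `snp_vcf`, `sv_vcf`, `depth_tsv`).
#' @export
emit_annotation_fixtures <- function(truth, dir, mean_depth = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(repeats_out = file.path(dir, "repeats.out"),
                genes_gff3 = file.path(dir, "genes.gff3"),
                snp_vcf = file.path(dir, "snps.vcf"),
                sv_vcf = file.path(dir, "svs.vcf"),
                depth_tsv = file.path(dir, "depth.tsv"))
  write_repeatmasker_out(truth$repeats, truth$chrom_lengths, paths$repeats_out)
  write_gff3(truth$genes, truth$cds, paths$genes_gff3)
  write_snp_vcf(truth$snps, truth$chrom_lengths, paths$snp_vcf)
  write_sv_vcf(truth$svs, truth$chrom_lengths, paths$sv_vcf)
  write_depth_tsv(truth$chrom_lengths, paths$depth_tsv, mean_depth)
  paths
}

# RepeatMasker .out: 3 header lines then 15-column alignment rows.
write_repeatmasker_out <- function(repeats, chrom_lengths, path) {
  hdr <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin  end          (left)  repeat         class/family     begin   end    (left)   ID",
    "")
  lines <- hdr
  if (nrow(repeats)) {
    len <- repeats$end - repeats$start
    lines <- c(lines, sprintf(
      "%5d %6.1f %4.1f %4.1f  %s %8d %8d (%d) %s %-14s %-16s %6d %6d (0) %5d",
      1000L, 0, 0, 0, repeats$chrom,
      repeats$start + 1L, repeats$end,
      chrom_lengths[repeats$chrom] - repeats$end,
      "+", repeats$family, repeats$class,
      1L, len, seq_len(nrow(repeats))))
  }
  writeLines(lines, path)
  invisible(path)
}

write_gff3 <- function(genes, cds, path) {
  lines <- "##gff-version 3"
  if (nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      lines <- c(lines,
        sprintf("%s\tteloscope\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                g$chrom, g$start + 1L, g$end, g$gene_id),
        sprintf("%s\tteloscope\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
                g$chrom, g$start + 1L, g$end, g$gene_id, g$gene_id))
      cc <- cds[cds$gene_id == g$gene_id, , drop = FALSE]
      if (nrow(cc))
        lines <- c(lines, sprintf(
          "%s\tteloscope\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds;Parent=%s.t1",
          cc$chrom, cc$start + 1L, cc$end, cc$gene_id, cc$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

vcf_header <- function(chrom_lengths, sv = FALSE) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths), chrom_lengths),
    if (sv) c(
      '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
      '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of structural variant">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

write_snp_vcf <- function(snps, chrom_lengths, path) {
  lines <- vcf_header(chrom_lengths)
  if (nrow(snps))
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                              snps$chrom, snps$pos + 1L, snps$ref, snps$alt))
  writeLines(lines, path)
  invisible(path)
}

# SV VCF convention: POS is the base before the event (1-based), so the
# affected reference bases are [POS, POS + length) in 0-based half-open
# coordinates; END = POS + length except for insertions (END = POS); SVLEN
# is negative for deletions.
write_sv_vcf <- function(svs, chrom_lengths, path) {
  lines <- vcf_header(chrom_lengths, sv = TRUE)
  if (nrow(svs)) {
    pos <- svs$start # 0-based first affected base == 1-based base before it
    svlen <- ifelse(svs$type == "DEL", -svs$length, svs$length)
    end <- ifelse(svs$type == "INS", pos, pos + svs$length)
    alt <- sprintf("<%s>", svs$type)
    lines <- c(lines, sprintf(
      "%s\t%d\tsv%d\tN\t%s\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d",
      svs$chrom, pos, seq_len(nrow(svs)), alt, svs$type, svlen, end))
  }
  writeLines(lines, path)
  invisible(path)
}

write_depth_tsv <- function(chrom_lengths, path, mean_depth = 30L) {
  if (!length(chrom_lengths)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  dt <- data.table::data.table(
    contig = rep(names(chrom_lengths), chrom_lengths),
    position = unlist(lapply(chrom_lengths, seq_len), use.names = FALSE),
    depth = as.integer(mean_depth))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
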