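#' Filter structural variants by size and summarise the type spectrum
#'
#' Reads SV records (`SVTYPE` plus `SVLEN` or `END` in INFO), computes each
#' variant's length as `|SVLEN|` — falling back to `END - POS` when `SVLEN`
#' is absent — drops records below `min_sv_size` (default 50 bp, the
#' conventional lower bound separating SVs from indels), and tabulates the
#' five SV categories: deletion, insertion, inversion, interspersed
#' duplication and tandem duplication. A log10 length histogram per type is
#' returned for spectrum plots.
#'
#' @param svs VCF path or a data.frame with columns `contig`, `pos`,
#'   `type`, `length`.
#' @param min_sv_size Minimum retained variant length in bp (default 50).
#' @return An `sv_spectrum` list: `records` (data.frame `contig`, `pos`,
#'   `type`, `length`), `counts` (named integer over the five types),
#'   `length_hist` (data.frame `type`, `log10_bin`, `n`),
#'   `n_dropped` (records below the size threshold).
#' @export
filter_and_spectrum_svs <- function(svs, min_sv_size = 50L) {
  rec <- if (is.character(svs)) read_sv_vcf(svs) else {
    stopifnot(all(c("contig", "pos", "type", "length") %in% names(svs)))
    svs
  }
  rec$type <- normalize_sv_type(rec$type)
  n0 <- nrow(rec)
  rec <- rec[rec$length >= min_sv_size, , drop = FALSE]
  rownames(rec) <- NULL
  counts <- setNames(integer(length(SV_TYPES)), SV_TYPES)
  tab <- table(rec$type)
  counts[names(tab)] <- as.integer(tab)
  lh <- if (nrow(rec)) {
    lb <- floor(log10(rec$length) * 2) / 2 # half-decade bins
    agg <- as.data.frame(table(type = rec$type, log10_bin = lb),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0L, , drop = FALSE]
    data.frame(type = agg$type, log10_bin = as.numeric(agg$log10_bin),
               n = agg$Freq, stringsAsFactors = FALSE)
  } else data.frame(type = character(0), log10_bin = numeric(0),
                    n = integer(0), stringsAsFactors = FALSE)
  structure(list(records = rec, counts = counts, length_hist = lh,
                 n_dropped = n0 - nrow(rec), min_sv_size = min_sv_size),
            class = "sv_spectrum")
}

#' @export
print.sv_spectrum <- function(x, ...) {
  cat(sprintf("Structural variants >= %d bp: %d retained, %d dropped\n",
              x$min_sv_size, nrow(x$records), x$n_dropped))
  for (t in names(x$counts))
    cat(sprintf("  %-11s %d\n", t, x$counts[[t]]))
  invisible(x)
}

# DUP without a subtype annotation is treated as a tandem duplication.
normalize_sv_type <- function(type) {
  type[type == "DUP"] <- "DUP:TANDEM"
  bad <- setdiff(unique(type), SV_TYPES)
  if (length(bad))
    stop("unknown SVTYPE value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  type
}

# Parse an SV VCF via vcfR; SVLEN preferred, END - POS fallback.
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      type = character(0), length = integer(0),
                      stringsAsFactors = FALSE))
  contig <- as.character(v@fix[, "CHROM"])
  pos <- as.integer(v@fix[, "POS"])
  id <- as.character(v@fix[, "ID"])
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
  end <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  len <- abs(svlen)
  fall <- is.na(len)
  len[fall] <- end[fall] - pos[fall]
  if (anyNA(len) | anyNA(svtype)) {
    bad <- which(is.na(len) | is.na(svtype))[1]
    stop(sprintf("SV record %s at %s:%d has neither SVLEN nor END",
                 id[bad], contig[bad], pos[bad]), call. = FALSE)
  }
  data.frame(contig = contig, pos = pos, type = as.character(svtype),
             length = as.integer(len), stringsAsFactors = FALSE)
}

#' Genes whose coding sequence is affected by structural variants
#'
#' A gene is affected when at least one of its CDS intervals overlaps at
#' least one SV footprint by >= 1 bp in half-open coordinates. Footprints
#' on the reference are `[POS, POS + length)` for deletions, inversions and
#' duplications, and a single base at `POS` for insertions. Each gene is
#' counted once regardless of how many of its CDS parts are hit.
#'
#' @param cds CDS intervals: data.frame with `gene_id`, `chrom` (or
#'   `contig`), `start`, `end` (0-based half-open), or a GFF3 path.
#' @param svs SV records (`contig`, `pos`, `type`, `length`), an
#'   `sv_spectrum`, or an SV VCF path (filtered at 50 bp).
#' @return List with `n_affected`, `affected_genes` (character) and
#'   `per_gene` (data.frame `gene_id`, `n_sv`).
#' @export
genes_affected_by_sv <- function(cds, svs) {
  if (is.character(cds) && length(cds) == 1L) cds <- read_gff3_cds(cds)$cds
  if (is.character(svs)) svs <- filter_and_spectrum_svs(svs)
  if (inherits(svs, "sv_spectrum")) svs <- svs$records
  chrom <- if (!is.null(cds$chrom)) cds$chrom else cds$contig
  if (nrow(cds) == 0L || nrow(svs) == 0L)
    return(list(n_affected = 0L, affected_genes = character(0),
                per_gene = data.frame(gene_id = character(0), n_sv = integer(0),
                                      stringsAsFactors = FALSE)))
  fp_len <- ifelse(svs$type == "INS", 1L, svs$length)
  # 0-based half-open footprints [pos, pos + len); CDS already half-open
  lvls <- union(unique(chrom), unique(svs$contig))
  sv_gr <- GenomicRanges::GRanges(factor(svs$contig, lvls),
                                  IRanges::IRanges(svs$pos + 1L,
                                                   svs$pos + fp_len))
  cds_gr <- GenomicRanges::GRanges(factor(chrom, lvls),
                                   IRanges::IRanges(cds$start + 1L, cds$end))
  ov <- GenomicRanges::findOverlaps(cds_gr, sv_gr)
  hit_gene <- cds$gene_id[S4Vectors::queryHits(ov)]
  hit_sv <- S4Vectors::subjectHits(ov)
  pairs <- unique(data.frame(gene_id = hit_gene, sv = hit_sv,
                             stringsAsFactors = FALSE))
  per_gene <- if (nrow(pairs)) {
    tab <- table(pairs$gene_id)
    data.frame(gene_id = names(tab), n_sv = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene_id = character(0), n_sv = integer(0),
               stringsAsFactors = FALSE)
  }
  genes <- sort(unique(pairs$gene_id))
  list(n_affected = length(genes), affected_genes = genes,
       per_gene = per_gene)
}
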