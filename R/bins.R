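#' Read gene and CDS intervals from a GFF3 file
#'
#' Imports via rtracklayer and converts to 0-based half-open intervals.
#' CDS records are tied back to their gene through the `Parent` chain
#' (CDS -> mRNA -> gene) or, failing that, the ID prefix.
#'
#' @param path GFF3 path.
#' @return List with `genes` and `cds` data.frames (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @export
read_gff3_cds <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   type = as.character(gr$type),
                   id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
                   stringsAsFactors = FALSE)
  parent <- if (!is.null(gr$Parent))
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))
  genes <- df[df$type == "gene", c("chrom", "start", "end")]
  genes$gene_id <- df$id[df$type == "gene"]
  genes <- genes[, c("gene_id", "chrom", "start", "end")]
  # map transcript id -> gene id
  tx <- df$type %in% c("mRNA", "transcript")
  tx_gene <- setNames(parent[tx], df$id[tx])
  is_cds <- df$type == "CDS"
  cds_parent <- parent[is_cds]
  gene_of <- ifelse(cds_parent %in% names(tx_gene),
                    tx_gene[cds_parent], cds_parent)
  cds <- data.frame(gene_id = unname(gene_of),
                    chrom = df$chrom[is_cds],
                    start = df$start[is_cds],
                    end = df$end[is_cds],
                    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  list(genes = genes, cds = cds)
}

#' Read SNP positions from a VCF
#'
#' @param path VCF path.
#' @return Data.frame with `contig` and `pos` (1-based, as in the VCF).
#' @export
read_snp_positions <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  data.frame(contig = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             stringsAsFactors = FALSE)
}

#' Read a three-column per-base depth table
#'
#' The `samtools depth -a` layout: contig, 1-based position, depth.
#'
#' @param path TSV path.
#' @return A data.frame with columns `contig`, `position`, `depth`.
#' @export
read_depth_tsv <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "position", "depth"),
                          colClasses = list(character = 1))
  as.data.frame(dt)
}

#' Aggregate depth, repeat, gene and variant densities into fixed bins
#'
#' Tiles every retained contig (length >= `min_contig_len`) with
#' `bin_width` windows from position 0, the final bin truncated at the
#' contig end, and aggregates: summed and mean per-base depth (positions
#' missing from the depth table count as depth 0), masked-base fraction
#' from the union of repeat intervals clipped to the bin, and gene / SNP /
#' SV counts assigned by each feature's start coordinate.
#'
#' @param contig_lengths Named vector of contig lengths.
#' @param depth Depth table (data.frame from [read_depth_tsv()] or a path);
#'   optional.
#' @param repeats Repeat intervals: data.frame with `contig`/`start`/`end`
#'   (0-based half-open), a RepeatMasker `.out` path, or the result of
#'   [parse_repeatmasker_out()]; optional.
#' @param genes Gene intervals (`chrom`, `start`) or a GFF3 path; optional.
#' @param snps SNP table (`contig`, `pos` 1-based) or a VCF path; optional.
#' @param svs SV records (`contig`, `pos`) — e.g.
#'   `filter_and_spectrum_svs()$records` — or an SV VCF path; optional.
#' @param bin_width Bin width in bp (default 100000).
#' @param min_contig_len Minimum contig length retained (default 0).
#' @return A `genomic_bins` data.frame: `contig`, `start`, `end`,
#'   `depth_sum`, `depth_mean`, `repeat_ratio`, `gene_count`, `snp_count`,
#'   `sv_count`; contig lengths kept in attribute `contig_lengths`.
#' @export
compute_bins <- function(contig_lengths, depth = NULL, repeats = NULL,
                         genes = NULL, snps = NULL, svs = NULL,
                         bin_width = 1e5, min_contig_len = 0) {
  stopifnot(length(contig_lengths) > 0, !is.null(names(contig_lengths)))
  keep <- contig_lengths >= min_contig_len
  if (!any(keep)) stop("no contig passes min_contig_len", call. = FALSE)
  cl <- contig_lengths[keep]
  bin_width <- as.integer(bin_width)

  bins <- do.call(rbind, lapply(names(cl), function(cn) {
    starts <- seq(0L, cl[[cn]] - 1L, by = bin_width)
    data.frame(contig = cn, start = starts,
               end = pmin(starts + bin_width, cl[[cn]]),
               stringsAsFactors = FALSE)
  }))
  bins$depth_sum <- 0
  bins$depth_mean <- 0
  bins$repeat_ratio <- 0
  bins$gene_count <- 0L
  bins$snp_count <- 0L
  bins$sv_count <- 0L
  bin_key <- paste(bins$contig, bins$start %/% bin_width)

  if (!is.null(depth)) {
    d <- if (is.character(depth)) read_depth_tsv(depth) else depth
    unknown <- setdiff(unique(d$contig), names(contig_lengths))
    if (length(unknown))
      stop("depth rows for unknown contig(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(d$position < 1L | d$position > contig_lengths[d$contig]))
      stop("depth positions beyond contig length", call. = FALSE)
    d <- d[d$contig %in% names(cl), , drop = FALSE]
    if (nrow(d)) {
      dt <- data.table::as.data.table(d)
      dt[, bin := (position - 1L) %/% bin_width]
      agg <- dt[, list(depth_sum = sum(as.numeric(depth))),
                by = c("contig", "bin")]
      idx <- match(paste(agg$contig, agg$bin), bin_key)
      bins$depth_sum[idx] <- agg$depth_sum
    }
    bins$depth_mean <- bins$depth_sum / (bins$end - bins$start)
  }

  if (!is.null(repeats)) {
    r <- if (is.character(repeats)) parse_repeatmasker_out(repeats)$intervals
    else if (is.list(repeats) && !is.null(repeats$intervals)) repeats$intervals
    else repeats
    r <- r[r$contig %in% names(cl), , drop = FALSE]
    if (nrow(r)) {
      # union of masked bases per contig, then arithmetic overlap per bin
      for (cn in unique(r$contig)) {
        rr <- r[r$contig == cn, , drop = FALSE]
        red <- IRanges::reduce(IRanges::IRanges(rr$start + 1L, rr$end))
        s0 <- IRanges::start(red) - 1L
        e0 <- IRanges::end(red)
        first_bin <- s0 %/% bin_width
        last_bin <- (e0 - 1L) %/% bin_width
        sel_bins <- which(bins$contig == cn)
        for (j in seq_along(s0)) {
          for (b in first_bin[j]:last_bin[j]) {
            row <- sel_bins[b + 1L]
            ov <- min(e0[j], bins$end[row]) - max(s0[j], bins$start[row])
            bins$repeat_ratio[row] <- bins$repeat_ratio[row] + ov
          }
        }
      }
      bins$repeat_ratio <- bins$repeat_ratio / (bins$end - bins$start)
    }
  }

  count_by_start <- function(contig, start0) {
    sel <- contig %in% names(cl)
    key <- paste(contig[sel], start0[sel] %/% bin_width)
    tab <- table(key)
    idx <- match(names(tab), bin_key)
    cnt <- integer(nrow(bins))
    cnt[idx[!is.na(idx)]] <- as.integer(tab[!is.na(idx)])
    cnt
  }
  if (!is.null(genes)) {
    g <- if (is.character(genes)) read_gff3_cds(genes)$genes else genes
    cn <- if (!is.null(g$chrom)) g$chrom else g$contig
    bins$gene_count <- count_by_start(cn, g$start)
  }
  if (!is.null(snps)) {
    s <- if (is.character(snps)) read_snp_positions(snps) else snps
    bins$snp_count <- count_by_start(s$contig, s$pos - 1L)
  }
  if (!is.null(svs)) {
    v <- if (is.character(svs)) filter_and_spectrum_svs(svs)$records else svs
    bins$sv_count <- count_by_start(v$contig, v$pos - 1L)
  }
  structure(bins, contig_lengths = cl,
            bin_width = bin_width,
            class = c("genomic_bins", "data.frame"))
}

#' Compare read depth between less and more repetitive bins
#'
#' Splits bins at the median repeat fraction (bins at or below the
#' threshold form the "less repetitive" group) and summarises the mean
#' per-base depth of each group, the diagnostic used to judge whether
#' repeat-dense regions assembled with skewed coverage.
#'
#' @param bins A `genomic_bins` data.frame from [compute_bins()].
#' @return A `repeat_depth_split` data.frame with one row per group
#'   (`group`, `n`, `median_depth`, `sd_depth`); threshold kept in
#'   attribute `threshold`.
#' @export
repeat_split_depth_summary <- function(bins) {
  if (nrow(bins) < 2L) stop("need at least 2 bins", call. = FALSE)
  thr <- median(bins$repeat_ratio)
  grp <- ifelse(bins$repeat_ratio <= thr, "less repetitive", "more repetitive")
  out <- do.call(rbind, lapply(c("less repetitive", "more repetitive"),
    function(g) {
      d <- bins$depth_mean[grp == g]
      data.frame(group = g, n = length(d),
                 median_depth = if (length(d)) median(d) else NA_real_,
                 sd_depth = if (length(d) > 1L) sd(d) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  structure(out, threshold = thr,
            class = c("repeat_depth_split", "data.frame"))
}

#' @export
print.repeat_depth_split <- function(x, ...) {
  cat(sprintf("Depth by repeat content (median repeat-ratio threshold %.3f)\n",
              attr(x, "threshold")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
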