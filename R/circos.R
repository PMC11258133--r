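#' Export Circos karyotype and density track files
#'
#' Writes the file set behind a genome-overview Circos figure: a karyotype
#' (contigs in descending length order), a read-depth histogram track, and
#' four heatmap tracks (gene, SNP, SV and repeat densities), each as
#' whitespace-separated "contig start end value" rows, plus a minimal
#' configuration file referencing them with the observed value ranges. The
#' contract is the data files and declared ranges; rendering is left to
#' Circos itself.
#'
#' @param bins A `genomic_bins` data.frame from [compute_bins()].
#' @param out_dir Output directory (created if needed).
#' @return A `circos_trackset` list (`karyotype`, `tracks`, `ranges`,
#'   `files`), invisibly.
#' @export
export_circos_tracks <- function(bins, out_dir) {
  if (is.null(bins) || nrow(bins) == 0L) stop("empty bins", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cl <- attr(bins, "contig_lengths")
  if (is.null(cl)) {
    agg <- tapply(bins$end, bins$contig, max)
    cl <- setNames(as.numeric(agg), names(agg))
  }
  cl <- sort(cl, decreasing = TRUE)

  kar_path <- file.path(out_dir, "karyotype.txt")
  writeLines(sprintf("chr - %s %s 0 %d grey", names(cl), names(cl),
                     as.integer(cl)), kar_path)

  tracks <- c(depth = "depth_mean", gene = "gene_count", snp = "snp_count",
              sv = "sv_count", repeat_density = "repeat_ratio")
  files <- c(karyotype = kar_path)
  ranges <- list()
  for (t in names(tracks)) {
    val <- bins[[tracks[[t]]]]
    p <- file.path(out_dir, paste0(t, ".txt"))
    writeLines(sprintf("%s %d %d %s", bins$contig, as.integer(bins$start),
                       as.integer(bins$end), format(val, trim = TRUE,
                                                    scientific = FALSE)),
               p)
    files[[t]] <- p
    ranges[[t]] <- c(min = min(val), max = max(val))
  }

  conf <- c(
    "# minimal circos configuration over the exported tracks",
    sprintf("karyotype = %s", basename(kar_path)),
    "<plots>",
    "<plot>", "type = histogram",
    sprintf("file = %s", basename(files[["depth"]])),
    sprintf("min = %s", ranges$depth[["min"]]),
    sprintf("max = %s", ranges$depth[["max"]]),
    "r0 = 0.80r", "r1 = 0.95r", "</plot>",
    unlist(lapply(seq_along(c("gene", "snp", "sv", "repeat_density")),
      function(i) {
        t <- c("gene", "snp", "sv", "repeat_density")[i]
        r1 <- 0.78 - (i - 1) * 0.08
        c("<plot>", "type = heatmap",
          sprintf("file = %s", basename(files[[t]])),
          "color = blues-9-seq",
          sprintf("min = %s", ranges[[t]][["min"]]),
          sprintf("max = %s", ranges[[t]][["max"]]),
          sprintf("r0 = %.2fr", r1 - 0.06), sprintf("r1 = %.2fr", r1),
          "</plot>")
      })),
    "</plots>")
  conf_path <- file.path(out_dir, "circos.conf")
  writeLines(conf, conf_path)
  files[["conf"]] <- conf_path

  invisible(structure(list(karyotype = data.frame(contig = names(cl),
                                                  length = as.numeric(cl)),
                           tracks = names(tracks), ranges = ranges,
                           files = files),
                      class = "circos_trackset"))
}

#' Read back an exported Circos track file
#'
#' @param path Track file path.
#' @return Data.frame `contig`, `start`, `end`, `value`.
#' @export
read_circos_track <- function(path) {
  df <- read.table(path, header = FALSE, sep = "",
                   col.names = c("contig", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  df
}
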