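#' Contig summary statistics of an assembly
#'
#' Total size, longest contig, contig N50 and contig count. N50 is the
#' length of the contig at which the cumulative length, taken in descending
#' order, first reaches half the assembly size.
#'
#' @param assembly FASTA path, [Biostrings::DNAStringSet], or a numeric
#'   vector of contig lengths.
#' @return An `assembly_stats` list: `total_size`, `max_contig`, `n50`,
#'   `n_contigs`.
#' @examples
#' assembly_stats(c(40, 30, 20, 10)) # N50 = 30
#' @export
assembly_stats <- function(assembly) {
  lens <- if (is.numeric(assembly)) as.numeric(assembly)
  else as.numeric(Biostrings::width(as_sequences(assembly)))
  if (length(lens) == 0L) stop("empty assembly", call. = FALSE)
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1]]
  structure(list(total_size = total, max_contig = lens[1], n50 = n50,
                 n_contigs = length(lens)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  Total size:     %s bp\n", format(x$total_size, big.mark = ",")))
  cat(sprintf("  Longest contig: %s bp\n", format(x$max_contig, big.mark = ",")))
  cat(sprintf("  Contig N50:     %s bp\n", format(x$n50, big.mark = ",")))
  cat(sprintf("  Contigs:        %d\n", x$n_contigs))
  invisible(x)
}

#' Scan contig ends for telomeric repeat arrays
#'
#' Searches the terminal `end_window` of every contig for clustered copies
#' of a telomere motif: the G-rich display form near 3' ends and its
#' reverse complement near 5' ends (the G-strand runs toward the terminus).
#' Consecutive copies with inter-copy gaps of at most `max_gap` bp form a
#' cluster; a cluster of at least `min_copies` copies yields a call.
#'
#' @param assembly FASTA path or [Biostrings::DNAStringSet].
#' @param motif Telomere motif display form (default TTTAGGG).
#' @param end_window Bases scanned from each terminus (default 10000).
#' @param min_copies Minimum clustered copies per call (default 10).
#' @param max_gap Maximum gap between consecutive copies (default 50).
#' @return Data.frame with columns `contig`, `end` (`"5'"`/`"3'"`), `motif`,
#'   `copies`, `span` (bp from the contig terminus covered by the cluster).
#' @export
scan_contig_ends <- function(assembly, motif = "TTTAGGG",
                             end_window = 10000L, min_copies = 10L,
                             max_gap = 50L) {
  motif <- assert_dna(motif, "motif")
  contigs <- as_sequences(assembly)
  rc <- revcomp_chr(motif)
  mlen <- nchar(motif)
  calls <- list()
  for (i in seq_along(contigs)) {
    len <- Biostrings::width(contigs[i])
    w <- min(end_window, len)
    # 5' terminus: C-strand copies
    head_seq <- Biostrings::subseq(contigs[[i]], 1L, w)
    st <- Biostrings::start(Biostrings::matchPattern(rc, head_seq))
    cl <- best_cluster(st, mlen, max_gap)
    if (!is.null(cl) && cl$n >= min_copies)
      calls[[length(calls) + 1L]] <- data.frame(
        contig = names(contigs)[i], end = "5'", motif = motif,
        copies = cl$n, span = cl$last_end, stringsAsFactors = FALSE)
    # 3' terminus: G-strand copies
    tail_seq <- Biostrings::subseq(contigs[[i]], len - w + 1L, len)
    st <- Biostrings::start(Biostrings::matchPattern(motif, tail_seq))
    cl <- best_cluster(st, mlen, max_gap)
    if (!is.null(cl) && cl$n >= min_copies)
      calls[[length(calls) + 1L]] <- data.frame(
        contig = names(contigs)[i], end = "3'", motif = motif,
        copies = cl$n, span = w - cl$first_start + 1L,
        stringsAsFactors = FALSE)
  }
  if (length(calls)) do.call(rbind, calls)
  else data.frame(contig = character(0), end = character(0),
                  motif = character(0), copies = integer(0),
                  span = integer(0), stringsAsFactors = FALSE)
}

# Largest run of match starts whose consecutive gaps (distance between the
# end of one copy and the start of the next) stay within max_gap.
best_cluster <- function(starts, mlen, max_gap) {
  if (length(starts) == 0L) return(NULL)
  starts <- sort(starts)
  gap <- starts[-1] - (starts[-length(starts)] + mlen)
  brk <- c(0L, which(gap > max_gap), length(starts))
  best <- NULL
  for (j in seq_len(length(brk) - 1L)) {
    idx <- (brk[j] + 1L):brk[j + 1L]
    if (is.null(best) || length(idx) > best$n)
      best <- list(n = length(idx), first_start = starts[idx[1]],
                   last_end = starts[idx[length(idx)]] + mlen - 1L)
  }
  best
}
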