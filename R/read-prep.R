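#' Deterministically subsample record indices
#'
#' Core of the read subsampler: draws `n` of `n_total` record indices
#' uniformly without replacement under a fixed seed and returns them in
#' increasing order, so downstream record selection preserves the input's
#' relative order.
#'
#' @param n_total Number of records available.
#' @param n Number to keep.
#' @param seed RNG seed (default 42).
#' @param first_n Take the first `n` records instead of a uniform draw.
#' @return Sorted integer vector of length `n`.
#' @export
subsample_indices <- function(n_total, n, seed = 42L, first_n = FALSE) {
  stopifnot(n > 0, n <= n_total)
  if (first_n) return(seq_len(n))
  if (n == n_total) return(seq_len(n_total))
  with_seed(seed, sort(sample.int(n_total, n)))
}

#' Subsample sequencing reads without replacement
#'
#' Draws a fixed-size uniform subsample of FASTQ records (default 20
#' million, the depth used for telomere motif screening of ~30x Illumina
#' runs) with the input order preserved. Deterministic under `seed`.
#'
#' @param reads A FASTQ path or a [Biostrings::DNAStringSet].
#' @param n Records to keep (default 2e7).
#' @param seed RNG seed (default 42).
#' @param allow_fewer If the input holds fewer than `n` records, pass all of
#'   them through with a warning instead of erroring.
#' @param first_n Keep the first `n` records instead of sampling.
#' @param out Optional FASTQ output path; when given, the subsample is
#'   written there and the path returned invisibly.
#' @return The subsampled reads (same container as the input), or `out`.
#' @export
subsample_reads <- function(reads, n = 2e7, seed = 42L, allow_fewer = FALSE,
                            first_n = FALSE, out = NULL) {
  from_file <- is.character(reads) && length(reads) == 1L
  x <- if (from_file) read_fastq(reads) else reads
  n_total <- length(x)
  if (n > n_total) {
    if (!allow_fewer)
      stop(sprintf("requested %d records but input has only %d", n, n_total),
           call. = FALSE)
    warning(sprintf("input has %d < %d records; passing all through",
                    n_total, n), call. = FALSE)
    keep <- seq_len(n_total)
  } else {
    keep <- subsample_indices(n_total, n, seed = seed, first_n = first_n)
  }
  x <- x[keep]
  if (!is.null(out)) {
    write_fastq_records(x, out)
    return(invisible(out))
  }
  x
}

#' Trimming policy for telomere window extraction
#'
#' The screening design keeps a fixed interior window of each 151-bp read:
#' the first 10 bp and the last 81 bp are discarded, leaving a 60-bp window
#' (10 + 60 + 81 = 151). The leading cut avoids adapter/quality artefacts at
#' read starts; the short window keeps the fully-periodic requirement of the
#' tandem scan strict.
#'
#' @param leading_trim Bases removed from the read start (default 10).
#' @param window_width Window width retained (default 60).
#' @param trailing_trim Nominal bases removed from the read end (default 81;
#'   informational — not enforced against actual read length, so
#'   mixed-length input is tolerated).
#' @return A `trim_policy` list.
#' @export
trim_policy <- function(leading_trim = 10L, window_width = 60L,
                        trailing_trim = 81L) {
  stopifnot(leading_trim >= 0L, window_width > 0L, trailing_trim >= 0L)
  structure(list(leading_trim = as.integer(leading_trim),
                 window_width = as.integer(window_width),
                 trailing_trim = as.integer(trailing_trim)),
            class = "trim_policy")
}

#' Extract fixed interior windows from reads
#'
#' Returns positions `[leading_trim, leading_trim + window_width)` (0-based
#' half-open) of each read. Reads too short to contain the window are
#' skipped, not truncated: skipped count + emitted count equals the input
#' count.
#'
#' @param reads Character vector, [Biostrings::DNAStringSet], or FASTQ path.
#' @param policy A [trim_policy()].
#' @return Character vector of windows with attribute `n_skipped`.
#' @examples
#' trim_to_window(strrep("A", 151)) # 60-bp window starting at position 10
#' @export
trim_to_window <- function(reads, policy = trim_policy()) {
  stopifnot(inherits(policy, "trim_policy"))
  x <- if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    as.character(read_fastq(reads))
  else if (is.character(reads)) reads
  else as.character(as_sequences(reads))
  need <- policy$leading_trim + policy$window_width
  ok <- nchar(x) >= need
  win <- substr(x[ok], policy$leading_trim + 1L, need)
  structure(win, n_skipped = sum(!ok))
}
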