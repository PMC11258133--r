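## Internal helpers shared across modules.

# data.table is used via :: only; mark the package data.table-aware so
# `:=` works inside functions.
.datatable.aware <- TRUE

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# Vectorised reverse complement on plain character vectors.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All rotations of a single string.
rotations_chr <- function(x) {
  n <- nchar(x)
  if (n == 1L) return(x)
  dbl <- paste0(x, x)
  substring(dbl, seq_len(n), seq_len(n) + n - 1L)
}

assert_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x) || grepl("[^ACGTacgt]", x))
    stop(sprintf("%s must be a non-empty string over A/C/G/T", what),
         call. = FALSE)
  toupper(x)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Read sequences from a DNAStringSet, character vector, or FASTA/FASTQ path.
as_sequences <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- sniff_seq_format(x)
    return(Biostrings::readDNAStringSet(x, format = fmt))
  }
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("cannot interpret input as sequences (DNAStringSet, character, or file path)",
       call. = FALSE)
}

sniff_seq_format <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("fasta")
  if (startsWith(first, "@")) "fastq" else "fasta"
}

#' Write sequences as FASTQ with constant qualities
#'
#' Emits 4-line FASTQ records with every base at quality `I` (Q40). No stage
#' of the pipeline consumes base qualities, so a constant placeholder keeps
#' the simulated files small and byte-reproducible.
#'
#' @param x A [Biostrings::DNAStringSet] (names become record ids).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' @param path FASTQ path (gzip-transparent).
#' @return A [Biostrings::DNAStringSet]; per-record qualities are kept in the
#'   `qualities` metadata column so records round-trip through
#'   [write_fastq_records()].
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
}

# Write records read by read_fastq() preserving their original qualities.
write_fastq_records <- function(x, path) {
  q <- S4Vectors::mcols(x)$qualities
  if (is.null(q)) return(write_fastq(x, path))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}
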