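#' Simulate Illumina-like short reads from a (diploid) genome
#'
#' Fixed-length reads drawn uniformly from both haplotypes and both strands,
#' with independent per-base substitution errors. Deterministic under
#' `seed`.
#'
#' @param genome Output of [simulate_genome()], its `haplotypes` element, or
#'   any [Biostrings::DNAStringSet].
#' @param n_reads Number of reads (> 0).
#' @param read_length Read length in bp (default 151, the standard
#'   paired-end NovaSeq read length).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed RNG seed.
#' @param out Optional FASTQ output path (constant Q40 qualities).
#' @return A named [Biostrings::DNAStringSet], or `out` invisibly.
#' @export
simulate_short_reads <- function(genome, n_reads, read_length = 151L,
                                 error_rate = 0, seed = 1L, out = NULL) {
  if (n_reads <= 0) stop("n_reads must be positive", call. = FALSE)
  pool <- genome_pool(genome)
  if (read_length > min(nchar(pool$seq)))
    stop("read_length exceeds the shortest chromosome", call. = FALSE)
  reads <- with_seed(seed, {
    x <- draw_reads(pool, n_reads, rep(as.integer(read_length), n_reads))
    if (error_rate > 0) x <- add_substitution_errors(x, error_rate)
    x
  })
  res <- Biostrings::DNAStringSet(reads)
  names(res) <- sprintf("read_%d", seq_len(n_reads))
  if (!is.null(out)) {
    write_fastq(res, out)
    return(invisible(out))
  }
  res
}

#' Simulate HiFi-like long reads at a target coverage
#'
#' Read lengths follow a lognormal distribution with the requested mean
#' (HiFi libraries centre near 17–18 kb); reads are error-free by default,
#' matching >= Q20 consensus accuracy. Reads are drawn until the summed
#' bases first reach `coverage` times the haploid genome size, so total
#' yield matches the request to within one read length.
#'
#' @inheritParams simulate_short_reads
#' @param coverage Fold coverage of the haploid genome (> 0).
#' @param mean_length Mean read length in bp (default 17289).
#' @param sdlog Lognormal shape parameter (default 0.35).
#' @param error_rate Optional per-base substitution rate (default 0).
#' @param out Optional FASTA output path.
#' @return A named [Biostrings::DNAStringSet], or `out` invisibly.
#' @export
simulate_long_reads <- function(genome, coverage, mean_length = 17289,
                                sdlog = 0.35, error_rate = 0, seed = 1L,
                                out = NULL) {
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  pool <- genome_pool(genome)
  min_chrom <- min(nchar(pool$seq))
  if (mean_length >= min_chrom)
    stop("mean_length must be below the shortest chromosome length",
         call. = FALSE)
  target <- coverage * pool$haploid_size
  reads <- with_seed(seed, {
    meanlog <- log(mean_length) - sdlog^2 / 2
    lens <- integer(0)
    while (sum(lens) < target) {
      batch <- pmin(pmax(round(rlnorm(ceiling(target / mean_length) + 100L,
                                      meanlog, sdlog)), 100L), min_chrom)
      lens <- c(lens, batch)
    }
    lens <- lens[seq_len(which(cumsum(lens) >= target)[1])]
    x <- draw_reads(pool, length(lens), as.integer(lens))
    if (error_rate > 0) x <- add_substitution_errors(x, error_rate)
    x
  })
  res <- Biostrings::DNAStringSet(reads)
  names(res) <- sprintf("longread_%d", seq_along(res))
  if (!is.null(out)) {
    Biostrings::writeXStringSet(res, out)
    return(invisible(out))
  }
  res
}

# Flatten a genome argument into a chromosome pool. haploid_size is the
# reference (haplotype A) size when a diploid is given.
genome_pool <- function(genome) {
  if (is.list(genome) && !is.null(genome$haplotypes))
    genome <- genome$haplotypes
  if (methods::is(genome, "DNAStringSet")) genome <- list(genome)
  sets <- lapply(genome, function(g) as.character(as_sequences(g)))
  list(seq = unlist(sets, use.names = FALSE),
       haploid_size = sum(nchar(sets[[1]])))
}

# Vectorised extraction of n reads with given lengths: uniform over valid
# start positions across the pool, both strands equally.
draw_reads <- function(pool, n, lens) {
  seqs <- pool$seq
  L <- nchar(seqs)
  out <- character(n)
  # chromosome weights proportional to valid start positions for each length;
  # length variation across reads is small relative to chromosomes, so
  # weight by chromosome length (exact for fixed-length reads after
  # conditioning on validity)
  ci <- sample.int(length(seqs), n, replace = TRUE, prob = L)
  valid <- L[ci] - lens + 1L
  redo <- which(valid < 1L)
  while (length(redo)) { # resample reads longer than their chromosome
    ci[redo] <- sample.int(length(seqs), length(redo), replace = TRUE, prob = L)
    valid <- L[ci] - lens + 1L
    redo <- which(valid < 1L)
  }
  starts <- floor(runif(n) * valid) + 1L
  for (s in unique(ci)) {
    sel <- ci == s
    out[sel] <- substring(seqs[s], starts[sel], starts[sel] + lens[sel] - 1L)
  }
  rc <- runif(n) < 0.5
  if (any(rc)) out[rc] <- revcomp_chr(out[rc])
  out
}

# Independent per-base substitution errors.
add_substitution_errors <- function(reads, rate) {
  n_err <- rbinom(length(reads), nchar(reads), rate)
  for (j in which(n_err > 0L)) {
    s <- strsplit(reads[j], "")[[1]]
    pos <- sample.int(length(s), n_err[j])
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
    reads[j] <- paste(s, collapse = "")
  }
  reads
}
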