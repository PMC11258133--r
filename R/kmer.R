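#' Count canonical k-mers into a multiplicity histogram
#'
#' Counts every k-mer of every input sequence in canonical form (the
#' lexicographically smaller of the k-mer and its reverse complement, so
#' both sequencing strands collapse onto one key) and tabulates the
#' multiplicity spectrum: how many distinct k-mers were seen exactly m
#' times. k-mers containing any non-ACGT base are skipped. The spectrum's
#' peaks encode sequencing coverage, heterozygosity and repeat content and
#' feed [fit_genome_profile()].
#'
#' @param reads FASTA/FASTQ path, [Biostrings::DNAStringSet], or character
#'   vector of sequences.
#' @param k K-mer size, 1–31 (27 is the usual choice for 151-bp short reads,
#'   21 for HiFi reads; odd k avoids palindromic self-canonical k-mers).
#' @return A `kmer_histogram`: data.frame with columns `multiplicity` and
#'   `count`, attributes `k` and `total_kmers` (= sum of
#'   multiplicity * count = number of valid k-mer positions).
#' @examples
#' count_kmers("ACGT", k = 3) # ACG and CGT share a canonical form: {2: 1}
#' @export
count_kmers <- function(reads, k = 27L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) stop("k must be in 1..31", call. = FALSE)
  seqs <- if (is.character(reads) && !(length(reads) == 1L && file.exists(reads)))
    reads else as.character(as_sequences(reads))
  res <- kmer_histogram_cpp(seqs, k)
  new_kmer_histogram(data.frame(multiplicity = res$multiplicity,
                                count = res$count), k, res$total_kmers)
}

new_kmer_histogram <- function(df, k, total = sum(df$multiplicity * df$count)) {
  structure(df, k = as.integer(k), total_kmers = total,
            class = c("kmer_histogram", "data.frame"))
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer multiplicity histogram (k = %d): %d distinct multiplicities, %s k-mers\n",
              attr(x, "k"), nrow(x),
              format(attr(x, "total_kmers"), big.mark = ",")))
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a k-mer histogram from two-column text
#'
#' Whitespace-separated "multiplicity count" lines, the dump format shared
#' by the common k-mer counters; `#`-prefixed header lines are skipped.
#'
#' @param path Input path.
#' @param k K-mer size to record on the histogram (optional; `NA` if
#'   unknown).
#' @return A `kmer_histogram`.
#' @export
read_kmer_histogram <- function(path, k = NA_integer_) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  if (length(body) == 0L)
    return(new_kmer_histogram(data.frame(multiplicity = numeric(0),
                                         count = numeric(0)), k, 0))
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("malformed histogram line %d: %s",
                 which(keep)[bad[1]], body[bad[1]]), call. = FALSE)
  m <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  cnt <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  bad <- which(is.na(m) | is.na(cnt) | m < 1 | cnt < 0)
  if (length(bad))
    stop(sprintf("invalid multiplicity/count on histogram line %d: %s",
                 which(keep)[bad[1]], body[bad[1]]), call. = FALSE)
  o <- order(m)
  new_kmer_histogram(data.frame(multiplicity = m[o], count = cnt[o]), k)
}

#' Write a k-mer histogram as two-column text
#'
#' @param hist A `kmer_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  write.table(as.data.frame(hist)[, c("multiplicity", "count")], path,
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a genome profile from a k-mer spectrum
#'
#' A peak-based diploid model of the k-mer multiplicity spectrum. The error
#' boundary `m0` is the first trough scanned from multiplicity 1 (erroneous
#' k-mers are near-unique and pile up at low multiplicity); the dominant
#' peak above it is located, and if a companion peak sits near twice its
#' position the spectrum is read as heterozygous + homozygous peaks
#' (`kcov` = lower peak), otherwise the single peak is the homozygous one.
#' The estimates are then:
#' \itemize{
#'   \item `len` — genome size: k-mer mass above `m0` divided by the
#'     homozygous coverage;
#'   \item `ab` — per-base heterozygosity from the heterozygous mass
#'     fraction `f` via `ab = 1 - (1 - f)^(1/k)` (a k-bp window is
#'     haplotype-specific if any of its k bases carries a SNP);
#'   \item `aa` — homozygosity, `1 - ab`;
#'   \item `err` — fraction of k-mer mass below the error boundary;
#'   \item `uniq` — fraction of the genome in single-copy sequence (mass up
#'     to 1.5x the homozygous coverage over `hom * len`);
#'   \item `dup` — read duplication rate, not estimated by this model
#'     (`NA`).
#' }
#' This is a deliberately simple estimator: no mixture model is fitted, so
#' it recovers simulated truth well but is not expected to match
#' GenomeScope-style fits on real, repeat-rich spectra.
#'
#' @param hist A `kmer_histogram`.
#' @param ploidy Reported ploidy (the model itself is diploid; default 2).
#' @param max_multiplicity Histogram tail cap (default 1e6).
#' @param smooth Moving-average window applied to counts before peak
#'   finding; 0 (default) disables, 3 suits noisy desk-scale spectra.
#' @return A `genome_profile` list with fields `len`, `uniq`, `aa`, `ab`,
#'   `kcov`, `err`, `dup`, `k`, `p`, plus diagnostic attributes
#'   `error_boundary` and `hom_coverage`.
#' @export
fit_genome_profile <- function(hist, ploidy = 2L, max_multiplicity = 1e6,
                               smooth = 0L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  df <- as.data.frame(hist)
  df <- df[df$multiplicity <= max_multiplicity, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty histogram", call. = FALSE)
  M <- max(df$multiplicity)
  h <- numeric(M)
  h[df$multiplicity] <- df$count
  hs <- h
  if (smooth > 0L) {
    w <- 2L * (as.integer(smooth) %/% 2L) + 1L # force odd window
    hs <- as.numeric(stats::filter(h, rep(1 / w, w), sides = 2))
    hs[is.na(hs)] <- h[is.na(hs)]
  }

  # first trough from the left: local minimum (plateau-tolerant)
  m0 <- NA_integer_
  for (m in seq_len(M - 1L)) {
    if (hs[m] <= hs[m + 1L] && (m == 1L || hs[m] <= hs[m - 1L])) {
      m0 <- m
      break
    }
  }
  if (is.na(m0) || m0 >= M || max(hs[(m0 + 1L):M]) <= hs[m0])
    stop("cannot separate error k-mers: histogram has no interior minimum followed by a peak",
         call. = FALSE)

  peak <- which.max(hs[(m0 + 1L):M]) + m0
  # companion peak near twice the main peak's position?
  lo <- max(peak + 1L, round(1.6 * peak))
  hi <- min(M, round(2.4 * peak))
  two_peaks <- FALSE
  if (lo < hi) {
    cand <- which.max(hs[lo:hi]) + lo - 1L
    if (cand > 1L && cand < M &&
        hs[cand] >= hs[cand - 1L] && hs[cand] >= hs[cand + 1L] &&
        hs[cand] >= 0.1 * hs[peak])
      two_peaks <- TRUE
  }
  if (two_peaks) {
    kcov <- peak
    hom <- 2 * kcov
  } else {
    hom <- peak
    kcov <- hom / 2
  }

  mass <- h * seq_len(M)
  genomic_mass <- sum(mass[(m0 + 1L):M])
  len <- genomic_mass / hom
  het_hi <- min(M, floor(1.5 * kcov))
  f_het <- if (het_hi > m0) sum(mass[(m0 + 1L):het_hi]) / genomic_mass else 0
  k <- attr(hist, "k")
  ab <- 1 - (1 - f_het)^(1 / k)
  total <- sum(mass)
  err <- sum(mass[seq_len(m0)]) / total
  uniq_hi <- min(M, floor(1.5 * hom))
  uniq <- sum(mass[(m0 + 1L):uniq_hi]) / (hom * len)

  structure(list(len = len, uniq = uniq, aa = 1 - ab, ab = ab,
                 kcov = kcov, err = err, dup = NA_real_,
                 k = k, p = as.integer(ploidy)),
            error_boundary = m0, hom_coverage = hom,
            class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  fmt_bp <- function(b) {
    if (b >= 1e6) sprintf("%.1f Mb", b / 1e6)
    else if (b >= 1e3) sprintf("%.1f kb", b / 1e3)
    else sprintf("%.0f bp", b)
  }
  cat("Genome profile (k-mer spectrum fit)\n")
  cat(sprintf("  len:  %s (estimated genome size)\n", fmt_bp(x$len)))
  cat(sprintf("  uniq: %.1f%% (unique-sequence fraction)\n", 100 * x$uniq))
  cat(sprintf("  aa:   %.3f%%  ab: %.3f%% (homo/heterozygosity)\n",
              100 * x$aa, 100 * x$ab))
  cat(sprintf("  kcov: %.1f (heterozygous k-mer coverage)\n", x$kcov))
  cat(sprintf("  err:  %.2f%% (error k-mer mass)\n", 100 * x$err))
  cat(sprintf("  dup:  %s\n", if (is.na(x$dup)) "not estimated" else x$dup))
  cat(sprintf("  k: %d  p: %d\n", x$k, x$p))
  invisible(x)
}
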