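# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# Smallest period of a window under the mismatch rule, trying every u up to
# max_len; returns NA when no in-range period qualifies.
oracle_tandem <- function(w, min_len = 6L, max_len = 10L, max_mismatch = 0L,
                          min_copies = 4L) {
  s <- strsplit(w, "")[[1]]
  L <- length(s)
  if (L < 2L * min_len) return(NULL)
  for (u in seq_len(min(max_len, L %/% 2L))) {
    i <- seq_len(L - u)
    bad <- sum(s[i] != s[i + u] | !(s[i] %in% c("A", "C", "G", "T")) |
                 !(s[i + u] %in% c("A", "C", "G", "T")))
    if (bad <= max_mismatch) {
      if (u < min_len || u > max_len) return(NULL)
      copies <- L %/% u
      if (copies < min_copies) return(NULL)
      unit <- paste(s[seq_len(u)], collapse = "")
      # primitive?
      for (d in seq_len(u %/% 2L)) {
        if (u %% d == 0L &&
            identical(strrep(paste(s[seq_len(d)], collapse = ""), u %/% d),
                      unit))
          return(NULL)
      }
      return(list(unit = unit, copies = copies))
    }
  }
  NULL
}

# Plain dynamic-programming Levenshtein distance.
oracle_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- numeric(length(b) + 1L)
    cur[1] <- i
    for (j in seq_along(b)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[length(b) + 1L]
}

oracle_rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n), function(i)
    paste0(substr(x, i, n), substr(x, 1, i - 1L)), character(1))
}

oracle_circular_edit <- function(unit, motif) {
  forms <- c(oracle_rotations(unit), oracle_rotations(oracle_revcomp(unit)))
  min(vapply(forms, oracle_levenshtein, numeric(1), b = motif))
}

# N50 by explicit scan over the sorted lengths.
oracle_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  run <- 0
  for (l in lens) {
    run <- run + l
    if (run >= half) return(l)
  }
}

# Canonical k-mer counts with a plain R dictionary.
oracle_kmer_histogram <- function(seqs, k) {
  counts <- new.env(hash = TRUE)
  n_pos <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      canon <- if (km <= rc) km else rc
      counts[[canon]] <- (counts[[canon]] %||% 0L) + 1L
      n_pos <- n_pos + 1L
    }
  }
  mult <- unlist(as.list(counts), use.names = FALSE)
  list(hist = table(mult), n_positions = n_pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-open interval overlap by exhaustive pairwise comparison.
oracle_affected_genes <- function(cds, foot) {
  hit <- character(0)
  for (i in seq_len(nrow(cds))) {
    for (j in seq_len(nrow(foot))) {
      if (cds$chrom[i] == foot$contig[j] &&
          cds$start[i] < foot$end[j] && foot$start[j] < cds$end[i])
        hit <- c(hit, cds$gene_id[i])
    }
  }
  sort(unique(hit))
}

random_dna_string <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
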