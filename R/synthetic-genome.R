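#' Specification of a synthetic diploid test genome
#'
#' Describes a small diploid genome with telomeric tandem arrays at both
#' ends of every chromosome, interspersed repeat families, and a planted
#' haplotype divergence (SNPs and structural variants). The defaults mirror
#' a compact diploid plant design: a handful of chromosomes, the
#' Arabidopsis-type telomere TTTAGGG arrayed at chromosome termini, and
#' sub-percent heterozygosity.
#'
#' @param n_chromosomes Number of chromosomes (default 1).
#' @param chrom_length_bp Length of each chromosome (default 100000); must
#'   exceed twice the telomere span.
#' @param telomere_motif Telomere repeat unit, G-rich strand (default
#'   `"TTTAGGG"`).
#' @param telomere_copies_per_end Tandem copies per chromosome end (default
#'   50).
#' @param repeat_fraction Fraction of the genome covered by interspersed
#'   repeat families, in `[0, 1)` (default 0).
#' @param snp_rate Heterozygous substitutions per bp, in `[0, 0.05)`
#'   (default 0).
#' @param sv_events Structural variants to plant on haplotype B: a
#'   data.frame (or list of lists) with columns `type` (one of DEL, INS,
#'   INV, DUP:INT, DUP:TANDEM), `length` (bp) and `count`.
#' @param seed RNG seed; a fixed seed makes every output byte-identical.
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 1L,
                                  chrom_length_bp = 1e5,
                                  telomere_motif = "TTTAGGG",
                                  telomere_copies_per_end = 50L,
                                  repeat_fraction = 0,
                                  snp_rate = 0,
                                  sv_events = NULL,
                                  seed = 1L) {
  telomere_motif <- assert_dna(telomere_motif, "telomere_motif")
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_length_bp <- as.integer(chrom_length_bp)
  telomere_copies_per_end <- as.integer(telomere_copies_per_end)
  stopifnot(n_chromosomes >= 1L, telomere_copies_per_end >= 1L)
  span <- nchar(telomere_motif) * telomere_copies_per_end
  if (chrom_length_bp <= 2L * span)
    stop(sprintf(
      "infeasible spec: chromosome length %d must exceed twice the telomere span (2 x %d bp)",
      chrom_length_bp, span), call. = FALSE)
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    stop("repeat_fraction must be in [0, 1)", call. = FALSE)
  if (snp_rate < 0 || snp_rate >= 0.05)
    stop("snp_rate must be in [0, 0.05)", call. = FALSE)
  if (!is.null(sv_events)) {
    if (!is.data.frame(sv_events))
      sv_events <- do.call(rbind, lapply(sv_events, function(e)
        data.frame(type = e$type, length = e$length, count = e$count,
                   stringsAsFactors = FALSE)))
    stopifnot(all(c("type", "length", "count") %in% names(sv_events)))
    bad <- setdiff(sv_events$type, SV_TYPES)
    if (length(bad))
      stop("unknown SV type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 telomere_motif = telomere_motif,
                 telomere_copies_per_end = telomere_copies_per_end,
                 telomere_span = span,
                 repeat_fraction = repeat_fraction,
                 snp_rate = snp_rate,
                 sv_events = sv_events,
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

SV_TYPES <- c("DEL", "INS", "INV", "DUP:INT", "DUP:TANDEM")

# Repeat-family classes cycled over generated families, chosen so every
# RepeatMasker summary category is exercised.
REPEAT_FAMILY_CLASSES <- c("LTR/Gypsy", "DNA/hAT", "LINE/L1", "RC/Helitron",
                           "Satellite", "Simple_repeat", "Low_complexity",
                           "snRNA", "Unknown")

#' Simulate a diploid genome with recorded ground truth
#'
#' Builds haplotype A (the reference) chromosome by chromosome: a C-strand
#' telomere array at the 5' terminus, random single-copy interior sequence
#' interrupted by shuffled copies of a small set of random repeat families,
#' planted gene/CDS intervals, and a G-strand telomere array at the 3'
#' terminus. Haplotype B is haplotype A with the requested SNPs substituted
#' and structural variants applied. Every planted feature is recorded in
#' the returned truth set, so downstream stages can be validated exactly.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list with elements `haplotypes` (list of two named
#'   [Biostrings::DNAStringSet]s, `A` and `B`) and `truth` (a list holding
#'   `telomere_motif`, `snps`, `svs`, `repeats`, `genes`, `cds`,
#'   `chrom_lengths`, `genome_size`, `het_rate`).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  with_seed(spec$seed, simulate_genome_impl(spec))
}

simulate_genome_impl <- function(spec) {
  L <- spec$chrom_length_bp
  span <- spec$telomere_span
  motif <- spec$telomere_motif
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  telo_g <- strsplit(strrep(motif, spec$telomere_copies_per_end), "")[[1]]
  telo_c <- strsplit(revcomp_chr(paste(telo_g, collapse = "")), "")[[1]]

  hapA <- vector("list", length(chroms))
  names(hapA) <- chroms
  for (ci in seq_along(chroms)) {
    interior <- sample(DNA_BASES, L - 2L * span, replace = TRUE)
    hapA[[ci]] <- c(telo_c, interior, telo_g)
  }

  ## interspersed repeat families
  repeats <- empty_repeat_truth()
  if (spec$repeat_fraction > 0) {
    n_fam <- sample(3:10, 1L)
    fam_len <- sample(300:5000, n_fam, replace = TRUE)
    fam_seq <- lapply(fam_len, function(n) sample(DNA_BASES, n, replace = TRUE))
    fam_name <- sprintf("synthFam%02d", seq_len(n_fam))
    fam_class <- rep_len(REPEAT_FAMILY_CLASSES, n_fam)
    target <- spec$repeat_fraction * L * length(chroms)
    placed <- 0
    occupied <- lapply(chroms, function(x) cbind(start = integer(0), end = integer(0)))
    names(occupied) <- chroms
    rows <- list()
    attempts <- 0L
    fam_i <- 0L
    while (placed < target && attempts < 50000L) {
      attempts <- attempts + 1L
      fam_i <- fam_i %% n_fam + 1L
      len <- fam_len[fam_i]
      ci <- sample.int(length(chroms), 1L)
      lo <- span
      hi <- L - span - len
      if (hi <= lo) next
      s0 <- lo + sample.int(hi - lo, 1L) # 0-based start
      occ <- occupied[[ci]]
      if (nrow(occ) && any(s0 < occ[, "end"] & s0 + len > occ[, "start"])) next
      hapA[[ci]][(s0 + 1L):(s0 + len)] <- fam_seq[[fam_i]]
      occupied[[ci]] <- rbind(occ, cbind(start = s0, end = s0 + len))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chroms[ci], start = s0, end = s0 + len,
        family = fam_name[fam_i], class = fam_class[fam_i],
        stringsAsFactors = FALSE)
      placed <- placed + len
    }
    if (length(rows)) repeats <- do.call(rbind, rows)
  }

  ## gene / CDS intervals (annotation consumers only; sequence untouched)
  genes <- empty_gene_truth()
  cds <- empty_cds_truth()
  g_rows <- list()
  c_rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    n_genes <- max(1L, (L - 2L * span) %/% 20000L)
    cursor <- span + 100L
    for (g in seq_len(n_genes)) {
      glen <- sample(1000:5000, 1L)
      gap <- sample(2000:10000, 1L)
      s0 <- cursor + gap
      if (s0 + glen > L - span - 100L) break
      gid <- gid + 1L
      id <- sprintf("gene%04d", gid)
      g_rows[[length(g_rows) + 1L]] <- data.frame(
        gene_id = id, chrom = chroms[ci], start = s0, end = s0 + glen,
        stringsAsFactors = FALSE)
      n_cds <- sample(1:3, 1L)
      bounds <- sort(sample(seq(0L, glen - 100L, by = 50L), n_cds))
      for (b in bounds) {
        clen <- min(sample(100:400, 1L), glen - b)
        c_rows[[length(c_rows) + 1L]] <- data.frame(
          gene_id = id, chrom = chroms[ci], start = s0 + b,
          end = s0 + b + clen, stringsAsFactors = FALSE)
      }
      cursor <- s0 + glen
    }
  }
  if (length(g_rows)) genes <- do.call(rbind, g_rows)
  if (length(c_rows)) {
    cds <- do.call(rbind, c_rows)
    # collapse accidental overlaps among a gene's CDS parts
    cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  }

  ## SNPs: heterozygous substitutions in the interior
  snps <- empty_snp_truth()
  if (spec$snp_rate > 0) {
    s_rows <- list()
    for (ci in seq_along(chroms)) {
      interior_len <- L - 2L * span
      pos0 <- which(runif(interior_len) < spec$snp_rate) + span - 1L
      if (!length(pos0)) next
      ref <- hapA[[ci]][pos0 + 1L]
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                    character(1), USE.NAMES = FALSE)
      s_rows[[length(s_rows) + 1L]] <- data.frame(
        chrom = chroms[ci], pos = pos0, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    }
    if (length(s_rows)) snps <- do.call(rbind, s_rows)
  }

  ## haplotype B: substitutions, then SV edits applied right-to-left
  hapB <- hapA
  if (nrow(snps)) {
    for (ci in seq_along(chroms)) {
      sel <- snps$chrom == chroms[ci]
      if (any(sel)) hapB[[ci]][snps$pos[sel] + 1L] <- snps$alt[sel]
    }
  }

  svs <- empty_sv_truth()
  if (!is.null(spec$sv_events) && nrow(spec$sv_events)) {
    ev <- spec$sv_events[rep(seq_len(nrow(spec$sv_events)),
                             spec$sv_events$count), c("type", "length")]
    n_sv <- nrow(ev)
    # footprints (plus insertion sites for interspersed duplications) are
    # sampled without overlap inside the interior
    taken <- lapply(chroms, function(x) cbind(start = integer(0), end = integer(0)))
    names(taken) <- chroms
    rows <- list()
    edits <- list()
    for (j in seq_len(n_sv)) {
      len <- as.integer(ev$length[j])
      type <- ev$type[j]
      placed_ok <- FALSE
      for (try in 1:1000) {
        ci <- sample.int(length(chroms), 1L)
        lo <- span + 10L
        hi <- L - span - len - 10L
        if (hi <= lo) break
        s0 <- lo + sample.int(hi - lo, 1L)
        occ <- taken[[ci]]
        if (nrow(occ) && any(s0 < occ[, "end"] + 10L &
                             s0 + len + 10L > occ[, "start"])) next
        ins_at <- NA_integer_
        if (type == "DUP:INT") {
          ok2 <- FALSE
          for (try2 in 1:1000) {
            i0 <- lo + sample.int(hi - lo, 1L)
            occ2 <- taken[[ci]]
            if (nrow(occ2) && any(i0 < occ2[, "end"] + 10L &
                                  i0 + 10L > occ2[, "start"])) next
            if (abs(i0 - s0) < len + 20L) next
            ins_at <- i0
            ok2 <- TRUE
            break
          }
          if (!ok2) next
          taken[[ci]] <- rbind(taken[[ci]], cbind(start = ins_at, end = ins_at + 1L))
        }
        taken[[ci]] <- rbind(taken[[ci]], cbind(start = s0, end = s0 + len))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chroms[ci], start = s0, type = type, length = len,
          stringsAsFactors = FALSE)
        edits[[length(edits) + 1L]] <- list(chrom = ci, start = s0,
                                            type = type, length = len,
                                            ins_at = ins_at)
        placed_ok <- TRUE
        break
      }
      if (!placed_ok)
        stop("could not place all requested SV events; reduce counts/lengths",
             call. = FALSE)
    }
    svs <- do.call(rbind, rows)
    # apply per chromosome, highest coordinate first, so earlier (left)
    # coordinates stay valid
    for (ci in seq_along(chroms)) {
      ed <- Filter(function(e) e$chrom == ci, edits)
      if (!length(ed)) next
      # order by the point where haplotype B is modified (interspersed
      # duplications read from the reference but write at ins_at)
      key <- vapply(ed, function(e)
        if (!is.na(e$ins_at)) e$ins_at else e$start, numeric(1))
      ed <- ed[order(-key)]
      v <- hapB[[ci]]
      for (e in ed) {
        i1 <- e$start + 1L # first affected base, 1-based
        i2 <- e$start + e$length
        v <- switch(e$type,
          DEL = v[-(i1:i2)],
          INS = append(v, sample(DNA_BASES, e$length, replace = TRUE),
                       after = e$start),
          INV = {
            v[i1:i2] <- strsplit(revcomp_chr(paste(v[i1:i2], collapse = "")),
                                 "")[[1]]
            v
          },
          `DUP:TANDEM` = append(v, v[i1:i2], after = i2),
          `DUP:INT` = {
            seg <- hapA[[ci]][i1:i2] # copy from the reference segment
            append(v, seg, after = e$ins_at)
          })
      }
      hapB[[ci]] <- v
    }
  }

  to_set <- function(h) {
    s <- Biostrings::DNAStringSet(vapply(h, paste, character(1), collapse = ""))
    names(s) <- chroms
    s
  }
  genome_size <- L * length(chroms)
  truth <- list(
    telomere_motif = motif,
    snps = snps, svs = svs, repeats = repeats, genes = genes, cds = cds,
    chrom_lengths = setNames(rep(L, length(chroms)), chroms),
    telomere_span = span,
    genome_size = genome_size,
    het_rate = nrow(snps) / genome_size)
  validate_truth(truth)
  list(haplotypes = list(A = to_set(hapA), B = to_set(hapB)), truth = truth)
}

empty_repeat_truth <- function()
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             family = character(0), class = character(0),
             stringsAsFactors = FALSE)
empty_gene_truth <- function()
  data.frame(gene_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)
empty_cds_truth <- empty_gene_truth
empty_snp_truth <- function()
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), stringsAsFactors = FALSE)
empty_sv_truth <- function()
  data.frame(chrom = character(0), start = integer(0), type = character(0),
             length = integer(0), stringsAsFactors = FALSE)

# every truth interval must lie inside its chromosome
validate_truth <- function(truth) {
  cl <- truth$chrom_lengths
  chk <- function(df, s, e) {
    if (!nrow(df)) return(invisible())
    stopifnot(all(df[[s]] >= 0), all(df[[e]] <= cl[df$chrom]))
  }
  chk(truth$repeats, "start", "end")
  chk(truth$genes, "start", "end")
  chk(truth$cds, "start", "end")
  if (nrow(truth$snps)) stopifnot(all(truth$snps$pos < cl[truth$snps$chrom]))
  if (nrow(truth$svs))
    stopifnot(all(truth$svs$start + truth$svs$length <= cl[truth$svs$chrom]))
  invisible(truth)
}
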