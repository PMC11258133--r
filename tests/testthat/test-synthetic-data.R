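test_that("zero-divergence spec yields identical haplotypes and zero het", {
  spec <- synthetic_genome_spec(1, 1e5, "TTTAGGG", 50,
                                repeat_fraction = 0, snp_rate = 0, seed = 1)
  g <- simulate_genome(spec)
  expect_identical(as.character(g$haplotypes$A), as.character(g$haplotypes$B))
  expect_identical(g$truth$het_rate, 0)
  expect_equal(g$truth$telomere_motif, "TTTAGGG")
  # telomere arrays are present at both termini of the reference
  chr <- as.character(g$haplotypes$A[[1]])
  expect_identical(substr(chr, 1, 350),
                   strrep(oracle_revcomp("TTTAGGG"), 50))
  expect_identical(substr(chr, nchar(chr) - 349, nchar(chr)),
                   strrep("TTTAGGG", 50))
})

test_that("planted SNP count matches the requested rate within binomial error", {
  spec <- synthetic_genome_spec(1, 1e6, "TTTAGGG", 50, snp_rate = 0.004,
                                seed = 2)
  g <- simulate_genome(spec)
  n <- nrow(g$truth$snps)
  sigma <- sqrt(1e6 * 0.004 * 0.996)
  expect_lt(abs(n - 4000), 4 * sigma)
  # substitutions only: haplotype lengths are equal without SVs
  expect_equal(sum(Biostrings::width(g$haplotypes$B)), 1e6)
  # every SNP really differs between haplotypes
  a <- as.character(g$haplotypes$A[[1]])
  b <- as.character(g$haplotypes$B[[1]])
  i <- g$truth$snps$pos[1:20] + 1L
  expect_true(all(substring(a, i, i) != substring(b, i, i)))
})

test_that("a non-canonical telomere motif is carried through to the truth set", {
  spec <- synthetic_genome_spec(1, 5e4, "TTCAGGG", 30, seed = 3)
  g <- simulate_genome(spec)
  expect_equal(g$truth$telomere_motif, "TTCAGGG")
})

test_that("infeasible and invalid specs are rejected with diagnostics", {
  expect_error(synthetic_genome_spec(1, 600, "TTTAGGG", 50),
               "telomere span")
  expect_error(synthetic_genome_spec(1, 1e5, snp_rate = 0.2), "snp_rate")
  expect_error(synthetic_genome_spec(1, 1e5, repeat_fraction = 1),
               "repeat_fraction")
  expect_error(synthetic_genome_spec(1, 1e5, sv_events = data.frame(
    type = "BND", length = 100, count = 1)), "unknown SV type")
})

test_that("simulated genomes are byte-identical under a fixed seed", {
  spec <- synthetic_genome_spec(2, 2e4, "TTTAGGG", 20, repeat_fraction = 0.3,
                                snp_rate = 0.01, seed = 9)
  g1 <- simulate_genome(spec)
  g2 <- simulate_genome(spec)
  expect_identical(as.character(g1$haplotypes$B), as.character(g2$haplotypes$B))
  expect_identical(g1$truth$repeats, g2$truth$repeats)
})

test_that("error-free short reads are exact genomic substrings of either strand", {
  spec <- synthetic_genome_spec(1, 3e4, "TTTAGGG", 20, seed = 4)
  g <- simulate_genome(spec)
  reads <- simulate_short_reads(g, 1000, error_rate = 0, seed = 5)
  expect_length(reads, 1000)
  expect_true(all(Biostrings::width(reads) == 151))
  chr <- as.character(g$haplotypes$A[[1]])
  rcchr <- oracle_revcomp(chr)
  hits <- vapply(as.character(reads[1:50]), function(r)
    grepl(r, chr, fixed = TRUE) || grepl(r, rcchr, fixed = TRUE), logical(1))
  expect_true(all(hits))
})

test_that("short-read FASTQ output is deterministic under a fixed seed", {
  spec <- synthetic_genome_spec(1, 3e4, "TTTAGGG", 20, seed = 4)
  g <- simulate_genome(spec)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  simulate_short_reads(g, 200, error_rate = 0.01, seed = 7, out = f1)
  simulate_short_reads(g, 200, error_rate = 0.01, seed = 7, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    as.character(simulate_short_reads(g, 200, seed = 7)),
    as.character(simulate_short_reads(g, 200, seed = 8))))
})

test_that("substitution errors land at the requested rate", {
  spec <- synthetic_genome_spec(1, 3e4, "TTTAGGG", 20, seed = 4)
  g <- simulate_genome(spec)
  reads <- simulate_short_reads(g, 2000, error_rate = 0.01, seed = 11)
  chr <- as.character(g$haplotypes$A[[1]])
  rcchr <- oracle_revcomp(chr)
  exact <- vapply(as.character(reads[1:200]), function(r)
    grepl(r, chr, fixed = TRUE) || grepl(r, rcchr, fixed = TRUE), logical(1))
  # P(read error-free) = 0.99^151 ~ 0.22: most reads must carry an error
  expect_gt(mean(!exact), 0.5)
})

test_that("long reads hit the requested mean length and coverage", {
  spec <- synthetic_genome_spec(1, 5e5, "TTTAGGG", 20, seed = 6)
  g <- simulate_genome(spec)
  reads <- simulate_long_reads(g, coverage = 40, mean_length = 17289,
                               seed = 12)
  total <- sum(Biostrings::width(reads))
  expect_gte(total, 0.95 * 40 * 5e5)
  expect_lte(total, 1.05 * 40 * 5e5)
  lens <- Biostrings::width(simulate_long_reads(g, coverage = 40,
                                                mean_length = 17289,
                                                seed = 13))
  expect_gte(length(lens), 1000)
  expect_lt(abs(mean(lens) - 17289) / 17289, 0.10)
  expect_identical(
    as.character(simulate_long_reads(g, 2, seed = 3)),
    as.character(simulate_long_reads(g, 2, seed = 3)))
  expect_error(simulate_long_reads(g, 0), "coverage")
  expect_error(simulate_short_reads(g, 0), "n_reads")
})

test_that("annotation fixtures round-trip exactly through the QC parsers", {
  spec <- synthetic_genome_spec(
    2, 5e4, "TTTAGGG", 20, repeat_fraction = 0.15, snp_rate = 0.003,
    sv_events = data.frame(type = c("DEL", "INS", "INV", "DUP:TANDEM", "DUP:INT"),
                           length = c(80, 120, 300, 150, 200),
                           count = c(2, 1, 1, 1, 1)),
    seed = 21)
  g <- simulate_genome(spec)
  tr <- g$truth
  d <- withr::local_tempdir()
  paths <- emit_annotation_fixtures(tr, d)

  rm <- parse_repeatmasker_out(paths$repeats_out)
  expect_equal(nrow(rm$intervals), nrow(tr$repeats))
  expect_equal(rm$intervals$start, tr$repeats$start)
  expect_equal(rm$intervals$end, tr$repeats$end)
  expect_equal(rm$intervals$contig, tr$repeats$chrom)

  gf <- read_gff3_cds(paths$genes_gff3)
  expect_equal(gf$genes$start, tr$genes$start)
  expect_equal(gf$genes$end, tr$genes$end)
  expect_equal(gf$genes$gene_id, tr$genes$gene_id)
  expect_equal(nrow(gf$cds), nrow(tr$cds))
  expect_setequal(paste(gf$cds$gene_id, gf$cds$start, gf$cds$end),
                  paste(tr$cds$gene_id, tr$cds$start, tr$cds$end))

  sn <- read_snp_positions(paths$snp_vcf)
  expect_equal(sn$pos, tr$snps$pos + 1L)

  sv <- filter_and_spectrum_svs(paths$sv_vcf)
  expect_equal(sv$records$pos, tr$svs$start)
  expect_equal(sv$records$length, tr$svs$length)
  expect_equal(sv$records$type, tr$svs$type)
})

test_that("empty truth yields header-only fixture files", {
  spec <- synthetic_genome_spec(1, 2e4, "TTTAGGG", 10, seed = 30)
  g <- simulate_genome(spec)
  tr <- g$truth
  tr$repeats <- tr$repeats[0, ]
  tr$genes <- tr$genes[0, ]
  tr$cds <- tr$cds[0, ]
  tr$snps <- tr$snps[0, ]
  tr$svs <- tr$svs[0, ]
  d <- withr::local_tempdir()
  paths <- emit_annotation_fixtures(tr, d)
  expect_equal(nrow(parse_repeatmasker_out(paths$repeats_out)$intervals), 0)
  expect_equal(nrow(read_snp_positions(paths$snp_vcf)), 0)
  expect_equal(nrow(filter_and_spectrum_svs(paths$sv_vcf)$records), 0)
})
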