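test_that("assembly statistics match hand-computed and oracle N50", {
  st <- assembly_stats(c(40, 30, 20, 10))
  expect_equal(st$total_size, 100)
  expect_equal(st$n50, 30) # cumulative 40, 70 >= 50
  expect_equal(st$max_contig, 40)
  expect_equal(st$n_contigs, 4L)
  # identities
  expect_equal(assembly_stats(1234)$n50, 1234)
  expect_equal(assembly_stats(rep(70, 5))$n50, 70)
  expect_error(assembly_stats(Biostrings::DNAStringSet()), "empty")
  # randomized oracle agreement
  set.seed(37)
  for (i in 1:1000) {
    lens <- sample.int(1e6, sample(1:40, 1), replace = TRUE)
    expect_equal(assembly_stats(lens)$n50, oracle_n50(lens))
  }
})

test_that("contig-end telomere scan finds planted arrays in both orientations", {
  set.seed(41)
  mid <- random_dna_string(5e4)
  g_arr <- strrep("TTTAGGG", 30)
  c_arr <- oracle_revcomp(g_arr)
  asm <- Biostrings::DNAStringSet(c(
    both = paste0(c_arr, mid, g_arr),
    none = random_dna_string(5e4),
    only3 = paste0(random_dna_string(2e4), g_arr)))
  calls <- scan_contig_ends(asm, "TTTAGGG")
  expect_equal(nrow(calls), 3L)
  both <- calls[calls$contig == "both", ]
  expect_setequal(both$end, c("5'", "3'"))
  expect_true(all(both$copies == 30))
  expect_equal(calls$end[calls$contig == "only3"], "3'")
  expect_false("none" %in% calls$contig)
  # min_copies gates the call
  expect_equal(nrow(scan_contig_ends(asm, "TTTAGGG", min_copies = 31)), 0L)
})

test_that("contig-end scan tolerates gaps up to max_gap inside a cluster", {
  g_arr <- paste0(strrep("TTTAGGG", 6), random_dna_string(40),
                  strrep("TTTAGGG", 6))
  asm <- Biostrings::DNAStringSet(c(x = paste0(random_dna_string(2e4), g_arr)))
  calls <- scan_contig_ends(asm, "TTTAGGG", min_copies = 10, max_gap = 50)
  expect_equal(calls$copies, 12L)
  calls2 <- scan_contig_ends(asm, "TTTAGGG", min_copies = 10, max_gap = 10)
  expect_equal(nrow(calls2), 0L) # cluster splits into two runs of 6
})

test_that("repeatmasker parsing handles single records, overlaps and empty bodies", {
  d <- withr::local_tempdir()
  hdr <- c("h1", "h2", "")
  f <- file.path(d, "one.out")
  writeLines(c(hdr,
    "1000 1.0 0.0 0.0 chr1 101 600 (400) + LTR1 LTR/Copia 1 500 (0) 1"), f)
  rm <- parse_repeatmasker_out(f)
  expect_equal(rm$intervals$start, 100L)
  expect_equal(rm$intervals$end, 600L)
  expect_equal(unname(rm$class_totals[["Retroelement"]]), 500)
  # overlapping annotations: class totals are not deduplicated
  f2 <- file.path(d, "two.out")
  writeLines(c(hdr,
    "1000 1.0 0.0 0.0 chr1 101 600 (400) + LTR1 LTR/Copia 1 500 (0) 1",
    "1000 1.0 0.0 0.0 chr1 301 800 (200) C DNA9 DNA/hAT 1 500 (0) 2"), f2)
  rm2 <- parse_repeatmasker_out(f2)
  expect_equal(sum(rm2$class_totals), 1000)
  # ...but bin repeat ratios count each base once
  bins <- compute_bins(c(chr1 = 1000), repeats = rm2$intervals,
                       bin_width = 1000)
  expect_equal(bins$repeat_ratio, 700 / 1000) # union [100, 800)
  # empty body and malformed line
  f3 <- file.path(d, "empty.out")
  writeLines(hdr, f3)
  expect_equal(sum(parse_repeatmasker_out(f3)$class_totals), 0)
  f4 <- file.path(d, "bad.out")
  writeLines(c(hdr, "1000 1.0 0.0"), f4)
  expect_error(parse_repeatmasker_out(f4), "line 4")
})

test_that("repeat classes map onto the seven summary categories", {
  cls <- c("LTR/Gypsy", "LINE/L1", "SINE/tRNA", "DNA/hAT", "RC/Helitron",
           "snRNA", "Satellite/centr", "Simple_repeat", "Low_complexity",
           "Unknown")
  expect_equal(teloscope:::repeat_category(cls),
               c("Retroelement", "Retroelement", "Retroelement",
                 "DNA transposon", "Rolling-circle", "Small RNA",
                 "Satellite", "Simple repeat", "Low complexity",
                 "Unclassified"))
})

test_that("bin tiling, contig filtering and saturation follow the contract", {
  bins <- compute_bins(c(a = 250000), bin_width = 1e5)
  expect_equal(bins$start, c(0, 1e5, 2e5))
  expect_equal(bins$end, c(1e5, 2e5, 250000))
  # min_contig_len drops short contigs entirely
  bins2 <- compute_bins(c(a = 1.2e6, b = 250000), bin_width = 1e5,
                        min_contig_len = 1e6)
  expect_true(all(bins2$contig == "a"))
  expect_equal(nrow(bins2), 12L)
  expect_error(compute_bins(c(a = 100), min_contig_len = 1000), "no contig")
  # a fully-masked bin saturates at ratio 1
  bins3 <- compute_bins(c(a = 150000),
                        repeats = data.frame(contig = "a", start = 0,
                                             end = 150000),
                        bin_width = 1e5)
  expect_equal(bins3$repeat_ratio, c(1, 1))
})

test_that("depth aggregation conserves totals and validates inputs", {
  d <- data.frame(contig = "a", position = 1:250, depth = rep(c(2L, 5L), 125))
  bins <- compute_bins(c(a = 250), depth = d, bin_width = 100)
  expect_equal(sum(bins$depth_sum), sum(d$depth))
  expect_equal(bins$depth_mean, bins$depth_sum / c(100, 100, 50))
  # missing positions count as zero depth
  d2 <- d[1:50, ]
  bins2 <- compute_bins(c(a = 250), depth = d2, bin_width = 100)
  expect_equal(bins2$depth_mean[1], sum(d2$depth) / 100)
  expect_error(compute_bins(c(a = 250), depth = data.frame(
    contig = "zz", position = 1, depth = 1)), "unknown contig")
  expect_error(compute_bins(c(a = 250), depth = data.frame(
    contig = "a", position = 999, depth = 1)), "beyond contig length")
})

test_that("features land in the bin containing their start coordinate", {
  bins <- compute_bins(c(a = 300000),
                       genes = data.frame(chrom = "a",
                                          start = c(0, 99999, 100000, 250000)),
                       snps = data.frame(contig = "a",
                                         pos = c(1, 100000, 100001)),
                       svs = data.frame(contig = "a", pos = c(99999, 299999)),
                       bin_width = 1e5)
  expect_equal(bins$gene_count, c(2L, 1L, 1L))
  expect_equal(bins$snp_count, c(2L, 1L, 0L))
  expect_equal(bins$sv_count, c(1L, 0L, 1L))
})

test_that("median repeat split groups bins and summarises depth per group", {
  bins <- structure(data.frame(
    contig = "a", start = 0:3 * 1e5, end = 1:4 * 1e5,
    depth_sum = c(1e6, 1e6, 3e6, 3e6), depth_mean = c(10, 10, 30, 30),
    repeat_ratio = c(0.1, 0.2, 0.8, 0.9),
    gene_count = 0L, snp_count = 0L, sv_count = 0L),
    class = c("genomic_bins", "data.frame"))
  sp <- repeat_split_depth_summary(bins)
  expect_equal(attr(sp, "threshold"), 0.5)
  expect_equal(sp$median_depth, c(10, 30))
  expect_equal(sp$n, c(2L, 2L))
  # two bins: group medians are the bins' own depths
  sp3 <- repeat_split_depth_summary(bins[c(1, 3), ])
  expect_equal(sp3$median_depth, c(10, 30))
  expect_equal(sp3$n, c(1L, 1L))
  expect_error(repeat_split_depth_summary(bins[1, ]), "at least 2")
  # identical ratios: every bin is <= threshold, high group empty
  bins$repeat_ratio <- rep(0.4, 4)
  sp2 <- repeat_split_depth_summary(bins)
  expect_equal(sp2$n, c(4L, 0L))
  expect_true(is.na(sp2$median_depth[2]))
})

test_that("SV size filter retains >= 50 bp and maps the five categories", {
  d <- withr::local_tempdir()
  svs <- data.frame(
    contig = "chr1", pos = c(100, 300, 500, 700, 900, 1100),
    type = c("DEL", "DEL", "INS", "INV", "DUP:TANDEM", "DUP:INT"),
    length = c(49, 50, 60, 55, 80, 52), stringsAsFactors = FALSE)
  sp <- filter_and_spectrum_svs(svs)
  expect_equal(min(sp$records$length), 50)
  expect_equal(sp$n_dropped, 1L)
  expect_equal(unname(sp$counts),
               c(1L, 1L, 1L, 1L, 1L))
  # idempotence
  sp2 <- filter_and_spectrum_svs(sp$records)
  expect_equal(sp2$records, sp$records)
  # VCF path: SVLEN preferred, END - POS fallback, errors when both absent
  f <- file.path(d, "sv.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-80",
    "chr1\t500\tb\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=560",
    "chr1\t900\tc\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;SVLEN=120"), f)
  spv <- filter_and_spectrum_svs(f)
  expect_equal(spv$records$length, c(80L, 60L, 120L))
  expect_equal(spv$records$type[3], "DUP:TANDEM")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\tbad1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL"), f)
  expect_error(filter_and_spectrum_svs(f), "bad1")
})

test_that("gene x SV intersection counts genes once and respects half-open overlap", {
  cds <- data.frame(gene_id = c("g1", "g2", "g2", "g2", "g3"),
                    chrom = "chr1",
                    start = c(100, 1000, 1200, 1400, 5000),
                    end = c(200, 1100, 1300, 1500, 5100),
                    stringsAsFactors = FALSE)
  svs <- data.frame(contig = "chr1", pos = c(150, 1000, 200),
                    type = c("DEL", "DEL", "INS"),
                    length = c(10, 600, 60), stringsAsFactors = FALSE)
  res <- genes_affected_by_sv(cds, svs)
  # g1 hit by DEL [150,160); g2's three CDS all inside DEL [1000,1600) but
  # counted once; INS footprint is 1 bp at 200 — adjacent to g1's CDS
  # [100,200) so no overlap
  expect_equal(res$n_affected, 2L)
  expect_setequal(res$affected_genes, c("g1", "g2"))
  expect_equal(res$per_gene$n_sv[res$per_gene$gene_id == "g2"], 1L)
  # brute-force oracle on random instances
  set.seed(43)
  for (i in 1:20) {
    n_cds <- sample(3:12, 1)
    cds_r <- data.frame(
      gene_id = paste0("g", sample(1:5, n_cds, replace = TRUE)),
      chrom = sample(c("c1", "c2"), n_cds, replace = TRUE),
      start = sample(0:500, n_cds))
    cds_r$end <- cds_r$start + sample(10:100, n_cds, replace = TRUE)
    n_sv <- sample(1:6, 1)
    sv_r <- data.frame(
      contig = sample(c("c1", "c2"), n_sv, replace = TRUE),
      pos = sample(0:500, n_sv),
      type = sample(c("DEL", "INS", "INV"), n_sv, replace = TRUE),
      length = sample(50:200, n_sv, replace = TRUE))
    foot <- data.frame(contig = sv_r$contig, start = sv_r$pos,
                       end = sv_r$pos + ifelse(sv_r$type == "INS", 1,
                                               sv_r$length))
    names(foot)[2:3] <- c("start", "end")
    expect_equal(genes_affected_by_sv(cds_r, sv_r)$affected_genes,
                 oracle_affected_genes(
                   within(cds_r, chrom <- as.character(chrom)), foot))
  }
})

test_that("synthetic assemblies recover exactly the planted telomeric ends", {
  spec <- synthetic_genome_spec(3, 3e4, "TTTAGGG", 25, seed = 47)
  g <- simulate_genome(spec)
  calls <- scan_contig_ends(g$haplotypes$A, "TTTAGGG")
  expect_equal(nrow(calls), 6L) # both ends of all three chromosomes
  expect_setequal(unique(calls$end), c("5'", "3'"))
  expect_true(all(calls$copies >= 25))
})
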