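tiny_ref <- function(seed = 1, L = 8e3) {
  set.seed(seed)
  c(chrA = paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), L / 2, TRUE), collapse = ""))
}

test_that("error-free simulated reads place at their encoded origin", {
  g <- simulate_xy_genome(c(chrX = 2e4, chr2 = 8e3),
                          sdr_interval = c(5e3, 1.5e4), msr_length = 1e3,
                          sdr_divergence = 0.02, seed = 21)
  rs <- simulate_reads(g, n_males = 1, n_females = 0, coverage = 2,
                       read_length = 80, error_rate = 0, seed = 22)
  reads <- rs$M1$reads
  pl <- place_reads(reads, g$genome$Y, k = 40, dedup = FALSE)
  expect_gt(nrow(pl), length(reads) * 0.8)
  info <- strsplit(pl$read, "|", fixed = TRUE)
  hap <- vapply(info, `[`, "", 2)
  # Y-haplotype reads carry Y coordinates == male assembly coordinates
  ypl <- pl[hap == "Y"]
  ypos <- as.integer(vapply(info[hap == "Y"], `[`, "", 4))
  expect_true(all(ypl$start == ypos))
  expect_true(all(ypl$chrom == vapply(info[hap == "Y"], `[`, "", 3)))
})

test_that("reads from the Y-only insertion do not place on the X assembly", {
  g <- simulate_xy_genome(c(chrX = 2e4), sdr_interval = c(5e3, 1.5e4),
                          msr_length = 3e3, sdr_divergence = 0, seed = 31)
  ins <- substr(g$genome$Y[["chrX"]], g$truth$msr[1] + 1, g$truth$msr[2])
  reads <- vapply(seq(1, 3e3 - 100, by = 50), function(i)
    substr(ins, i, i + 99), "")
  pl <- place_reads(reads, g$genome$X, k = 40)
  expect_equal(nrow(pl), 0L)
  # but they place on the male assembly
  pl2 <- place_reads(reads, g$genome$Y, k = 40, dedup = FALSE)
  expect_equal(nrow(pl2), length(reads))
})

test_that("ambiguous seeds and positional duplicates are handled", {
  unit <- tiny_ref(3)[["chrB"]]
  ref <- c(chr1 = paste0(unit, unit))        # every k-mer occurs twice
  read <- substr(unit, 101, 200)
  expect_equal(nrow(place_reads(read, ref, k = 40)), 0L)
  ref2 <- tiny_ref(4)
  read2 <- substr(ref2[["chrA"]], 501, 600)
  pl <- place_reads(c(a = read2, b = read2), ref2, k = 40, dedup = TRUE)
  expect_equal(nrow(pl), 1L)
  pl2 <- place_reads(c(a = read2, b = read2), ref2, k = 40, dedup = FALSE)
  expect_equal(nrow(pl2), 2L)
})

test_that("window depth tallies and normalizes correctly", {
  lens <- c(chr1 = 1000, chr2 = 450)
  empty <- window_depth(data.table::data.table(chrom = character(),
                                               start = integer()),
                        lens, w = 100)
  expect_true(all(empty$count == 0))
  expect_true(empty[chrom == "chr2" & start == 400, partial])

  one <- window_depth(data.table::data.table(chrom = "chr1", start = 250L),
                      lens, w = 100)
  expect_equal(one[chrom == "chr1" & start == 200, cpm], 1e6)
  expect_equal(sum(one$cpm), 1e6)

  # conservation + naive binning oracle on random placements
  set.seed(50)
  pl <- data.table::data.table(
    chrom = sample(names(lens), 10000, TRUE, prob = c(0.7, 0.3)))
  pl[, start := as.integer(floor(runif(.N) * lens[chrom]))]
  track <- window_depth(pl, lens, w = 100)
  expect_equal(sum(track$count), nrow(pl))
  for (i in sample(nrow(track), min(15L, nrow(track)))) {
    expect_equal(track$count[i],
                 pl[chrom == track$chrom[i] & start >= track$start[i] &
                      start < track$end[i], .N])
  }
  expect_error(window_depth(data.table::data.table(chrom = "chr1",
                                                   start = 1000L),
                            lens, w = 100), "beyond")
})

test_that("call_sdr seeds, merges and ranks regions per the rules", {
  lens <- c(c1 = 2000)
  mk <- function(counts) {
    t <- tile_windows(lens, 100)
    t[, count := as.integer(counts)]
    t[, cpm := count * 1e6 / max(sum(count), 1)]
    t
  }
  zero <- mk(rep(0, 20))
  expect_equal(nrow(call_sdr(mk(rep(0, 20)), zero)), 0L)

  # two clusters separated by merge_gap + 1 empty windows -> two regions
  counts <- rep(0, 20)
  counts[c(3, 4)] <- 500
  counts[c(8, 9)] <- 300   # gap of 3 windows (5,6,7) with merge_gap = 2
  res <- call_sdr(mk(counts), zero, merge_gap = 2, min_windows = 1,
                  min_reads = 10)
  expect_equal(nrow(res), 2L)
  expect_equal(res$start, c(200, 700))
  expect_equal(res$rank, c(1L, 2L))   # ranked by total reads

  # gap of exactly merge_gap windows -> merged
  counts2 <- rep(0, 20)
  counts2[c(3, 6)] <- 500  # separated by 2 empty windows
  res2 <- call_sdr(mk(counts2), zero, merge_gap = 2, min_windows = 1,
                   min_reads = 10)
  expect_equal(nrow(res2), 1L)
  expect_equal(res2$n_windows, 4L)

  # min_windows drops small regions; min_reads suppresses stray windows
  res3 <- call_sdr(mk(counts2), zero, merge_gap = 0, min_windows = 2,
                   min_reads = 10)
  expect_equal(nrow(res3), 0L)
  counts3 <- rep(0, 20); counts3[3] <- 5; counts3[10:12] <- 800
  res4 <- call_sdr(mk(counts3), zero, min_windows = 1, min_reads = 10)
  expect_equal(res4$start, 900)

  # elevated female depth vetoes seeds
  fem <- mk(c(rep(0, 10), 600, rep(0, 9)))
  counts4 <- rep(0, 20); counts4[c(10, 11, 12)] <- 700
  res5 <- call_sdr(mk(counts4), fem, min_windows = 1, min_reads = 10)
  expect_false(1000 %in% res5$start)

  expect_error(call_sdr(mk(counts), window_depth(
    data.table::data.table(chrom = character(), start = integer()),
    c(c1 = 1000), 100)), "grids")
})

test_that("coverage_ratio computes the log2 pseudo-count ratio", {
  lens <- c(c1 = 500)
  t1 <- window_depth(data.table::data.table(chrom = "c1",
                                            start = c(10L, 110L, 120L)),
                     lens, 100)
  t0 <- window_depth(data.table::data.table(chrom = character(),
                                            start = integer()), lens, 100)
  same <- coverage_ratio(t1, t1, pseudocount = 1)
  expect_true(all(same$log2_ratio == 0))
  hemi <- coverage_ratio(t1, t0, pseudocount = 1)
  i <- which(t1$count > 0)
  expect_equal(hemi$log2_ratio[i], log2(t1$cpm[i] + 1), tolerance = 1e-12)
  expect_true(all(hemi$log2_ratio[i] > 0))
  set.seed(1)
  t2 <- data.table::copy(t1); t2[, cpm := runif(.N) * 100]
  r <- coverage_ratio(t1, t2, pseudocount = 0.5)
  expect_equal(r$log2_ratio, log2((t1$cpm + 0.5) / (t2$cpm + 0.5)))
})

test_that("sex_variant_density matches hand enumeration on a toy VCF", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  geno <- rbind(
    c(1L, 1L, 0L, 0L),  # SNP, het both males, hom-ref females -> male-specific
    c(2L, 2L, 0L, 0L),  # SNP, hom-alt males -> male-specific
    c(1L, 0L, 0L, 0L),  # SNP, het one male only
    c(1L, 1L, 1L, 0L),  # SNP, het male + one female -> not male-specific
    c(1L, 1L, 0L, NA),  # indel, uncalled female disqualifies
    c(0L, 1L, 1L, 1L))  # indel, het in three samples
  write_vcf(geno, "chr1", pos = c(50L, 150L, 250L, 1050L, 1150L, 1250L),
            ref = c("A", "C", "G", "T", "TA", "G"),
            alt = c("G", "T", "A", "C", "T", "GAA"),
            samples = c("m1", "m2", "f1", "f2"),
            contig_lengths = c(chr1 = 2000), path = vcf)
  sex <- c(m1 = "male", m2 = "male", f1 = "female", f2 = "female")
  d <- sex_variant_density(vcf, sex, c(chr1 = 2000), w = 1000)
  w1 <- d[start == 0]; w2 <- d[start == 1000]
  expect_equal(w1$het_snp_male, (1 + 1 + 1) / 2)    # per-sample mean
  expect_equal(w1$het_snp_female, 0)
  expect_equal(w1$male_specific_snp, 2)
  expect_equal(w2$het_snp_male, 2 / 2)              # site 4: both males het
  expect_equal(w2$het_snp_female, 1 / 2)            # site 4: one female het
  expect_equal(w2$het_indel_male, 2 / 2 + 1 / 2)    # sites 5 + 6
  expect_equal(w2$het_indel_female, 0 + 2 / 2)      # site 5 (f2 uncalled) + 6
  expect_equal(w2$male_specific_indel, 0)
  expect_equal(w2$male_specific_snp, 0)
  # empty VCF -> all-zero track
  write_vcf(geno[0, , drop = FALSE], character(), integer(), character(),
            character(), samples = names(sex), path = vcf)
  d0 <- sex_variant_density(vcf, sex, c(chr1 = 2000), w = 1000)
  expect_true(all(d0$het_snp_male == 0 & d0$male_specific_snp == 0))
  expect_error(sex_variant_density(vcf, c(sex, zz = "male"),
                                   c(chr1 = 2000), 1000), "missing")
})

test_that("external SAM ingestion filters, converts and deduplicates", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "aln.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t0\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",   # same pos, other strand
    "r3\t0\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",    # positional duplicate of r1
    "r4\t1024\tchr1\t200\t60\t50M\t*\t0\t0\t*\t*", # PCR duplicate flag
    "r5\t256\tchr1\t300\t60\t50M\t*\t0\t0\t*\t*",  # secondary
    "r6\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",            # unmapped
    "r7\t0\tchr1\t400\t5\t50M\t*\t0\t0\t*\t*"      # low MAPQ
  ), sam)
  pl <- place_reads_external(sam, min_mapq = 20)
  expect_equal(nrow(pl), 2L)
  expect_equal(pl$start, c(100L, 100L))
  expect_setequal(pl$strand, c("+", "-"))
  writeLines(c("@SQ\tSN:chr1\tLN:10000",
               "r1\t0\tchr1\t500\t60\t50M\t*\t0\t0\t*\t*",
               "r2\t0\tchr1\t100\t60\t50M\t*\t0\t0\t*\t*"), sam)
  expect_error(place_reads_external(sam), "sorted")
})

test_that("bedGraph export round-trips through rtracklayer", {
  lens <- c(c1 = 300)
  t1 <- window_depth(data.table::data.table(chrom = "c1", start = c(5L, 150L)),
                     lens, 100)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(t1, f, column = "count")
  back <- rtracklayer::import(f, format = "bedGraph")
  expect_equal(sum(back$score), 2)
})
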