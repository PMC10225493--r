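random_geno <- function(n_sites, n1, n2, L = 1000, seed = NULL,
                        missing = 0) {
  if (!is.null(seed)) set.seed(seed)
  p <- rbeta(n_sites, 0.8, 0.8)
  g <- cbind(matrix(rbinom(n_sites * n1, 2, rep(p, n1)), n_sites, n1),
             matrix(rbinom(n_sites * n2, 2, rep(pmin(1, p + 0.1), n2)),
                    n_sites, n2))
  if (missing > 0) g[runif(length(g)) < missing] <- NA
  genotype_matrix(g, "chr1", pos = sort(sample.int(L, n_sites)),
                  pops = rep(c("wild", "dom"), c(n1, n2)),
                  genome_length = L)
}

geno_subset_for_test <- function(g, idx) {
  g$geno <- g$geno[idx, , drop = FALSE]
  g$chrom <- g$chrom[idx]; g$pos <- g$pos[idx]
  g$ref <- g$ref[idx]; g$alt <- g$alt[idx]
  g
}

test_that("site_filter applies MAF, missingness and biallelism rules", {
  # 10 hand-written sites, 10 samples (MAF floor 0.05 => >= 1 alt allele)
  g10 <- rbind(
    rep(0L, 10),                      # monomorphic ref     -> drop
    rep(2L, 10),                      # monomorphic alt     -> drop
    c(1L, rep(0L, 9)),                # MAF 0.05            -> keep (>=)
    c(2L, 1L, rep(0L, 8)),            # MAF 0.15            -> keep
    c(1L, rep(NA, 2), rep(0L, 7)),    # missing 0.2         -> drop
    c(1L, NA, rep(0L, 8)),            # missing 0.1 (= max) -> drop (strict <)
    c(rep(1L, 10)),                   # MAF 0.5             -> keep
    c(1L, rep(0L, 9)),                # multiallelic        -> drop
    c(rep(2L, 9), 1L),                # MAF 0.05            -> keep
    c(2L, rep(0L, 9)))                # MAF 0.1             -> keep
  g <- genotype_matrix(g10, "chr1", pos = 1:10 * 10,
                       pops = rep(c("wild", "dom"), each = 5),
                       alt = c(rep("T", 7), "T,G", "T", "T"),
                       genome_length = 100)
  f <- site_filter(g, sweep_params())
  expect_equal(f$pos, c(30, 40, 70, 90, 100))
  empty <- site_filter(geno_subset_for_test(g, integer()), sweep_params())
  expect_equal(nrow(empty$geno), 0L)
})

test_that("window pi: forced example and pairwise-difference oracle", {
  # one site, n = 4 alleles, j = 2, window 100 bp
  g <- genotype_matrix(matrix(c(1L, 1L), 1, 2), "chr1", pos = 5,
                       pops = c("wild", "wild"), genome_length = 100)
  pi <- window_pi(g, "wild", sweep_params(window = 100, min_sites = 0))
  expect_equal(pi$value, 2 * 2 * 2 / (4 * 3) / 100, tolerance = 1e-12)

  # a window with no segregating sites has pi = 0
  g0 <- genotype_matrix(matrix(c(0L, 0L), 1, 2), "chr1", pos = 5,
                        pops = c("wild", "wild"), genome_length = 100)
  expect_equal(window_pi(g0, "wild",
                         sweep_params(window = 100, min_sites = 0))$value, 0)
  # fully empty matrix gives an empty grid
  expect_equal(nrow(window_pi(geno_subset_for_test(g, integer()), "wild",
                              sweep_params(window = 100, min_sites = 0))), 0L)

  # random matrices vs brute-force allele-pair oracle
  for (rep in 1:30) {
    g <- random_geno(rpois(1, 12) + 1, 4, 3, L = 200, seed = rep,
                     missing = 0.05)
    prm <- sweep_params(window = 200, min_sites = 0)
    for (pop in c("wild", "dom")) {
      got <- window_pi(g, pop, prm)$value
      want <- oracle_pi(g$geno[, g$pops == pop, drop = FALSE], 200)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("pi is invariant under sample reordering", {
  g <- random_geno(40, 6, 5, L = 500, seed = 77)
  prm <- sweep_params(window = 250, min_sites = 0)
  base <- window_pi(g, "wild", prm)
  perm <- sample(ncol(g$geno))
  g2 <- g; g2$geno <- g$geno[, perm]; g2$pops <- g$pops[perm]
  expect_equal(window_pi(g2, "wild", prm), base)
})

test_that("Weir-Cockerham FST: forced cases and random oracle", {
  prm <- sweep_params(window = 100, min_sites = 1)
  # fixed difference, no heterozygotes -> per-site FST 1
  g <- genotype_matrix(matrix(c(0L, 0L, 0L, 2L, 2L, 2L), 1, 6), "chr1",
                       pos = 10, pops = rep(c("wild", "dom"), each = 3),
                       genome_length = 100)
  sf <- site_fst_wc(g)
  expect_equal(sf$fst, 1, tolerance = 1e-12)
  w <- window_fst_wc(g, params = prm)
  expect_equal(w$fst_weighted, 1, tolerance = 1e-12)

  # monomorphic site excluded (zero denominator)
  gm <- genotype_matrix(matrix(0L, 1, 6), "chr1", pos = 10,
                        pops = rep(c("wild", "dom"), each = 3),
                        genome_length = 100)
  expect_false(site_fst_wc(gm)$valid)
  expect_true(is.na(site_fst_wc(gm)$fst))

  # 500 random site configurations vs the independent oracle
  set.seed(505)
  for (i in 1:500) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    g1 <- sample(0:2, n1, TRUE); g2 <- sample(0:2, n2, TRUE)
    if (i %% 7 == 0) g1[1] <- NA
    gg <- genotype_matrix(matrix(c(g1, g2), 1), "chr1", pos = 1,
                          pops = rep(c("wild", "dom"), c(n1, n2)),
                          genome_length = 10)
    want <- oracle_wc_site(g1, g2)
    sf <- site_fst_wc(gg)
    if (is.null(want)) {
      expect_false(sf$valid)
    } else {
      expect_equal(c(a = sf$a, b = sf$b, c = sf$c), want,
                   tolerance = 1e-10)
      denom <- sum(want)
      if (denom != 0)
        expect_equal(sf$fst, want["a"] / denom, tolerance = 1e-10,
                     ignore_attr = TRUE)
    }
  }
})

test_that("window weighted FST equals the ratio of summed components", {
  g <- random_geno(60, 6, 6, L = 300, seed = 31)
  prm <- sweep_params(window = 100, min_sites = 1)
  w <- window_fst_wc(g, params = prm)
  sf <- site_fst_wc(g)
  for (i in seq_len(nrow(w))) {
    idx <- which(g$pos - 1 >= w$start[i] & g$pos - 1 < w$end[i] & sf$valid)
    if (length(idx) == 0) next
    expect_equal(w$fst_weighted[i],
                 sum(sf$a[idx]) / sum(sf$a[idx] + sf$b[idx] + sf$c[idx]),
                 tolerance = 1e-12)
  }
})

test_that("Tajima constants and windowed D match the oracle", {
  k <- tajima_constants(10)
  expect_equal(k$a1, sum(1 / 1:9))
  expect_true(all(unlist(tajima_constants(2))[1:4] > 0))

  # n = 2 alleles (one diploid sample): a1 = 1 forces theta_pi = theta_W = S
  # and the variance constants vanish, so D is defined as exactly 0.
  g1 <- genotype_matrix(matrix(c(1L, 1L, 1L, 0L), 4, 1), "chr1",
                        pos = c(10, 20, 30, 40), pops = "wild",
                        genome_length = 100)
  d <- window_tajima_d(g1, "wild", sweep_params(window = 100, min_sites = 0))
  expect_identical(d$tajima_d, 0)
  expect_equal(d$S, 3L)

  # S = 0 -> NA
  g0 <- genotype_matrix(matrix(2L, 3, 4), "chr1", pos = c(10, 20, 30),
                        pops = rep("wild", 4), genome_length = 100)
  expect_true(is.na(window_tajima_d(g0, "wild",
                                    sweep_params(window = 100))$tajima_d))

  # n = 8 toy matrix with 5 segregating sites vs independent oracle
  set.seed(8)
  m <- matrix(rbinom(5 * 4, 2, 0.4), 5, 4)
  m[1, ] <- c(1, 0, 0, 0)
  g8 <- genotype_matrix(m, "chr1", pos = c(5, 15, 25, 35, 45),
                        pops = rep("wild", 4), genome_length = 100)
  got <- window_tajima_d(g8, "wild", sweep_params(window = 100),
                         min_S = 1)$tajima_d
  expect_equal(got, oracle_tajima_d(m), tolerance = 1e-10)

  # n in 4..50: random matrices vs oracle
  for (n in c(4, 6, 8, 14, 22, 34, 50)) {
    set.seed(n)
    m <- matrix(rbinom(12 * n / 2, 2, runif(12, 0.1, 0.9)), 12, n / 2)
    gg <- genotype_matrix(m, "chr1", pos = seq(5, 115, by = 10),
                          pops = rep("wild", n / 2), genome_length = 200)
    got <- window_tajima_d(gg, "wild", sweep_params(window = 200),
                           min_S = 1)$tajima_d
    expect_equal(got, oracle_tajima_d(m), tolerance = 1e-10)
  }
})

test_that("D is invariant under allele-label swap", {
  set.seed(14)
  m <- matrix(rbinom(20 * 5, 2, 0.3), 20, 5)
  g <- genotype_matrix(m, "chr1", pos = 1:20 * 4, pops = rep("w", 5),
                       genome_length = 100)
  g_sw <- genotype_matrix(2L - m, "chr1", pos = 1:20 * 4, pops = rep("w", 5),
                          genome_length = 100)
  prm <- sweep_params(window = 100)
  expect_equal(window_tajima_d(g, "w", prm)$tajima_d,
               window_tajima_d(g_sw, "w", prm)$tajima_d)
})

test_that("pi ln-ratio handles forced values and NA rules", {
  mk <- function(vals, ns) data.table::data.table(
    chrom = "c", start = seq(0, by = 100, length.out = length(vals)),
    end = seq(100, by = 100, length.out = length(vals)),
    n_sites = ns, value = vals)
  prm <- sweep_params(window = 100, min_sites = 2)
  r <- pi_ln_ratio(mk(c(0.02, 0.02, exp(2) * 0.01, 0.01), c(5, 1, 5, 5)),
                   mk(c(0.02, 0.02, 0.01, 0), c(5, 5, 5, 5)), prm)
  expect_equal(r$ln_ratio[1], 0)
  expect_true(is.na(r$ln_ratio[2]))     # wild window below min_sites
  expect_equal(r$ln_ratio[3], 2, tolerance = 1e-12)
  expect_true(is.na(r$ln_ratio[4]))     # pi_dom = 0
  expect_error(pi_ln_ratio(mk(1, 5), mk(c(1, 1), c(5, 5)), prm), "grids")
})

test_that("select_sweeps thresholds, ties and merging behave as specified", {
  mk <- function(f, l) list(
    fst = data.table::data.table(chrom = "c",
                                 start = seq(0, by = 100,
                                             length.out = length(f)),
                                 end = seq(100, by = 100,
                                           length.out = length(f)),
                                 fst_weighted = f),
    lnr = data.table::data.table(chrom = "c",
                                 start = seq(0, by = 100,
                                             length.out = length(l)),
                                 end = seq(100, by = 100,
                                           length.out = length(l)),
                                 ln_ratio = l))
  prm <- sweep_params(window = 100, quantile = 0.9)
  # constant tracks: threshold equals the constant, all windows outliers
  tr <- mk(rep(0.3, 10), rep(1, 10))
  res <- select_sweeps(tr$fst, tr$lnr, prm)
  expect_equal(attr(res, "fst_threshold"), 0.3)
  expect_equal(res$n_windows, 10L)       # merged into one region
  expect_equal(nrow(res), 1L)

  # nothing passes both thresholds -> empty
  f <- c(rep(0, 8), 5, 9); l <- c(9, 5, rep(0, 8))
  res2 <- select_sweeps(mk(f, l)$fst, mk(f, l)$lnr, prm)
  expect_equal(attr(res2, "fst_threshold"), 5)
  expect_equal(nrow(res2), 0L)

  # dual outliers merge only when adjacent
  f2 <- c(9, 9, 0, 0, 9, 0, 0, 0, 0, 0)
  l2 <- c(9, 9, 0, 0, 9, 0, 0, 0, 0, 0)
  res3 <- select_sweeps(mk(f2, l2)$fst, mk(f2, l2)$lnr,
                        sweep_params(window = 100, quantile = 0.75))
  expect_equal(nrow(res3), 2L)
  expect_equal(res3$start, c(0, 400))
  # every reported window exceeded both thresholds (by construction of the
  # merge this is region-level: check bounds)
  expect_true(all(res3$mean_fst >= attr(res3, "fst_threshold")))
  expect_error(select_sweeps(mk(rep(NA_real_, 3), rep(1, 3))$fst,
                             mk(rep(1, 3), rep(1, 3))$lnr, prm), "NA")
})

test_that("gene overlap follows the half-open conversion", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t150\t250\t.\t+\t.\tID=gene1",
    "chr1\tsrc\tgene\t301\t400\t.\t+\t.\tID=gene2",   # abuts region end
    "chr1\tsrc\tgene\t500\t550\t.\t-\t.\tID=gene3",   # nested in region 2
    "chr1\tsrc\tmRNA\t150\t250\t.\t+\t.\tID=rna1",    # not a gene feature
    "chr2\tsrc\tgene\t10\t90\t.\t+\t.\tID=gene4",     # other chromosome
    "chr1\tsrc\tgene\t700\t800\t.\t+\t.\tID=gene5"),  # outside regions
    gff)
  regions <- data.table::data.table(chrom = "chr1",
                                    start = c(100, 450), end = c(300, 600))
  res <- overlap_genes(regions, gff)
  expect_equal(res$gene_ids[[1]], "gene1")
  expect_equal(res$gene_ids[[2]], "gene3")
  expect_equal(res$n_genes, c(1L, 1L))
})
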