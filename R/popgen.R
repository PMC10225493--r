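# Windowed population-genetic statistics for sweep scans: site filtering,
# nucleotide diversity (pi), Weir-Cockerham FST, Tajima's D, pi ln-ratio,
# dual-statistic top-quantile outlier selection, and gene overlap.

#' Construct a genotype matrix container
#'
#' @param geno Sites x samples alt-allele dosage matrix (0/1/2/NA).
#' @param chrom Chromosome per site (scalar recycled).
#' @param pos 1-based positions, strictly increasing per chromosome.
#' @param pops Population label per sample (factor or character).
#' @param ref,alt Allele strings per site (default single-base placeholders).
#' @param genome_length Total length used for window tiling (default: max
#'   position rounded up).
#' @return A list of class `dioscan_geno`.
#' @export
genotype_matrix <- function(geno, chrom = "chr1", pos, pops,
                            ref = NULL, alt = NULL, genome_length = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  stopifnot(length(pos) == n, length(pops) == ncol(geno))
  chrom <- rep_len(chrom, n)
  sp <- split(pos, chrom)
  if (any(vapply(sp, is.unsorted, TRUE, strictly = TRUE)))
    stop("positions must be strictly increasing per chromosome")
  if (!all(is.na(geno) | (geno >= 0L & geno <= 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  structure(list(geno = geno, chrom = chrom, pos = as.integer(pos),
                 ref = ref %||% rep("A", n), alt = alt %||% rep("T", n),
                 pops = factor(pops),
                 genome_length = genome_length %||%
                   (if (n) max(pos) else 0),
                 samples = colnames(geno) %||% paste0("S", seq_len(ncol(geno)))),
            class = "dioscan_geno")
}

# subset sites of a dioscan_geno
geno_subset <- function(g, idx) {
  g$geno <- g$geno[idx, , drop = FALSE]
  g$chrom <- g$chrom[idx]
  g$pos <- g$pos[idx]
  g$ref <- g$ref[idx]
  g$alt <- g$alt[idx]
  g
}

#' Parameters for the sweep scan
#'
#' @param window Window size in bp (default 50 kb).
#' @param step Step size in bp (default = window, i.e. non-overlapping).
#' @param quantile Outlier quantile for both statistics (default 0.99, the
#'   top 1 percent).
#' @param min_sites Minimum usable sites for a window statistic (default 2).
#' @param maf Minor-allele-frequency floor (default 0.05).
#' @param max_missing Maximum per-site missing fraction (default 0.1,
#'   exclusive).
#' @return A list of class `sweep_params`.
#' @export
sweep_params <- function(window = 50000, step = window, quantile = 0.99,
                         min_sites = 2L, maf = 0.05, max_missing = 0.1) {
  stopifnot(quantile > 0, quantile < 1, step <= window, step > 0, window > 0,
            maf >= 0, maf <= 0.5, max_missing >= 0, max_missing <= 1)
  structure(list(window = window, step = step, quantile = quantile,
                 min_sites = as.integer(min_sites), maf = maf,
                 max_missing = max_missing),
            class = "sweep_params")
}

#' Filter sites on biallelism, minor allele frequency and missingness
#'
#' Retains biallelic SNP records with `MAF >= params$maf` (computed over all
#' called alleles of all samples) and missing genotype fraction strictly
#' below `params$max_missing`. Monomorphic sites fail the MAF floor.
#'
#' @param g A `dioscan_geno` object.
#' @param params A [sweep_params()] object.
#' @return The filtered `dioscan_geno`.
#' @export
site_filter <- function(g, params = sweep_params()) {
  if (!nrow(g$geno)) return(g)
  biallelic <- !grepl(",", g$alt)
  called <- rowSums(!is.na(g$geno))
  miss <- (ncol(g$geno) - called) / ncol(g$geno)
  ac <- rowSums(g$geno, na.rm = TRUE)
  an <- 2 * called
  p <- ifelse(an > 0, ac / an, 0)
  maf <- pmin(p, 1 - p)
  keep <- biallelic & maf >= params$maf & miss < params$max_missing
  geno_subset(g, which(keep))
}

# windows along each chromosome honoring window/step; returns data.table
# with chrom, start, end (0-based half-open)
sweep_windows_grid <- function(g, params) {
  if (!length(g$pos))
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric()))
  lens <- tapply(g$pos, g$chrom, max)
  L <- g$genome_length
  out <- lapply(unique(g$chrom), function(cn) {
    len <- max(L, lens[[cn]])
    s <- seq(0, max(len - 1, 0), by = params$step)
    s <- s[s < len]
    data.table(chrom = cn, start = s, end = pmin(s + params$window, len))
  })
  rbindlist(out)
}

# Map each site to its grid row. Fast O(S) path for non-overlapping grids
# (step == window); NULL signals the generic per-window scan (overlapping
# windows).
site_window_index <- function(g, grid, params) {
  if (params$step != params$window) return(NULL)
  pos0 <- g$pos - 1L
  key <- paste(g$chrom, (pos0 %/% params$window) * params$window)
  gkey <- paste(grid$chrom, grid$start)
  match(key, gkey)
}

# per-site allele counts for one population: list(j = alt alleles,
# n = called alleles)
pop_allele_counts <- function(g, pop) {
  cols <- g$pops == pop
  if (!any(cols)) stop("unknown population: ", pop)
  sub <- g$geno[, cols, drop = FALSE]
  list(j = rowSums(sub, na.rm = TRUE), n = 2 * rowSums(!is.na(sub)))
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site pi is the unbiased heterozygosity `2 j (n - j) / (n (n - 1))`
#' with `j` alt alleles among `n` called alleles of the population; window
#' pi is the sum of site pi divided by the full window length in bp
#' (invariant sites count toward the denominator, the `--window-pi`
#' convention).
#'
#' @param g A `dioscan_geno` object.
#' @param pop Population label to compute pi for.
#' @param params A [sweep_params()] object.
#' @return A `data.table` with `chrom`, `start`, `end`, `n_sites` and the
#'   window pi in column `value`.
#' @export
window_pi <- function(g, pop, params = sweep_params()) {
  grid <- sweep_windows_grid(g, params)
  ac <- pop_allele_counts(g, pop)
  ok <- ac$n >= 2
  site_pi <- ifelse(ok, 2 * ac$j * (ac$n - ac$j) /
                      (ac$n * pmax(ac$n - 1, 1)), 0)
  seg <- ok & ac$j > 0 & ac$j < ac$n
  agg_window(grid, g, site_pi, seg, params)
}

# shared window aggregation for sum-type statistics divided by window
# length; n_sites counts segregating sites
agg_window <- function(grid, g, vals, seg, params) {
  out <- data.table::copy(grid)
  widx <- site_window_index(g, grid, params)
  if (!is.null(widx)) {
    keep <- !is.na(widx)
    sums <- rowsum(as.numeric(vals[keep]), widx[keep])
    nseg <- rowsum(as.integer(seg[keep]), widx[keep])
    rows <- as.integer(rownames(sums))
    res <- numeric(nrow(grid)); ns <- integer(nrow(grid))
    res[rows] <- sums[, 1L]
    ns[rows] <- nseg[, 1L]
  } else {
    pos0 <- g$pos - 1L
    res <- numeric(nrow(grid)); ns <- integer(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      idx <- which(g$chrom == grid$chrom[i] & pos0 >= grid$start[i] &
                     pos0 < grid$end[i])
      ns[i] <- sum(seg[idx])
      res[i] <- sum(vals[idx])
    }
  }
  out[, n_sites := ns]
  out[, value := res / (end - start)]
  out[]
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Returns a data.table with a, b, c and a validity flag (non-zero
# denominator). Sites where either population has < 2 called alleles are
# invalid.
wc_site_components <- function(g, pops = levels(g$pops)) {
  stopifnot(length(pops) == 2)
  a1 <- pop_allele_counts(g, pops[1L])
  a2 <- pop_allele_counts(g, pops[2L])
  het <- function(pop) {
    cols <- g$pops == pop
    sub <- g$geno[, cols, drop = FALSE]
    list(h = rowSums(sub == 1L, na.rm = TRUE),
         ind = rowSums(!is.na(sub)))
  }
  h1 <- het(pops[1L]); h2 <- het(pops[2L])
  r <- 2
  n1 <- h1$ind; n2 <- h2$ind                   # individuals per pop
  p1 <- ifelse(a1$n > 0, a1$j / a1$n, 0)
  p2 <- ifelse(a2$n > 0, a2$j / a2$n, 0)
  hb1 <- ifelse(n1 > 0, h1$h / n1, 0)          # observed het fraction
  hb2 <- ifelse(n2 > 0, h2$h / n2, 0)
  nbar <- (n1 + n2) / r
  nc <- ifelse(nbar > 0, (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1), 0)
  pbar <- ifelse(nbar > 0, (n1 * p1 + n2 * p2) / (r * nbar), 0)
  s2 <- ifelse(nbar > 0,
               (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar), 0)
  hbar <- ifelse(nbar > 0, (n1 * hb1 + n2 * hb2) / (r * nbar), 0)
  valid <- n1 >= 1 & n2 >= 1 & nbar > 1 & nc > 0
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!valid] <- NA_real_; b[!valid] <- NA_real_; cc[!valid] <- NA_real_
  data.table(a = a, b = b, c = cc,
             valid = valid & !is.na(a) & is.finite(a + b + cc) &
               (a + b + cc) != 0)
}

#' Windowed Weir-Cockerham FST between two populations
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) follow Weir & Cockerham
#' (1984), including the observed-heterozygosity terms. The window summary
#' `fst_weighted = sum(a) / sum(a + b + c)` (the ratio-of-sums estimator,
#' used for outlier selection) and `fst_mean` (mean of per-site ratios over
#' sites with non-zero denominator) are both reported; negative estimates
#' are reported as computed, without clamping.
#'
#' @param g A `dioscan_geno` with exactly two populations (or `pops` naming
#'   two of them).
#' @param pops Length-2 character of population labels (default: the two
#'   factor levels).
#' @param params A [sweep_params()] object.
#' @return A `data.table` with `chrom`, `start`, `end`, `n_sites`,
#'   `fst_weighted`, `fst_mean` (NA where fewer than `min_sites` usable
#'   sites).
#' @export
window_fst_wc <- function(g, pops = levels(g$pops),
                          params = sweep_params()) {
  if (length(pops) < 2) stop("two populations required")
  comp <- wc_site_components(g, pops)
  grid <- sweep_windows_grid(g, params)
  out <- data.table::copy(grid)
  out[, `:=`(n_sites = 0L, fst_weighted = NA_real_, fst_mean = NA_real_)]
  widx <- site_window_index(g, grid, params)
  if (!is.null(widx)) {
    # vectorized aggregation over the non-overlapping grid
    keep <- comp$valid & !is.na(widx)
    wi <- widx[keep]
    sa <- rowsum(comp$a[keep], wi)
    sabc <- rowsum(comp$a[keep] + comp$b[keep] + comp$c[keep], wi)
    sr <- rowsum(comp$a[keep] / (comp$a[keep] + comp$b[keep] + comp$c[keep]),
                 wi)
    cnt <- rowsum(rep(1L, sum(keep)), wi)
    rows <- as.integer(rownames(sa))
    data.table::set(out, rows, "n_sites", cnt[, 1L])
    okr <- cnt[, 1L] >= params$min_sites
    wrows <- rows[okr]
    data.table::set(out, wrows, "fst_weighted",
                    ifelse(sabc[okr, 1L] != 0, sa[okr, 1L] / sabc[okr, 1L],
                           NA_real_))
    data.table::set(out, wrows, "fst_mean", sr[okr, 1L] / cnt[okr, 1L])
  } else {
    pos0 <- g$pos - 1L
    for (i in seq_len(nrow(out))) {
      idx <- which(g$chrom == out$chrom[i] & pos0 >= out$start[i] &
                     pos0 < out$end[i] & comp$valid)
      ns <- length(idx)
      data.table::set(out, i, "n_sites", ns)
      if (ns >= params$min_sites) {
        denom <- sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
        data.table::set(out, i, "fst_weighted",
                        if (denom != 0) sum(comp$a[idx]) / denom
                        else NA_real_)
        ratio <- comp$a[idx] / (comp$a[idx] + comp$b[idx] + comp$c[idx])
        data.table::set(out, i, "fst_mean", mean(ratio))
      }
    }
  }
  out[]
}

#' Per-site Weir-Cockerham FST
#'
#' Convenience wrapper exposing the per-site variance components and the
#' per-site ratio `a / (a + b + c)`; sites with a zero denominator are
#' flagged invalid and get `NA`.
#'
#' @inheritParams window_fst_wc
#' @return A `data.table` with `chrom`, `pos`, `a`, `b`, `c`, `fst`,
#'   `valid`.
#' @export
site_fst_wc <- function(g, pops = levels(g$pops)) {
  comp <- wc_site_components(g, pops)
  comp[, fst := ifelse(valid, a / (a + b + c), NA_real_)]
  data.table(chrom = g$chrom, pos = g$pos, comp)
}

#' Tajima's D constants for sample size n
#'
#' The standard constants a1, a2, b1, b2, c1, c2, e1, e2 as functions of the
#' number of sequences (alleles) n.
#'
#' @param n Number of alleles (>= 2).
#' @return A named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D for one population
#'
#' Within each window: `theta_pi` is the mean pairwise difference count
#' (sum over sites of `2 j (n - j) / (n (n - 1))`), `theta_W = S / a1`, and
#' `D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S - 1))`. Windows with
#' fewer than `min_S` segregating sites are `NA`. With missing data, n is
#' taken as the rounded mean called-allele count over the window's
#' segregating sites. At n = 2 the variance constants vanish; D is defined
#' as 0 there because the numerator is identically 0.
#'
#' @param g A `dioscan_geno` object.
#' @param pop Population label.
#' @param params A [sweep_params()] object.
#' @param min_S Minimum segregating sites (default 3).
#' @return A `data.table` with `chrom`, `start`, `end`, `S`, `tajima_d`.
#' @export
window_tajima_d <- function(g, pop, params = sweep_params(), min_S = 3L) {
  ac <- pop_allele_counts(g, pop)
  if (any(ac$n < 2 & ac$n > 0))
    warning("sites with fewer than 2 called alleles are ignored")
  if (!any(ac$n >= 2)) stop("population has fewer than 2 called alleles")
  grid <- sweep_windows_grid(g, params)
  pos0 <- g$pos - 1L
  seg <- ac$n >= 2 & ac$j > 0 & ac$j < ac$n
  site_pi <- ifelse(seg, 2 * ac$j * (ac$n - ac$j) /
                      (ac$n * pmax(ac$n - 1, 1)), 0)
  out <- data.table::copy(grid)
  out[, `:=`(S = 0L, tajima_d = NA_real_)]
  widx <- site_window_index(g, grid, params)
  if (!is.null(widx)) {
    idx_list <- split(which(seg), widx[seg])
    win_idx <- as.integer(names(idx_list))
  } else {
    win_idx <- seq_len(nrow(out))
    idx_list <- NULL
  }
  for (wi in seq_along(win_idx)) {
    i <- win_idx[wi]
    idx <- if (!is.null(idx_list)) idx_list[[wi]]
           else which(g$chrom == out$chrom[i] & pos0 >= out$start[i] &
                        pos0 < out$end[i] & seg)
    S <- length(idx)
    data.table::set(out, i, "S", S)
    if (S < min_S) next
    n <- round(mean(ac$n[idx]))
    if (n < 2) next
    k <- tajima_constants(n)
    theta_pi <- sum(site_pi[idx])
    theta_w <- S / k$a1
    varD <- k$e1 * S + k$e2 * S * (S - 1)
    num <- theta_pi - theta_w
    d <- if (varD > 0) num / sqrt(varD) else if (abs(num) < 1e-12) 0
         else NA_real_
    data.table::set(out, i, "tajima_d", d)
  }
  out[]
}

#' Per-window ln(pi_wild / pi_domestic)
#'
#' @param pi_wild,pi_dom [window_pi()] outputs on the same grid (columns
#'   `chrom`, `start`, `end`, `n_sites`, `value`).
#' @param params A [sweep_params()] object (`min_sites` rule).
#' @return The grid with a `ln_ratio` column; `NA` where either window has
#'   fewer than `min_sites` sites or the denominator pi is 0.
#' @export
pi_ln_ratio <- function(pi_wild, pi_dom, params = sweep_params()) {
  if (!identical(pi_wild[, .(chrom, start, end)],
                 pi_dom[, .(chrom, start, end)]))
    stop("window grids differ")
  out <- pi_wild[, .(chrom, start, end)]
  ok <- pi_wild$n_sites >= params$min_sites &
    pi_dom$n_sites >= params$min_sites & pi_dom$value > 0
  out[, ln_ratio := ifelse(ok, log(pi_wild$value / pi_dom$value), NA_real_)]
  out[]
}

# nearest-rank-above empirical quantile: smallest element whose rank is at
# least ceiling(q * n) among the sorted non-NA values
quantile_nearest_rank <- function(x, q) {
  v <- sort(x[!is.na(x)])
  if (!length(v)) stop("all values NA")
  v[ceiling(q * length(v))]
}

#' Select sweep regions as dual-statistic top-quantile outlier windows
#'
#' Thresholds are the empirical `q`-quantiles (nearest-rank-above) of the
#' non-NA FST and pi-ln-ratio window values; an outlier window must reach
#' both thresholds (>= comparison, so ties at the threshold are outliers).
#' Overlapping or adjacent outlier windows are merged into regions.
#'
#' @param fst A [window_fst_wc()] output (uses `fst_weighted`).
#' @param lnratio A [pi_ln_ratio()] output.
#' @param params A [sweep_params()] object (`quantile`).
#' @return A `data.table` with `chrom`, `start`, `end`, `n_windows`,
#'   `mean_fst`, `mean_ln_ratio`, plus attributes `fst_threshold` and
#'   `lnratio_threshold`.
#' @export
select_sweeps <- function(fst, lnratio, params = sweep_params()) {
  if (!identical(fst[, .(chrom, start, end)],
                 lnratio[, .(chrom, start, end)]))
    stop("window grids differ")
  ft <- quantile_nearest_rank(fst$fst_weighted, params$quantile)
  lt <- quantile_nearest_rank(lnratio$ln_ratio, params$quantile)
  out_w <- !is.na(fst$fst_weighted) & !is.na(lnratio$ln_ratio) &
    fst$fst_weighted >= ft & lnratio$ln_ratio >= lt
  wins <- data.table(chrom = fst$chrom, start = fst$start, end = fst$end,
                     fst = fst$fst_weighted, lnr = lnratio$ln_ratio)[out_w]
  if (!nrow(wins)) {
    res <- data.table(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      mean_fst = numeric(), mean_ln_ratio = numeric())
  } else {
    setorder(wins, chrom, start)
    # merge overlapping or adjacent windows: new group when a window starts
    # strictly after the running max end of its predecessors
    wins[, grp := {
      run_end <- cummax(c(-Inf, head(end, -1)))
      cumsum(start > run_end)
    }, by = chrom]
    res <- wins[, .(start = min(start), end = max(end), n_windows = .N,
                    mean_fst = mean(fst), mean_ln_ratio = mean(lnr)),
                by = .(chrom, grp)][, grp := NULL][]
  }
  setattr(res, "fst_threshold", ft)
  setattr(res, "lnratio_threshold", lt)
  res
}

#' Annotate sweep regions with overlapping genes from a GFF3 file
#'
#' A gene is assigned to a region iff it overlaps by at least 1 bp after
#' converting GFF3's 1-based inclusive coordinates to 0-based half-open.
#'
#' @param regions A [select_sweeps()] output (or any table with `chrom`,
#'   `start`, `end` in 0-based half-open coordinates).
#' @param genes A GFF3 path or a `GRanges` with a `type` column; feature
#'   type `gene` is used. Gene ids come from the `ID` attribute (fallback:
#'   `Name`).
#' @return `regions` with an added list-column `gene_ids` and count
#'   `n_genes`.
#' @export
overlap_genes <- function(regions, genes) {
  gr <- if (is.character(genes))
    rtracklayer::import(genes, format = "GFF3") else genes
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  res <- data.table::copy(as.data.table(regions))
  if (!nrow(res)) {
    res[, `:=`(gene_ids = list(), n_genes = integer())]
    return(res[])
  }
  rgr <- GenomicRanges::GRanges(res$chrom,
                                IRanges::IRanges(res$start + 1L, res$end))
  hits <- GenomicRanges::findOverlaps(rgr, gr, minoverlap = 1L)
  lst <- split(ids[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(res))))
  res[, gene_ids := lapply(lst, as.character)]
  res[, n_genes := lengths(gene_ids)]
  res[]
}

#' Export the per-window major/minor allele pattern matrix
#'
#' Reduces the haplotype-panel visualization to a TSV-ready table: for each
#' retained site (MAF > `maf`), the per-sample dosage recoded relative to
#' the major allele of the reference population.
#'
#' @param g A `dioscan_geno` object.
#' @param ref_pop Population whose major allele defines the coding.
#' @param maf MAF floor (default 0.05).
#' @return A `data.table` with `chrom`, `pos` and one column per sample:
#'   dosage of the `ref_pop` *minor* allele.
#' @export
allele_pattern <- function(g, ref_pop = levels(g$pops)[1L], maf = 0.05) {
  ac_all <- list(j = rowSums(g$geno, na.rm = TRUE),
                 n = 2 * rowSums(!is.na(g$geno)))
  p <- ifelse(ac_all$n > 0, ac_all$j / ac_all$n, 0)
  keep <- pmin(p, 1 - p) > maf
  ac <- pop_allele_counts(g, ref_pop)
  major_is_alt <- ac$j > ac$n / 2
  m <- g$geno[keep, , drop = FALSE]
  flip <- major_is_alt[keep]
  m[flip, ] <- 2L - m[flip, ]
  out <- data.table(chrom = g$chrom[keep], pos = g$pos[keep])
  cbind(out, as.data.table(m))
}
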