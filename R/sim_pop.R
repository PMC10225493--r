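# Simulation of a wild vs domesticated SNP panel with planted selective-sweep
# windows: neutral sites drift mildly between the populations, sweep windows
# are driven to near-fixation in the domesticated group and depleted of sites.

#' Simulate a wild/domesticated genotype panel with planted sweeps
#'
#' Neutral sites: ancestral frequency `p ~ Beta(a, b)`; the wild population
#' keeps `p`, the domesticated population gets `p` plus truncated-normal
#' drift with sd `drift_sd`. Both frequencies are clipped to
#' `[1/(2n), 1 - 1/(2n)]` (n = diploids of that population) so sites stay
#' polymorphic and minor-allele-frequency filters remain meaningful.
#' In sweep windows, each site's domesticated frequency is moved to the
#' nearer of `eps` / `1 - eps` with probability `s` (near-fixation without
#' degenerate monomorphic records; `eps` fixed at 0.01) and the site density
#' is multiplied by the thinning factor `f` (diversity loss). Genotypes are
#' binomial draws per diploid.
#'
#' @param genome_length Total length (bp) of the single simulated chromosome.
#' @param window Window size in bp (the sweep-planting unit).
#' @param n_wild,n_dom Diploid sample sizes.
#' @param beta_shape Length-2 ancestral-frequency Beta shape `(a, b)`.
#' @param drift_sd Standard deviation of the neutral drift offset.
#' @param sweep_windows Count of sweep windows to place uniformly at random
#'   (ignored when `sweep_window_idx` is given).
#' @param sweep_window_idx Optional integer vector of explicit 0-based sweep
#'   window indices.
#' @param s Per-site probability that a sweep-window site is driven to
#'   near-fixation in the domesticated group.
#' @param f Sweep site-thinning factor in `(0, 1]`.
#' @param sites_per_window Mean polymorphic-site count per neutral window
#'   (default 100, i.e. 2 SNPs/kb at the default 50-kb window).
#' @param missing_rate Per-genotype missing probability (default 0).
#' @param chrom Chromosome name used in output.
#' @param seed Integer seed.
#' @return A list of class `dioscan_geno` with `geno` (sites x samples dosage
#'   matrix), `chrom`, `pos` (1-based), `ref`, `alt`, `pops` (factor
#'   `wild`/`dom`), `window`, `genome_length`, `samples`, and `truth`
#'   (a `data.table` of planted sweep windows: `chrom`, `start`, `end`,
#'   `window_index`).
#' @export
simulate_population_vcf <- function(genome_length = 1e8, window = 50000,
                                    n_wild = 12L, n_dom = 40L,
                                    beta_shape = c(0.5, 0.5),
                                    drift_sd = 0.05, sweep_windows = 20L,
                                    sweep_window_idx = NULL,
                                    s = 0.9, f = 0.1,
                                    sites_per_window = 100,
                                    missing_rate = 0, chrom = "chr1",
                                    seed = 1L) {
  stopifnot(n_wild >= 1, n_dom >= 1, f > 0, f <= 1, s >= 0, s <= 1,
            drift_sd >= 0, genome_length >= window, window > 0)
  if (n_wild + n_dom == 0) stop("zero samples")
  eps <- 0.01
  n_win <- as.integer(floor(genome_length / window))
  with_stream_seed(seed, "popvcf", {
    sweep_idx <- if (is.null(sweep_window_idx))
      sort(sample.int(n_win, as.integer(sweep_windows)) - 1L)
    else sort(unique(as.integer(sweep_window_idx)))
    stopifnot(all(sweep_idx >= 0), all(sweep_idx < n_win))
    is_sweep <- rep(FALSE, n_win)
    is_sweep[sweep_idx + 1L] <- TRUE

    n_sites_w <- rpois(n_win, sites_per_window * ifelse(is_sweep, f, 1))
    total <- sum(n_sites_w)
    win_of <- rep.int(seq_len(n_win) - 1L, n_sites_w)
    off <- floor(runif(total) * window)
    pos <- as.integer(win_of * window + off + 1)           # 1-based
    dup <- duplicated(pos)
    if (any(dup)) { pos <- pos[!dup]; win_of <- win_of[!dup] }
    o <- order(pos)
    pos <- pos[o]; win_of <- win_of[o]
    total <- length(pos)

    p <- rbeta(total, beta_shape[1], beta_shape[2])
    clip <- function(x, n) pmin(pmax(x, 1 / (2 * n)), 1 - 1 / (2 * n))
    pw <- clip(p, n_wild)
    pd <- clip(pw + rnorm(total, 0, drift_sd), n_dom)
    sw_site <- is_sweep[win_of + 1L] & (runif(total) < s)
    pd[sw_site] <- ifelse(pd[sw_site] >= 0.5, 1 - eps, eps)

    gw <- matrix(rbinom(total * n_wild, 2L, rep(pw, n_wild)), total, n_wild)
    gd <- matrix(rbinom(total * n_dom, 2L, rep(pd, n_dom)), total, n_dom)
    geno <- cbind(gw, gd)
    if (missing_rate > 0)
      geno[runif(length(geno)) < missing_rate] <- NA_integer_
    samples <- c(paste0("W", seq_len(n_wild)), paste0("D", seq_len(n_dom)))
    colnames(geno) <- samples
    bases <- c("A", "C", "G", "T")
    ref_i <- sample.int(4L, total, TRUE)
    alt_i <- (ref_i - 1L + sample.int(3L, total, TRUE)) %% 4L + 1L
    ref <- bases[ref_i]
    alt <- bases[alt_i]
    truth <- data.table(chrom = chrom,
                        start = sweep_idx * window,
                        end = (sweep_idx + 1) * window,
                        window_index = sweep_idx)
    structure(list(geno = geno, chrom = rep(chrom, total), pos = pos,
                   ref = ref, alt = alt,
                   pops = factor(c(rep("wild", n_wild), rep("dom", n_dom)),
                                 levels = c("wild", "dom")),
                   window = window, genome_length = genome_length,
                   samples = samples, truth = truth),
              class = "dioscan_geno")
  })
}

#' Write a simulated panel to VCF and its sweep truth to BED
#'
#' @param sim Output of [simulate_population_vcf()].
#' @param vcf_path,bed_path Output paths.
#' @return Invisibly, `vcf_path`.
#' @export
write_population_vcf <- function(sim, vcf_path, bed_path = NULL) {
  write_vcf(sim$geno, sim$chrom, sim$pos, sim$ref, sim$alt,
            samples = sim$samples,
            contig_lengths = setNames(sim$genome_length, sim$chrom[1L] %||%
                                        "chr1"),
            path = vcf_path)
  if (!is.null(bed_path)) write_bed(sim$truth, bed_path)
  invisible(vcf_path)
}
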