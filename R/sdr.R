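# SDR localization: placement of sex-specific reads on an assembly, windowed
# depth tracks, per-sex variant density, per-window coverage log-ratio, and
# candidate-region calling by a robust depth threshold.

#' Place reads on a reference by unique exact seed plus bounded mismatches
#'
#' Internal, aligner-free placement for desk-scale testing: the first N-free
#' k-length substring of the read (and of its reverse complement) is looked
#' up in an exact index of reference k-mers; the read is placed only when
#' exactly one seed hit exists across both orientations and the full read
#' aligns there with at most `max_mismatch` substitutions. Reads whose seed
#' occurs more than once are discarded. Placements identical in
#' (chromosome, start, strand) are deduplicated when `dedup = TRUE`
#' (positional duplicate removal).
#'
#' @param reads Named or unnamed character vector of reads, FASTQ path(s),
#'   or a `labeled_reads` partition.
#' @param reference Named character vector of chromosome sequences or a
#'   FASTA path.
#' @param k Seed length (default 40).
#' @param max_mismatch Maximum substitutions over the full read (default 2).
#' @param dedup Remove positional duplicates (default `TRUE`).
#' @param group Optional factor-like vector (one element per read); the
#'   index is built once and deduplication is applied within each group
#'   (used to place several read partitions in one pass).
#' @return A `data.table` with `read`, `chrom`, `start` (0-based), `strand`
#'   (and `group` when given); one row per placed (surviving) read.
#' @export
place_reads <- function(reads, reference, k = 40L, max_mismatch = 2L,
                        dedup = TRUE, group = NULL) {
  reads <- as_reads(reads)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && is.null(names(reference)))
    reference <- read_fasta(reference)
  stopifnot(!is.null(names(reference)))
  if (!is.null(group)) stopifnot(length(group) == length(reads))
  res <- cpp_place_reads(as.character(reference), as.character(reads),
                         as.integer(k), as.integer(max_mismatch))
  keep <- !is.na(res$chrom)
  dt <- data.table(read = if (!is.null(names(reads))) names(reads)[keep]
                   else as.character(which(keep)),
                   chrom = names(reference)[res$chrom[keep]],
                   start = res$start[keep],
                   strand = res$strand[keep])
  if (!is.null(group)) dt[, group := group[keep]]
  if (dedup) {
    by <- c(if (!is.null(group)) "group", "chrom", "start", "strand")
    dt <- unique(dt, by = by)
  }
  setorder(dt, chrom, start)
  dt[]
}

#' Ingest external alignments (SAM/BAM) as placements
#'
#' Records are kept if mapped, primary (neither secondary nor
#' supplementary), not flagged as duplicate, and `MAPQ >= min_mapq`;
#' positional duplicates — identical (chromosome, start, strand) — are then
#' removed. The file must be coordinate-sorted. SAM text is parsed directly;
#' BAM requires the `Rsamtools` package.
#'
#' @param path Path to a coordinate-sorted SAM or BAM file.
#' @param min_mapq Minimum mapping quality (default 20).
#' @return A `data.table` as in [place_reads()].
#' @export
place_reads_external <- function(path, min_mapq = 20L) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("BAM ingestion requires Rsamtools")
    b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq")))[[1L]]
    dt <- data.table(read = b$qname, flag = b$flag,
                     chrom = as.character(b$rname), pos = b$pos,
                     mapq = b$mapq)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    if (!length(lines))
      return(data.table(read = character(), chrom = character(),
                        start = integer(), strand = character()))
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 11L)
    if (length(bad)) stop("malformed SAM line ", bad[1L])
    dt <- data.table(read = vapply(f, `[`, "", 1L),
                     flag = as.integer(vapply(f, `[`, "", 2L)),
                     chrom = vapply(f, `[`, "", 3L),
                     pos = as.integer(vapply(f, `[`, "", 4L)),
                     mapq = as.integer(vapply(f, `[`, "", 5L)))
  }
  dt <- dt[!bitwAnd(flag, 0x4L) & !bitwAnd(flag, 0x100L) &
             !bitwAnd(flag, 0x800L) & !bitwAnd(flag, 0x400L) &
             mapq >= min_mapq]
  if (nrow(dt) && dt[, any(diff(pos) < 0), by = chrom][, any(V1)])
    stop("alignments are not coordinate-sorted")
  dt[, strand := ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+")]
  dt[, start := pos - 1L]
  dt <- unique(dt[, .(read, chrom, start, strand)],
               by = c("chrom", "start", "strand"))
  setorder(dt, chrom, start)
  dt[]
}

#' Windowed read-depth track
#'
#' Each placement is assigned to the window containing its start. Windows
#' tile each chromosome (0-based half-open, non-overlapping); the raw counts
#' sum to the number of placements, and the normalized value is counts per
#' million placed reads (CPM).
#'
#' @param placements A `data.table` from [place_reads()] (needs `chrom`,
#'   `start`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param w Window size in bp.
#' @param normalize Compute the CPM column (default `TRUE`).
#' @return A `data.table` of class `window_track` with `chrom`, `start`,
#'   `end`, `partial`, `count`, `cpm`.
#' @export
window_depth <- function(placements, chrom_lengths, w = 1e5,
                         normalize = TRUE) {
  track <- tile_windows(chrom_lengths, w)
  track[, count := 0L]
  if (nrow(placements)) {
    bad <- placements[!chrom %in% names(chrom_lengths)]
    if (nrow(bad)) stop("placement on unknown chromosome ", bad$chrom[1L])
    p <- as.data.table(placements)
    if (p[, any(start < 0 | start >= chrom_lengths[chrom])])
      stop("placement beyond chromosome end")
    tally <- p[, .N, by = .(chrom, win_start = (start %/% w) * w)]
    track[tally, count := i.N, on = c("chrom", start = "win_start")]
  }
  total <- sum(track$count)
  if (normalize)
    track[, cpm := if (total > 0) count * 1e6 / total else 0]
  setattr(track, "class", c("window_track", class(track)))
  setattr(track, "w", w)
  track[]
}

#' Call candidate SDR intervals from male/female depth tracks
#'
#' Seed windows must satisfy: male normalized depth strictly greater than
#' the male track's `median + z * MAD` with raw read support of at least
#' `min_reads`, and female depth *not* elevated — i.e. not simultaneously
#' above the female track's `median + z * MAD` and supported by
#' `min_reads` raw reads. The `min_reads` floor guards both rules against
#' the degenerate sparse-track case (median = MAD = 0, where any stray
#' read would otherwise flip a window). Seeds separated by at most
#' `merge_gap` windows are merged; merged regions with fewer than
#' `min_windows` windows are dropped; regions are ranked by total
#' supporting reads.
#'
#' @param male_track,female_track [window_depth()] tracks on the same grid.
#' @param z Robust threshold multiplier (default 4).
#' @param merge_gap Maximum separating windows to merge across (default 2).
#' @param min_windows Minimum windows per region (default 2).
#' @param min_reads Minimum raw read count for a seed window (default 10).
#' @return A `data.table` with `chrom`, `start`, `end`, `n_windows`,
#'   `total_reads`, `mean_cpm`, `rank`; sorted by coordinate, disjoint.
#' @export
call_sdr <- function(male_track, female_track, z = 4, merge_gap = 2L,
                     min_windows = 2L, min_reads = 10L) {
  if (!identical(male_track[, .(chrom, start, end)],
                 female_track[, .(chrom, start, end)]))
    stop("window grids differ between tracks")
  m_med <- median(male_track$cpm); m_mad <- mad(male_track$cpm)
  f_med <- median(female_track$cpm); f_mad <- mad(female_track$cpm)
  female_high <- female_track$cpm > f_med + z * f_mad &
    female_track$count >= min_reads
  seed <- male_track$cpm > m_med + z * m_mad &
    male_track$count >= min_reads & !female_high
  dt <- data.table::copy(male_track)[, seed := seed]
  dt[, widx := seq_len(.N), by = chrom]
  seeds <- dt[seed == TRUE]
  if (!nrow(seeds))
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      total_reads = integer(), mean_cpm = numeric(),
                      rank = integer()))
  seeds[, grp := cumsum(c(1L, diff(widx) > merge_gap + 1L)), by = chrom]
  regions <- seeds[, .(start = min(start), end = max(end), n_seed = .N,
                       first = min(widx), last = max(widx)),
                   by = .(chrom, grp)]
  # region statistics over all windows inside the merged span
  stats <- regions[, {
    win <- dt[chrom == .BY$chrom & widx >= first & widx <= last]
    .(n_windows = nrow(win), total_reads = sum(win$count),
      mean_cpm = mean(win$cpm))
  }, by = .(chrom, grp, start, end)]
  stats <- stats[n_windows >= min_windows]
  if (!nrow(stats)) return(stats[, .(chrom, start, end, n_windows,
                                     total_reads, mean_cpm,
                                     rank = integer())])
  setorder(stats, -total_reads)
  stats[, rank := seq_len(.N)]
  setorder(stats, chrom, start)
  stats[, grp := NULL]
  stats[]
}

#' Per-window, per-sex variant density from a multi-sample VCF
#'
#' For each window: the mean per-sample heterozygous SNP and indel counts in
#' each sex, plus male-specific variant counts. A site is male-specific when
#' every male sample carries a non-reference allele (dosage >= 1) and every
#' female sample is called homozygous reference; an uncalled female genotype
#' disqualifies the site (conservative). SNPs and indels are distinguished
#' by REF/ALT lengths.
#'
#' @param vcf A VCF path or a [read_vcf()]-style list.
#' @param sex Named character vector mapping sample id to `"male"`/`"female"`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param w Window size in bp.
#' @return A `data.table` with per-window columns `het_snp_male`,
#'   `het_snp_female`, `het_indel_male`, `het_indel_female`,
#'   `male_specific_snp`, `male_specific_indel`.
#' @export
sex_variant_density <- function(vcf, sex, chrom_lengths, w = 1e5) {
  v <- if (is.character(vcf)) read_vcf(vcf) else vcf
  missing_samples <- setdiff(names(sex), v$samples)
  if (length(missing_samples))
    stop("sample missing from VCF: ", missing_samples[1L])
  sex <- sex[v$samples[v$samples %in% names(sex)]]
  males <- names(sex)[sex == "male"]
  females <- names(sex)[sex == "female"]
  if (!length(males) || !length(females))
    stop("need at least one sample of each sex")
  track <- tile_windows(chrom_lengths, w)
  for (col in c("het_snp_male", "het_snp_female", "het_indel_male",
                "het_indel_female", "male_specific_snp",
                "male_specific_indel"))
    track[, (col) := 0]
  if (!length(v$pos)) return(track[])
  is_snp <- nchar(v$ref) == 1L & nchar(v$alt) == 1L & !grepl(",", v$alt)
  g <- v$geno
  gm <- g[, males, drop = FALSE]
  gf <- g[, females, drop = FALSE]
  het_m <- rowSums(gm == 1L, na.rm = TRUE) / length(males)
  het_f <- rowSums(gf == 1L, na.rm = TRUE) / length(females)
  msp <- rowSums(!is.na(gm) & gm >= 1L) == length(males) &
    rowSums(!is.na(gf) & gf == 0L) == length(females)
  site <- data.table(chrom = v$chrom,
                     win_start = ((v$pos - 1L) %/% w) * w,
                     het_m = het_m, het_f = het_f,
                     msp = msp, is_snp = is_snp)
  agg <- site[, .(het_snp_male = sum(het_m[is_snp]),
                  het_snp_female = sum(het_f[is_snp]),
                  het_indel_male = sum(het_m[!is_snp]),
                  het_indel_female = sum(het_f[!is_snp]),
                  male_specific_snp = sum(msp & is_snp),
                  male_specific_indel = sum(msp & !is_snp)),
              by = .(chrom, win_start)]
  for (col in names(agg)[-(1:2)])
    track[agg, (col) := get(paste0("i.", col)),
          on = c("chrom", start = "win_start")]
  track[]
}

#' Per-window log2 male/female coverage ratio
#'
#' @param male_track,female_track [window_depth()] tracks on the same grid.
#' @param pseudocount Added to both normalized values (must be > 0).
#' @return The window grid with a `log2_ratio` column:
#'   `log2((m + c) / (f + c))` on CPM values.
#' @export
coverage_ratio <- function(male_track, female_track, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (!identical(male_track[, .(chrom, start, end)],
                 female_track[, .(chrom, start, end)]))
    stop("window grids differ between tracks")
  out <- male_track[, .(chrom, start, end)]
  out[, log2_ratio := log2((male_track$cpm + pseudocount) /
                             (female_track$cpm + pseudocount))]
  out[]
}

#' Export a window track as bedGraph
#'
#' @param track A [window_depth()]-style table.
#' @param path Output path.
#' @param column Which column to export (default `"cpm"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, column = "cpm") {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = as.numeric(track[[column]]))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
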