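# Karyotype evolution: evolutionary fusion regions (EFRs) between adjacent
# homologous synteny blocks (HSBs), parsimony fusion/fission event counts
# against an ancestral karyotype, and repeat-class content of EFRs.

#' Load and filter a synteny block table
#'
#' Expected columns: `target_chrom`, `start`, `end` (0-based half-open),
#' `ancestral_chrom`, `orientation` (header optional, this column order).
#' Blocks shorter than `min_block_length` are dropped; the rest are sorted
#' per target chromosome. Overlap among retained blocks is an error.
#'
#' @param table A TSV path or a data.frame.
#' @param min_block_length Minimum retained block length in bp (default
#'   1.2 Mb, the large-scale HSB resolution).
#' @return A `data.table` of class `block_table`, sorted by chromosome and
#'   start, with attribute `min_block_length`.
#' @export
load_blocks <- function(table, min_block_length = 1.2e6) {
  cols <- c("target_chrom", "start", "end", "ancestral_chrom", "orientation")
  if (is.character(table) && length(table) == 1L) {
    first <- readLines(table, n = 1L)
    has_header <- grepl("target_chrom", first, fixed = TRUE)
    dt <- fread(table, header = has_header, sep = "\t")
    if (ncol(dt) < 5L) stop("block table needs 5 columns")
    dt <- dt[, 1:5]
    setnames(dt, cols)
  } else {
    dt <- as.data.table(table)
    if (!all(cols %in% names(dt)))
      stop("block table needs columns: ", paste(cols, collapse = ", "))
    dt <- dt[, cols, with = FALSE]
  }
  if (nrow(dt)) {
    bad <- which(!is.finite(dt$start) | !is.finite(dt$end) |
                   dt$end <= dt$start |
                   !dt$orientation %in% c("+", "-"))
    if (length(bad)) stop("malformed block table row ", bad[1L])
  }
  dt <- dt[end - start >= min_block_length]
  setorder(dt, target_chrom, start)
  if (nrow(dt) > 1L) {
    ov <- dt[, any(head(end, -1) > tail(start, -1)), by = target_chrom]
    if (any(ov$V1)) stop("retained blocks overlap on ",
                         ov$target_chrom[which(ov$V1)[1L]])
  }
  setattr(dt, "min_block_length", min_block_length)
  setattr(dt, "class", c("block_table", class(dt)))
  dt[]
}

#' Detect evolutionary fusion regions between adjacent blocks
#'
#' One EFR per adjacent retained-block pair per target chromosome: the
#' interval between the left block's end and the right block's start.
#' Junction type is `ancestry-switch` when the flanking ancestral ids
#' differ, else `same-ancestry gap`. Zero-length EFRs (touching blocks) are
#' kept and flagged.
#'
#' @param blocks A [load_blocks()] table.
#' @return A `data.table` with `chrom`, `start`, `end`, `type`,
#'   `left_block`, `right_block` (ancestral ids), `zero_length`.
#' @export
detect_efrs <- function(blocks) {
  dt <- as.data.table(blocks)
  if (nrow(dt) < 2L)
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric(), type = character(),
                      left_block = character(), right_block = character(),
                      zero_length = logical()))
  efr <- dt[, if (.N >= 2L) .(start = head(end, -1L),
                              end = tail(start, -1L),
                              left_block = head(ancestral_chrom, -1L),
                              right_block = tail(ancestral_chrom, -1L)),
            by = .(chrom = target_chrom)]
  if (!nrow(efr))
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric(), type = character(),
                      left_block = character(), right_block = character(),
                      zero_length = logical()))
  efr[, type := ifelse(left_block != right_block, "ancestry-switch",
                       "same-ancestry gap")]
  efr[, zero_length := end <= start]
  efr[, .(chrom, start, end, type, left_block, right_block, zero_length)]
}

#' Parsimony fusion/fission event counts from a block table
#'
#' `n_fusion` is the sum over target chromosomes of (number of maximal runs
#' of constant ancestral id - 1); `n_fission` is the sum over ancestral
#' chromosomes of (number of distinct target chromosomes carrying at least
#' one of its blocks - 1). Orientation is ignored (inversions are not
#' events in this model); translocation-type rearrangements are not
#' modelled, so both counts are lower bounds.
#'
#' @param blocks A [load_blocks()] table (or any table with `target_chrom`,
#'   `start`, `ancestral_chrom`).
#' @return A list with `n_fusion`, `n_fission`.
#' @export
count_events <- function(blocks) {
  dt <- as.data.table(blocks)
  if (!nrow(dt)) return(list(n_fusion = 0L, n_fission = 0L))
  setorder(dt, target_chrom, start)
  runs <- dt[, .(r = length(rle(ancestral_chrom)$lengths)),
             by = target_chrom]
  n_fusion <- sum(runs$r - 1L)
  spread <- dt[, .(t = data.table::uniqueN(target_chrom)),
               by = ancestral_chrom]
  n_fission <- sum(spread$t - 1L)
  list(n_fusion = as.integer(n_fusion), n_fission = as.integer(n_fission))
}

#' Repeat-class content of EFRs versus genome background
#'
#' For each repeat class, intervals are merged (bases are never double
#' counted within a class) before computing the fraction of EFR bases and
#' of whole-genome bases covered; the enrichment ratio is EFR fraction over
#' background fraction (`NA` when the background fraction is 0).
#'
#' @param efrs A [detect_efrs()] table (uses `chrom`, `start`, `end`).
#' @param repeats A BED path (4th column = repeat class) or a table with
#'   `chrom`, `start`, `end`, `class` (0-based half-open).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A `data.table` with `class`, `efr_bases`, `efr_fraction`,
#'   `genome_fraction`, `enrichment`.
#' @export
repeat_enrichment <- function(efrs, repeats, chrom_lengths) {
  rep_dt <- if (is.character(repeats) && length(repeats) == 1L) {
    dt <- read_bed(repeats)
    if ("name" %in% names(dt)) setnames(dt, "name", "class")
    dt
  } else as.data.table(repeats)
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(rep_dt)))
  if (nrow(rep_dt)) {
    if (any(!rep_dt$chrom %in% names(chrom_lengths)) ||
        any(rep_dt$end > chrom_lengths[rep_dt$chrom]) ||
        any(rep_dt$start < 0))
      stop("repeat interval beyond chromosome bounds")
  }
  genome_bp <- sum(chrom_lengths)
  efr_dt <- as.data.table(efrs)[end > start]
  efr_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    efr_dt$chrom, IRanges::IRanges(efr_dt$start + 1, efr_dt$end)))
  efr_bp <- sum(GenomicRanges::width(efr_gr))
  classes <- sort(unique(rep_dt$class))
  out <- rbindlist(lapply(classes, function(cl) {
    sub <- rep_dt[class == cl]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$start + 1, sub$end)))
    gbp <- sum(GenomicRanges::width(gr))
    ebp <- if (efr_bp > 0)
      sum(GenomicRanges::width(GenomicRanges::intersect(gr, efr_gr))) else 0
    data.table(class = cl,
               efr_bases = ebp,
               efr_fraction = if (efr_bp > 0) ebp / efr_bp else 0,
               genome_fraction = gbp / genome_bp)
  }))
  if (!nrow(out))
    return(data.table(class = character(), efr_bases = numeric(),
                      efr_fraction = numeric(), genome_fraction = numeric(),
                      enrichment = numeric()))
  out[, enrichment := ifelse(genome_fraction > 0,
                             efr_fraction / genome_fraction, NA_real_)]
  out[]
}
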