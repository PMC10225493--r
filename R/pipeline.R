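# End-to-end convenience wrapper: sexed read sets -> sex-specific k-mers ->
# labeled reads -> placements on the male assembly -> windowed depth tracks
# -> candidate SDR regions.

#' Run the full k-mer based SDR discovery pipeline
#'
#' Catalogues prefix-subsampled k-mers per sample, classifies MSKs/FSKs,
#' labels every read, places the male- and female-specific partitions on the
#' male assembly, builds windowed depth tracks and calls candidate SDR
#' regions.
#'
#' @param samples A list of samples as returned by [simulate_reads()] (each
#'   with `sample_id`, `sex`, `reads`), or a manifest `data.frame` with
#'   `sample_id`, `sex`, `fastq` columns.
#' @param reference Male (Y-bearing) assembly: named character vector of
#'   chromosome sequences or a FASTA path.
#' @param params A [kmer_params()] object.
#' @param window Window size (bp) for the depth tracks (default 100 kb).
#' @param z,merge_gap,min_windows,min_reads Passed to [call_sdr()].
#' @param max_mismatch Passed to [place_reads()].
#' @return A list with `sets` (MSK/FSK), `male_track`, `female_track`,
#'   `regions`, `n_labeled` (per-sample partition sizes).
#' @export
sdr_pipeline <- function(samples, reference, params = kmer_params(),
                         window = 1e5, z = 4, merge_gap = 2L,
                         min_windows = 2L, min_reads = 10L,
                         max_mismatch = 2L) {
  if (is.data.frame(samples)) {
    samples <- lapply(seq_len(nrow(samples)), function(i)
      list(sample_id = samples$sample_id[i], sex = samples$sex[i],
           reads = read_fastq(samples$fastq[i])))
  }
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && is.null(names(reference)))
    reference <- read_fasta(reference)
  grouped <- grouped_counts_fast(lapply(samples, `[[`, "reads"),
                                 vapply(samples, `[[`, "", "sample_id"),
                                 vapply(samples, `[[`, "", "sex"), params,
                                 decode = FALSE)
  sets <- classify_sex_kmers(grouped, params)
  male_reads <- list(); female_reads <- list(); sizes <- list()
  for (s in samples) {
    lab <- label_reads(s$reads, sets, params)
    male_reads[[s$sample_id]] <- lab$male_specific
    female_reads[[s$sample_id]] <- lab$female_specific
    sizes[[s$sample_id]] <- vapply(lab, length, 1L)
  }
  chrom_lengths <- setNames(nchar(reference), names(reference))
  male_reads <- do.call(c, unname(male_reads)) %||% character()
  female_reads <- do.call(c, unname(female_reads)) %||% character()
  pl <- place_reads(c(male_reads, female_reads), reference, k = params$k,
                    max_mismatch = max_mismatch,
                    group = rep(c("male", "female"),
                                c(length(male_reads),
                                  length(female_reads))))
  male_pl <- pl[group == "male"][, group := NULL]
  female_pl <- pl[group == "female"][, group := NULL]
  male_track <- window_depth(male_pl, chrom_lengths, window)
  female_track <- window_depth(female_pl, chrom_lengths, window)
  regions <- call_sdr(male_track, female_track, z = z,
                      merge_gap = merge_gap, min_windows = min_windows,
                      min_reads = min_reads)
  list(sets = sets, male_track = male_track, female_track = female_track,
       male_placements = male_pl, female_placements = female_pl,
       regions = regions, n_labeled = sizes)
}
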