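# Simulation of an XY dioecious genome pair: identical X/Y haplotypes outside
# a sex-determining region (SDR), elevated X/Y divergence inside it, and a
# single hemizygous (Y-only) insertion — the male-specific region whose reads
# cannot map to a female assembly.

#' Simulate an XY genome pair with a diverged SDR and Y-only insertion
#'
#' Generates one X and one Y haplotype per chromosome. Outside the SDR the
#' two haplotypes are identical (optionally diverged at a low background
#' rate); inside the SDR the Y carries substitutions at `sdr_divergence` per
#' site plus one Y-only insertion of `msr_length` random bases at a uniform
#' position. Truth coordinates are reported on the male (Y-bearing) assembly,
#' where positions downstream of the insertion are shifted by `msr_length`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp). If
#'   unnamed, chromosomes are named `chr1..chrN`.
#' @param sex_chrom Index or name of the sex chromosome (default 1).
#' @param sdr_interval Numeric length-2: 0-based half-open SDR interval on
#'   the sex chromosome (X coordinates).
#' @param msr_length Length (bp) of the Y-only insertion placed inside the
#'   SDR; 0 disables it.
#' @param sdr_divergence Per-site X/Y substitution probability inside the SDR.
#' @param background_polymorphism Per-site X/Y substitution probability
#'   outside the SDR (default 0, giving byte-identical haplotypes there).
#' @param base_composition A, C, G, T frequencies for the ancestral sequence.
#' @param seed Integer seed; identical parameters and seed give byte-identical
#'   output.
#' @return A list with elements `genome` (list with `X` and `Y`, each a named
#'   character vector of chromosome sequences; `sex_chrom` name) and `truth`
#'   (list with `sdr` and `msr` 0-based half-open intervals on the male
#'   assembly, the insertion point `ins_x` in X coordinates, the Y-divergent
#'   site positions, and the male-assembly chromosome lengths).
#' @examples
#' g <- simulate_xy_genome(c(chrX = 2e4), sdr_interval = c(5e3, 1e4),
#'                         msr_length = 1e3, sdr_divergence = 0.02, seed = 1)
#' g$truth$sdr
#' @export
simulate_xy_genome <- function(chrom_lengths, sex_chrom = 1L,
                               sdr_interval, msr_length = 0L,
                               sdr_divergence = 0, background_polymorphism = 0,
                               base_composition = c(0.25, 0.25, 0.25, 0.25),
                               seed = 1L) {
  chrom_lengths <- as.numeric(chrom_lengths) |>
    setNames(names(chrom_lengths) %||% paste0("chr", seq_along(chrom_lengths)))
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  sc <- if (is.character(sex_chrom)) match(sex_chrom, names(chrom_lengths))
        else as.integer(sex_chrom)
  if (is.na(sc) || sc < 1 || sc > length(chrom_lengths))
    stop("sex_chrom not found")
  Ls <- chrom_lengths[[sc]]
  stopifnot(length(sdr_interval) == 2, msr_length >= 0,
            sdr_divergence >= 0, sdr_divergence <= 1,
            background_polymorphism >= 0, background_polymorphism <= 1)
  if (sdr_interval[1] < 0 || sdr_interval[2] > Ls ||
      sdr_interval[2] <= sdr_interval[1])
    stop("sdr_interval outside the sex chromosome")

  with_stream_seed(seed, "xy_genome", {
    X <- vapply(chrom_lengths, random_dna, "",
                base_composition = base_composition)
    names(X) <- names(chrom_lengths)
    Y <- X
    s0 <- sdr_interval[1]; s1 <- sdr_interval[2]
    div_pos <- integer()
    # background X/Y divergence outside the SDR (all chromosomes)
    if (background_polymorphism > 0) {
      for (i in seq_along(Y)) {
        if (i == sc) {
          m1 <- mutate_region(Y[[i]], 0, s0, background_polymorphism)
          m2 <- mutate_region(m1$seq, s1, nchar(m1$seq),
                              background_polymorphism)
          Y[[i]] <- m2$seq
        } else {
          Y[[i]] <- mutate_region(Y[[i]], 0, nchar(Y[[i]]),
                                  background_polymorphism)$seq
        }
      }
    }
    if (sdr_divergence > 0) {
      m <- mutate_region(Y[[sc]], s0, s1, sdr_divergence)
      Y[[sc]] <- m$seq
      div_pos <- m$positions
    }
    ins_x <- NA_integer_
    if (msr_length > 0) {
      ins_x <- s0 + floor(runif(1) * (s1 - s0 + 1))
      ins_seq <- random_dna(msr_length, base_composition)
      Y[[sc]] <- paste0(substr(Y[[sc]], 1, ins_x), ins_seq,
                        substr(Y[[sc]], ins_x + 1, nchar(Y[[sc]])))
    }
    male_lengths <- chrom_lengths
    male_lengths[[sc]] <- Ls + msr_length
    truth <- list(
      sex_chrom = names(chrom_lengths)[sc],
      sdr = c(s0, s1 + msr_length),                 # male-assembly coords
      sdr_x = c(s0, s1),
      msr = if (msr_length > 0) c(ins_x, ins_x + msr_length) else NULL,
      ins_x = ins_x,
      div_pos_x = div_pos,
      male_chrom_lengths = male_lengths
    )
    list(genome = list(X = X, Y = Y, sex_chrom = names(chrom_lengths)[sc]),
         truth = truth)
  })
}

#' Simulate sexed resequencing cohorts from an XY genome pair
#'
#' Male samples draw reads from one X plus one Y haplotype; female samples
#' from two (identical) X haplotypes. The per-haplotype read number per
#' chromosome is Poisson with mean `coverage/2 * L / read_length`. Read names
#' deterministically encode sample, haplotype, chromosome, 0-based origin and
#' strand (`sample|hap|chrom|pos|strand|i`) — the truth channel used by
#' placement tests. Sequencing errors are uniform substitutions.
#'
#' @param genome A genome pair from [simulate_xy_genome()] (the `$genome`
#'   element, or the full return value).
#' @param n_males,n_females Number of samples per sex.
#' @param coverage Mean per-sample depth (x).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error probability.
#' @param paired If `TRUE`, emit read pairs from fragments of `insert_size`
#'   with `/1` and `/2` name suffixes.
#' @param insert_size Fragment length for paired mode.
#' @param name_reads Emit read names (default `TRUE`). Disabling halves the
#'   string allocation for large runs where the placement truth channel is
#'   not needed; the drawn reads are identical either way.
#' @param seed Integer seed.
#' @return A list of samples; each is a list with `sample_id`, `sex`
#'   (`"male"`/`"female"`) and `reads` (named character vector). The
#'   `manifest` attribute holds a `data.table(sample_id, sex)`.
#' @export
simulate_reads <- function(genome, n_males = 3L, n_females = 3L,
                           coverage = 10, read_length = 100L,
                           error_rate = 0.002, paired = FALSE,
                           insert_size = 300L, name_reads = TRUE,
                           seed = 1L) {
  if (!is.null(genome$genome)) genome <- genome$genome
  stopifnot(coverage >= 0, error_rate >= 0, error_rate < 1, read_length > 0)
  min_len <- min(nchar(genome$X), nchar(genome$Y))
  span <- if (paired) insert_size else read_length
  if (span > min_len)
    stop("read/fragment length exceeds the shortest chromosome")
  samples <- list()
  ids <- c(if (n_males) paste0("M", seq_len(n_males)),
           if (n_females) paste0("F", seq_len(n_females)))
  sexes <- c(rep("male", n_males), rep("female", n_females))
  with_stream_seed(seed, "reads", {
    for (si in seq_along(ids)) {
      id <- ids[si]; sex <- sexes[si]
      haps <- if (sex == "male") list(X1 = genome$X, Y = genome$Y)
              else list(X1 = genome$X, X2 = genome$X)
      all_names <- list(); all_seqs <- list(); part <- 1L
      for (hn in names(haps)) {
        for (cn in names(haps[[hn]])) {
          L <- nchar(haps[[hn]][[cn]])
          n <- rpois(1L, coverage / 2 * L / read_length)
          if (n == 0L) next
          pre <- paste(id, hn, cn, sep = "|")
          if (!paired) {
            r <- cpp_sim_reads(haps[[hn]][[cn]], n, read_length, error_rate,
                               pre, name_reads)
            if (name_reads) all_names[[part]] <- r$name
            all_seqs[[part]] <- r$seq
            part <- part + 1L
          } else {
            n2 <- max(1L, as.integer(ceiling(n / 2)))
            fr <- cpp_sim_reads(haps[[hn]][[cn]], n2, insert_size, 0, pre,
                                TRUE)
            r1 <- substr(fr$seq, 1L, read_length)
            r2 <- revcomp(substr(fr$seq, insert_size - read_length + 1L,
                                 insert_size))
            if (error_rate > 0) {
              r1 <- apply_errors(r1, error_rate)
              r2 <- apply_errors(r2, error_rate)
            }
            all_names[[part]] <- c(paste0(fr$name, "/1"),
                                   paste0(fr$name, "/2"))
            all_seqs[[part]] <- c(r1, r2)
            part <- part + 1L
          }
        }
      }
      reads <- unlist(all_seqs) %||% character()
      if (name_reads || paired)
        names(reads) <- unlist(all_names) %||% character()
      samples[[id]] <- list(sample_id = id, sex = sex, reads = reads)
    }
  })
  attr(samples, "manifest") <- data.table(sample_id = ids, sex = sexes)
  samples
}

# substitution errors on a character vector of reads (R fallback for the
# paired path; single-end reads get errors inside cpp_sim_reads)
apply_errors <- function(reads, error_rate) {
  n <- nchar(reads)
  nerr <- rbinom(length(reads), n, error_rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    off <- sample.int(n[i], nerr[i])
    for (o in off) {
      alt <- setdiff(c("A", "C", "G", "T"), ch[o])
      ch[o] <- alt[sample.int(3L, 1L)]
    }
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Write simulated samples to gzipped FASTQ files plus a JSON manifest
#'
#' @param samples Output of [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest `data.table` with file paths.
#' @export
write_sample_fastqs <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- rbindlist(lapply(samples, function(s) {
    f <- file.path(dir, paste0(s$sample_id, ".fastq.gz"))
    write_fastq(s$reads, f)
    data.table(sample_id = s$sample_id, sex = s$sex, fastq = f)
  }))
  write_manifest(manifest, file.path(dir, "manifest.json"))
  fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}
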