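# Sex-specific k-mer discovery: prefix-subsampled k-mer cataloguing per
# sample, male-/female-specific k-mer (MSK/FSK) classification, and read
# labelling by sex-specific k-mer content.

#' Parameters for k-mer cataloguing and classification
#'
#' Defaults mirror the field's sex-linked-region k-mer workflow: 40-bp
#' k-mers subsampled to those starting with `AG` (a 1/16 literal-prefix
#' subsample), with a strict pooled-count validity threshold of more than
#' ten across all samples of both sexes.
#'
#' @param k K-mer length.
#' @param prefix Literal subsampling prefix (`""` disables subsampling).
#' @param min_total_count Validity threshold: a k-mer is considered only if
#'   its summed count across all samples is strictly greater than this.
#' @param require_presence_all_focal If `TRUE` (default), an MSK must in
#'   addition be present (count >= 1) in every male sample, and an FSK in
#'   every female sample.
#' @param min_read_hits Number of set k-mers needed to label a read.
#' @return A list of class `kmer_params`.
#' @export
kmer_params <- function(k = 40L, prefix = "AG", min_total_count = 10L,
                        require_presence_all_focal = TRUE,
                        min_read_hits = 1L) {
  k <- as.integer(k)
  stopifnot(k > nchar(prefix), nchar(prefix) >= 0, min_total_count >= 0,
            min_read_hits >= 1, k <= 64)
  if (nchar(prefix) && grepl("[^ACGT]", prefix))
    stop("prefix must contain only ACGT")
  structure(list(k = k, prefix = prefix,
                 min_total_count = as.integer(min_total_count),
                 require_presence_all_focal = isTRUE(require_presence_all_focal),
                 min_read_hits = as.integer(min_read_hits)),
            class = "kmer_params")
}

#' Catalogue prefix-subsampled k-mers of a read set
#'
#' Every k-length substring of each read **and of its reverse complement**
#' that starts with `params$prefix` and contains no `N` is counted with
#' multiplicity. K-mers are not canonicalized: the prefix filter operates on
#' literal strings and strand symmetry is restored by scanning both
#' orientations.
#'
#' @param reads Character vector of reads, or path(s) to FASTQ/FASTQ.gz files.
#' @param params A [kmer_params()] object.
#' @return A `data.table` with columns `kmer`, `count`, sorted by `kmer`.
#' @examples
#' extract_prefix_kmers("AGACGTAG", kmer_params(k = 4, prefix = "AG",
#'                                              min_total_count = 0))
#' @export
extract_prefix_kmers <- function(reads, params = kmer_params()) {
  stopifnot(inherits(params, "kmer_params"))
  reads <- as_reads(reads)
  res <- cpp_count_kmers(as.character(reads), params$k, params$prefix)
  dt <- data.table(kmer = res$kmer, count = res$count)
  setkey(dt, kmer)
  dt[]
}

#' Catalogue one sample's k-mers with its sex label
#'
#' @inheritParams extract_prefix_kmers
#' @param sample_id Unique sample identifier.
#' @param sex `"male"` or `"female"`.
#' @return A list of class `sample_kmer_counts`.
#' @export
sample_kmer_counts <- function(reads, sample_id, sex,
                               params = kmer_params()) {
  sex <- match.arg(sex, c("male", "female"))
  structure(list(sample_id = sample_id, sex = sex,
                 counts = extract_prefix_kmers(reads, params),
                 k = params$k, prefix = params$prefix),
            class = "sample_kmer_counts")
}

#' Merge per-sample k-mer tables into a grouped count matrix
#'
#' Performs a full outer join over k-mer keys; counts absent from a sample
#' are zero. Sample order is preserved.
#'
#' @param samples List of [sample_kmer_counts()] objects (>= 1 per sex for
#'   downstream classification).
#' @return A list of class `grouped_counts` with `kmer` (character vector),
#'   `counts` (k-mers x samples integer matrix), `sample_ids`, `sex`.
#' @export
merge_samples <- function(samples) {
  stopifnot(length(samples) >= 1)
  ids <- vapply(samples, function(s) s$sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample id: ",
                               ids[duplicated(ids)][1L])
  sexes <- vapply(samples, function(s) s$sex, "")
  ks <- vapply(samples, function(s) s$k, 1L)
  if (length(unique(ks)) != 1L) stop("samples counted with different k")
  tabs <- lapply(seq_along(samples), function(i) {
    dt <- data.table::copy(samples[[i]]$counts)
    setnames(dt, "count", ids[i])
    dt
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "kmer", all = TRUE), tabs)
  m <- as.matrix(merged[, -1L])
  m[is.na(m)] <- 0L
  storage.mode(m) <- "integer"
  colnames(m) <- ids
  structure(list(kmer = merged$kmer, counts = m, sample_ids = ids,
                 sex = sexes, k = ks[1L], prefix = samples[[1L]]$prefix),
            class = "grouped_counts")
}

#' Merge samples via the fused multi-sample counting kernel
#'
#' Equivalent to [sample_kmer_counts()] on each sample followed by
#' [merge_samples()], but counts all samples in one pass without
#' materializing per-sample tables; used by [sdr_pipeline()] at scale.
#' The equivalence is asserted by the test suite.
#'
#' @param read_sets List of character vectors (reads per sample).
#' @param sample_ids,sexes Parallel vectors of ids and `male`/`female`
#'   labels.
#' @param params A [kmer_params()] object.
#' @param decode Materialize k-mer strings (default `TRUE`). With `FALSE`
#'   the k-mer keys stay 2-bit packed (`hi`/`lo` numeric columns) and are
#'   only decoded for the classified MSK/FSK rows — the memory-lean path
#'   for genome-scale runs.
#' @return A `grouped_counts` object as from [merge_samples()] (with
#'   `kmer = NULL` plus packed `hi`/`lo` when `decode = FALSE`).
#' @export
grouped_counts_fast <- function(read_sets, sample_ids, sexes,
                                params = kmer_params(), decode = TRUE) {
  stopifnot(length(read_sets) == length(sample_ids),
            length(sample_ids) == length(sexes))
  if (anyDuplicated(sample_ids)) stop("duplicate sample id")
  res <- cpp_grouped_counts(lapply(read_sets, as.character), params$k,
                            params$prefix, decode)
  m <- res$counts
  colnames(m) <- sample_ids
  structure(list(kmer = if (decode) res$kmer else NULL,
                 hi = res$hi, lo = res$lo,
                 counts = m, sample_ids = sample_ids,
                 sex = sexes, k = params$k, prefix = params$prefix),
            class = "grouped_counts")
}

#' Classify male- and female-specific k-mers
#'
#' A k-mer is an MSK iff its summed count over **all** samples (both sexes)
#' is strictly greater than `min_total_count`, its count is zero in every
#' female sample and — when `require_presence_all_focal` — at least one in
#' every male sample. FSK classification is symmetric. The pooled-total
#' reading of the validity threshold is used because a per-sex reading would
#' contradict the zero-count rule.
#'
#' @param grouped A [merge_samples()] result.
#' @param params A [kmer_params()] object.
#' @return A list of class `sex_kmer_sets` with `msk`, `fsk` (character
#'   vectors), `msk_counts`, `fsk_counts` (retained count matrices), and the
#'   `k`/`prefix` used.
#' @export
classify_sex_kmers <- function(grouped, params = kmer_params()) {
  stopifnot(inherits(grouped, "grouped_counts"))
  male <- grouped$sex == "male"
  female <- grouped$sex == "female"
  if (!any(male) || !any(female))
    stop("both sexes must be represented among samples")
  m <- grouped$counts
  total_ok <- rowSums(m) > params$min_total_count
  zero_f <- rowSums(m[, female, drop = FALSE] > 0L) == 0L
  zero_m <- rowSums(m[, male, drop = FALSE] > 0L) == 0L
  if (params$require_presence_all_focal) {
    all_m <- rowSums(m[, male, drop = FALSE] > 0L) == sum(male)
    all_f <- rowSums(m[, female, drop = FALSE] > 0L) == sum(female)
  } else {
    all_m <- rowSums(m[, male, drop = FALSE]) > 0L
    all_f <- rowSums(m[, female, drop = FALSE]) > 0L
  }
  is_msk <- total_ok & zero_f & all_m
  is_fsk <- total_ok & zero_m & all_f
  pick <- if (!is.null(grouped$kmer)) {
    function(sel) grouped$kmer[sel]
  } else {
    function(sel) cpp_decode_packed(grouped$hi[sel], grouped$lo[sel],
                                    grouped$k)
  }
  structure(list(msk = pick(is_msk), fsk = pick(is_fsk),
                 msk_counts = m[is_msk, , drop = FALSE],
                 fsk_counts = m[is_fsk, , drop = FALSE],
                 k = grouped$k, prefix = grouped$prefix),
            class = "sex_kmer_sets")
}

#' Partition reads by sex-specific k-mer content
#'
#' Both orientations of each read are scanned against the MSK and FSK
#' catalogs. A read is male-specific iff it has at least
#' `params$min_read_hits` MSK hits and zero FSK hits; female-specific
#' symmetric; reads hitting both catalogs are ambiguous; all others are
#' unlabeled. The four partitions are disjoint and their union is the input.
#'
#' @param reads Character vector of reads (named or not) or FASTQ path(s).
#' @param sets A [classify_sex_kmers()] result.
#' @param params A [kmer_params()] object; its `k` and `prefix` must match
#'   the ones the sets were built with.
#' @return A list of class `labeled_reads` with character vectors
#'   `male_specific`, `female_specific`, `ambiguous`, `unlabeled`.
#' @export
label_reads <- function(reads, sets, params = kmer_params()) {
  stopifnot(inherits(sets, "sex_kmer_sets"))
  if (sets$k != params$k || !identical(sets$prefix, params$prefix))
    stop("k/prefix mismatch between sets and params")
  reads <- as_reads(reads)
  code <- cpp_label_reads(as.character(reads), sets$msk, sets$fsk,
                          params$k, params$prefix, params$min_read_hits)
  structure(list(male_specific = reads[code == 1L],
                 female_specific = reads[code == 2L],
                 ambiguous = reads[code == 3L],
                 unlabeled = reads[code == 0L]),
            class = "labeled_reads")
}

#' Write MSK/FSK sets as FASTA (one k-mer per record)
#'
#' @param sets A [classify_sex_kmers()] result.
#' @param msk_path,fsk_path Output FASTA paths.
#' @return Invisibly, a character vector of the written paths.
#' @export
write_sex_kmer_fasta <- function(sets, msk_path, fsk_path) {
  write_fasta(setNames(sets$msk,
                       sprintf("MSK_%06d", seq_along(sets$msk))), msk_path)
  write_fasta(setNames(sets$fsk,
                       sprintf("FSK_%06d", seq_along(sets$fsk))), fsk_path)
  invisible(c(msk_path, fsk_path))
}
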