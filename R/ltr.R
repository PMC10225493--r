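# LTR retrotransposon insertion dating: global alignment of the 5' and 3'
# LTRs of an element, Kimura two-parameter distance, and T = K/(2r).

#' Globally align a 5'/3' LTR pair
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap -2 and
#' deterministic tie-breaking (prefer diagonal, then up, then left).
#' Pre-aligned input (equal-length sequences containing `-`, or
#' `prealigned = TRUE`) is accepted verbatim.
#'
#' @param seq5,seq3 Sequences over ACGTN (gaps `-` allowed when pre-aligned).
#' @param prealigned Treat the input as already aligned.
#' @return A list of class `aligned_pair` with `aln5`, `aln3` (equal-length
#'   gapped strings), `score` (NA for pre-aligned input) and
#'   `n_comparable` (ungapped, N-free columns).
#' @export
align_ltrs <- function(seq5, seq3, prealigned = FALSE) {
  stopifnot(is.character(seq5), is.character(seq3),
            length(seq5) == 1L, length(seq3) == 1L)
  if (!nzchar(seq5) || !nzchar(seq3)) stop("empty sequence")
  up5 <- toupper(seq5); up3 <- toupper(seq3)
  if (grepl("[^ACGTN-]", up5) || grepl("[^ACGTN-]", up3))
    stop("sequences must contain only ACGTN (and '-' when pre-aligned)")
  if (!grepl("[ACGT]", up5) || !grepl("[ACGT]", up3))
    stop("no informative columns: sequence contains no ACGT bases")
  if (prealigned || grepl("-", up5, fixed = TRUE) ||
      grepl("-", up3, fixed = TRUE)) {
    if (nchar(up5) != nchar(up3))
      stop("pre-aligned sequences must have equal length")
    aln <- list(aln1 = up5, aln2 = up3, score = NA_real_)
  } else {
    aln <- cpp_nw_align(up5, up3, 1, -1, -2)
  }
  a <- strsplit(aln$aln1, "", fixed = TRUE)[[1L]]
  b <- strsplit(aln$aln2, "", fixed = TRUE)[[1L]]
  comparable <- sum(a %in% c("A", "C", "G", "T") &
                      b %in% c("A", "C", "G", "T"))
  if (comparable < 1) stop("no comparable (ungapped, N-free) columns")
  structure(list(aln5 = aln$aln1, aln3 = aln$aln2, score = aln$score,
                 n_comparable = comparable),
            class = "aligned_pair")
}

#' Kimura two-parameter distance of an aligned pair
#'
#' Columns containing a gap or N in either sequence are excluded pairwise
#' (complete-column deletion). P is the transition proportion, Q the
#' transversion proportion over the comparable columns, and
#' `K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`.
#'
#' @param pair An [align_ltrs()] result (or any list with `aln5`, `aln3`).
#' @return A list of class `k2p_result` with `P`, `Q`, `K`,
#'   `n_comparable`.
#' @export
k2p_distance <- function(pair) {
  a <- strsplit(toupper(pair$aln5), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(pair$aln3), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n < 1) stop("no comparable columns")
  a <- a[ok]; b <- b[ok]
  purine <- c("A", "G")
  transition <- a != b & ((a %in% purine) == (b %in% purine))
  transversion <- a != b & ((a %in% purine) != (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(transversion) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P saturation: distance undefined for P=", signif(P, 4),
         ", Q=", signif(Q, 4))
  K <- -0.5 * log(w1) - 0.25 * log(w2)
  structure(list(P = P, Q = Q, K = K, n_comparable = n),
            class = "k2p_result")
}

#' Insertion age from K2P divergence
#'
#' `T = K / (2 r)`: the two LTRs are identical on insertion and each
#' accumulates substitutions at rate `r` per site per year, so their
#' divergence K corresponds to `2 r T`.
#'
#' @param k A [k2p_distance()] result or a bare numeric K value.
#' @param rate Substitution rate per site per year (default 1.8e-8).
#' @return Age in years.
#' @export
insertion_age <- function(k, rate = 1.8e-8) {
  if (rate <= 0) stop("rate must be > 0")
  K <- if (inherits(k, "k2p_result")) k$K else as.numeric(k)
  if (!is.finite(K)) stop("K must be finite")
  K / (2 * rate)
}

#' Batch-date LTR pairs
#'
#' Accepts a named list of `list(seq5, seq3)` pairs, or a FASTA path whose
#' records are named `<element>_5p` / `<element>_3p` (pre-aligned FASTA
#' accepted via `prealigned`).
#'
#' @param pairs Named list or FASTA path.
#' @param rate Substitution rate per site per year.
#' @param prealigned Passed to [align_ltrs()].
#' @return A `data.table` with `element`, `P`, `Q`, `K`, `T_years`.
#' @export
ltr_age_table <- function(pairs, rate = 1.8e-8, prealigned = FALSE) {
  if (is.character(pairs) && length(pairs) == 1L && file.exists(pairs)) {
    seqs <- read_fasta(pairs)
    el5 <- grep("_5p$", names(seqs), value = TRUE)
    elements <- sub("_5p$", "", el5)
    pairs <- setNames(lapply(elements, function(e) {
      if (!paste0(e, "_3p") %in% names(seqs))
        stop("missing 3' record for element ", e)
      list(seq5 = seqs[[paste0(e, "_5p")]],
           seq3 = seqs[[paste0(e, "_3p")]])
    }), elements)
  }
  stopifnot(length(pairs) >= 1, !is.null(names(pairs)))
  rbindlist(lapply(names(pairs), function(e) {
    aln <- align_ltrs(pairs[[e]]$seq5, pairs[[e]]$seq3,
                      prealigned = prealigned)
    k <- k2p_distance(aln)
    data.table(element = e, P = k$P, Q = k$Q, K = k$K,
               T_years = insertion_age(k, rate))
  }))
}

#' Histogram of insertion ages
#'
#' @param ages Numeric vector of ages in years (or an [ltr_age_table()]
#'   output).
#' @param bin_mya Bin width in million years (default 0.1).
#' @return A `data.table` with `bin_start_mya`, `bin_end_mya`, `count`.
#' @export
ltr_age_histogram <- function(ages, bin_mya = 0.1) {
  if (is.data.frame(ages)) ages <- ages$T_years
  mya <- ages / 1e6
  b <- floor(mya / bin_mya)
  tab <- table(b)
  data.table(bin_start_mya = as.numeric(names(tab)) * bin_mya,
             bin_end_mya = (as.numeric(names(tab)) + 1) * bin_mya,
             count = as.integer(tab))
}
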