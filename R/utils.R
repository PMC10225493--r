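# Small shared helpers: per-stream seed derivation, window grids, sequence
# utilities, input validation.

#' Derive an independent RNG seed for a named generator stream
#'
#' Each simulator derives its own stream seed from the user seed and a stream
#' label, so adding one generator never shifts another generator's output.
#' The result is a deterministic 31-bit non-negative integer.
#'
#' @param seed Integer user seed.
#' @param stream Character stream label.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (c in utf8ToInt(stream)) h <- (h * 131 + c) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 1000003 + h) %% 2147483647)
}

# Evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards.
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

#' Tile chromosomes with fixed-width windows
#'
#' Windows are 0-based half-open and non-overlapping; the final window of a
#' chromosome is truncated at the chromosome end and flagged as partial.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param w Window width in bp.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `partial`.
#' @export
tile_windows <- function(chrom_lengths, w) {
  stopifnot(w > 0, length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    s <- seq(0, max(L - 1, 0), by = w)
    data.table(chrom = cn, start = s, end = pmin(s + w, L),
               partial = (s + w) > L)
  })
  rbindlist(out)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over `ACGTN` (case-insensitive).
#' @return Character vector of reverse complements (uppercase).
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

#' Generate a random DNA sequence
#'
#' @param n Length in bases.
#' @param base_composition Numeric vector of A, C, G, T frequencies.
#' @return A single string of length `n`.
#' @export
random_dna <- function(n, base_composition = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(length(base_composition) == 4, all(base_composition >= 0),
            sum(base_composition) > 0)
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = base_composition), collapse = "")
}

# mutate a string region [start0, end0) (0-based half-open) with per-site
# substitution probability `rate`; returns list(seq, positions) where
# positions are 0-based substituted sites.
mutate_region <- function(seq, start0, end0, rate) {
  if (rate <= 0 || end0 <= start0) return(list(seq = seq, positions = integer()))
  region <- substr(seq, start0 + 1, end0)
  ch <- strsplit(region, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) {
      alt <- setdiff(c("A", "C", "G", "T"), ch[i])
      ch[i] <- alt[sample.int(3L, 1L)]
    }
    region <- paste(ch, collapse = "")
    seq <- paste0(substr(seq, 1, start0), region,
                  substr(seq, end0 + 1, nchar(seq)))
  }
  list(seq = seq, positions = start0 + hit - 1L)
}

# interval Jaccard for 0-based half-open intervals on the same chromosome
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (uni <= 0) return(0)
  inter / uni
}

`%||%` <- function(a, b) if (is.null(a)) b else a
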