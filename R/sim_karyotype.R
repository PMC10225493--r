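# Simulation of a derived karyotype from an ancestral one by chromosome
# fusions and fissions, with a block table recording the ancestral origin of
# every segment. Events are guaranteed non-cancelling: all fusions are applied
# before all fissions, fused junctions always join blocks of different
# ancestral ids (each ancestral id is unique before fissions), and a fission
# splits strictly inside a single block — never at a junction created by a
# prior fusion. Under these rules the parsimony counts of count_events()
# recover the applied event numbers exactly.

#' Simulate a derived karyotype with known fusion/fission events
#'
#' @param n_ancestral Number of ancestral chromosomes.
#' @param n_fusions Number of fusion events (at most `n_ancestral - 1`).
#' @param n_fissions Number of fission events.
#' @param ancestral_lengths Optional lengths (bp) of the ancestral
#'   chromosomes; default uniform in 10-30 Mb.
#' @param junction_gap Unassigned bp inserted at each fusion junction; this
#'   is the evolutionary-fusion-region (EFR) truth recovered by
#'   [detect_efrs()]. Default 100 kb.
#' @param seed Integer seed.
#' @return A list with `blocks` (a `data.table` with `target_chrom`, `start`,
#'   `end` 0-based half-open, `ancestral_chrom`, `orientation`),
#'   `chrom_lengths` (named vector of derived chromosome lengths) and
#'   `truth` (list: `n_fusions`, `n_fissions`, `efrs` data.table of fusion
#'   junction gaps).
#' @export
simulate_karyotype <- function(n_ancestral = 21L, n_fusions = 0L,
                               n_fissions = 0L, ancestral_lengths = NULL,
                               junction_gap = 1e5, seed = 1L) {
  n_ancestral <- as.integer(n_ancestral)
  n_fusions <- as.integer(n_fusions)
  n_fissions <- as.integer(n_fissions)
  stopifnot(n_ancestral >= 1, n_fusions >= 0, n_fissions >= 0,
            junction_gap >= 0)
  if (n_fusions > n_ancestral - 1L)
    stop("infeasible: cannot fuse ", n_ancestral, " chromosomes ",
         n_fusions, " times")
  with_stream_seed(seed, "karyotype", {
    if (is.null(ancestral_lengths))
      ancestral_lengths <- round(runif(n_ancestral, 10e6, 30e6))
    stopifnot(length(ancestral_lengths) == n_ancestral)
    # a chromosome = list of blocks (anc id, length, orientation)
    chroms <- lapply(seq_len(n_ancestral), function(i)
      data.table(ancestral_chrom = paste0("A", i),
                 len = ancestral_lengths[i], orientation = "+"))
    # fusions: pick two chromosomes, optionally flip each, concatenate
    for (e in seq_len(n_fusions)) {
      pick <- sample.int(length(chroms), 2L)
      a <- chroms[[pick[1L]]]; b <- chroms[[pick[2L]]]
      flip <- function(x) {
        x <- x[rev(seq_len(nrow(x)))]
        x$orientation <- ifelse(x$orientation == "+", "-", "+")
        x
      }
      if (runif(1) < 0.5) a <- flip(a)
      if (runif(1) < 0.5) b <- flip(b)
      fused <- rbind(a, b)
      chroms[[pick[1L]]] <- fused
      chroms[[pick[2L]]] <- NULL
    }
    # fissions: split strictly inside one block
    for (e in seq_len(n_fissions)) {
      ci <- sample.int(length(chroms), 1L)
      x <- chroms[[ci]]
      bi <- sample.int(nrow(x), 1L)
      L <- x$len[bi]
      cut <- round(L * runif(1, 0.25, 0.75))
      left <- x[seq_len(bi)]
      right <- x[bi:nrow(x)]
      left$len[bi] <- cut
      right$len[1L] <- L - cut
      chroms[[ci]] <- left
      chroms[[length(chroms) + 1L]] <- right
    }
    # lay out derived coordinates with junction_gap between adjacent blocks
    # that came from different ancestral units (i.e. at every inter-block
    # junction: within a chromosome every junction is a fusion junction,
    # because fissions split blocks, not junctions)
    blocks <- list(); efrs <- list(); lens <- numeric()
    for (ci in seq_along(chroms)) {
      cn <- paste0("chr", ci)
      x <- chroms[[ci]]
      pos <- 0
      for (bi in seq_len(nrow(x))) {
        if (bi > 1L) {
          if (junction_gap > 0)
            efrs[[length(efrs) + 1L]] <- data.table(
              chrom = cn, start = pos, end = pos + junction_gap)
          pos <- pos + junction_gap
        }
        blocks[[length(blocks) + 1L]] <- data.table(
          target_chrom = cn, start = pos, end = pos + x$len[bi],
          ancestral_chrom = x$ancestral_chrom[bi],
          orientation = x$orientation[bi])
        pos <- pos + x$len[bi]
      }
      lens[cn] <- pos
    }
    blocks <- rbindlist(blocks)
    setorder(blocks, target_chrom, start)
    efrs <- if (length(efrs)) rbindlist(efrs) else
      data.table(chrom = character(), start = numeric(), end = numeric())
    list(blocks = blocks, chrom_lengths = lens,
         truth = list(n_fusions = n_fusions, n_fissions = n_fissions,
                      efrs = efrs))
  })
}
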