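# Independent oracles used across the suite. These are deliberately written
# as plain, slow, loop-based R so they share no code path with the package
# implementations they check.

# -- k-mer enumeration oracle -------------------------------------------------

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            a = "T", c = "G", g = "C", t = "A", n = "N")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(comp[ch], collapse = "")
  }, "", USE.NAMES = FALSE)
}

# count all k-substrings of reads and their reverse complements that start
# with `prefix` and contain no N
oracle_kmers <- function(reads, k, prefix) {
  counts <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(km) {
    old <- counts[[km]]
    counts[[km]] <- if (is.null(old)) 1L else old + 1L
  }
  for (read in reads) {
    for (s in c(toupper(read), oracle_revcomp(toupper(read)))) {
      n <- nchar(s)
      if (n < k) next
      for (i in seq_len(n - k + 1)) {
        km <- substr(s, i, i + k - 1)
        if (nchar(prefix) && substr(km, 1, nchar(prefix)) != prefix) next
        if (grepl("[^ACGT]", km)) next
        bump(km)
      }
    }
  }
  kms <- sort(ls(counts))
  data.frame(kmer = kms,
             count = vapply(kms, function(k2) counts[[k2]], 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

# -- MSK/FSK predicate oracle -------------------------------------------------

# counts: k-mers x samples matrix; sex: per-column "male"/"female"
oracle_classify <- function(counts, sex, min_total = 10L,
                            require_all = TRUE) {
  res <- character(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    total <- sum(row)
    m <- row[sex == "male"]; f <- row[sex == "female"]
    is_msk <- total > min_total && all(f == 0) &&
      (!require_all || all(m >= 1))
    is_fsk <- total > min_total && all(m == 0) &&
      (!require_all || all(f >= 1))
    res[i] <- if (is_msk) "msk" else if (is_fsk) "fsk" else "none"
  }
  res
}

# -- Weir & Cockerham (1984) per-site oracle ---------------------------------

# g1, g2: dosage vectors (0/1/2, NA allowed) of the two populations at one
# site. Returns c(a, b, c) or NULL when undefined.
oracle_wc_site <- function(g1, g2) {
  r <- 2
  pops <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  n <- vapply(pops, length, 1)
  if (any(n < 1)) return(NULL)
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), 1)
  h <- vapply(pops, function(g) mean(g == 1), 1)
  nbar <- mean(n)
  if (nbar <= 1) return(NULL)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  if (nc <= 0) return(NULL)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = unname(a), b = unname(b), c = unname(cc))
}

# -- pi via explicit allele-pair comparison ----------------------------------

# mean pairwise difference over all pairs of called alleles, per site,
# summed and divided by window length
oracle_pi <- function(geno_pop, win_len) {
  tot <- 0
  for (i in seq_len(nrow(geno_pop))) {
    g <- geno_pop[i, ]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0; pairs <- 0
    for (x in seq_len(n - 1)) for (y in (x + 1):n) {
      pairs <- pairs + 1
      if (alleles[x] != alleles[y]) diffs <- diffs + 1
    }
    tot <- tot + diffs / pairs
  }
  tot / win_len
}

# -- Tajima's D oracle --------------------------------------------------------

oracle_tajima_d <- function(geno_pop) {
  n <- 2 * ncol(geno_pop)
  j <- rowSums(geno_pop)
  seg <- j > 0 & j < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  theta_pi <- sum(2 * j[seg] * (n - j[seg]) / (n * (n - 1)))
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  num <- theta_pi - S / a1
  if (denom == 0) return(if (abs(num) < 1e-12) 0 else NA_real_)
  num / denom
}

# -- brute-force global alignment oracle (tiny inputs) ------------------------

# enumerate all global alignments recursively; return the maximum score
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- if (i == 0 && j == 0) 0
    else {
      best <- -Inf
      if (i > 0 && j > 0) {
        sc <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
        best <- max(best, rec(i - 1, j - 1) + sc)
      }
      if (i > 0) best <- max(best, rec(i - 1, j) + gap)
      if (j > 0) best <- max(best, rec(i, j - 1) + gap)
      best
    }
    memo[[key]] <- res
    res
  }
  rec(nchar(a), nchar(b))
}

# -- per-base interval coverage oracle ---------------------------------------

# fraction of [0, L) covered by intervals (0-based half-open), per-base
oracle_coverage <- function(starts, ends, L) {
  covered <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i])
      covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(covered) / L
}

# intersect fraction: bases covered by intervals A inside the union of B,
# divided by bases of union of B
oracle_frac_within <- function(sa, ea, sb, eb, L) {
  ca <- logical(L); cb <- logical(L)
  for (i in seq_along(sa)) if (ea[i] > sa[i]) ca[(sa[i] + 1):ea[i]] <- TRUE
  for (i in seq_along(sb)) if (eb[i] > sb[i]) cb[(sb[i] + 1):eb[i]] <- TRUE
  if (!any(cb)) return(NA_real_)
  sum(ca & cb) / sum(cb)
}

# -- misc ---------------------------------------------------------------------

random_reads <- function(n, len_range = c(30, 120), n_prob = 0.02) {
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(rep((1 - n_prob) / 4, 4), n_prob)),
          collapse = "")
  }, "")
}

jaccard_interval <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (uni <= 0) 0 else inter / uni
}
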