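# Simulation of a 5'/3' LTR pair: both copies are identical at insertion and
# then evolve independently under a Kimura two-parameter substitution process,
# so their divergence K dates the insertion via T = K/(2r).

# K80 transition probabilities after branch length d (expected subs/site)
# with transition/transversion ratio kappa. Returns P(identical),
# P(transition), P(each single transversion).
k80_probs <- function(d, kappa) {
  a <- d * kappa / (kappa + 2)     # transition rate x time
  b <- d / (kappa + 2)             # each transversion rate x time
  e1 <- exp(-4 * b)
  e2 <- exp(-2 * (a + b))
  c(same = 1 / 4 + 1 / 4 * e1 + 1 / 2 * e2,
    ts = 1 / 4 + 1 / 4 * e1 - 1 / 2 * e2,
    tv = 1 / 4 - 1 / 4 * e1)
}

# evolve a character vector of bases along one branch of length d
k80_evolve <- function(ch, d, kappa) {
  if (d <= 0) return(ch)
  pr <- k80_probs(d, kappa)
  u <- runif(length(ch))
  ts_map <- c(A = "G", C = "T", G = "A", T = "C")
  tv1_map <- c(A = "C", C = "A", G = "C", T = "A")
  tv2_map <- c(A = "T", C = "G", G = "T", T = "G")
  out <- ch
  i <- u < pr["ts"]
  out[i] <- ts_map[ch[i]]
  i <- u >= pr["ts"] & u < pr["ts"] + pr["tv"]
  out[i] <- tv1_map[ch[i]]
  i <- u >= pr["ts"] + pr["tv"] & u < pr["ts"] + 2 * pr["tv"]
  out[i] <- tv2_map[ch[i]]
  out
}

#' Simulate a diverged 5'/3' LTR pair of known age
#'
#' An ancestral LTR of `length` random bases is copied and each copy evolves
#' independently for `age` years at substitution rate `rate` per site per
#' year under a K80 model with transition/transversion ratio `kappa`. The
#' expected pairwise divergence is `2 * rate * age` substitutions per site.
#' No indels are introduced, so the two sequences are already aligned.
#'
#' @param age True insertion age in years.
#' @param rate Substitution rate per site per year.
#' @param length LTR length in bp.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param base_composition A, C, G, T frequencies of the ancestral LTR.
#' @param seed Integer seed.
#' @return A list with `seq5`, `seq3` (equal-length strings) and `true_age`.
#' @export
simulate_ltr_pair <- function(age = 1e6, rate = 1.8e-8, length = 5000,
                              kappa = 2,
                              base_composition = c(0.25, 0.25, 0.25, 0.25),
                              seed = 1L) {
  stopifnot(age >= 0, rate >= 0, length >= 1, kappa > 0)
  with_stream_seed(seed, "ltr", {
    anc <- strsplit(random_dna(length, base_composition), "", fixed = TRUE)[[1]]
    d <- rate * age
    s5 <- paste(k80_evolve(anc, d, kappa), collapse = "")
    s3 <- paste(k80_evolve(anc, d, kappa), collapse = "")
    list(seq5 = s5, seq3 = s3, true_age = age)
  })
}
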