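# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (regexes, all-pairs loops, direct enumeration) so
# they stay independent of the implementation they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

iupac_regex <- function(pattern) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
               D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(classes[strsplit(pattern, "")[[1]]], collapse = "")
}

# All overlapping forward-orientation regex matches (via lookahead).
regex_starts <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), sequence,
                perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Brute-force k-mer scan oracle with the same once-per-palindromic-site rule
# as the scanner contract: forward matches get '+', reverse-only get '-'.
oracle_scan <- function(sequence, pattern) {
  k <- nchar(pattern)
  fwd <- regex_starts(sequence, pattern)
  rc_pattern <- paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                                          pattern), "")[[1]]), collapse = "")
  rev <- regex_starts(sequence, rc_pattern)
  starts <- sort(union(fwd, rev))
  data.frame(start = starts, end = starts + k,
             strand = if (length(starts)) ifelse(starts %in% fwd, "+", "-")
                      else character(0),
             stringsAsFactors = FALSE)
}

CATALOG_PATTERNS <- c("TGASTCA", "VTGACTCAB", "VTGAATCAB", "VTTAGTCAY",
                      "GGAAT", "GGAATK", "TGASVDB")

# Null fixture counts without sequence simulation: negative-binomial counts
# for n loci with no disruptions anywhere.
null_counts <- function(n_loci, depth = 100, dispersion = 10, n_rep = 2,
                        seed = 1) {
  cfg <- synthetic_config(n_loci = n_loci, depth_mean = depth,
                          dispersion = dispersion, n_replicates = n_rep,
                          seed = seed)
  gt <- data.frame(chrom = character(0), motif_id = character(0),
                   disrupted = logical(0))
  simulate_counts(gt, sprintf("locus_%04d", seq_len(n_loci)), cfg, seed = seed)
}
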