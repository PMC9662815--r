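# AP-1/TEAD co-binding structure: summit-proximity co-binding classes,
# motif-mutation enrichment at allele-specific vs shared peaks (Fisher
# exact), and the partner-loss fractions that expose the binding hierarchy
# (AP-1 loss usually takes TEAD with it; the converse is rare).

#' Classify AP-1/TEAD co-binding by summit proximity
#'
#' Pairs Fos and Tead summits greedily by increasing distance (ties broken
#' towards the smaller Fos coordinate), each summit used at most once; a
#' pair within `max_summit_distance` is one co-bound locus. Unpaired
#' summits become `AP1_only` / `TEAD_only` loci.
#'
#' @param fos_peaks,tead_peaks Data frames with `chrom`, `summit` (and
#'   optionally `id`).
#' @param max_summit_distance Pairing distance in bp (default 100,
#'   inclusive).
#' @return List of class `cobind_table`: `counts` (named vector over
#'   `AP1_only`, `TEAD_only`, `cobound`), `pairs` (data frame of matched
#'   summit indices), `fos_class`, `tead_class` (per-input-row classes).
#' @export
classify_cobinding <- function(fos_peaks, tead_peaks,
                               max_summit_distance = 100L) {
  nf <- nrow(fos_peaks); nt <- nrow(tead_peaks)
  fos_class <- rep("AP1_only", nf)
  tead_class <- rep("TEAD_only", nt)
  pairs <- data.frame(fos = integer(0), tead = integer(0), distance = integer(0))
  if (nf && nt) {
    cand <- do.call(rbind, lapply(seq_len(nf), function(i) {
      j <- which(tead_peaks$chrom == fos_peaks$chrom[i] &
                   abs(tead_peaks$summit - fos_peaks$summit[i]) <=
                     max_summit_distance)
      if (!length(j)) return(NULL)
      data.frame(fos = i, tead = j,
                 distance = abs(tead_peaks$summit[j] - fos_peaks$summit[i]))
    }))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$distance, fos_peaks$summit[cand$fos],
                         tead_peaks$summit[cand$tead]), , drop = FALSE]
      used_f <- logical(nf); used_t <- logical(nt)
      for (r in seq_len(nrow(cand))) {
        i <- cand$fos[r]; j <- cand$tead[r]
        if (!used_f[i] && !used_t[j]) {
          used_f[i] <- used_t[j] <- TRUE
          pairs <- rbind(pairs, cand[r, ])
        }
      }
      fos_class[used_f] <- "cobound"
      tead_class[used_t] <- "cobound"
    }
  }
  counts <- c(AP1_only = sum(fos_class == "AP1_only"),
              TEAD_only = sum(tead_class == "TEAD_only"),
              cobound = nrow(pairs))
  structure(list(counts = counts, pairs = pairs,
                 fos_class = fos_class, tead_class = tead_class),
            class = "cobind_table")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables no more likely than the observed one (the standard two-sided
#' convention).
#'
#' @param tab 2x2 nonnegative integer matrix.
#' @return List `p`, `odds_ratio` (sample odds ratio, `Inf`/`NaN` preserved).
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1L, 1L]
  m1 <- sum(tab[1L, ]); m2 <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  support <- max(0L, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
  list(p = p, odds_ratio = or)
}

#' Motif-mutation enrichment at allele-specific vs shared peaks
#'
#' Builds the 2x2 table of (allele-specific vs shared) x (has a
#' strain-specific k-mer vs not) from disruption calls and tests it with
#' the two-sided Fisher exact test.
#'
#' @param as_calls,shared_calls Disruption-call data frames (from
#'   [disruption_calls()]) for the allele-specific and shared peak sets.
#' @return List of class `enrichment_result`: `table`, `fractions` (per
#'   group, fraction with a strain-specific k-mer), `odds_ratio`, `p`.
#' @export
mutation_enrichment <- function(as_calls, shared_calls) {
  n_as <- nrow(as_calls); n_sh <- nrow(shared_calls)
  if (!n_as || !n_sh) stop("both groups must be nonempty")
  a <- sum(as_calls$category == "strain_specific")
  b <- sum(shared_calls$category == "strain_specific")
  tab <- matrix(c(a, n_as - a, b, n_sh - b), nrow = 2L, byrow = TRUE,
                dimnames = list(c("allele_specific", "shared"),
                                c("strain_specific", "other")))
  ft <- fisher_exact_2x2(tab)
  structure(list(table = tab,
                 fractions = c(allele_specific = a / n_as, shared = b / n_sh),
                 odds_ratio = ft$odds_ratio, p = ft$p),
            class = "enrichment_result")
}

#' Partner-loss fraction
#'
#' The percentage of a reference set of allele-specific peaks that also
#' lose the partner factor, e.g. the fraction of allele-specific Fos-bound
#' sites with a concordant allele-specific loss of Tead1.
#'
#' @param n_joint Number of peaks allele-specific for both factors.
#' @param n_reference Size of the reference allele-specific set.
#' @return Percentage rounded to one decimal.
#' @export
partner_loss_fraction <- function(n_joint, n_reference) {
  if (length(n_reference) != 1L || n_reference <= 0) {
    stop("n_reference must be a positive count")
  }
  if (n_joint < 0 || n_joint > n_reference) {
    stop("n_joint must lie in [0, n_reference]")
  }
  round(100 * n_joint / n_reference, 1L)
}

#' Fraction of peaks per class carrying any listed k-mer near the summit
#'
#' @param peak_classes Named list mapping class label to a data frame with
#'   `sequence` and `summit` (0-based, within the sequence).
#' @param patterns Character vector of IUPAC patterns (any match counts).
#' @param halfwidth Summit window half-width in bp (default 50, inclusive).
#' @return Named numeric vector: per class, the fraction of peaks with at
#'   least one match within the window.
#' @export
kmer_presence_fraction <- function(peak_classes, patterns, halfwidth = 50L) {
  vapply(peak_classes, function(df) {
    if (!nrow(df)) return(NA_real_)
    has <- vapply(seq_len(nrow(df)), function(i) {
      w <- make_window(df$summit[i], halfwidth)
      any(vapply(patterns, function(p) {
        hits <- scan_kmer(df$sequence[i], p)
        nrow(hits) > 0 && any(hits$start < w$end & hits$end > w$start)
      }, logical(1L)))
    }, logical(1L))
    mean(has)
  }, numeric(1L))
}
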