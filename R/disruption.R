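# Per-allele motif comparison: does each allele carry a match to a given
# degenerate k-mer near the summit, how many half sites does the central
# window hold, and does a variant hit the core of a match or only its
# flanks. The flank analysis mirrors the observation that the three
# nucleotides on each side of the core AP-1 element modulate binding.

#' Classify motif disruption for one allele pair
#'
#' Scans both allele sequences for the pattern within `halfwidth` bp of the
#' summit (each allele in its own coordinates) and reports the joint
#' category: `shared_intact` (both alleles match), `strain_specific`
#' (exactly one allele matches), or `absent_both`.
#'
#' @param maternal_seq,paternal_seq Full allele sequences.
#' @param maternal_summit,paternal_summit 0-based summit coordinate on each
#'   allele (they differ when indels shift coordinates).
#' @param pattern IUPAC pattern.
#' @param halfwidth bp around the summit a match may start/end in
#'   (default 75, inclusive).
#' @param peak_id Carried into the result.
#' @return List: `peak_id`, `pattern`, `halfwidth`, `maternal_has`,
#'   `paternal_has`, `category`, `truncated` (window clipped at a sequence
#'   edge).
#' @export
classify_disruption <- function(maternal_seq, paternal_seq,
                                maternal_summit, paternal_summit,
                                pattern, halfwidth = 75L, peak_id = NA) {
  has_near <- function(seq, summit) {
    w <- make_window(summit, halfwidth)
    truncated <- w$start == 0L && summit - halfwidth < 0L ||
      w$end > nchar(seq)
    hits <- scan_kmer(seq, pattern)
    near <- nrow(hits) > 0 && any(hits$start < min(w$end, nchar(seq)) &
                                    hits$end > w$start)
    list(has = near, truncated = truncated)
  }
  m <- has_near(maternal_seq, maternal_summit)
  p <- has_near(paternal_seq, paternal_summit)
  category <- if (m$has && p$has) "shared_intact"
    else if (m$has || p$has) "strain_specific"
    else "absent_both"
  list(peak_id = peak_id, pattern = pattern, halfwidth = halfwidth,
       maternal_has = m$has, paternal_has = p$has, category = category,
       truncated = m$truncated || p$truncated)
}

#' Disruption calls for a table of allele pairs
#'
#' @param pairs Data frame with `peak_id`, `maternal_seq`, `paternal_seq`,
#'   `maternal_summit`, `paternal_summit`.
#' @param pattern IUPAC pattern.
#' @param halfwidth Summit window half-width.
#' @return Data frame of [classify_disruption()] results, one row per pair.
#' @export
disruption_calls <- function(pairs, pattern, halfwidth = 75L) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    as.data.frame(classify_disruption(
      pairs$maternal_seq[i], pairs$paternal_seq[i],
      pairs$maternal_summit[i], pairs$paternal_summit[i],
      pattern, halfwidth, peak_id = pairs$peak_id[i]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count AP-1 half sites in a central window
#'
#' Counts all (overlapping) matches of the half-site pattern (default
#' `TGASVDB`) on both strands of the window, and how many of those matches
#' intersect at least one variant.
#'
#' @param sequence_window Central window sequence (typically 150 bp).
#' @param variants Variant table in window coordinates (0-based relative to
#'   the window start); may be empty.
#' @param pattern Half-site IUPAC pattern.
#' @return List `n_half_sites`, `n_variant_overlapping`.
#' @export
count_half_sites <- function(sequence_window, variants = NULL,
                             pattern = MOTIF_CATALOG[["ap1_half_site"]]) {
  hits <- scan_kmer(sequence_window, pattern)
  n <- nrow(hits)
  n_var <- 0L
  if (n && !is.null(variants) && nrow(variants)) {
    n_var <- sum(vapply(seq_len(n), function(i) {
      any(variants$start < hits$end[i] & variants$end > hits$start[i])
    }, logical(1L)))
  }
  list(n_half_sites = n, n_variant_overlapping = n_var)
}

#' Where does a variant hit relative to a motif match?
#'
#' `core_hit` if any variant intersects the match span; otherwise
#' `flank_hit` if any variant intersects the `flank`-bp extensions on either
#' side; otherwise `none`. Core takes precedence over flank.
#'
#' @param match One-row match (`start`, `end`, 0-based half-open).
#' @param variants Variant table on the same sequence.
#' @param flank Flank width in bp (default 3, the core-adjacent nucleotides
#'   that modulate AP-1 binding).
#' @param seq_length Sequence length, used to flag truncated flanks.
#' @return List `hit` (`core_hit`/`flank_hit`/`none`) and `truncated`.
#' @export
flank_variant_overlap <- function(match, variants, flank = 3L,
                                  seq_length = Inf) {
  s <- match$start[1L]; e <- match$end[1L]
  truncated <- (s - flank) < 0L || (e + flank) > seq_length
  if (is.null(variants) || !nrow(variants)) {
    return(list(hit = "none", truncated = truncated))
  }
  core <- any(variants$start < e & variants$end > s)
  if (core) return(list(hit = "core_hit", truncated = truncated))
  fs <- max(0L, s - flank)
  fe <- min(seq_length, e + flank)
  in_flank <- any((variants$start < s & variants$end > fs) |
                    (variants$start < fe & variants$end > e))
  list(hit = if (in_flank) "flank_hit" else "none", truncated = truncated)
}
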