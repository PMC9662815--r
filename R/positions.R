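# Positional enrichment of SNPs/indels relative to summits or motif
# anchors. Offsets use the "closest nucleotide" rule: a variant's offset is
# the signed distance from the anchor to the variant nucleotide nearest it,
# so a span crossing the anchor reports 0.

#' Signed variant offsets around per-region anchors
#'
#' For each (region, variant) pair with the variant's affected span within
#' `halfwidth` bp of the region anchor, reports the signed offset of the
#' variant nucleotide closest to the anchor (0 when the span covers the
#' anchor).
#'
#' @param regions Data frame with `chrom` and `anchor` (0-based coordinate;
#'   use summits or motif midpoints).
#' @param variants Variant table.
#' @param halfwidth Window half-width in bp (default 200, inclusive).
#' @return Integer vector of offsets, one per in-window (region, variant)
#'   event.
#' @export
variant_offsets <- function(regions, variants, halfwidth = 200L) {
  if (!nrow(regions) || !nrow(variants)) return(integer(0))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    a <- regions$anchor[i]
    v <- variants[variants$chrom == regions$chrom[i], , drop = FALSE]
    if (!nrow(v)) return(integer(0))
    off <- ifelse(v$start > a, v$start - a,
           ifelse(v$end <= a, v$end - 1L - a, 0L))
    off[abs(off) <= halfwidth]
  })
  as.integer(unlist(out))
}

#' Build a position histogram from offsets
#'
#' @param offsets Integer offsets (from [variant_offsets()]).
#' @param halfwidth Histogram half-width.
#' @param n_regions Number of regions the offsets came from.
#' @param anchor_kind `"summit"` or `"motif"`.
#' @return List of class `position_histogram` with `offsets` (the axis),
#'   `counts`, `n_regions`, `halfwidth`, `anchor_kind`.
#' @export
position_histogram <- function(offsets, halfwidth = 200L, n_regions = NA_integer_,
                               anchor_kind = c("summit", "motif")) {
  anchor_kind <- match.arg(anchor_kind)
  axis <- seq.int(-halfwidth, halfwidth)
  counts <- tabulate(match(offsets, axis), nbins = length(axis))
  structure(list(anchor_kind = anchor_kind, halfwidth = halfwidth,
                 offsets = axis, counts = counts,
                 n_regions = n_regions),
            class = "position_histogram")
}

#' Central-window chi-squared comparison of two offset histograms
#'
#' Collapses each histogram into (inside the central window) vs (outside,
#' within the full window) counts and applies the Pearson chi-squared test
#' on the 2x2 table, without continuity correction, with 1 degree of
#' freedom. The central window is `[-central_width/2, +central_width/2]`
#' inclusive.
#'
#' @param as_hist,shared_hist Two [position_histogram()]s over the same
#'   window (e.g. allele-specific vs shared peaks).
#' @param central_width Width of the central window in bp (default 100).
#' @return List `statistic`, `p`, `table` (2x2), `expected`, and
#'   `low_expected` (`TRUE` with a warning if any expected cell < 5).
#' @export
offset_histogram_compare <- function(as_hist, shared_hist,
                                     central_width = 100L) {
  stopifnot(inherits(as_hist, "position_histogram"),
            inherits(shared_hist, "position_histogram"),
            as_hist$halfwidth == shared_hist$halfwidth)
  hw <- central_width / 2
  split_counts <- function(h) {
    inside <- sum(h$counts[abs(h$offsets) <= hw])
    c(inside = inside, outside = sum(h$counts) - inside)
  }
  tab <- rbind(allele_specific = split_counts(as_hist),
               shared = split_counts(shared_hist))
  res <- pearson_chisq_2x2(tab)
  res$table <- tab
  res
}

#' Pearson chi-squared test on a 2x2 table (no continuity correction)
#'
#' @param tab 2x2 integer matrix.
#' @return List `statistic`, `p` (from the chi-squared distribution with
#'   1 df), `expected`, `low_expected`.
#' @export
pearson_chisq_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) return(list(statistic = 0, p = 1, expected = tab * 0,
                          low_expected = TRUE))
  expected <- outer(rowSums(tab), colSums(tab)) / n
  low <- any(expected < 5)
  if (low) warning("expected cell count < 5; chi-squared approximation is rough")
  if (any(expected == 0)) {
    return(list(statistic = 0, p = 1, expected = expected, low_expected = TRUE))
  }
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE),
       expected = expected, low_expected = low)
}

#' Variant offsets anchored on a shared motif
#'
#' Peaks carrying any variant that overlaps their cognate motif span are
#' excluded first; for the remainder, offsets are computed relative to the
#' motif midpoint (central base for odd-length motifs, left-of-center base
#' for even) and oriented by motif strand, so positive offsets are 3' of
#' the motif on its own strand.
#'
#' @param motifs Data frame with one shared motif per peak: `peak_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param variants Variant table.
#' @param halfwidth Offset window half-width (default 200).
#' @return Integer offsets pooled over retained peaks.
#' @export
motif_anchored_offsets <- function(motifs, variants, halfwidth = 200L) {
  if (!nrow(motifs)) return(integer(0))
  out <- lapply(seq_len(nrow(motifs)), function(i) {
    v <- variants[variants$chrom == motifs$chrom[i], , drop = FALSE]
    if (nrow(v) &&
        any(v$start < motifs$end[i] & v$end > motifs$start[i])) {
      return(integer(0))  # variant in the cognate motif: peak excluded
    }
    len <- motifs$end[i] - motifs$start[i]
    mid <- motifs$start[i] + (len - 1L) %/% 2L
    off <- variant_offsets(data.frame(chrom = motifs$chrom[i], anchor = mid),
                           v, halfwidth)
    if (motifs$strand[i] == "-") -off else off
  })
  as.integer(unlist(out))
}

#' Distance from each interval to its nearest neighbour in another set
#'
#' Edge-to-edge gap: 0 for overlapping or bookended intervals, `Inf` when
#' the other set has no interval on that chromosome.
#'
#' @param features_a,features_b Data frames with `chrom`, `start`, `end`.
#' @param exclude_self Drop coordinate-identical intervals before taking the
#'   minimum; defaults to `TRUE` when both arguments are the same set, so
#'   "nearest neighbour within a set" skips the interval itself.
#' @return Numeric vector, one distance per row of `features_a`.
#' @export
distance_to_nearest <- function(features_a, features_b,
                                exclude_self = identical(features_a, features_b)) {
  vapply(seq_len(nrow(features_a)), function(i) {
    b <- features_b[features_b$chrom == features_a$chrom[i], , drop = FALSE]
    if (exclude_self) {
      self <- b$start == features_a$start[i] & b$end == features_a$end[i]
      b <- b[!self, , drop = FALSE]
    }
    if (!nrow(b)) return(Inf)
    gap <- pmax(b$start - features_a$end[i], features_a$start[i] - b$end, 0L)
    min(gap)
  }, numeric(1L))
}
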