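# Aggregate signal profiles around summits, split by allele motif status:
# the intact-vs-mutated contrast that shows a factor's signal collapsing on
# the allele whose governing motif is disrupted.

#' Select peaks with a single, variant-hit motif and no shared motif
#'
#' Retains peaks where exactly one motif instance exists within `halfwidth`
#' bp of the summit across the union of alleles, that instance is
#' variant-overlapped (present on one allele only), and no shared intact
#' instance exists. These are the clean single-motif cases where the
#' intact/mutated allele contrast is interpretable.
#'
#' @param instances Data frame with one row per (peak, motif instance):
#'   `peak_id`, `offset` (instance start relative to summit),
#'   `maternal_has`, `paternal_has` (logical: allele carries the intact
#'   instance).
#' @param halfwidth Summit window half-width in bp (default 75, inclusive).
#' @return Data frame with `peak_id` and `intact_allele`
#'   (`maternal`/`paternal`) for retained peaks.
#' @export
select_single_motif_pairs <- function(instances, halfwidth = 75L) {
  inst <- instances[abs(instances$offset) <= halfwidth, , drop = FALSE]
  out <- lapply(split(inst, inst$peak_id), function(df) {
    if (nrow(df) != 1L) return(NULL)             # exactly one instance
    if (df$maternal_has && df$paternal_has) return(NULL)  # shared: excluded
    if (!df$maternal_has && !df$paternal_has) return(NULL)
    data.frame(peak_id = df$peak_id,
               intact_allele = if (df$maternal_has) "maternal" else "paternal",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peak_id = character(0), intact_allele = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Binned aggregate profile around anchors
#'
#' Sums event weights into fixed-width bins of the window around each
#' region's anchor and averages over regions per group. Bin edges are
#' half-open (`[-window, -window + bin)`, ..., `[window - bin, window)`);
#' events exactly at `+window` fall outside.
#'
#' @param events Data frame with `chrom`, `position` (0-based), `weight`,
#'   and `group`.
#' @param anchors Data frame with `chrom`, `anchor`, `group` (one row per
#'   region per group).
#' @param window Half-window in bp (default 1000).
#' @param bin Bin width in bp (default 10); must divide `2 * window`.
#' @return List of class `aggregate_profile`: `bin_start` (left edges),
#'   `groups` (named list of mean-signal vectors), `n` (regions per group).
#' @export
binned_profile <- function(events, anchors, window = 1000L, bin = 10L) {
  stopifnot((2L * window) %% bin == 0L)
  n_bins <- (2L * window) %/% bin
  edges <- seq.int(-window, window, by = bin)
  groups <- unique(anchors$group)
  out <- list(); ns <- integer(0)
  for (g in groups) {
    anc <- anchors[anchors$group == g, , drop = FALSE]
    ev <- events[events$group == g, , drop = FALSE]
    if (!nrow(anc)) {
      warning(sprintf("group '%s' has no regions; dropped", g))
      next
    }
    acc <- numeric(n_bins)
    for (i in seq_len(nrow(anc))) {
      e <- ev[ev$chrom == anc$chrom[i], , drop = FALSE]
      if (!nrow(e)) next
      rel <- e$position - anc$anchor[i]
      keep <- rel >= -window & rel < window
      if (!any(keep)) next
      b <- (rel[keep] + window) %/% bin + 1L
      acc <- acc + vapply(seq_len(n_bins), function(k) {
        sum(e$weight[keep][b == k])
      }, numeric(1L))
    }
    out[[as.character(g)]] <- acc / nrow(anc)
    ns[as.character(g)] <- nrow(anc)
  }
  structure(list(bin_start = edges[-length(edges)], groups = out, n = ns,
                 window = window, bin = bin),
            class = "aggregate_profile")
}
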