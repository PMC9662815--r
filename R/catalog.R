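# Building the catalog of analyzable CRE allele pairs. Peaks are
# summit-centered; the filters mirror the standard allele-specific workflow:
# a mappability requirement (>=1 variant within +/-60 bp of the summit),
# 1-kb summit deduplication keeping the strongest pooled ATAC signal, a
# bottom-quintile signal floor per group, and exclusion of peaks within
# 100 kb of imprinted gene bodies. All +/-w windows are inclusive of both
# endpoints (width 2w+1).

#' Catalog configuration with standard defaults
#'
#' @param mappability_halfwidth bp around the summit in which a variant is
#'   required (default 60).
#' @param central_width Width of the central counting window (default 150).
#' @param dedup_distance Summit deduplication distance in bp (default 1000).
#' @param quintile_floor Signal quantile below which peaks are dropped
#'   (default 0.2).
#' @param imprint_margin bp added around imprinted gene bodies (default 1e5).
#' @param proximal_threshold Summit-to-TSS distance separating proximal from
#'   distal peaks (default 1000).
#' @return List of class `catalog_config`.
#' @export
catalog_config <- function(mappability_halfwidth = 60L, central_width = 150L,
                           dedup_distance = 1000L, quintile_floor = 0.2,
                           imprint_margin = 100000L,
                           proximal_threshold = 1000L) {
  cfg <- list(mappability_halfwidth = mappability_halfwidth,
              central_width = central_width,
              dedup_distance = dedup_distance,
              quintile_floor = quintile_floor,
              imprint_margin = imprint_margin,
              proximal_threshold = proximal_threshold)
  bad <- names(cfg)[vapply(cfg, function(v) !is.numeric(v) || length(v) != 1L ||
                             is.na(v) || v <= 0, logical(1L))]
  if (length(bad)) stop("invalid catalog configuration field: ", bad[1L])
  if (quintile_floor >= 1) stop("invalid catalog configuration field: quintile_floor")
  class(cfg) <- "catalog_config"
  cfg
}

#' Summit-centered window
#'
#' @param summit 0-based summit coordinate(s).
#' @param half_width Window half-width in bp; the window is inclusive of both
#'   endpoints, i.e. `[summit - half_width, summit + half_width + 1)`,
#'   clipped at 0.
#' @return `data.frame(start, end)`, 0-based half-open.
#' @export
make_window <- function(summit, half_width) {
  if (any(half_width < 0)) stop("half_width must be nonnegative")
  if (any(summit < 0)) stop("summit must be nonnegative")
  data.frame(start = pmax(0L, as.integer(summit - half_width)),
             end = as.integer(summit + half_width + 1L))
}

#' Count variants intersecting a window
#'
#' A variant counts once when its affected reference span intersects the
#' half-open window; partial overlaps count.
#'
#' @param window One-row `data.frame(start, end)` or a length-2 vector.
#' @param variants Variant table ([genome_variants()]).
#' @param chrom Optional chromosome restriction.
#' @return Integer count.
#' @export
count_variants <- function(window, variants, chrom = NULL) {
  if (is.data.frame(window)) {
    wstart <- window$start[1L]; wend <- window$end[1L]
  } else {
    wstart <- window[1L]; wend <- window[2L]
  }
  if (!nrow(variants)) return(0L)
  sum(variant_overlaps(variants, wstart, wend, chrom))
}

#' Mappability flag: any variant within +/-60 bp of the summit
#'
#' @param summit 0-based summit coordinate.
#' @param variants Variant table.
#' @param chrom Chromosome of the summit.
#' @param half_width Mappability half-width (default 60, inclusive).
#' @return Logical.
#' @export
classify_mappable <- function(summit, variants, chrom = NULL, half_width = 60L) {
  w <- make_window(summit, half_width)
  count_variants(w, variants, chrom) >= 1L
}

#' Deduplicate summits within a distance, keeping the strongest
#'
#' Summits on the same chromosome are clustered by single linkage at
#' `min_distance`; within each (transitive) cluster only the summit with the
#' highest `pooled_signal` survives, ties broken by smaller coordinate.
#'
#' @param peaks `data.frame` with `chrom`, `summit`, `pooled_signal`.
#' @param min_distance Clustering distance in bp (default 1000).
#' @return Retained peaks, ordered by chromosome then summit.
#' @export
dedup_summits <- function(peaks, min_distance = 1000L) {
  if (!nrow(peaks)) return(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$summit), , drop = FALSE]
  new_cluster <- c(TRUE, diff(peaks$summit) > min_distance |
                     peaks$chrom[-1L] != peaks$chrom[-nrow(peaks)])
  cl <- cumsum(new_cluster)
  keep <- unlist(lapply(split(seq_len(nrow(peaks)), cl), function(idx) {
    sig <- peaks$pooled_signal[idx]
    idx[which.max(sig)]   # which.max takes the first (smallest coordinate) tie
  }), use.names = FALSE)
  out <- peaks[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove peaks below the per-group signal quantile floor
#'
#' Within each group, peaks with `pooled_signal` strictly below the
#' empirical `quantile` (linear-interpolation, type 7) are removed. Groups
#' with fewer than 5 peaks are passed through unfiltered with a warning.
#'
#' @param peaks Peak table with `pooled_signal`.
#' @param quantile Quantile in (0,1) (default 0.2, the bottom quintile).
#' @param grouping Factor/vector with one group label per peak; `NULL` for a
#'   single group.
#' @return Retained peaks.
#' @export
apply_signal_floor <- function(peaks, quantile = 0.2, grouping = NULL) {
  if (!nrow(peaks)) return(peaks)
  if (is.null(grouping)) grouping <- rep("all", nrow(peaks))
  stopifnot(length(grouping) == nrow(peaks))
  keep <- unlist(lapply(split(seq_len(nrow(peaks)), grouping), function(idx) {
    if (length(idx) < 5L) {
      warning("group with <5 peaks passed through the signal floor unfiltered")
      return(idx)
    }
    floor_val <- stats::quantile(peaks$pooled_signal[idx], probs = quantile,
                                 type = 7, names = FALSE)
    idx[peaks$pooled_signal[idx] >= floor_val]
  }), use.names = FALSE)
  out <- peaks[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude peaks near imprinted gene bodies
#'
#' Removes peaks whose summit lies within any imprint interval expanded by
#' `margin` bp on both sides (half-open expansion).
#'
#' @param peaks Peak table with `chrom`, `summit`.
#' @param imprint_intervals `data.frame(chrom, start, end)` of gene bodies.
#' @param margin Expansion in bp (default 100000).
#' @return Retained peaks.
#' @export
exclude_imprinted <- function(peaks, imprint_intervals, margin = 100000L) {
  if (!nrow(peaks) || is.null(imprint_intervals) || !nrow(imprint_intervals)) {
    return(peaks)
  }
  hit <- vapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]
    any(imprint_intervals$chrom == peaks$chrom[i] &
          s >= imprint_intervals$start - margin &
          s < imprint_intervals$end + margin)
  }, logical(1L))
  out <- peaks[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a peak as proximal/distal and active/primed
#'
#' Proximal iff the distance from the summit to the nearest TSS is at most
#' `threshold` (ties proximal); active iff the summit falls inside any
#' H3K27ac interval, else primed.
#'
#' @param peaks Peak table with `chrom`, `summit`.
#' @param tss_list `data.frame(chrom, pos)` of TSS coordinates (may be empty).
#' @param h3k27ac_intervals `data.frame(chrom, start, end)` (may be empty).
#' @param threshold Proximal distance cutoff in bp (default 1000).
#' @return `peaks` with added `locale` (`proximal`/`distal`) and `active`
#'   (logical) columns.
#' @export
classify_peak <- function(peaks, tss_list, h3k27ac_intervals,
                          threshold = 1000L) {
  n <- nrow(peaks)
  if (is.null(tss_list) || !nrow(tss_list)) {
    warning("empty TSS list: all peaks classified distal")
    peaks$locale <- rep("distal", n)
  } else {
    peaks$locale <- vapply(seq_len(n), function(i) {
      d <- abs(tss_list$pos[tss_list$chrom == peaks$chrom[i]] - peaks$summit[i])
      if (length(d) && min(d) <= threshold) "proximal" else "distal"
    }, character(1L))
  }
  if (is.null(h3k27ac_intervals) || !nrow(h3k27ac_intervals)) {
    peaks$active <- rep(FALSE, n)
  } else {
    peaks$active <- vapply(seq_len(n), function(i) {
      any(h3k27ac_intervals$chrom == peaks$chrom[i] &
            peaks$summit[i] >= h3k27ac_intervals$start &
            peaks$summit[i] < h3k27ac_intervals$end)
    }, logical(1L))
  }
  peaks
}

#' Run the full catalog filter pipeline
#'
#' Applies, in order: mappability (>=1 variant within the mappability
#' window), summit deduplication, the per-group signal floor, and the
#' imprint exclusion. Also annotates the central-window variant count. The
#' pipeline is idempotent: rerunning it on its own output changes nothing.
#'
#' @param peaks Peak table with `id`, `chrom`, `summit`, `pooled_signal`.
#' @param variants Variant table.
#' @param config A [catalog_config()].
#' @param imprint_intervals Optional imprinted gene-body intervals.
#' @param grouping Optional signal-floor grouping.
#' @return Filtered, annotated peak table with `mappable` and
#'   `n_variants_150` columns.
#' @export
build_catalog <- function(peaks, variants, config = catalog_config(),
                          imprint_intervals = NULL, grouping = NULL) {
  stopifnot(inherits(config, "catalog_config"))
  hw_cent <- (config$central_width %/% 2L)
  peaks$mappable <- vapply(seq_len(nrow(peaks)), function(i) {
    classify_mappable(peaks$summit[i], variants, peaks$chrom[i],
                      config$mappability_halfwidth)
  }, logical(1L))
  peaks$n_variants_150 <- vapply(seq_len(nrow(peaks)), function(i) {
    count_variants(make_window(peaks$summit[i], hw_cent), variants,
                   peaks$chrom[i])
  }, integer(1L))
  kept <- peaks[peaks$mappable, , drop = FALSE]
  if (!is.null(grouping)) grouping <- grouping[peaks$mappable]
  kept$..row <- seq_len(nrow(kept))
  kept <- dedup_summits(kept, config$dedup_distance)
  if (!is.null(grouping)) grouping <- grouping[kept$..row]
  kept$..row <- seq_len(nrow(kept))
  kept2 <- apply_signal_floor(kept, config$quintile_floor, grouping)
  kept2 <- exclude_imprinted(kept2, imprint_intervals, config$imprint_margin)
  kept2$..row <- NULL
  rownames(kept2) <- NULL
  kept2
}
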