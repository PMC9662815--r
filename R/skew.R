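# Allelic-imbalance testing. The skew test is a self-contained exact
# binomial test of the summed maternal count against the pair total at
# p0 = 0.5 (two-sided, minimum-likelihood convention), with an optional
# beta-binomial variant whose overdispersion is estimated across peaks by
# the method of moments. Peaks with BH-adjusted q below the FDR threshold
# are classified allele-specific; fold-change magnitude is binned strictly
# against the >2 and >4 fold thresholds on pseudocounted totals.

#' Skew-test configuration
#'
#' @param fdr_threshold FDR below which a pair is called allele-specific
#'   (default 0.1).
#' @param fold_thresholds Fold-change magnitude bin edges (default `c(2, 4)`).
#' @param tf_halfwidth,histone_halfwidth Counting half-windows in bp applied
#'   when totals are derived from positional tracks (defaults 250 and 500).
#' @param pseudocount Added to each total before the log2 ratio (default 1).
#' @param test `"binomial"` (default) or `"beta_binomial"`.
#' @return List of class `skew_config`.
#' @export
skew_config <- function(fdr_threshold = 0.1, fold_thresholds = c(2, 4),
                        tf_halfwidth = 250L, histone_halfwidth = 500L,
                        pseudocount = 1, test = c("binomial", "beta_binomial")) {
  test <- match.arg(test)
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must lie in (0,1)")
  }
  if (any(fold_thresholds <= 0) || tf_halfwidth <= 0 || histone_halfwidth <= 0) {
    stop("thresholds and halfwidths must be positive")
  }
  structure(list(fdr_threshold = fdr_threshold,
                 fold_thresholds = sort(fold_thresholds),
                 tf_halfwidth = tf_halfwidth,
                 histone_halfwidth = histone_halfwidth,
                 pseudocount = pseudocount, test = test),
            class = "skew_config")
}

# Two-sided exact binomial p at p0 = 0.5: sum of P(X = j) over all j whose
# likelihood does not exceed that of the observed count (the convention of
# standard exact-test implementations).
binom_two_sided <- function(k, n) {
  if (n == 0L) return(1)
  d <- dbinom(0:n, n, 0.5)
  # small relative tolerance guards against ties lost to floating point
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

# Beta-binomial pmf on log scale, parameterised by mean p and intra-class
# correlation rho: alpha = p(1-rho)/rho, beta = (1-p)(1-rho)/rho.
dbetabinom_log <- function(k, n, p = 0.5, rho = 0) {
  if (rho <= 0) return(dbinom(k, n, p, log = TRUE))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

betabinom_two_sided <- function(k, n, rho) {
  if (n == 0L) return(1)
  ld <- dbetabinom_log(0:n, n, 0.5, rho)
  min(1, sum(exp(ld[ld <= ld[k + 1L] + 1e-9])))
}

# Method-of-moments intra-class correlation of maternal fractions across
# peaks: rho = (var(k/n) - mean binomial variance) / excess capacity.
# Only safe when most peaks are null; prefer the replicate-based estimator
# when replicates are available.
estimate_bb_rho <- function(maternal, total) {
  ok <- total > 0
  m <- maternal[ok]; n <- total[ok]
  if (length(n) < 3L) return(0)
  phat <- sum(m) / sum(n)
  v_obs <- stats::var(m / n)
  v_bin <- mean(phat * (1 - phat) / n)
  v_max <- phat * (1 - phat) * mean(1 - 1 / n)
  if (v_max <= 0) return(0)
  max(0, min(0.99, (v_obs - v_bin) / v_max))
}

# Replicate-based intra-class correlation. Within a peak, every replicate
# shares the same true maternal fraction, so the across-replicate spread of
# per-replicate fractions estimates the sampling-plus-overdispersion noise
# free of contamination by genuine allelic effects:
#   Var(f_r) = p(1-p) (1 + (n_r - 1) rho) / n_r.
# Method of moments over all peaks with >= 2 informative replicates.
estimate_bb_rho_replicates <- function(m_rep, p_rep, peak) {
  n_rep <- m_rep + p_rep
  keep <- n_rep > 0
  m_rep <- m_rep[keep]; n_rep <- n_rep[keep]; peak <- peak[keep]
  f <- m_rep / n_rep
  num <- 0; den <- 0
  for (idx in split(seq_along(f), peak)) {
    if (length(idx) < 2L) next
    pbar <- sum(m_rep[idx]) / sum(n_rep[idx])
    if (pbar <= 0 || pbar >= 1) next
    s2 <- stats::var(f[idx])
    num <- num + s2 - pbar * (1 - pbar) * mean(1 / n_rep[idx])
    den <- den + pbar * (1 - pbar) * mean((n_rep[idx] - 1) / n_rep[idx])
  }
  if (den <= 0) return(0)
  max(0, min(0.99, num / den))
}

# The skew test runs on totals over replicates; a per-replicate rho maps to
# the total-count scale as rho_tot = rho * sum n_r (n_r - 1) / (N (N - 1)).
rho_for_totals <- function(rho, n_rep_totals) {
  N <- sum(n_rep_totals)
  if (N < 2L || rho <= 0) return(0)
  rho * sum(n_rep_totals * (n_rep_totals - 1)) / (N * (N - 1))
}

#' Test one allele pair for allelic imbalance
#'
#' @param maternal_counts,paternal_counts Nonnegative integer replicate
#'   counts (summed internally).
#' @param config A [skew_config()].
#' @param rho Beta-binomial intra-class correlation (only used when
#'   `config$test == "beta_binomial"`; estimate it across peaks with the
#'   table-level [skew_table()]).
#' @return List with `p`, `maternal_total`, `paternal_total`, and `no_data`
#'   (`TRUE` with `p = 1` when the pair total is zero).
#' @export
test_skew <- function(maternal_counts, paternal_counts,
                      config = skew_config(), rho = 0) {
  stopifnot(length(maternal_counts) >= 1L, length(paternal_counts) >= 1L,
            all(maternal_counts >= 0), all(paternal_counts >= 0))
  m <- sum(maternal_counts); pat <- sum(paternal_counts)
  n <- m + pat
  if (n == 0L) {
    return(list(p = 1, maternal_total = 0L, paternal_total = 0L,
                no_data = TRUE))
  }
  p <- if (config$test == "beta_binomial" && rho > 0) {
    betabinom_two_sided(m, n, rho)
  } else {
    binom_two_sided(m, n)
  }
  list(p = min(1, p), maternal_total = m, paternal_total = pat,
       no_data = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return q-values in the input order, with step-up monotonicity enforced;
#'   `q >= p` elementwise.
#' @export
bh_fdr <- function(pvalues) {
  m <- length(pvalues)
  if (!m) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  o <- order(pvalues)
  q_sorted <- pvalues[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  # guard the q >= p contract against floating-point rounding of m*p/i
  pmax(q, pvalues)
}

#' Fold change and magnitude bin for an allele pair
#'
#' @param maternal_total,paternal_total Summed counts.
#' @param config A [skew_config()] providing the pseudocount and thresholds.
#' @return List with `log2_fold` (maternal over paternal on pseudocounted
#'   totals), `magnitude` (`lt2`, `ge2`, `ge4`: strictly greater than 2- or
#'   4-fold in either direction), and `direction`.
#' @export
classify_fold <- function(maternal_total, paternal_total,
                          config = skew_config()) {
  pc <- config$pseudocount
  lf <- log2((maternal_total + pc) / (paternal_total + pc))
  th <- log2(config$fold_thresholds)
  magnitude <- if (abs(lf) > th[2L]) "ge4" else if (abs(lf) > th[1L]) "ge2" else "lt2"
  direction <- if (lf > 0) "maternal" else if (lf < 0) "paternal" else "none"
  list(log2_fold = lf, magnitude = magnitude, direction = direction)
}

#' Allelic-skew table for a set of peaks
#'
#' Runs [test_skew()] per peak, BH-adjusts across peaks, and classifies each
#' pair. In beta-binomial mode the overdispersion is first estimated by the
#' method of moments: from the across-replicate spread of per-replicate
#' maternal fractions when a `replicate` column with two or more replicates
#' is present (robust to genuine allelic effects), otherwise across peaks
#' (valid only when most peaks are null).
#'
#' @param counts Data frame with columns `peak_id`, `allele`
#'   (`maternal`/`paternal`), `count`, and optionally `replicate`;
#'   replicate rows are summed for testing.
#' @param config A [skew_config()].
#' @return Data frame with one row per peak: totals, `log2_fold`, `p`, `q`,
#'   `klass` (`allele_specific` iff `q < fdr_threshold`), `direction`,
#'   `magnitude`.
#' @export
skew_table <- function(counts, config = skew_config()) {
  stopifnot(all(c("peak_id", "allele", "count") %in% names(counts)),
            all(counts$allele %in% c("maternal", "paternal")))
  agg <- tapply(counts$count, list(counts$peak_id, counts$allele), sum,
                default = 0L)
  ids <- rownames(agg)
  m <- if ("maternal" %in% colnames(agg)) agg[, "maternal"] else rep(0L, length(ids))
  pat <- if ("paternal" %in% colnames(agg)) agg[, "paternal"] else rep(0L, length(ids))
  rho <- 0
  rep_totals <- NULL
  if (config$test == "beta_binomial") {
    if ("replicate" %in% names(counts) &&
        length(unique(counts$replicate)) >= 2L) {
      key <- paste(counts$peak_id, counts$replicate, sep = "\r")
      mr <- tapply(counts$count[counts$allele == "maternal"],
                   key[counts$allele == "maternal"], sum, default = 0L)
      pr <- tapply(counts$count[counts$allele == "paternal"],
                   key[counts$allele == "paternal"], sum, default = 0L)
      common <- intersect(names(mr), names(pr))
      peak_of <- sub("\r[^\r]*$", "", common)
      rho <- estimate_bb_rho_replicates(as.numeric(mr[common]),
                                        as.numeric(pr[common]), peak_of)
      rep_totals <- split(as.numeric(mr[common]) + as.numeric(pr[common]),
                          peak_of)
    } else {
      rho <- estimate_bb_rho(m, m + pat)
    }
  }
  p <- vapply(seq_along(ids), function(i) {
    rho_i <- if (!is.null(rep_totals)) {
      rho_for_totals(rho, rep_totals[[ids[i]]] %||% (m[i] + pat[i]))
    } else rho
    test_skew(m[i], pat[i], config, rho = rho_i)$p
  }, numeric(1L))
  q <- bh_fdr(p)
  folds <- lapply(seq_along(ids), function(i) classify_fold(m[i], pat[i], config))
  data.frame(peak_id = ids,
             maternal_total = as.integer(m),
             paternal_total = as.integer(pat),
             log2_fold = vapply(folds, `[[`, numeric(1L), "log2_fold"),
             p = p, q = q,
             klass = ifelse(q < config$fdr_threshold, "allele_specific", "shared"),
             direction = vapply(folds, `[[`, character(1L), "direction"),
             magnitude = vapply(folds, `[[`, character(1L), "magnitude"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Signal-matched subsampling of shared peaks
#'
#' Bins the reference signals into `n_bins` quantile bins and draws shared
#' peaks without replacement from each bin in proportion to the reference
#' bin mass (capped at bin availability), so the subsample's signal
#' distribution matches the reference set's.
#'
#' @param shared_signal Numeric signals of the candidate (shared) peaks.
#' @param reference_signal Numeric signals of the reference set.
#' @param n_bins Number of quantile bins (default 20).
#' @param size Target subsample size (default `length(reference_signal)`).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Integer indices into `shared_signal`.
#' @export
signal_match_subsample <- function(shared_signal, reference_signal,
                                   n_bins = 20L, size = length(reference_signal),
                                   seed = 1L) {
  stopifnot(length(shared_signal) > 0, length(reference_signal) > 0)
  probs <- seq(0, 1, length.out = n_bins + 1L)
  edges <- unique(stats::quantile(reference_signal, probs, type = 7,
                                  names = FALSE))
  if (length(edges) < 2L) edges <- c(edges, edges + 1e-9)
  bin_of <- function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = FALSE)
    pmin(pmax(b, 0L), length(edges) - 1L)  # 0 = below reference support
  }
  ref_bins <- bin_of(reference_signal)
  ref_bins[ref_bins == 0L] <- 1L
  shared_bins <- bin_of(shared_signal)
  n_eff_bins <- length(edges) - 1L
  ref_mass <- tabulate(ref_bins, nbins = n_eff_bins) / length(reference_signal)
  target <- round(size * ref_mass)
  picked <- integer(0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_eff_bins)) {
    cand <- which(shared_bins == b)
    want <- target[b]
    if (want == 0L) next
    if (!length(cand)) {
      warning(sprintf("no shared candidates in reference bin %d; bin skipped", b))
      next
    }
    take <- min(want, length(cand))
    picked <- c(picked, if (length(cand) == 1L) cand else sample(cand, take))
  }
  sort(picked)
}
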