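# IUPAC degenerate nucleotide alphabet. Every scanner in the package works on
# explicit expansion sets so that degenerate codes behave identically in
# forward and reverse-complement orientation.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# IUPAC complement, closed over the degenerate codes.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# Degenerate motif vocabulary used throughout the AP-1/TEAD analyses:
# the extended AP-1 element and its bindable variants, the palindromic core
# TRE, the TEAD core and extended k-mers, and the AP-1 half-site pattern.
MOTIF_CATALOG <- c(
  ap1_core      = "TGASTCA",
  ap1_extended  = "VTGACTCAB",
  ap1_variant1  = "VTGAATCAB",
  ap1_variant2  = "VTTAGTCAY",
  tead_core     = "GGAAT",
  tead_extended = "GGAATK",
  ap1_half_site = "TGASVDB"
)

validate_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      nchar(pattern) == 0L) {
    stop("pattern must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(pattern), "")[[1L]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC character '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Number of concrete expansions of an IUPAC pattern
#'
#' @param pattern IUPAC string (e.g. `"VTGACTCAB"`).
#' @return Integer: the product over positions of per-code cardinalities.
#' @examples
#' iupac_degeneracy("VTGACTCAB") # 9
#' @export
iupac_degeneracy <- function(pattern) {
  pattern <- validate_iupac(pattern)
  chars <- strsplit(pattern, "")[[1L]]
  prod(vapply(IUPAC_CODES[chars], length, integer(1L)))
}

#' Expand an IUPAC pattern into its concrete sequences
#'
#' Enumerates every ACGT string matching the degenerate pattern positionwise.
#'
#' @inheritParams iupac_degeneracy
#' @return Character vector of unique concrete sequences, length equal to
#'   [iupac_degeneracy()].
#' @examples
#' expand_iupac("TGASTCA") # TGACTCA, TGAGTCA
#' @export
expand_iupac <- function(pattern) {
  pattern <- validate_iupac(pattern)
  chars <- strsplit(pattern, "")[[1L]]
  grid <- expand.grid(IUPAC_CODES[chars], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  sort(do.call(paste0, grid))
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorised; accepts degenerate IUPAC codes.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1L), USE.NAMES = FALSE)
}

#' Scan a sequence for matches to a degenerate k-mer
#'
#' Reports every window equal to a member of the pattern's expansion on the
#' forward strand, and (when `both_strands`) every window equal to a member of
#' the reverse-complemented expansion on the minus strand. A window matching
#' through both routes (reverse-complement-closed patterns such as the core
#' TRE) is emitted once with strand `"+"`. All overlapping occurrences are
#' reported; `N` in the sequence never matches.
#'
#' @param sequence Single string over `A,C,G,T,N`.
#' @param pattern IUPAC pattern.
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @param id Pattern identifier carried into the result (defaults to the
#'   pattern itself).
#' @return `data.frame` with columns `start`, `end` (0-based half-open),
#'   `strand`, `pattern`, sorted by `start`.
#' @export
scan_kmer <- function(sequence, pattern, both_strands = TRUE, id = pattern) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  pattern <- validate_iupac(pattern)
  k <- nchar(pattern)
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), pattern = character(0),
                      stringsAsFactors = FALSE)
  if (n < k) return(empty)
  fwd <- expand_iupac(pattern)
  rev <- revcomp(fwd)
  starts <- seq_len(n - k + 1L)
  windows <- substring(sequence, starts, starts + k - 1L)
  is_fwd <- windows %in% fwd
  is_rev <- both_strands & (windows %in% rev)
  hit <- is_fwd | is_rev
  if (!any(hit)) return(empty)
  strand <- ifelse(is_fwd[hit], "+", "-")
  data.frame(start = starts[hit] - 1L,
             end = starts[hit] - 1L + k,
             strand = strand,
             pattern = id,
             stringsAsFactors = FALSE)
}

#' Scan several patterns at once
#'
#' @param sequence Single string.
#' @param patterns Named character vector of IUPAC patterns.
#' @param both_strands Scan both strands.
#' @return Row-bound [scan_kmer()] results with `pattern` set to the names of
#'   `patterns`.
#' @export
scan_kmers <- function(sequence, patterns, both_strands = TRUE) {
  if (is.null(names(patterns))) names(patterns) <- patterns
  out <- lapply(names(patterns), function(nm) {
    scan_kmer(sequence, patterns[[nm]], both_strands = both_strands, id = nm)
  })
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$pattern), , drop = FALSE]
}
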