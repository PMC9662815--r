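# Position weight matrix scanning. Thresholding is by fraction of the
# maximal achievable log-odds score rather than a p-value machinery; the
# fraction is configurable and 0.8 by default.

#' Construct a position weight matrix object
#'
#' @param counts 4 x L numeric matrix of base counts with rownames
#'   `A,C,G,T`.
#' @param id Matrix identifier (e.g. a JASPAR accession).
#' @param background Length-4 base composition, summing to 1.
#' @return Object of class `pwm`.
#' @export
pwm <- function(counts, id = "pwm", background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  sums <- colSums(counts)
  if (max(sums) - min(sums) > 0.5 + 1e-6 * max(sums)) {
    warning("per-column count sums differ beyond rounding")
  }
  structure(list(id = id, counts = counts,
                 background = setNames(background, c("A", "C", "G", "T"))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d columns), consensus %s\n",
              x$id, ncol(x$counts), pwm_consensus(x)))
  invisible(x)
}

#' Read a JASPAR plain-text matrix file
#'
#' Accepts the standard JASPAR format: a `>ID name` header followed by four
#' lines `A [ n n ... ]` etc. (brackets optional).
#'
#' @param path File path.
#' @return A [pwm()] object.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!startsWith(lines[1L], ">")) stop("not a JASPAR matrix: missing '>' header")
  id <- strsplit(sub("^>", "", lines[1L]), "[ \t]+")[[1L]][1L]
  rows <- lapply(lines[2:5], function(l) {
    l <- gsub("[][]", " ", l)
    parts <- strsplit(trimws(l), "[ \t]+")[[1L]]
    list(base = parts[1L], vals = as.numeric(parts[-1L]))
  })
  bases <- vapply(rows, `[[`, character(1L), "base")
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    stop("JASPAR matrix must have rows A, C, G, T")
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(counts) <- bases
  pwm(counts, id = id)
}

#' Write a PWM in JASPAR plain-text format
#'
#' @param x A [pwm()] object.
#' @param path Output file.
#' @export
write_jaspar <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  lines <- c(paste0(">", x$id),
             vapply(c("A", "C", "G", "T"), function(b) {
               sprintf("%s [ %s ]", b,
                       paste(format(x$counts[b, ], trim = TRUE), collapse = " "))
             }, character(1L)))
  writeLines(lines, path)
}

# Log-odds score matrix: log2((count + pc) / (colsum + 4 pc)) - log2(bg).
pwm_logodds <- function(x, pseudocount = 0.01) {
  probs <- sweep(x$counts + pseudocount, 2,
                 colSums(x$counts) + 4 * pseudocount, "/")
  log2(probs) - log2(x$background)
}

#' Consensus sequence of a PWM
#'
#' @param x A [pwm()] object.
#' @return String of per-column maximal bases (ties to the first of A,C,G,T).
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$counts)[apply(x$counts, 2, which.max)], collapse = "")
}

#' Scan a sequence with a PWM
#'
#' Scores every window with the log-odds matrix (pseudocount 0.01 per cell,
#' uniform background by default) on both strands and keeps windows scoring
#' at least `threshold_fraction` of the maximal achievable score. Windows
#' containing `N` never match.
#'
#' @param sequence Single string over `A,C,G,T,N`.
#' @param x A [pwm()] object.
#' @param threshold_fraction Fraction of the maximal score required
#'   (default 0.8).
#' @param both_strands Scan the minus strand too.
#' @param pseudocount Per-cell pseudocount for the log-odds transform.
#' @return `data.frame(start, end, strand, score)`, 0-based half-open,
#'   sorted by start.
#' @export
scan_pwm <- function(sequence, x, threshold_fraction = 0.8,
                     both_strands = TRUE, pseudocount = 0.01) {
  stopifnot(inherits(x, "pwm"), is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  lo <- pwm_logodds(x, pseudocount)
  L <- ncol(lo)
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0))
  if (n < L) return(empty)
  max_score <- sum(apply(lo, 2, max))
  threshold <- threshold_fraction * max_score
  chars <- strsplit(sequence, "")[[1L]]
  idx <- match(chars, c("A", "C", "G", "T"))   # NA for N
  score_strand <- function(mat) {
    # rolling sum of per-position column scores; NA (from N) poisons a window
    per_pos <- matrix(NA_real_, nrow = L, ncol = n - L + 1L)
    for (j in seq_len(L)) {
      pos <- idx[j:(j + n - L)]
      per_pos[j, ] <- mat[cbind(pos, j)]
    }
    colSums(per_pos)
  }
  scores_f <- score_strand(lo)
  keep_f <- !is.na(scores_f) & scores_f >= threshold
  hits <- data.frame(start = which(keep_f) - 1L,
                     strand = rep("+", sum(keep_f)),
                     score = scores_f[keep_f])
  if (both_strands) {
    # minus strand: score the reverse complement matrix against the forward
    # sequence; column j reads complement base at window position L+1-j
    lo_rc <- lo[c("T", "G", "C", "A"), rev(seq_len(L)), drop = FALSE]
    rownames(lo_rc) <- c("A", "C", "G", "T")
    scores_r <- score_strand(lo_rc)
    keep <- !is.na(scores_r) & scores_r >= threshold
    hits <- rbind(hits, data.frame(start = which(keep) - 1L,
                                   strand = rep("-", sum(keep)),
                                   score = scores_r[keep]))
  }
  if (!nrow(hits)) return(empty)
  hits$end <- hits$start + L
  hits <- hits[order(hits$start, hits$strand), c("start", "end", "strand", "score")]
  rownames(hits) <- NULL
  hits
}
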