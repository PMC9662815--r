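# Readers/writers for the plain-text interchange formats: FASTA, BED6, and
# the named-column TSVs used for counts and catalogs. All coordinates are
# 0-based half-open internally; only VCF conversion shifts base (variants.R).

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("[ \t].*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
}

#' Read a BED file (3-6 columns)
#'
#' @param path BED file.
#' @return `data.frame(chrom, start, end[, name, score, strand])`, 0-based
#'   half-open as in the file.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write intervals as BED6
#'
#' @param df Data frame with at least `chrom, start, end`; `name`, `score`,
#'   `strand` filled with `.`, `0`, `.` when absent.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0L,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read a named-column TSV
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a named-column TSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
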