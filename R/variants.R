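# Variants distinguishing the maternal and paternal alleles. Coordinates are
# 0-based half-open on the maternal (reference) allele. The affected span is
# the reference footprint: one base for SNPs, one base (the left anchor) for
# insertions, and all deleted bases for deletions.

#' Build a validated table of genome variants
#'
#' @param chrom Character vector of sequence ids.
#' @param start 0-based start of the affected reference span.
#' @param ref,alt Reference and alternate alleles (VCF-style for indels:
#'   insertions `ref = anchor base`, `alt = anchor + inserted`; deletions
#'   `ref = anchor + deleted`, `alt = anchor base`).
#' @param id Optional variant ids.
#' @return `data.frame` with columns `chrom, start, end, ref, alt, kind`.
#'   `end - start` is 1 for SNPs and insertions and `nchar(ref) - 1` ... the
#'   number of deleted bases ... for deletions.
#' @export
genome_variants <- function(chrom, start, ref, alt, id = NULL) {
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(ref) == 1L && n > 1L) ref <- rep(ref, n)
  if (length(alt) == 1L && n > 1L) alt <- rep(alt, n)
  stopifnot(length(chrom) == n, length(start) == n, length(ref) == n,
            length(alt) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref must differ from alt for every variant")
  if (any(!grepl("^[ACGT]+$", c(ref, alt)))) {
    stop("ref/alt must be nonempty ACGT strings")
  }
  nr <- nchar(ref); na <- nchar(alt)
  kind <- ifelse(nr == na & nr == 1L, "snp",
          ifelse(nr < na, "insertion",
          ifelse(nr > na, "deletion", "mnp")))
  if (any(kind == "mnp")) {
    stop("multi-nucleotide substitutions are not supported; split into SNPs")
  }
  # affected reference span: SNP = the base; insertion = the anchor base;
  # deletion = the deleted bases (excluding the retained anchor)
  span_start <- ifelse(kind == "deletion", start + 1L, start)
  span_end <- ifelse(kind == "deletion", start + nr, start + 1L)
  out <- data.frame(chrom = as.character(chrom),
                    start = as.integer(span_start),
                    end = as.integer(span_end),
                    ref = ref, alt = alt, kind = kind,
                    anchor = as.integer(start),
                    stringsAsFactors = FALSE)
  if (!is.null(id)) out$id <- id
  stopifnot(all(out$start < out$end))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Logical: does each variant's affected span intersect [wstart, wend)?
variant_overlaps <- function(variants, wstart, wend, chrom = NULL) {
  hit <- variants$start < wend & variants$end > wstart
  if (!is.null(chrom)) hit <- hit & variants$chrom == chrom
  hit
}

#' Read a VCF v4 subset into a variant table
#'
#' Reads the fixed CHROM/POS/ID/REF/ALT columns of a VCF (the only columns
#' the allele-pair analyses need; genotypes are ignored). Records whose
#' FILTER column is populated with anything other than `PASS` or `.` are
#' dropped, matching the use of PASS-filtered strain variants. Multi-allelic
#' records are split into one record per alternate allele. Records with
#' symbolic or non-ACGT alleles are skipped with a warning.
#'
#' @param path VCF file path (plain text).
#' @return Variant table as from [genome_variants()], 0-based spans.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(genome_variants(character(0), integer(0), character(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 5L) stop("VCF records need at least CHROM POS ID REF ALT")
  get <- function(i) vapply(fields, function(f) f[i], character(1L))
  chrom <- get(1L); pos <- as.integer(get(2L)); id <- get(3L)
  ref <- toupper(get(4L)); alt_raw <- toupper(get(5L))
  filt <- if (ncol_min >= 7L) get(7L) else rep(".", length(lines))
  keep <- filt %in% c("PASS", ".", "")
  chrom <- chrom[keep]; pos <- pos[keep]; id <- id[keep]
  ref <- ref[keep]; alt_raw <- alt_raw[keep]
  alt_split <- strsplit(alt_raw, ",", fixed = TRUE)
  rep_n <- lengths(alt_split)
  chrom <- rep(chrom, rep_n); pos <- rep(pos, rep_n); id <- rep(id, rep_n)
  ref <- rep(ref, rep_n); alt <- unlist(alt_split)
  ok <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt) & ref != alt
  if (any(!ok)) {
    warning(sprintf("skipped %d VCF record(s) with symbolic/non-ACGT alleles",
                    sum(!ok)))
  }
  genome_variants(chrom[ok], pos[ok] - 1L, ref[ok], alt[ok], id = id[ok])
}

#' Write a variant table as a minimal VCF
#'
#' @param variants Table from [genome_variants()].
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ids <- if ("id" %in% names(variants)) variants$id else rep(".", nrow(variants))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                  variants$chrom, variants$anchor + 1L, ids,
                  variants$ref, variants$alt)
  writeLines(c(header, body), path)
}
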