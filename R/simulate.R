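# Synthetic diploid fixture generator. Each locus is one "chromosome": a
# maternal reference sequence with motifs written in near the central
# summit, a paternal allele derived from it by background SNPs/indels at
# strain-like densities plus targeted motif-disrupting SNPs, and
# negative-binomial allele counts whose paternal means drop by per-assay
# multipliers when a governing motif is disrupted. Ground truth (placements,
# disruption flags, true mean ratios) is carried alongside so downstream
# modules can be tested against a known answer.

ASSAYS <- c("ATAC", "Fos", "Tead1", "CTCF", "H3K27ac", "H3K4me1")

with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default motif planting specification
#'
#' One extended AP-1 element, one extended TEAD element, and one CTCF-like
#' element, planted independently near the summit with normal offsets.
#'
#' @return List of per-motif specs (`id`, `pattern`, `prob`, `offset_sd`).
#' @export
default_motif_specs <- function() {
  list(list(id = "ap1", pattern = "VTGACTCAB", prob = 0.5, offset_sd = 25),
       list(id = "tead", pattern = "GGAATK", prob = 0.3, offset_sd = 25),
       list(id = "ctcf", pattern = "CCACYAGRKGGCR", prob = 0.2, offset_sd = 25))
}

#' Default per-assay effect multipliers for a disrupted motif
#'
#' Encodes the hierarchical AP-1/TEAD structure: losing the AP-1 element
#' collapses Fos binding and strongly reduces accessibility, active marks,
#' and Tead1 binding, whereas losing the TEAD element reduces Tead1 and
#' only mildly perturbs the rest, leaving Fos untouched.
#'
#' @return Named list mapping motif id to a named multiplier vector.
#' @export
default_effect_multipliers <- function() {
  list(ap1  = c(Fos = 0.10, ATAC = 0.30, H3K4me1 = 0.40, H3K27ac = 0.25,
                Tead1 = 0.30),
       tead = c(Tead1 = 0.20, ATAC = 0.70, H3K27ac = 0.60, Fos = 1.00),
       ctcf = c(CTCF = 0.15, ATAC = 0.85))
}

#' Configuration of the diploid fixture generator
#'
#' Defaults emulate a wild-derived strain cross: a combined SNP/indel
#' density of roughly one variant per 125 bp (the wild-derived strains run
#' about one per 85-170 bp; classical strains about one per 1000 bp - see
#' `variant_rate` to switch presets).
#'
#' @param n_loci Number of loci.
#' @param locus_length Locus length in bp (default 2000; the summit sits at
#'   the central base).
#' @param gc_fraction Expected GC content.
#' @param snp_rate,indel_rate Background variants per bp.
#' @param indel_max_len Maximal indel length in bp.
#' @param motif_specs See [default_motif_specs()].
#' @param disruption_prob Probability a planted motif is mutated on the
#'   paternal allele.
#' @param effect_multipliers See [default_effect_multipliers()].
#' @param depth_mean Expected counts per allele per assay.
#' @param dispersion Negative-binomial size parameter (variance
#'   `mu + mu^2 / dispersion`; the Poisson limit as it grows).
#' @param n_replicates Replicates per allele per assay.
#' @param seed Integer master seed.
#' @param variant_rate Optional preset: `"wild_derived"` (about 1/125 bp
#'   combined) or `"classical"` (about 1/1000 bp); overrides
#'   `snp_rate`/`indel_rate`.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_loci = 200L, locus_length = 2000L,
                             gc_fraction = 0.42,
                             snp_rate = 1 / 150, indel_rate = 1 / 750,
                             indel_max_len = 8L,
                             motif_specs = default_motif_specs(),
                             disruption_prob = 0.5,
                             effect_multipliers = default_effect_multipliers(),
                             depth_mean = 100, dispersion = 10,
                             n_replicates = 2L, seed = 1L,
                             variant_rate = NULL) {
  if (!is.null(variant_rate)) {
    variant_rate <- match.arg(variant_rate, c("wild_derived", "classical"))
    if (variant_rate == "wild_derived") {
      snp_rate <- 1 / 150; indel_rate <- 1 / 750
    } else {
      snp_rate <- 1 / 1200; indel_rate <- 1 / 6000
    }
  }
  cfg <- list(n_loci = as.integer(n_loci), locus_length = as.integer(locus_length),
              gc_fraction = gc_fraction, snp_rate = snp_rate,
              indel_rate = indel_rate, indel_max_len = as.integer(indel_max_len),
              motif_specs = motif_specs, disruption_prob = disruption_prob,
              effect_multipliers = effect_multipliers,
              depth_mean = depth_mean, dispersion = dispersion,
              n_replicates = as.integer(n_replicates), seed = as.integer(seed))
  check <- function(name, ok) if (!ok) stop("invalid configuration field: ",
                                            name, call. = FALSE)
  check("n_loci", cfg$n_loci >= 1L)
  check("locus_length", cfg$locus_length >= 1L)
  check("gc_fraction", cfg$gc_fraction >= 0 && cfg$gc_fraction <= 1)
  check("snp_rate", cfg$snp_rate >= 0 && cfg$snp_rate <= 1)
  check("indel_rate", cfg$indel_rate >= 0 && cfg$indel_rate <= 1)
  check("indel_max_len", cfg$indel_max_len >= 1L)
  check("disruption_prob", cfg$disruption_prob >= 0 && cfg$disruption_prob <= 1)
  check("depth_mean", cfg$depth_mean > 0)
  check("dispersion", cfg$dispersion > 0)
  check("n_replicates", cfg$n_replicates >= 1L)
  for (sp in cfg$motif_specs) {
    check("motif_specs", all(c("id", "pattern", "prob") %in% names(sp)) &&
            sp$prob >= 0 && sp$prob <= 1)
    validate_iupac(sp$pattern)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

locus_ids <- function(n) sprintf("locus_%04d", seq_len(n))

#' Simulate per-locus reference sequences
#'
#' @param config A [synthetic_config()].
#' @return Named character vector, one `locus_length`-bp sequence per locus,
#'   with base composition set by `gc_fraction`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  gc <- config$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_local_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_loci), function(i) {
      paste(sample(names(probs), config$locus_length, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1L))
    setNames(seqs, locus_ids(config$n_loci))
  })
}

#' Plant degenerate motifs near locus summits
#'
#' For each locus and motif spec (independently, with the spec's planting
#' probability) writes a uniformly drawn member of the pattern's expansion
#' at a normal offset from the summit, on a uniformly drawn strand (minus
#' strand writes the reverse complement). Placements never overlap one
#' another; an offset that would collide or leave the locus is redrawn.
#'
#' @param sequences Named sequences (from [simulate_reference()]).
#' @param motif_specs List of specs (`id`, `pattern`, `prob`, `offset_sd`).
#' @param seed Integer seed.
#' @param summit 0-based summit per locus (default central base).
#' @return List: `sequences` (with motifs written in), `placements`
#'   (`data.frame(chrom, motif_id, pattern, start, end, strand, written)`).
#' @export
plant_motifs <- function(sequences, motif_specs, seed,
                         summit = nchar(sequences[1L]) %/% 2L) {
  for (sp in motif_specs) {
    if (nchar(sp$pattern) > nchar(sequences[1L])) {
      stop("pattern longer than locus: ", sp$id)
    }
  }
  placements <- list()
  with_local_seed(seed, {
    for (locus in names(sequences)) {
      seq_chars <- strsplit(sequences[[locus]], "")[[1L]]
      occupied <- logical(length(seq_chars))
      for (sp in motif_specs) {
        if (runif(1L) > sp$prob) next
        k <- nchar(sp$pattern)
        expansion <- expand_iupac(sp$pattern)
        sd <- if (is.null(sp$offset_sd)) 25 else sp$offset_sd
        for (try in 1:100) {
          start <- summit + as.integer(round(rnorm(1L, 0, sd))) - k %/% 2L
          if (start < 0L || start + k > length(seq_chars)) next
          span <- (start + 1L):(start + k)
          if (any(occupied[span])) next
          member <- sample(expansion, 1L)
          strand <- sample(c("+", "-"), 1L)
          written <- if (strand == "-") revcomp(member) else member
          seq_chars[span] <- strsplit(written, "")[[1L]]
          occupied[span] <- TRUE
          placements[[length(placements) + 1L]] <-
            data.frame(chrom = locus, motif_id = sp$id, pattern = sp$pattern,
                       start = start, end = start + k, strand = strand,
                       written = written, stringsAsFactors = FALSE)
          break
        }
      }
      sequences[[locus]] <- paste(seq_chars, collapse = "")
    }
  })
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(chrom = character(0), motif_id = character(0),
               pattern = character(0), start = integer(0), end = integer(0),
               strand = character(0), written = character(0))
  list(sequences = sequences, placements = placements)
}

# Draw a SNP at a uniform position inside [start, end) of seq_chars that
# turns the placed window into a non-member of the pattern's expansion on
# either strand. Returns list(pos, ref, alt) or NULL.
draw_disrupting_snp <- function(seq_chars, start, end, pattern) {
  fwd <- expand_iupac(pattern)
  rev <- revcomp(fwd)
  for (try in 1:100) {
    pos <- sample(start:(end - 1L), 1L) + 1L   # 1-based index
    ref <- seq_chars[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    mutated <- seq_chars
    mutated[pos] <- alt
    window <- paste(mutated[(start + 1L):end], collapse = "")
    if (!(window %in% fwd) && !(window %in% rev)) {
      return(list(pos = pos - 1L, ref = ref, alt = alt))
    }
  }
  NULL
}

#' Derive the paternal allele: background variants plus motif disruptions
#'
#' Background SNPs and indels are placed at Poisson(`rate * length`)
#' numbers per locus at uniform positions, avoiding planted motif spans
#' (plus the 3-bp flanks) and one another so the ground truth stays clean.
#' Independently, each planted motif is disrupted with probability
#' `disruption_prob` by one targeted SNP inside its span that converts the
#' written window into a non-member of the pattern's expansion (checked on
#' both strands). Disruption flags are then fixed by re-scanning both
#' alleles around the summit.
#'
#' @param sequences Maternal sequences with motifs planted.
#' @param placements Placement table from [plant_motifs()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param summit 0-based summit (default central base).
#' @param scan_halfwidth Summit window half-width used to fix the
#'   ground-truth flags by re-scanning (default 75, matching
#'   [classify_disruption()]).
#' @return List: `paternal` (named sequences), `variants`
#'   ([genome_variants()] table on maternal coordinates), `ground_truth`
#'   (placements plus `disrupted`, `maternal_has`, `paternal_has`), and
#'   `paternal_summit` (named vector of lifted summit coordinates).
#' @export
mutate_allele <- function(sequences, placements, config, seed,
                          summit = nchar(sequences[1L]) %/% 2L,
                          scan_halfwidth = 75L) {
  stopifnot(inherits(config, "synthetic_config"))
  bases <- c("A", "C", "G", "T")
  var_rows <- list()
  gt_rows <- list()
  paternal <- character(0)
  pat_summit <- numeric(0)
  with_local_seed(seed, {
    for (locus in names(sequences)) {
      seq_chars <- strsplit(sequences[[locus]], "")[[1L]]
      L <- length(seq_chars)
      pl <- placements[placements$chrom == locus, , drop = FALSE]
      blocked <- logical(L)   # planted motif spans + flanks: no background hits
      if (nrow(pl)) {
        for (i in seq_len(nrow(pl))) {
          span <- max(1L, pl$start[i] - 2L):min(L, pl$end[i] + 3L)
          blocked[span] <- TRUE
        }
      }
      loc_vars <- list()
      # targeted disruptions
      disrupted <- logical(nrow(pl))
      if (nrow(pl)) {
        for (i in seq_len(nrow(pl))) {
          if (runif(1L) > config$disruption_prob) next
          snp <- draw_disrupting_snp(seq_chars, pl$start[i], pl$end[i],
                                     pl$pattern[i])
          if (is.null(snp)) next
          disrupted[i] <- TRUE
          loc_vars[[length(loc_vars) + 1L]] <-
            data.frame(anchor = snp$pos, ref = snp$ref, alt = snp$alt,
                       stringsAsFactors = FALSE)
        }
      }
      # background SNPs
      n_snp <- rpois(1L, config$snp_rate * L)
      free <- which(!blocked)
      if (n_snp > 0L && length(free)) {
        pos <- sample(free, min(n_snp, length(free)))
        for (p in pos) {
          ref <- seq_chars[p]
          loc_vars[[length(loc_vars) + 1L]] <-
            data.frame(anchor = p - 1L, ref = ref,
                       alt = sample(setdiff(bases, ref), 1L),
                       stringsAsFactors = FALSE)
        }
        blocked[pos] <- TRUE
      }
      # background indels (VCF-anchored; span must avoid blocked positions)
      n_indel <- rpois(1L, config$indel_rate * L)
      if (n_indel > 0L) {
        for (j in seq_len(n_indel)) {
          len <- sample.int(config$indel_max_len, 1L)
          is_ins <- runif(1L) < 0.5
          span_len <- if (is_ins) 1L else len + 1L
          cand <- which(!blocked)
          cand <- cand[cand + span_len - 1L <= L]
          cand <- cand[vapply(cand, function(p) !any(blocked[p:(p + span_len - 1L)]),
                              logical(1L))]
          if (!length(cand)) next
          p <- if (length(cand) == 1L) cand else sample(cand, 1L)
          anchor_base <- seq_chars[p]
          if (is_ins) {
            ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
            loc_vars[[length(loc_vars) + 1L]] <-
              data.frame(anchor = p - 1L, ref = anchor_base,
                         alt = paste0(anchor_base, ins),
                         stringsAsFactors = FALSE)
            blocked[p] <- TRUE
          } else {
            del <- paste(seq_chars[p:(p + len)], collapse = "")
            loc_vars[[length(loc_vars) + 1L]] <-
              data.frame(anchor = p - 1L, ref = del, alt = anchor_base,
                         stringsAsFactors = FALSE)
            blocked[p:(p + len)] <- TRUE
          }
        }
      }
      # apply variants right-to-left so earlier coordinates stay valid
      pat_chars <- seq_chars
      if (length(loc_vars)) {
        lv <- do.call(rbind, loc_vars)
        lv <- lv[order(-lv$anchor), , drop = FALSE]
        for (r in seq_len(nrow(lv))) {
          a <- lv$anchor[r] + 1L
          nref <- nchar(lv$ref[r])
          stopifnot(paste(pat_chars[a:(a + nref - 1L)], collapse = "") == lv$ref[r])
          pat_chars <- c(if (a > 1L) pat_chars[1:(a - 1L)] else character(0),
                         strsplit(lv$alt[r], "")[[1L]],
                         if (a + nref <= length(pat_chars))
                           pat_chars[(a + nref):length(pat_chars)] else character(0))
        }
        lv <- lv[order(lv$anchor), , drop = FALSE]
        var_rows[[locus]] <- data.frame(chrom = locus, lv,
                                        stringsAsFactors = FALSE)
      }
      paternal[locus] <- paste(pat_chars, collapse = "")
      # lift the summit through indels entirely 5' of it
      shift <- 0L
      if (length(loc_vars)) {
        lv2 <- var_rows[[locus]]
        before <- lv2$anchor + nchar(lv2$ref) - 1L <= summit
        shift <- sum(nchar(lv2$alt[before]) - nchar(lv2$ref[before]))
      }
      pat_summit[locus] <- summit + shift
      if (nrow(pl)) {
        pl$disrupted <- disrupted
        gt_rows[[locus]] <- pl
      }
    }
  })
  variants <- if (length(var_rows)) {
    all_v <- do.call(rbind, var_rows)
    genome_variants(all_v$chrom, all_v$anchor, all_v$ref, all_v$alt)
  } else genome_variants(character(0), integer(0), character(0), character(0))
  ground_truth <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    cbind(placements, disrupted = logical(0))
  rownames(ground_truth) <- NULL
  # re-scan both alleles around the summit (same rule as classify_disruption)
  # so the recorded flags are, by construction, what the scanner sees
  if (nrow(ground_truth)) {
    flags <- lapply(seq_len(nrow(ground_truth)), function(i) {
      locus <- ground_truth$chrom[i]
      classify_disruption(sequences[[locus]], paternal[[locus]],
                          summit, pat_summit[[locus]],
                          ground_truth$pattern[i], halfwidth = scan_halfwidth)
    })
    ground_truth$maternal_has <- vapply(flags, `[[`, logical(1L), "maternal_has")
    ground_truth$paternal_has <- vapply(flags, `[[`, logical(1L), "paternal_has")
  }
  list(paternal = paternal, variants = variants, ground_truth = ground_truth,
       paternal_summit = pat_summit)
}

#' Simulate allele counts from ground truth
#'
#' Counts are negative-binomial with maternal mean `depth_mean` and
#' paternal mean `depth_mean` times the product of effect multipliers of
#' every motif disrupted on the paternal allele, for the assays each motif
#' governs.
#'
#' @param ground_truth Ground-truth table from [mutate_allele()] (needs
#'   `chrom`, `motif_id`, `disrupted`).
#' @param loci Character vector of all locus ids (including motif-free ones).
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List: `counts`
#'   (`data.frame(locus, assay, allele, replicate, count)`) and
#'   `true_ratio` (locus x assay matrix of paternal:maternal mean ratios).
#' @export
simulate_counts <- function(ground_truth, loci, config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  ratio <- matrix(1, nrow = length(loci), ncol = length(ASSAYS),
                  dimnames = list(loci, ASSAYS))
  if (nrow(ground_truth)) {
    disrupted <- ground_truth[ground_truth$disrupted, , drop = FALSE]
    for (i in seq_len(nrow(disrupted))) {
      mult <- config$effect_multipliers[[disrupted$motif_id[i]]]
      if (is.null(mult)) next
      for (a in names(mult)) {
        ratio[disrupted$chrom[i], a] <- ratio[disrupted$chrom[i], a] * mult[[a]]
      }
    }
  }
  grid <- expand.grid(locus = loci, assay = ASSAYS,
                      allele = c("maternal", "paternal"),
                      replicate = seq_len(config$n_replicates),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  mu <- ifelse(grid$allele == "maternal", config$depth_mean,
               config$depth_mean * ratio[cbind(grid$locus, grid$assay)])
  counts <- with_local_seed(seed, {
    rnbinom(nrow(grid), size = config$dispersion, mu = mu)
  })
  grid$count <- as.integer(counts)
  list(counts = grid, true_ratio = ratio)
}

#' Generate a complete diploid fixture
#'
#' Runs reference simulation, motif planting, paternal mutation, and count
#' simulation with sub-seeds derived from `config$seed`. Identical configs
#' yield identical fixtures.
#'
#' @param config A [synthetic_config()].
#' @return List of class `cre_fixture`: `config`, `maternal`, `paternal`
#'   (named sequences), `summit` (maternal coordinate), `paternal_summit`,
#'   `placements`, `variants`, `ground_truth`, `counts`, `true_ratio`.
#' @export
simulate_cre_fixture <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sub <- function(k) (config$seed * 7L + k) %% 2147483647L
  maternal <- simulate_reference(config)
  planted <- plant_motifs(maternal, config$motif_specs, seed = sub(1L))
  summit <- config$locus_length %/% 2L
  mut <- mutate_allele(planted$sequences, planted$placements, config,
                       seed = sub(2L), summit = summit)
  cnt <- simulate_counts(mut$ground_truth, names(maternal), config,
                         seed = sub(3L))
  structure(list(config = config, maternal = planted$sequences,
                 paternal = mut$paternal, summit = summit,
                 paternal_summit = mut$paternal_summit,
                 placements = planted$placements, variants = mut$variants,
                 ground_truth = mut$ground_truth, counts = cnt$counts,
                 true_ratio = cnt$true_ratio),
            class = "cre_fixture")
}

#' Write a fixture bundle to disk
#'
#' Emits `maternal.fa`, `paternal.fa`, `variants.vcf` (1-based POS),
#' `summits.bed` and `motifs.bed` (0-based half-open), `counts.tsv`, and
#' `ground_truth.tsv`. All files round-trip through the package readers.
#'
#' @param fixture A `cre_fixture`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  stopifnot(inherits(fixture, "cre_fixture"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L) stop("unwritable directory: ", dir)
  write_fasta(fixture$maternal, file.path(dir, "maternal.fa"))
  write_fasta(fixture$paternal, file.path(dir, "paternal.fa"))
  write_vcf(fixture$variants, file.path(dir, "variants.vcf"))
  summits <- data.frame(chrom = names(fixture$maternal),
                        start = fixture$summit, end = fixture$summit + 1L,
                        name = names(fixture$maternal))
  write_bed(summits, file.path(dir, "summits.bed"))
  if (nrow(fixture$placements)) {
    write_bed(data.frame(chrom = fixture$placements$chrom,
                         start = fixture$placements$start,
                         end = fixture$placements$end,
                         name = fixture$placements$motif_id,
                         score = 0L,
                         strand = fixture$placements$strand),
              file.path(dir, "motifs.bed"))
  }
  write_tsv(fixture$counts, file.path(dir, "counts.tsv"))
  gt <- fixture$ground_truth
  if (nrow(gt)) write_tsv(gt, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Read a fixture bundle back from disk
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with `maternal`, `paternal`, `variants`, `summits`,
#'   `motifs` (`NULL` when absent), `counts`, `ground_truth`.
#' @export
read_fixture_bundle <- function(dir) {
  motifs_path <- file.path(dir, "motifs.bed")
  gt_path <- file.path(dir, "ground_truth.tsv")
  list(maternal = read_fasta(file.path(dir, "maternal.fa")),
       paternal = read_fasta(file.path(dir, "paternal.fa")),
       variants = read_vcf(file.path(dir, "variants.vcf")),
       summits = read_bed(file.path(dir, "summits.bed")),
       motifs = if (file.exists(motifs_path)) read_bed(motifs_path),
       counts = read_tsv(file.path(dir, "counts.tsv")),
       ground_truth = if (file.exists(gt_path)) read_tsv(gt_path))
}
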