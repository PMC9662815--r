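test_that("configuration validation names the offending field", {
  expect_error(synthetic_config(gc_fraction = 1.5), "gc_fraction")
  expect_error(synthetic_config(depth_mean = 0), "depth_mean")
  expect_error(synthetic_config(dispersion = -1), "dispersion")
  expect_error(synthetic_config(snp_rate = 2), "snp_rate")
  cfg <- synthetic_config(variant_rate = "classical")
  expect_equal(cfg$snp_rate, 1 / 1200)
})

test_that("reference simulation is deterministic with controlled GC", {
  cfg <- synthetic_config(n_loci = 1, locus_length = 100, gc_fraction = 0.5,
                          seed = 7)
  s1 <- simulate_reference(cfg)
  s2 <- simulate_reference(cfg)
  expect_identical(s1, s2)
  expect_equal(nchar(s1[[1]]), 100L)
  pure <- simulate_reference(synthetic_config(n_loci = 2, locus_length = 500,
                                              gc_fraction = 1, seed = 1))
  expect_true(all(grepl("^[GC]+$", pure)))
  many <- simulate_reference(synthetic_config(n_loci = 200,
                                              locus_length = 2000,
                                              gc_fraction = 0.42, seed = 3))
  gc <- mean(vapply(many, function(s) {
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1)))
  expect_true(gc >= 0.40 && gc <= 0.44)
})

test_that("planted motifs are expansion members on the drawn strand", {
  cfg <- synthetic_config(n_loci = 300, seed = 13,
                          motif_specs = list(list(id = "ap1",
                                                  pattern = "VTGACTCAB",
                                                  prob = 1, offset_sd = 20)))
  seqs <- simulate_reference(cfg)
  pl <- plant_motifs(seqs, cfg$motif_specs, seed = 14)
  expansion <- expand_iupac("VTGACTCAB")
  written_fwd <- vapply(seq_len(nrow(pl$placements)), function(i) {
    sub <- substr(pl$sequences[[pl$placements$chrom[i]]],
                  pl$placements$start[i] + 1L, pl$placements$end[i])
    if (pl$placements$strand[i] == "-") revcomp(sub) else sub
  }, character(1))
  expect_true(all(written_fwd %in% expansion))
  # all 9 expansions observed, roughly uniformly, over 300 plantings
  expect_setequal(unique(written_fwd), expansion)
  expect_gt(min(table(written_fwd)), 300 / 9 * 0.4)
  # planting probability 0 leaves sequences unchanged
  none <- plant_motifs(seqs, list(list(id = "x", pattern = "GGAATK",
                                       prob = 0, offset_sd = 20)), seed = 5)
  expect_identical(none$sequences, seqs)
  expect_equal(nrow(none$placements), 0L)
  expect_error(plant_motifs(setNames("ACGT", "s"),
                            list(list(id = "x", pattern = "VTGACTCAB",
                                      prob = 1)), seed = 1),
               "longer than locus")
})

test_that("background variant counts follow the Poisson rate", {
  cfg <- synthetic_config(n_loci = 400, locus_length = 2000,
                          snp_rate = 1 / 100, indel_rate = 0,
                          motif_specs = list(), seed = 31)
  seqs <- simulate_reference(cfg)
  empty_pl <- data.frame(chrom = character(0), motif_id = character(0),
                         pattern = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         written = character(0))
  mut <- mutate_allele(seqs, empty_pl, cfg, seed = 32)
  per_locus <- table(factor(mut$variants$chrom, levels = names(seqs)))
  expect_true(mean(per_locus) >= 18 && mean(per_locus) <= 22)
  expect_true(all(mut$variants$ref != mut$variants$alt))
})

test_that("disruption probability 0 and 1 behave as stated", {
  base <- list(list(id = "ap1", pattern = "TGACTCA", prob = 1,
                    offset_sd = 10))
  cfg0 <- synthetic_config(n_loci = 30, motif_specs = base,
                           disruption_prob = 0, seed = 41)
  fx0 <- simulate_cre_fixture(cfg0)
  expect_true(all(!fx0$ground_truth$disrupted))
  expect_true(all(fx0$ground_truth$paternal_has))
  cfg1 <- synthetic_config(n_loci = 30, motif_specs = base,
                           disruption_prob = 1, seed = 42)
  fx1 <- simulate_cre_fixture(cfg1)
  expect_true(all(fx1$ground_truth$disrupted))
  # zero matches to the core AP-1 within the planted span on the paternal
  # allele (span lifted through upstream indels)
  gt <- fx1$ground_truth
  for (i in seq_len(nrow(gt))) {
    v <- fx1$variants[fx1$variants$chrom == gt$chrom[i], ]
    shift <- sum((nchar(v$alt) - nchar(v$ref))[v$end <= gt$start[i]])
    span <- substr(fx1$paternal[[gt$chrom[i]]],
                   gt$start[i] + shift + 1L, gt$end[i] + shift)
    expect_equal(nrow(scan_kmer(span, "TGASTCA")), 0L)
  }
  # every disrupted motif has >= 1 variant overlapping its span
  for (i in which(fx1$ground_truth$disrupted)) {
    expect_gte(count_variants(c(gt$start[i], gt$end[i]),
                              fx1$variants, chrom = gt$chrom[i]), 1L)
  }
})

test_that("background variants avoid intact planted motif spans", {
  cfg <- synthetic_config(n_loci = 80, disruption_prob = 0, seed = 43)
  fx <- simulate_cre_fixture(cfg)
  gt <- fx$ground_truth
  for (i in seq_len(nrow(gt))) {
    expect_equal(count_variants(c(gt$start[i], gt$end[i]), fx$variants,
                                chrom = gt$chrom[i]), 0L)
  }
})

test_that("count simulation encodes the configured effect sizes", {
  # null symmetry: all multipliers 1
  cfg <- synthetic_config(n_loci = 600, depth_mean = 100, seed = 51)
  gt_null <- data.frame(chrom = character(0), motif_id = character(0),
                        disrupted = logical(0))
  sim <- simulate_counts(gt_null, sprintf("L%03d", 1:600), cfg, seed = 52)
  cc <- sim$counts[sim$counts$assay == "Fos", ]
  m <- tapply(cc$count[cc$allele == "maternal"],
              cc$locus[cc$allele == "maternal"], sum)
  p <- tapply(cc$count[cc$allele == "paternal"],
              cc$locus[cc$allele == "paternal"], sum)
  expect_lt(abs(mean(log2((m + 1) / (p + 1)))), 0.1)
  # effect recovery: Fos multiplier 0.25 at disrupted loci -> log2 ratio ~ 2
  cfg2 <- synthetic_config(n_loci = 500, depth_mean = 100, seed = 53,
                           effect_multipliers = list(ap1 = c(Fos = 0.25)))
  gt <- data.frame(chrom = sprintf("L%03d", 1:500), motif_id = "ap1",
                   disrupted = TRUE)
  sim2 <- simulate_counts(gt, gt$chrom, cfg2, seed = 54)
  expect_true(all(sim2$true_ratio[, "Fos"] == 0.25))
  cc2 <- sim2$counts[sim2$counts$assay == "Fos", ]
  m2 <- tapply(cc2$count[cc2$allele == "maternal"],
               cc2$locus[cc2$allele == "maternal"], sum)
  p2 <- tapply(cc2$count[cc2$allele == "paternal"],
               cc2$locus[cc2$allele == "paternal"], sum)
  expect_lt(abs(mean(log2(m2 / p2)) - 2), 0.3)
  # Poisson limit: dispersion -> infinity
  cfgP <- synthetic_config(n_loci = 2000, depth_mean = 100,
                           dispersion = 1e9, n_replicates = 1, seed = 55)
  simP <- simulate_counts(gt_null, sprintf("L%04d", 1:2000), cfgP, seed = 56)
  x <- simP$counts$count[simP$counts$assay == "ATAC" &
                           simP$counts$allele == "maternal"]
  expect_true(var(x) / mean(x) >= 0.9 && var(x) / mean(x) <= 1.2)
})

test_that("identical config + seed yields byte-identical bundles", {
  cfg <- synthetic_config(n_loci = 12, seed = 61)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(simulate_cre_fixture(cfg), d1)
  write_fixture_bundle(simulate_cre_fixture(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("bundles round-trip losslessly through the package readers", {
  cfg <- synthetic_config(n_loci = 15, seed = 62)
  fx <- simulate_cre_fixture(cfg)
  dir <- withr::local_tempdir()
  write_fixture_bundle(fx, dir)
  back <- read_fixture_bundle(dir)
  expect_identical(back$maternal, fx$maternal)
  expect_identical(back$paternal, fx$paternal)
  expect_equal(back$variants[c("chrom", "start", "end", "ref", "alt", "kind")],
               fx$variants[c("chrom", "start", "end", "ref", "alt", "kind")],
               ignore_attr = TRUE)
  expect_equal(back$counts, fx$counts, ignore_attr = TRUE)
  # coordinate conventions on disk
  lines <- readLines(file.path(dir, "variants.vcf"))
  body <- lines[!startsWith(lines, "#")]
  first <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(first[2]), fx$variants$anchor[1] + 1L)
  motifs <- read_bed(file.path(dir, "motifs.bed"))
  expect_equal(motifs$end - motifs$start,
               nchar(fx$placements$written))
})
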