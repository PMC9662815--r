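test_that("variant_offsets follows the closest-nucleotide rule", {
  reg <- data.frame(chrom = "c1", anchor = 1000L)
  snp <- genome_variants("c1", 1010, "A", "G")
  expect_equal(variant_offsets(reg, snp), 10L)
  # deletion spanning the anchor: [998, 1002) -> offset 0
  del_span <- genome_variants("c1", 997, "AAAAA", "A")
  expect_equal(del_span$start, 998L)
  expect_equal(variant_offsets(reg, del_span), 0L)
  # deletion [1005, 1009): nearest deleted base is 1005 -> +5
  del <- genome_variants("c1", 1004, "AAAAA", "A")
  expect_equal(variant_offsets(reg, del), 5L)
  # 5' side: span [990, 994) -> nearest base 993 -> -7
  del5 <- genome_variants("c1", 989, "AAAAA", "A")
  expect_equal(variant_offsets(reg, del5), -7L)
  expect_equal(variant_offsets(reg, snp[0, ]), integer(0))
})

test_that("offsets at halfwidth h filter consistently to any h' < h", {
  set.seed(12)
  reg <- data.frame(chrom = rep("c1", 5), anchor = c(500, 1500, 2500, 3500, 4500))
  v <- genome_variants(rep("c1", 200), sample.int(5000, 200), rep("A", 200),
                       rep("G", 200))
  wide <- variant_offsets(reg, v, halfwidth = 200)
  narrow <- variant_offsets(reg, v, halfwidth = 80)
  expect_equal(sort(narrow), sort(wide[abs(wide) <= 80]))
})

test_that("central-window chi-squared matches the closed form", {
  h1 <- position_histogram(c(-60, -10, 0, 10, 60), halfwidth = 200)
  same <- suppressWarnings(offset_histogram_compare(h1, h1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # [[20,10],[10,20]]: chi2 = 60^2 * (20*20-10*10)^2 / (30*30*30*30) = 20/3
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  res <- pearson_chisq_2x2(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$p, 0.009823, tolerance = 1e-3)
})

test_that("pearson_chisq_2x2 agrees with chisq.test on random tables", {
  set.seed(30)
  for (i in 1:100) {
    tab <- matrix(rpois(4, sample(c(8, 40, 200), 1)) + 1L, 2)
    got <- suppressWarnings(pearson_chisq_2x2(tab))
    want <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
  }
  expect_warning(pearson_chisq_2x2(matrix(c(2, 1, 1, 2), 2)), "expected cell")
})

test_that("motif-anchored offsets exclude motif-hit peaks and orient by strand", {
  motifs <- data.frame(peak_id = c("p1", "p2"), chrom = c("c1", "c2"),
                       start = c(100L, 100L), end = c(109L, 109L),
                       strand = c("+", "-"))
  # variant inside p1's motif: p1 excluded entirely
  v <- genome_variants(c("c1", "c1", "c2"), c(104, 130, 70), c("A", "A", "A"),
                       c("G", "G", "G"))
  offs <- motif_anchored_offsets(motifs, v)
  # p1 dropped (even its non-motif variant at 130); p2: midpoint = 104,
  # variant at 70 -> reference offset -34, minus strand -> +34
  expect_equal(offs, 34L)
  # plus-strand peak without motif hit keeps reference-signed offsets
  offs2 <- motif_anchored_offsets(motifs[2, ][, ],
                                  genome_variants("c2", 134, "A", "G"))
  expect_equal(offs2, -30L)  # 5' of the minus-strand motif on its own strand
  expect_equal(motif_anchored_offsets(motifs, v[0, ]), integer(0))
})

test_that("midpoint convention: central base (odd), left-of-center (even)", {
  v <- genome_variants("c1", 200, "A", "G")
  odd <- data.frame(peak_id = "p", chrom = "c1", start = 100L, end = 107L,
                    strand = "+")   # len 7, mid = 103
  expect_equal(motif_anchored_offsets(odd, v), 200L - 103L)
  even <- data.frame(peak_id = "p", chrom = "c1", start = 100L, end = 108L,
                     strand = "+")  # len 8, mid = 103 (left of center)
  expect_equal(motif_anchored_offsets(even, v), 200L - 103L)
})

test_that("distance_to_nearest equals the all-pairs brute-force oracle", {
  expect_equal(distance_to_nearest(data.frame(chrom = "c", start = 100, end = 200),
                                   data.frame(chrom = "c", start = 300, end = 400)),
               100)
  expect_equal(distance_to_nearest(data.frame(chrom = "c", start = 100, end = 200),
                                   data.frame(chrom = "c", start = 150, end = 400)),
               0)
  expect_equal(distance_to_nearest(data.frame(chrom = "c", start = 1, end = 2),
                                   data.frame(chrom = "other", start = 1, end = 2)),
               Inf)
  set.seed(40)
  a <- data.frame(chrom = sample(c("c1", "c2"), 40, TRUE),
                  start = sample.int(10000, 40))
  a$end <- a$start + sample.int(500, 40)
  b <- data.frame(chrom = sample(c("c1", "c2"), 40, TRUE),
                  start = sample.int(10000, 40))
  b$end <- b$start + sample.int(500, 40)
  got <- distance_to_nearest(a, b)
  want <- vapply(seq_len(nrow(a)), function(i) {
    ds <- c(Inf)
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      if (a$start[i] < b$end[j] && b$start[j] < a$end[i]) ds <- c(ds, 0)
      else ds <- c(ds, max(b$start[j] - a$end[i], a$start[i] - b$end[j]))
    }
    min(ds)
  }, numeric(1))
  expect_equal(got, want)
})
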