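test_that("make_window realizes inclusive +/-w windows, clipped at zero", {
  expect_equal(make_window(100, 75), data.frame(start = 25L, end = 176L))
  expect_equal(make_window(10, 75), data.frame(start = 0L, end = 86L))
  expect_equal(make_window(0, 0), data.frame(start = 0L, end = 1L))
  expect_error(make_window(10, -1), "nonnegative")
})

test_that("count_variants uses half-open span intersection", {
  w <- make_window(100, 75) # [25, 176)
  v <- genome_variants(c("chr1", "chr1"), c(25, 176), c("A", "A"), c("G", "G"))
  expect_equal(count_variants(w, v[v$start == 25, ]), 1L)
  expect_equal(count_variants(w, v[v$start == 176, ]), 0L)
  # deletion [170,180) partially overlaps [25,176): anchored at 169
  del <- genome_variants("chr1", 169, "ACGTACGTACG", "A")
  expect_equal(del$start, 170L)
  expect_equal(del$end, 180L)
  expect_equal(count_variants(w, del), 1L)
  expect_equal(count_variants(w, v[0, ]), 0L)
})

test_that("mappability is inclusive at exactly 60 bp and span-aware", {
  snp_at <- function(pos) genome_variants("chr1", pos, "A", "G")
  expect_true(classify_mappable(1000, snp_at(1060)))
  expect_true(classify_mappable(1000, snp_at(940)))
  expect_false(classify_mappable(1000, snp_at(1061)))
  expect_false(classify_mappable(1000, snp_at(939)))
  # deletion spanning the summit
  del <- genome_variants("chr1", 989, paste(rep("A", 31), collapse = ""), "A")
  expect_true(classify_mappable(1000, del))
})

test_that("dedup keeps the strongest summit per transitive 1-kb cluster", {
  pk <- function(s, sig) data.frame(chrom = "chr1", summit = s,
                                    pooled_signal = sig)
  two <- rbind(pk(1000, 10), pk(1500, 20))
  expect_equal(dedup_summits(two)$summit, 1500)
  apart <- rbind(pk(1000, 10), pk(3000, 5))
  expect_equal(nrow(dedup_summits(apart)), 2L)
  chain <- rbind(pk(0, 5), pk(900, 9), pk(1800, 7))
  expect_equal(dedup_summits(chain)$summit, 900)
})

test_that("dedup matches a brute-force single-linkage oracle", {
  oracle_dedup <- function(peaks, d = 1000) {
    n <- nrow(peaks)
    adj <- outer(seq_len(n), seq_len(n), function(i, j) {
      peaks$chrom[i] == peaks$chrom[j] &
        abs(peaks$summit[i] - peaks$summit[j]) <= d
    })
    # transitive closure
    repeat {
      nxt <- adj | (adj %*% adj > 0)
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    comp <- apply(adj, 1, function(r) min(which(r)))
    keep <- vapply(split(seq_len(n), comp), function(idx) {
      idx[order(-peaks$pooled_signal[idx], peaks$summit[idx])][1]
    }, integer(1))
    sort(unname(keep))
  }
  set.seed(5)
  for (i in 1:20) {
    peaks <- data.frame(chrom = sample(c("c1", "c2"), 30, replace = TRUE),
                        summit = sample.int(20000, 30),
                        pooled_signal = round(runif(30, 1, 50)))
    got <- dedup_summits(peaks)
    ord <- peaks[order(peaks$chrom, peaks$summit), ]
    want <- ord[oracle_dedup(ord), ]
    expect_equal(got$summit, want$summit)
    expect_equal(got$chrom, want$chrom)
  }
})

test_that("signal floor removes strict inferiors of the 20th percentile", {
  peaks <- data.frame(chrom = "c1", summit = seq(0, by = 5000, length.out = 10),
                      pooled_signal = 1:10)
  kept <- apply_signal_floor(peaks)
  floor_val <- quantile(1:10, 0.2, type = 7)
  expect_true(all(kept$pooled_signal >= floor_val))
  expect_true((nrow(peaks) - nrow(kept)) %in% c(2L, 3L))
  # no strict inferiors when all signals equal
  eq <- transform(peaks, pooled_signal = 7)
  expect_equal(nrow(apply_signal_floor(eq)), 10L)
  # groups filtered independently
  two <- rbind(peaks, transform(peaks, chrom = "c2",
                                pooled_signal = pooled_signal * 100))
  kept2 <- apply_signal_floor(two, grouping = two$chrom)
  expect_true(min(kept2$pooled_signal[kept2$chrom == "c2"]) >
                max(kept2$pooled_signal[kept2$chrom == "c1"]))
  expect_warning(apply_signal_floor(peaks[1:3, ]), "<5 peaks")
})

test_that("imprint exclusion expands gene bodies half-open by the margin", {
  peaks <- data.frame(chrom = "c1",
                      summit = c(1.05e6, 1.1e6 + 1e5 - 1, 1.1e6 + 1e5),
                      pooled_signal = 1)
  gb <- data.frame(chrom = "c1", start = 1e6, end = 1.1e6)
  kept <- exclude_imprinted(peaks, gb)
  expect_equal(kept$summit, 1.1e6 + 1e5)
  expect_equal(exclude_imprinted(peaks, gb[0, ]), peaks)
})

test_that("classify_peak assigns locale and activity", {
  peaks <- data.frame(chrom = "c1", summit = c(500, 5000, 2000))
  tss <- data.frame(chrom = "c1", pos = 1000)
  k27 <- data.frame(chrom = "c1", start = 4900, end = 5100)
  out <- classify_peak(peaks, tss, k27, threshold = 1000)
  expect_equal(out$locale, c("proximal", "distal", "proximal"))
  expect_equal(out$active, c(FALSE, TRUE, FALSE))
  # tie at exactly the threshold is proximal
  expect_equal(classify_peak(data.frame(chrom = "c1", summit = 2000),
                             tss, NULL, 1000)$locale, "proximal")
  expect_warning(out2 <- classify_peak(peaks, tss[0, ], k27),
                 "empty TSS")
  expect_true(all(out2$locale == "distal"))
})

test_that("catalog filter pipeline is idempotent and fully mappable", {
  cfg <- synthetic_config(n_loci = 40, seed = 19)
  fx <- simulate_cre_fixture(cfg)
  peaks <- data.frame(id = names(fx$maternal), chrom = names(fx$maternal),
                      summit = fx$summit,
                      pooled_signal = runif(length(fx$maternal), 1, 100))
  cat1 <- build_catalog(peaks, fx$variants)
  expect_true(all(cat1$mappable))
  # mappability, dedup and imprint exclusion are idempotent; the quintile
  # floor recomputes its threshold, so rerunning can only shrink the set
  expect_equal(dedup_summits(cat1), cat1, ignore_attr = TRUE)
  expect_equal(exclude_imprinted(cat1, NULL), cat1)
  cat2 <- build_catalog(cat1[names(peaks)], fx$variants)
  expect_true(all(cat2$id %in% cat1$id))
  # no retained summit pair within 1 kb on a chromosome (trivially true here:
  # one locus per chromosome)
  expect_false(anyDuplicated(cat1$chrom) > 0)
})
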