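---
title: "Methods: allele-specific CRE analysis in hybridcre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific CRE analysis in hybridcre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridcre)
```

# Scope and design

`hybridcre` analyses summit-centered CRE allele pairs in F1-hybrid
genomes. All internal coordinates are 0-based half-open; VCF conversion
(1-based) happens only at the file boundary. Every `±w bp` window around a
summit is inclusive of both endpoints, i.e. `[summit - w, summit + w + 1)`,
so the "central 150 bp" is realized as ±75 around the summit base. One
synthetic locus is one FASTA record ("chromosome"), which removes
inter-locus interval edge cases by construction.

# The catalog filters

Four filters, applied in a fixed order (mappability → summit dedup →
signal floor → imprint exclusion):

1. **Mappability.** A pair is analyzable only if ≥1 variant's affected
   reference span intersects the ±60-bp summit window. The affected span is
   the variant's reference footprint: the single base for SNPs, the left
   anchor base for insertions, the deleted bases for deletions. Inclusivity
   at exactly 60 bp is a declared choice (the phrasing "±60 bp" does not
   resolve it).
2. **Summit deduplication.** Summits on a chromosome are clustered by
   single linkage at 1 kb (transitive chains merge); only the summit with
   the highest pooled ATAC signal survives, ties to the smaller
   coordinate. Chain behaviour is underdetermined by the rule "summits
   within 1 kb of one another"; single linkage is the declared reading and
   is what the brute-force oracle in the test suite implements
   independently.
3. **Signal floor.** Within each condition/line group, peaks strictly below
   the empirical 20th percentile (linear-interpolation, R type-7 quantile)
   of pooled ATAC signal are removed. Groups with <5 peaks pass through
   with a warning. Note this filter is intentionally *not* idempotent: the
   quantile is a property of the set it is applied to, so re-running the
   pipeline on its own output can only shrink the set further. The other
   three filters are idempotent.
4. **Imprint exclusion.** Peaks whose summit falls inside any imprinted
   gene body expanded by 100 kb on each side (half-open expansion) are
   removed, since parent-of-origin effects would masquerade as
   sequence-driven allelic skew.

Gene-proximal vs gene-distal classification uses the distance from summit
to nearest TSS with a default threshold of 1000 bp (ties proximal). The
source analyses defer the exact cutoff to a supplement; 1 kb is the
package's default and is configurable. "Active" means the summit falls in
an H3K27ac interval; otherwise the element is "primed".

# The allelic skew test

For each pair the replicate counts are summed per allele and the maternal
total `m` is tested against the pair total `n = m + p` at p0 = 1/2.

* **Binomial mode (default).** Two-sided exact binomial p-value under the
  minimum-likelihood convention (sum of all `P(X = j) ≤ P(X = m)`). This is
  exact when counts are conditionally binomial — e.g. Poisson-distributed
  allele signal — and is the mode whose p-values are validated against a
  uniform null in the test suite.
* **Beta-binomial mode.** Real allele counts are overdispersed. When
  replicate-level counts are available, the intra-class correlation ρ is
  estimated by the method of moments from the *across-replicate* spread of
  per-replicate maternal fractions: within a peak every replicate shares
  the same true allelic ratio, so this spread measures noise free of
  contamination by genuine allelic effects (the same reason
  replicate-based dispersion estimation is standard in count-based
  differential analysis). The per-replicate ρ is mapped to the
  total-count scale as `ρ_tot = ρ · Σ n_r (n_r − 1) / (N (N − 1))` and the
  two-sided test enumerates the beta-binomial pmf. Without replicates, an
  across-peak moment estimator is used; it is upward-biased when many
  peaks carry true effects, which makes the test conservative, never
  anticonservative.

A deliberate divergence from the original tooling: DESeq2 is not called.
The published workflow feeds HOMER-annotated counts into DESeq2 and takes
FDR < 0.1; here the classification contract (BH-adjusted q < 0.1 ⇒
allele-specific) is preserved while the test itself is a self-contained
allelic-imbalance test. On negative-binomial fixtures the plain binomial
test is provably anticonservative (two independent NB(μ, size r) alleles
give a Beta(r, r) allele fraction, ρ = 1/(2r+1) > 0), so the calibration,
power, and hierarchy analyses in the acceptance suite run the beta-binomial
mode; the binomial default remains appropriate for Poisson-like data.

Fold changes are `log2((m + 1)/(p + 1))` (pseudocount 1, configurable; the
source is silent on its handling of zeros). Magnitude bins are strict:
`ge2` iff the fold difference exceeds 2 (|log2 FC| > 1), `ge4` iff it
exceeds 4; the finest applicable bin is reported.

Benjamini–Hochberg adjustment is implemented directly (step-up with
monotonicity enforcement and a floating-point guard for the `q ≥ p`
contract) and cross-checked against `stats::p.adjust` in the tests.

**Signal matching.** To compare shared peaks against allele-specific ones
without a signal confounder, reference signals are cut into 20 quantile
bins and shared peaks are drawn without replacement from each bin in
proportion to reference bin mass. The draw is deterministic given a seed.

# Motif scanning and disruption calls

Degenerate IUPAC k-mers are scanned by explicit expansion: a window
matches iff it equals a member of the pattern's expansion (forward strand)
or of the reverse-complemented expansion (minus strand). All overlapping
occurrences count — the analyses report "occurrences per peak", which
implies no greedy masking. A window matching through both routes (the core
TRE `TGASTCA` is closed under reverse complement) is emitted once, on the
plus strand, so palindromic sites are never double-counted. `N` never
matches.

Disruption calls compare the two allele sequences of a pair, each in its
own coordinates (paternal summits are lifted through upstream indels);
`strain_specific` means exactly one allele carries a match within the
summit window (75 bp by default for k-mer contrasts, 50 bp for the
bindable-k-mer presence analyses). The bindable AP-1 set is
{`VTGACTCAB`, `VTGAATCAB`, `VTTAGTCAY`}; one published figure prints the
8-letter "VTGACTCB" in a list of 9-mers, which this package treats as a
typo for `VTGACTCAB`.

AP-1 half sites are counted with `TGASVDB` in the central 150-bp window,
both strands, overlapping occurrences all counted, together with how many
occurrences a variant intersects. Flank analysis classifies a variant as a
`core_hit` (intersects the match span) or `flank_hit` (intersects the
3-bp extension on either side — the nucleotides that modulate AP-1 binding
through motif shape), with core taking precedence.

PWM scanning (e.g. a CTCF profile in JASPAR plain-text format) scores
log-odds with a 0.01 per-cell pseudocount against a uniform background and
keeps windows scoring ≥ 80% of the maximal achievable score by default.
This fraction-of-max rule replaces FIMO's p-value machinery (out of
scope); the threshold is configurable and the scanner is verified against
a brute-force scoring oracle. The shipped matrix
`inst/extdata/ctcf_like_synthetic.jaspar` is a synthetic stand-in, not the
real JASPAR profile.

# Positional enrichment

A variant's offset relative to an anchor is the signed distance of the
variant nucleotide *closest* to the anchor; a span covering the anchor
yields 0. Distributions are collected within ±200 bp. The
allele-specific-vs-shared contrast collapses each distribution into
(inside ±50 bp) vs (outside, within the window) and applies Pearson's
chi-squared on the 2×2 table without continuity correction (1 df). The
exact 2×2 construction is not printed in the source; in/out counting over
a 100-bp central window is the declared convention here.

Motif-anchored distributions first exclude any peak with a variant
overlapping its cognate motif (otherwise motif SNPs dominate), then anchor
on the motif midpoint — central base for odd lengths, left-of-center for
even — with strand-oriented signs (positive = 3' on the motif's own
strand).

# Co-binding hierarchy

Fos and Tead summits are paired greedily by increasing distance (ties to
the smaller coordinate), each summit used once; a pair within 100 bp is a
co-bound locus. The overlap criterion is not defined numerically in the
source; 100-bp summit proximity is the declared default, configurable.
Motif-mutation enrichment between allele-specific and shared peaks uses a
two-sided Fisher exact test (sum of hypergeometric probabilities ≤ the
observed table's, the R convention). Partner-loss fractions are plain
percentages at one decimal: 821/1635 → 50.2%, 821/9416 → 8.7%.

# The synthetic fixture generator

The generator states a world and the tests measure the package against it;
none of its defaults were tuned against test outcomes.

* **Variant densities.** Wild-derived preset: SNPs 1/150 bp + indels
  1/750 bp ≈ one variant per 125 bp, the midpoint of the quoted "one per
  ~85–170 bp" range for wild-derived strains; classical preset 1/1200 +
  1/6000 ≈ 1/1000 bp. Indels ≤8 bp, insertion:deletion 1:1.
* **Loci.** 2 kb, GC 0.42 (typical mammalian regulatory neighbourhood),
  summit at the central base.
* **Motifs.** AP-1 `VTGACTCAB` planted with probability 0.5, TEAD `GGAATK`
  0.3, a CTCF-like 13-mer 0.2; offsets normal with sd 25 bp (variants that
  matter concentrate in the central ~50 bp); uniform expansion member and
  uniform strand; placements never overlap.
* **Disruption.** With probability 0.5 a planted motif receives one
  targeted SNP inside its span that converts the window into a non-member
  of the expansion on either strand. Background variants avoid planted
  motif spans plus 3-bp flanks — a fixture property that keeps ground
  truth clean, not a biological claim. Ground-truth intact/disrupted flags
  are fixed by re-scanning both emitted alleles around the summit with the
  same rule as `classify_disruption`, so scanner/fixture consistency is
  exact rather than probabilistic.
* **Counts.** Negative binomial with maternal mean `depth_mean` (default
  100) and size `dispersion` (default 10; variance μ + μ²/size — the
  spec's "dispersion → ∞ is Poisson" convention pins "dispersion" to the
  size parameter). The paternal mean is multiplied by the effect of every
  motif disrupted on that allele. Default multipliers encode the
  hierarchical structure qualitatively observed in the aggregate
  intact-vs-mutated contrasts: AP-1 loss → Fos 0.10, ATAC 0.30, H3K27ac
  0.25, H3K4me1 0.40, **Tead1 0.30**; TEAD loss → Tead1 0.20, ATAC 0.70,
  H3K27ac 0.60, **Fos 1.00**; CTCF-like loss → CTCF 0.15, ATAC 0.85. The
  source reports no quantitative effect sizes, so these are invented
  calibrations of the qualitative contrasts, all configurable; the
  asymmetry (AP-1 loss removes TEAD binding, not vice versa) is the part
  that matters and is what the hierarchy-recovery test measures.

What the generator does *not* emulate: read-level sampling and mapping
bias, GC or fragment-length biases, more than two alleles, linked variants
within a locus beyond independent placement, or chromatin-domain effects.
A green test therefore establishes correctness of the statistics and
interval logic under the stated model — not robustness to alignment
artefacts.

Determinism: all randomness derives from the config seed (sub-seeds
`7·seed + k mod 2^31 − 1`); identical configs give byte-identical
bundles. Fixture bundles (FASTA + VCF + BED + TSV) round-trip losslessly
through the package readers.

# Numerical and degenerate-input choices

* Two-sided exact tests (binomial, beta-binomial, Fisher) use the
  minimum-likelihood convention with a 1 + 1e-7 relative tolerance on
  probability ties so floating-point noise cannot drop a tied table.
* A pair with zero total count gets p = 1 and a `no_data` flag.
* Aggregate-profile bins are half-open `[−1000, −990) … [990, 1000)`;
  an event exactly at +1000 is excluded. Profiles are simple means over
  regions; the synthetic counts are already depth-controlled, so no
  library-size scaling is applied.
* Empty TSS lists classify everything distal with a warning; empty imprint
  lists are identities; chi-squared tables with an expected cell < 5 warn
  but still return the statistic.
* `make_window` clips at coordinate 0; disruption windows truncated at a
  sequence edge proceed on the truncated window and set a flag.

# Known limitations

* The skew test is a principled stand-in for the published DESeq2-based
  classification, not a reproduction; no shrinkage across peaks is
  performed, and the published genome-wide fractions (e.g. 24.4%
  allele-specific enhancers) depend on the deposited data and are not
  reproducible at fixture scale.
* The across-peak ρ estimator assumes most peaks are null; use replicates
  whenever possible.
* k-mer discovery (KMAC), gkm-SVM classification, FIMO p-values, peak
  calling, read alignment, and Hi-ChIP loop analyses are out of scope.
* Chromosome X and trans-acting comparisons across hybrid lines are not
  modelled.
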