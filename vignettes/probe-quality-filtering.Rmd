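---
title: "Probe quality annotation and filtering for HM450K-style methylation arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe quality annotation and filtering for HM450K-style methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeQC)
```

## The problem

Infinium-style methylation arrays measure the methylation fraction (beta
value, in [0, 1]) of hundreds of thousands of CpGs by hybridizing
bisulfite-converted genomic fragments to 50-mer probes. Hybridization is
blind to *why* a template does or does not bind: a probe whose sequence
occurs at more than one genomic locus, overlaps a repeat element, spans an
INDEL, or carries a SNP — especially at the interrogated CpG itself — can
report a beta value that reflects genotype or cross-hybridization rather
than methylation. Left in place, such probes inflate within-tissue variance
and generate false differential-methylation calls.

probeQC annotates each probe for these genomic factors, quantifies the
noise each factor category actually contributes by comparing array betas
against matched whole-genome bisulfite sequencing (WGBS), and applies a
keep/discard workflow in which factors that demonstrably do not corrupt the
signal are *rescued* rather than dropped wholesale.

## The annotation model

Each probe record carries its Infinium chemistry (type I or II), the
1-based forward-strand position of the C of the interrogated CpG, strand,
and the 50-mer probe sequence. From these the package derives a 50-bp
hybridization *footprint* on forward coordinates. The footprint convention
is a genuine design choice — array documentation, not the underlying
science, fixes it — so it is exposed as a configuration enum:

* under the default `"sbe"` convention a type I probe covers the
  interrogated C at its terminal position and extends in the strand
  direction, while a type II probe terminates one base short of the C (the
  single-base extension step reads the C itself), so its footprint abuts
  the CpG;
* `"typeII_covers"` treats both chemistries alike, for callers that prefer
  a C-covering window.

Either way the footprint has length 50 and contains or abuts the CpG
dinucleotide, on either strand.

### Bisulfite space and multi-mapping

Bisulfite conversion collapses unmethylated C to T, reducing the genome's
effective alphabet and making more probes ambiguous than plain sequence
comparison would suggest. The package builds a fully converted genome
(every C to T on the forward text, and on the reverse-complement text) and
converts each probe to a bisulfite-space query: C outside CpG context is
fixed to T; CpG-context C becomes the wildcard Y (C or T, depending on
methylation); the degenerate R bases of type II probes match A or G.
Matching is exact by default (`max_mismatch = 0`): the product of this
stage is *uniqueness*, not alignment sensitivity, and exact matching is
deterministic and checkable against a brute-force sliding-window oracle,
which the test suite does on randomized genomes. Genomic N never matches
any query letter. A probe is flagged as multi-mapping when its query
occurs at more than one location across both strand texts of all
chromosomes; zero-hit probes are reported separately as unmappable.

### SNPs, INDELs, repeats

Variants are classified by allele length (SNP vs INDEL, with multi-allelic
rows split first). A repeat or INDEL flag requires at least one shared
base between the footprint and the repeat interval or INDEL reference
span (half-open intersection; abutment does not count). SNPs are assigned
strand-oriented offsets from the interrogated C, positive into the probe
body; SNPs at the two CpG dinucleotide positions set the CpG-site flags
(an INDEL spanning those positions sets both the INDEL and CpG flags —
the workflow's CpG test concerns SNPs, but a disrupted CpG is disrupted
regardless of variant class).

The *bisulfite-okay* rescue: a C/T substitution whose 3' neighbour is not
G is invisible after conversion — the base reads as T either way — so such
body SNPs are counted but do not contribute to the effective body-SNP
count. The rule is applied in forward coordinates with alleles normalised
to the forward strand; the sources defining the rule are strand-silent,
so G/A substitutions (the reverse-strand mirror) are deliberately *not*
rescued, which errs on the conservative side. The downstream base is read
from the reference genome; at a chromosome end it is undefined and the SNP
is conservatively treated as not bisulfite-okay.

Average heterozygosity, when present on the variant record, is carried to
the probe as the maximum over its SNPs and can stratify SNP-affected
probes into bins (default edges 0, 0.1, 0.2, 0.3, 0.4, 0.5; the last bin
closed). One open point inherited from the array literature: a SNP at the
type II single-base-extension position is classified here as a CpG-site
SNP when it falls on the dinucleotide and as a body SNP otherwise, and the
offset table makes the position visible to callers who want to treat it
specially.

## The WGBS comparison

WGBS provides a per-base, digital measurement of methylation: a beta value
is methylated reads over total reads. Sites with fewer than 5 supporting
reads are excluded (the conventional floor; configurable). Each probe is
paired with the WGBS site at its interrogated C position exactly — no
merging of the symmetric reverse-strand measurement by default, though a
coverage-weighted merge of the two strand positions is available.

For a probe category (multimap, repeats, INDELs, bisulfite-okay, SNP at
CpG C/G, one body SNP, two or more, unknown) the package reports the
number of paired probes, the median absolute beta difference, the Pearson
correlation between WGBS and array betas, and a two-sided Wilcoxon
rank-sum p-value of the category's absolute differences against the
high-quality background (probes carrying no factor flag). Two-sided is the
package-wide default since the question is "different from background",
and no multiple-testing correction is applied across the handful of
category rows — these are descriptive screen statistics, not discoveries.
The Wilcoxon implementation uses the exact distribution when both samples
have at most 8 observations and no ties, and otherwise the normal
approximation with tie and continuity corrections. The test suite
enumerates all achievable U statistics at n = 8/8: the approximation
agrees with the exact p within 10% wherever the exact p is at least 0.05
and within about 0.011 absolute everywhere; in the extreme tail its
*relative* error is large — an intrinsic property of the approximation
worth knowing when reading very small category p-values.

Probes whose absolute array-vs-WGBS difference exceeds 0.3 (strictly; a
difference of exactly 0.3 does not fire) with no other explanation are
flagged as affected by *unknown factors*. Without a WGBS pairing the flag
is unevaluable (`NA`) and never fires. The 2-D density matrix bins
(WGBS, array) beta pairs into 0.02 windows — a 50 × 50 grid whose last
bin is closed so beta = 1 is countable — for contour-style visualisation
by any plotting layer; plotting itself is outside the computational
contract.

## The decision workflow

Factors are evaluated in a fixed order (multimap, repeat, INDEL, CpG SNP,
body SNP, unknown) and reason codes *accumulate* rather than
short-circuit: the accounting of probes affected by multiple factors is
not derivable from first-fired-reason records. A probe is discarded iff
at least one enabled reason fires. Presets encode study types:

| preset | departs from `default` by | rationale |
|---|---|---|
| `default` | — | drop multimap, repeat, CpG-SNP, type I body-SNP probes; keep INDEL and type II body-SNP probes |
| `population` | drops INDEL probes | unannotated genotype variation across subjects |
| `cell_line` | keeps CpG-SNP probes | genetically homogeneous material |
| `conservative` | drops everything, disables the bisulfite-okay rescue | maximal stringency baseline |

Type II probes tolerate body SNPs because their degenerate body bases
already absorb C/T variation; type I probes demand an exact match, so a
single effective body SNP removes them. Kept-though-flagged probes record
how they survived (`BIS_OKAY`, `TYPE_II_TOLERANT`, `INDEL_TOLERANT`,
`GENOTYPE`, or `POLICY` for any other configured keep), which feeds the
rescue accounting.

When genotype calls for the profiled sample exist, they override the
population-level CpG-SNP decision: homozygous reference at both
dinucleotide positions rescues the probe (the SNP is absent from this
sample); homozygous alternate forces a discard (the interrogated C is
gone and the probe reads unmethylated regardless of methylation);
heterozygous calls leave the default verdict.

Accounting comes in two views: *any-overlap* (each probe counted in every
category it touches) and *unique-category* (each affected probe counted
once, under its single factor or under "multiple factors", with kept
counts reflecting rescues). Partition identities — kept + discarded =
total, high-quality + rescued = kept, per chemistry and overall — are
checked by `verifyAccounting()` on every run, and `arrayAccounting()`
applies the same arithmetic to externally supplied per-chemistry counts,
reporting any internal inconsistency of the supplied table rather than
forcing agreement (the published full-array tables contain one such
transcription-level quirk in the unknown-factors row).

## The synthetic study

`generateFixture()` builds a complete toy study with known ground truth,
so every pipeline stage is testable without external downloads. Design
choices, and what they do and do not emulate:

* **Genome and probes.** Random chromosomes (default 2 × 15 kb); probes
  are genuine 50-mers of that genome, planted in disjoint 110-bp slots so
  each probe carries exactly the factors of its label. Multimapping
  probes are created by duplicating their segment elsewhere. Defaults
  plant roughly 4–5% of probes per category, about 70% type II.
* **Methylation.** True betas come from a two-component Beta mixture with
  modes near 0 and 1, reproducing the genome-wide bimodality (and the
  (0,0)/(1,1) concentration of the 2-D density). WGBS is simulated as
  binomial reads at Poisson coverage (mean 30) — a digital measurement —
  while array betas are true beta plus clamped Gaussian noise — an analog
  one. Background array noise SD is 0.05; corrupted categories add extra
  SD (repeat 0.10, multimap 0.05, CpG-SNP 0.08, body-SNP 0.02), chosen so
  that category effects rank the way the WGBS comparison literature ranks
  them, with repeats worst.
* **CpG-SNP collapse.** Probes homozygous-alternate at the interrogated C
  read a beta near 0.02 in all samples, emulating a destroyed CpG.
* **Unknown factors.** A 0.35–0.5 beta shift directed away from the nearer
  boundary (so clamping cannot swallow it), with the ground-truth flag
  computed from the realized values exactly as the pipeline computes it.
* **Determinism.** One master seed; every track derives a labeled sub-seed,
  so identical seeds give byte-identical files and adding a track does not
  perturb the others.

What the generator does **not** emulate: real human sequence composition
(CpG islands, repeat families with internal structure), linkage between
variants, probe-design biases, batch and normalization effects, or
coverage non-uniformity along the genome. Passing the end-to-end
recovery tests therefore demonstrates that the annotation and decision
machinery is correct, not that any particular biological noise level will
be observed on real arrays.

`expectedDecisions()` restates the keep/discard rules directly from the
ground-truth labels, sharing no code with `applyFilter()`, and serves as
its oracle: on seeded fixtures the two agree on 100% of probes under all
presets.

## Numerical choices and degenerate inputs

* Medians of even-length samples are midpoint means (R's default).
* Per-probe SD uses the sample (n − 1) denominator; probes with fewer
  than two non-missing betas are skipped and listed, not zero-filled.
* Density and histogram binning guards the floating-point boundary with a
  1e-9 nudge so a beta lying exactly on a bin edge lands in the upper bin,
  and the last bin is closed.
* The unknown-factor threshold is a strict inequality at 0.3.
* Pearson correlation is undefined (NA) for categories with fewer than 3
  pairs or zero variance on either axis.
* Duplicate WGBS rows at one position keep the higher-coverage row, with a
  warning.
* Probes on chromosomes absent from the genome are carried through with
  genome-dependent verdicts marked unevaluable rather than dropped;
  unevaluable flags never fire a discard.
* Hit-location lists are capped (default 16) for memory predictability;
  hit *counts* are always exact.

## Problem sizes used by the test suite

The shared unit-test fixture uses 150 probes on a 2 × 15 kb genome; the
end-to-end acceptance fixture uses 2,000 probes on a 4 × 60 kb genome with
100/100/100/80/80/100/80/100/80 planted probes per category; the mapping
oracle is cross-checked on 100 randomized two-chromosome genomes (6 kb +
4 kb) × 100 queries; power and calibration use 100 seeded replicates of
500 + 500 paired betas; the SD comparison uses 1,000 + 1,000 probes over
20 samples. These sizes were chosen so the whole suite exercises every
code path at comfortably interactive runtimes while keeping all
statistical checks well-powered.

## Known limitations

* Exact matching with CpG wildcards is the uniqueness criterion; a
  mismatch-tolerant aligner would flag somewhat more probes as ambiguous.
  Published multimap counts obtained with such aligners are therefore not
  reproduction targets for this package.
* The bisulfite-okay rule is applied on the forward strand only (see
  above); strand-aware rescue of G/A SNPs would rescue more probes at the
  cost of an assumption the defining sources do not state.
* The WGBS pairing is single-sample; cross-sample WGBS designs need
  external aggregation before pairing.
* `verifyProbes()` reports per-probe verdicts (consistent, strand-flipped,
  mismatch, unevaluable) and leaves resolution policy to the caller, since
  manifest sources disagree among themselves about source-sequence
  annotation.
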