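---
title: "ltrscape: models and methods for LTR-retrotransposon annotation, dating and epigenomic profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ltrscape methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Long terminal repeat retrotransposons (LTR-RTs) dominate many plant genomes.
An intact element has a characteristic architecture: two near-identical LTRs
in direct orientation flanking an internal region with Gag and Pol coding
domains, the whole element bracketed by a short (4-6 bp) target site
duplication (TSD) created at insertion, with a canonical `TG...CA`
dinucleotide at the element termini. This architecture makes three analyses
possible without any sequence homology database:

1. **Structural detection** of intact elements from genome sequence alone.
2. **Insertion dating**: the two LTRs are identical at insertion and diverge
   neutrally afterwards, so the inter-LTR divergence K converts to an
   insertion time `T = K / (2 r)` for a substitution rate r.
3. **Solo-LTR detection**: unequal intra-element recombination excises the
   internal region and one LTR, leaving a single LTR still flanked by the
   original TSD; the solo:intact ratio (S/I) indexes element removal.

Around this core, ltrscape classifies elements into the *Copia* and *Gypsy*
superfamilies by the order of the Pol domains (INT-RT-RH versus RT-RH-INT)
and into REXdb-style lineages from annotated domain hits, relates insertions
to gene models (promoter / exon / intron / downstream) and compares the
expression of the associated genes, calls transcriptionally active elements
from read counts (CPM > 1), and builds per-context (CG / CHG / CHH)
DNA-methylation metaprofiles over element bodies and their 2-kb flanks,
stratified by lineage and activity.

## Structural detection

`find_ltr_pairs()` is a seed-and-extend repeat-pair finder:

* exact k-mer seeds (default k = 20) on the forward strand are grouped by
  diagonal and chained (maximum chain gap 50 bp);
* each chain is extended by X-drop (match +1, mismatch -1, drop threshold
  12) into a maximal near-identical block pair;
* pairs are kept when each block is 100-7000 bp long, the inter-block
  distance (the internal region) is 200-15000 bp, and the global pairwise
  identity of the two blocks is at least 0.90. Identity is computed from a
  global alignment (match +1, mismatch -1, gap open 4, gap extend 1) as
  matches / alignment columns including gaps.

Only the forward strand is scanned: both LTRs of one element lie on the same
strand, so a same-strand pair search finds elements on either genomic
strand; element strand is reported as `"."`.

`validate_element()` checks the micro-structures. The X-drop boundary is a
maximum of a random walk and can wander a handful of base pairs when the
flanking sequence is locally similar, so validation refines both LTR
boundaries jointly within a +/-25 bp window. In strict mode (the default)
the refinement is *motif-anchored*: it only considers start offsets at which
**both** LTR copies begin `TG` and end offsets at which both copies end
`CA`, then requires an exact TSD - identical 4-6 bp strings immediately left
of the 5' LTR and right of the 3' LTR, searched longest-first (6, 5, 4).
Requiring the motif in both copies makes a spurious joint anchor
(motif x motif x TSD) vanishingly rare while pinning the boundary exactly on
genuine elements. Lenient mode drops the motif requirement and searches a
+/-10 bp window for the TSD alone. Candidates that overlap an accepted
element are resolved greedily by descending identity, then length
(`allow_nested = TRUE` retains nested candidates).

Elements flush with a sequence end cannot present a TSD and are rejected
with reason `"edge"`.

## Superfamily and lineage classification

The classifier uses only the relative order of INT, RT and RH among the
domains present: consistent with `...INT...RT...RH...` only is *Copia*,
with `...RT...RH...INT...` only is *Gypsy*; fewer than two of the three
domains, or an order consistent with both templates (e.g. RT before RH
alone), is `Unknown`. Lineage labels ride along on the domain-hit table and
are aggregated by majority vote; ties or absent labels give NA, and a label
that is illegal for the assigned superfamily (the nine *Copia* lineages Ale,
Alesia, Angela, Bianca, Ikeros, Ivana, SIRE, TAR, Tork versus the seven
*Gypsy* lineages Athila, CRM, Galadriel, Ogre, Reina, Retand, Tekay) raises
a conflict flag rather than silently overriding either annotation.

## Insertion dating

`ltr_divergence()` globally aligns the two LTRs with the same scoring as the
detector, so identity and K cannot disagree about the alignment. Columns
containing a gap or N are excluded; the raw mismatch fraction p is corrected
with Jukes-Cantor, `K = -(3/4) ln(1 - 4p/3)`. JC69 was chosen because it is
the standard correction for LTR dating, is analytically invertible (which
makes parameter-recovery tests exact), and differs from raw p by less than
0.7 percentage points for K <= 0.10, the regime where nearly all intact
elements live. `estimate_ages(..., correction = "raw")` reproduces
uncorrected behaviour. p >= 0.75 is flagged `saturated` (K undefined);
alignments under 50 usable columns are flagged `short_alignment`.

`insertion_time()` applies `T = K/(2r)` with r = 1.3e-8 substitutions per
site per year by default - the widely used plant synonymous rate - and is
overridable per run because a single rate across species is itself an
approximation. `age_summary()` reports per-genome and per-lineage means,
medians, a 0.1-MY histogram, and the fraction of elements younger than
0.5 MY (the recent-burst statistic).

## Solo LTRs and S/I

`detect_solo_ltrs()` operationalises the solo rule on a repeat-hit table:

* identity with the LTR consensus > 0.80 (exclusive, as stated);
* consensus coverage >= 0.80. Literal 100% coverage would reject nearly
  every real hit, so "covering the consensus" is a configurable coverage
  threshold;
* no intact element (or its internal region) within a 100-bp exclusion
  margin - the distance is not biologically canonical and is exposed as
  `margin`;
* an exact 4-6 bp TSD anchored flush at the hit boundaries, longest-first.
  `tsd_slack` (default 0) allows the TSD to sit a few bases off the
  annotated boundary for imprecise hit tables.

`si_ratio()` returns solo/intact counts and flags the undefined case
(`n_intact = 0`). `correlate_pearson()` provides the Pearson r with the
two-sided t-distribution p-value used for S/I-versus-age comparisons.

## Gene association and expression

`associate_elements_genes()` classifies every (gene, element) pair with >= 1
bp overlap into promoter (5 kb upstream of the TSS, strand-aware), exon,
intron, or downstream (5 kb past the TTS). When one pair overlaps several
region types the precedence is exon > intron > promoter > downstream:
inside-gene evidence outranks flanking evidence. Flanking windows never
extend into the annotated gene body of the same gene. One element may
associate with several genes and vice versa.

`tpm()` is the usual two-step normalisation (length in kb, then library).
`compare_expression()` runs a Welch two-sample t-test of `log2(TPM + 1)`,
group versus the *entire* gene set (group members included - the comparison
is deliberately against the whole-genome distribution), with TPM averaged
across replicates first and no multiple-testing correction (per-category
p-values are reported as-is).

## Activity and methylation

`cpm()` / `call_activity()` implement the strict `mean CPM > 1` rule over
replicates; CPM exactly 1 is silent. `compare_active_silent()` contrasts
element length and age between activity classes with Welch t-tests.

`metaprofile()` bins each feature into 20 fixed 100-bp bins over the
upstream 2 kb, 20 proportionally scaled bins over the body, and 20 bins over
the downstream 2 kb (all half-open, so no cytosine is counted twice within a
region). The per-bin estimator is the *weighted* methylation level,
`sum(meth) / sum(meth + unmeth)` pooled over all cytosines of all features
in the (context x stratum) cell - robust to coverage heterogeneity, unlike a
mean of per-site fractions. Cytosines with coverage below `min_cov`
(default 4; the minimum coverage is not canonical and is exposed as a
parameter) are excluded; bins with no covered cytosine are reported as
missing (NA), never as 0. Features with strand `"-"` are profiled 5'->3';
elements carry strand `"."` and are profiled as-is, with calls from both DNA
strands pooled per position. Features shorter than the body bin count
degrade gracefully (several bins share sites by nearest assignment).

`flank_te_density()` reports, per lineage, the fraction of flanking bases
(both 2-kb flanks pooled, each flank weighted by its own length) covered by
at least one repeat annotation - the statistic used to explain why
pericentromeric lineages (CRM, SIRE, Athila) show flat or inverted flank
methylation. `gene_vs_ltr_profile()` runs the identical binning code over
gene bodies for side-by-side comparison.

## The synthetic-genome simulator

`simulate_genome()` is first-class, tested code: every downstream module is
validated against its planted truth.

What it emulates:

* intact elements as `TSD + 5'LTR + internal + 3'LTR + TSD`, the two LTRs
  being independent per-site mutations of one ancestral LTR with
  substitution probability k/2 each, `k = 2 r T 1e6` for the planted age T.
  The terminal TG/CA dinucleotides are exempt from mutation, and the TSD is
  duplicated exactly - planted elements are, by construction, the
  "perfect micro-structure" class the detector targets;
* internal regions carrying five fixed 30-bp domain sentinels in the
  superfamily-specific order, also emitted as a domain-hit table with
  genomic coordinates and lineage labels, so classification is testable
  without any HMM machinery;
* solo LTRs with exact TSDs; TSD-less solos whose 6-bp flanks are
  constructed to fail every anchored 4/5/6-bp comparison; truncated
  fragments with 30-60% consensus coverage;
* multi-exon genes, optionally with an element embedded in an intron or
  exon or planted within the promoter/downstream window (the
  gene-association ground truth);
* replicate count tables in which active elements receive Poisson counts
  with rates 50-500 and silent elements zero counts, so the CPM > 1 call
  set equals the planted active set exactly;
* per-cytosine calls for the whole genome: contexts derived from the
  sequence on both strands, coverage Poisson(20), methylated counts
  binomial around class means - defaults: silent bodies mCG 0.85 / mCHG
  0.70 / mCHH 0.10, active bodies 0.45 / 0.30 / 0.06, genes and background
  0.05. These are free simulation parameters chosen to mirror the
  qualitative silent > active ordering, not measurements;
* repeat-cluster annotations covering ~85% of the 2-kb flanks of CRM, SIRE
  and Athila elements, emulating pericentromeric nesting.

What it does **not** emulate - and hence what passing tests do not show
about real data: indels and nested-insertion stratigraphy inside elements,
TSD decay, back mutation (substitutions are i.i.d. per site, so the
expected pairwise mismatch is `k - k^2/3`, a second-order discrepancy that
the JC69 correction over-corrects by a similar amount in the K <= 0.10
regime; the age-recovery slope of ~1.03 reflects this), sequencing error,
read-level sampling (counts and cytosine calls are drawn at feature/site
level), bisulfite conversion failure, and genome-scale base-composition
heterogeneity. Placement is random with a 300-bp margin, so elements can
legitimately fall inside another gene's 5-kb windows; association tables on
simulated data therefore contain more pairs than the designed truth.

`shuffle_background()` provides the matched negative control (identical
per-sequence base multiset, no structure).

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GFF3 and CX-report
  I/O converts exactly once at the boundary. This removes the usual
  off-by-one class from interval arithmetic.
* Zero-coverage cytosines are retained on read; coverage filtering happens
  only in `metaprofile()`, so there is a single configurable filter point.
* Canonical transcript = mRNA with the largest summed exon length, tie
  broken by file order.
* Seed k = 20, chain gap 50, X-drop 12, alignment scores (+1, -1, -4 open,
  -1 extend): values of this kind are inherited from standard LTR detectors;
  the specific numbers are this package's own, exposed in `detect_params()`.
* Internal-region bounds 200-15000 bp bracket the intact-element sizes
  typically observed in plant genome surveys (roughly 1-22 kb total
  element length).
* Ties between overlapping candidates: identity first, then length, then
  masking - deterministic and independent of input order.
* Degenerate inputs error early with specific messages (empty FASTA,
  duplicate ids, exon outside mRNA, zero library, zero variance, undefined
  S/I), rather than propagating NaNs.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate on: a 2-Mb genome with 50
planted 1-kb-LTR elements (divergences 0-0.08) plus its shuffled control;
200 dated LTR pairs with ages uniform on 0.1-4 MY; a 30 solo / 10 TSD-less /
20 intact mixture (S/I = 1.5 by construction); 1000 random (element, gene)
association fixtures checked against a brute-force per-base oracle; a 9-Mb
genome with 650 genes of which 3 x 200 carry planted promoter/intron/
downstream insertions with 0.2x / 5x / 0.2x expression multipliers; and a
0.7-Mb genome with 120 elements split evenly into active and silent
methylation classes (>= 50 per stratum). These sizes give each statistical
check comfortable power while keeping a full validation run around a minute
on a single CPU.

## Known limitations

* The detector targets the "perfect micro-structure" class: real elements
  with decayed TSDs or mutated termini require lenient mode and will lack
  TSD evidence.
* One substitution rate is applied to all elements and lineages.
* No PBS/PPT annotation, no protein translation, no profile-HMM search:
  superfamily/lineage calls depend entirely on the supplied domain-hit
  table.
* Solo-LTR detection consumes a repeat-hit table; it does not rediscover
  LTR matches from raw sequence.
* Methylation profiles are descriptive; no differential-methylation test is
  performed beyond the stratum contrasts.
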