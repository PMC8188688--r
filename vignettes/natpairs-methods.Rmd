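---
title: "Methods: natural antisense transcript pairs and their stress response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: natural antisense transcript pairs and their stress response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natpairs)
```

## The problem

A cis-natural antisense transcript (NAT) pair is two transcripts on opposite
strands of the same locus whose genomic intervals overlap. When one member
is a protein-coding mRNA and the other a long noncoding RNA, the noncoding
member is a lncNAT, and such pairs are candidate regulatory units: under a
stress treatment the two members may move together (concordant) or in
opposite directions (discordant). `natpairs` implements the complete desk
analysis: classify transcripts, find and type pairs, call per-accession
differential expression, classify pair responses, partition results across
accessions, and link sense genes to stress-related GO terms.

All internal coordinates are 1-based and inclusive (the GTF convention), so
published coordinate tables can be used verbatim; only BED output converts
to 0-based half-open, at the boundary.

## Transcript classification

`assign_coding()` resolves coding capacity. Coding-potential classifiers
(CPC-like tools, Pfam scans) run upstream of this package; their verdicts
enter as an override table that always wins. Transcripts without an override
fall back to a longest-ORF heuristic on the transcript sequence: coding when
the longest forward-strand reading frame from an ATG through an in-frame
stop (any of the three frames, stop codon counted) reaches `min_orf_codons`
(default 100). The heuristic is a deliberate, declared stand-in — analyses
that care should supply overrides, and the test suite does exactly that so
the heuristic never gates a classification result.

`classify_lnc()` then applies the identification cascade: coding → `mRNA`;
noncoding with spliced length < 200 nt → `excluded_short` (the conventional
lncRNA floor, boundary included — "longer than 200 nt" in the literature is
ambiguous at exactly 200, and the inclusive reading is the common one);
matching a small-RNA exclusion list (miRNA/rRNA/tRNA hits from an upstream
database scan) → `excluded_smallRNA`; remaining long noncoding RNAs are
`lncNAT` when their span overlaps a coding transcript's span by ≥ 1 bp on
the opposite strand, else `lincRNA`. Note the asymmetry, which is
deliberate: lncNAT status needs only 1 bp of antisense overlap with a coding
gene, while *pair* calling (below) uses a 25 nt floor. The two thresholds
answer different questions (location class vs. pair evidence) and are
configured independently.

## The pair scan

`scan_pairs()` emits every unordered opposite-strand pair with span overlap
≥ `min_overlap` (default 25 nt, boundary included; "greater than 25 nt" is
ambiguous at the boundary, and the flag makes either reading a one-character
change). Overlap is computed on genomic spans because published coordinate
tables report spans; `overlap_mode = "exon"` instead requires ≥ `min_overlap`
summed exon-intersection bases, for annotations where intron-only span
overlap would be misleading.

Orientation is decided by containment first — either span containing the
other (ties included) is `enclosed`, which makes the three classes
exhaustive — then by which transcript ends the overlap covers: with the plus
member `[p1, p2]` and minus member `[m1, m2]`,

* `divergent` (head-to-head): `m1 < p1 <= m2 < p2` — the overlap covers
  `p1` (P's 5' end) and `m2` (M's 5' end);
* `convergent` (tail-to-tail): `p1 < m1 <= p2 < m2`.

Two symmetries are worth recording because they are easy to get wrong.
Reflecting all coordinates (`x -> L - x`) *and* flipping strands is the same
configuration seen in a mirror and preserves every class; swapping the two
strands at fixed coordinates turns every 5' end into a 3' end and therefore
swaps divergent with convergent while preserving enclosed. The test suite
asserts both.

The scan itself runs on the interval index of
`GenomicRanges::findOverlaps()`, so cost is near-linear in transcripts plus
overlaps; the test suite holds an all-pairs double loop alongside it as an
independent oracle on hundreds of random annotations.

## Differential expression and pair response

`call_de()` works per accession on a replicated FPKM matrix. The fold change
is the pseudocounted ratio of condition means,
`(mean drought + 1) / (mean control + 1)`: FPKM of 0 is common for
condition-specific transcripts, and without a pseudocount their fold change
is undefined. The p-value comes from a two-group comparison of
`log2(FPKM + 1)` across replicates; the default statistic is limma's
moderated t. This choice matters at the replicate numbers typical of these
designs: with three replicates per condition an unmoderated per-transcript
test has at most four (Welch: as few as two) degrees of freedom, and its
p-values bottom out near 10^-3 even for clean eight-fold effects — too weak
to clear a 1% BH-FDR cutoff among a thousand transcripts. Variance
moderation restores the power the per-transcript test lacks, which is
precisely why it is the field's standard for small-n expression data. A
plain Welch test remains available as `method = "welch"` behind the same
interface.

Calls use the study thresholds: `DEG` at fold change ≥ 2 (either direction)
and BH q ≤ 0.01, `HDEG` at fold change ≥ 4 at the same q; HDEGs are a subset
of DEGs by construction. BH adjustment is applied across all transcripts of
one accession's contrast, mirroring one differential run per accession.

`classify_pair_response()` is deliberately strict: a pair is responsive in
an accession only when *both* members are DEGs there, and responsive pairs
are `concordant_up`, `concordant_down` or `discordant` — exactly one of the
three for any (DEG, DEG) pair.

`venn_partition()` decomposes any per-accession membership into the seven
regions of a three-set Venn diagram (region counts always sum to the union;
each accession's marginal is the sum of its four regions), and
`expand_venn_counts()` inverts published region tallies back into synthetic
membership sets so that unions and marginals can be recomputed rather than
trusted. "Expressed in an accession" (`expressed_in()`) means mean FPKM
≥ 0.1 in at least one condition — the threshold is a package choice, made
explicit and configurable because presence calls are otherwise
irreproducible.

`go_link()` attaches stress-related GO terms (default: response to stress,
response to jasmonic acid stimulus, oxidation reduction, jasmonic acid
mediated signaling pathway) to coding–noncoding pairs via the sense gene's
annotation, flat, exactly as annotated — no GO-graph propagation.
`enrich_hypergeom()` scores study sets with the upper-tail hypergeometric
probability `P(X >= k)` and BH adjustment, skipping terms absent from the
study set.

## The simulator

`simulate_nat_data()` exists so that every stage can be checked against
planted truth. Its defaults encode the targeted study design: three
accessions (Nip, BJ89, BJ278) × control/drought × three replicates. Each
lncRNA draws an orientation from
`enclosed 0.282 / divergent 0.108 / convergent 0.070 / none 0.540`: the
paired share splits 61/23/15 as observed genome-wide in rice, and the 54%
`none` share leaves roughly the lincRNA:lncNAT proportion reported there. A
fraction (default 20%) of leftover coding transcripts form coding–coding
pairs.

Placement is by disjoint loci separated by ≥ 2 kb gaps, so every overlap in
the output is planted, and pair geometry is solved directly from the
orientation inequalities above — planted labels are correct by construction.
Half the loci are mirror-reflected with flipped strands (the
class-preserving symmetry), so the coding member is not always the plus
strand. One geometric constraint follows from the class definitions: a
lncRNA planted *inside* its sense gene equals its own overlap interval, so
enclosed overlaps of that shape are drawn ≥ 200 nt to keep planted lncNATs
above the length floor.

Expression is `2^(baseline + effect + noise)`: baseline log2 FPKM uniform
on [3, 8] (tens to hundreds of FPKM, typical of expressed leaf transcripts),
replicate noise Normal(0, 0.25) on the log2 scale, and planted effects of
±3 log2 units (8-fold) applied under drought in each pair's randomly drawn
responsive accession subset, per its response class
(`concordant_up`/`concordant_down`/`discordant`/`null`, default
0.2/0.2/0.2/0.4). The log-normal noise model is the simplest under which the
log-scale test is well-specified: the simulator's job is to exercise
classification logic, not to emulate read-count mean–variance structure,
library-size effects, isoform-level quantification uncertainty, or
correlated sense/antisense noise. Passing recovery tests therefore
demonstrates the pipeline's logic, not performance on real sequencing data.

Everything is deterministic per seed; the default scale (500 coding + 500
noncoding transcripts on 3 × 2 Mb chromosomes) keeps a 20-seed recovery
study, under which ≥ 95% of planted responsive pairs are recovered with
correct status at a realized FDR well under 5%, within a desk-scale test
run.

## Bench formulas

`water_loss_rate()` is `(FW - CW)/FW` for a detached-leaf drying series;
values where CW exceeds FW are returned negative with a warning rather than
clipped, because they flag weighing noise. `fold_change_ddct()` is
`2^-ΔΔCt` with ΔΔCt = (Ct_target − Ct_ref)_treated − (Ct_target −
Ct_ref)_control; swapping treated and control inverts the result.

## Limitations

* The ORF heuristic is not a coding-potential classifier; real analyses
  should supply override flags from dedicated tools.
* Pair detection is cis only (same-locus overlap); trans-acting antisense
  relationships are out of scope.
* The DE layer assumes FPKM-scale input and log-normal replicate noise; it
  is not a count model, and it will not reproduce the numbers of a
  count-based pipeline on real data.
* GO linkage is flat annotation matching; no term-graph propagation or
  term-size weighting is attempted.
* Genome-scale catalogues from the motivating study (thousands of pairs)
  require the original sequencing data and are not reproducible from the
  shipped fixtures, which cover the published coordinate-level worked
  examples only.
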