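---
title: "Models and methods of the destruxin-responsive miRNA workflow"
author: "dtxmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the destruxin-responsive miRNA workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Injecting destruxin A — an insecticidal cyclodepsipeptide of the
entomopathogenic fungus *Metarhizium anisopliae* — into larvae of the
diamondback moth *Plutella xylostella* perturbs the host's innate immune
signalling, and small regulatory RNAs are among the earliest responders. The
standard experimental design is a small-RNA sequencing time course: one
library from PBS-injected controls and one each at 2, 4 and 6 h
post-injection, followed by read cleaning, genome mapping, annotation,
known- and novel-miRNA identification, a count-based exact test for
differential expression, target-site prediction with several independent
algorithms intersected for confidence, term enrichment of the predicted
targets, and RT-qPCR confirmation of selected miRNAs.

`dtxmir` implements that entire computational chain as ordinary R functions,
and—because raw read archives for such experiments are frequently not
deposited—pairs it with a *simulation module* that generates every input
(genome, annotation, catalog, FASTQ libraries, UTRs, term maps, Ct table)
together with a machine-readable ground-truth ledger. Every stage of the
pipeline can therefore be validated against planted truth, and the
statistical components against independent oracles. The `analysis/` scripts
run the stages in order; `run_pipeline()` runs them in one call.

## Read cleaning

Reads pass a fixed cascade; the first failing filter claims the read, so the
per-filter counters plus the clean total always reconstruct the raw total:

1. **Low quality** — more than 20% of bases below Q20 (Phred+33). Public
   descriptions of such pipelines rarely define "low quality"; this
   operationalization is shared with the generator so planted counts are
   exact.
2. **5′ primer contaminant** — the read begins with an exact ≥8-nt prefix
   of the 5′ adapter.
3. **Missing 3′ adapter / insert** — the 3′ adapter is located as the first
   position (scanning 5′→3′) whose adapter-prefix match is ≥6 nt with ≤1
   mismatch; no such position, or an empty insert, removes the read.
4. **Length** — surviving inserts must be 18–30 nt.

Cleaned inserts are collapsed to unique tags with per-library counts
(ordering: descending total, ties lexicographic), and the read-weighted
length histogram is computed per library.

## Mapping and annotation

Tags are mapped to the genome by **exact, full-length matching on both
strands** (`Biostrings` PDict). Real pipelines allow mismatches with
aligner-specific heuristics; exact matching was chosen because it admits a
brute-force all-positions oracle, which the tests exercise. A tag
overlapping features of several classes receives the highest-priority
class — ncRNA classes (rRNA > tRNA > snRNA > snoRNA > scRNA) above known
miRNA, above repeat, exon, intron — with ≥1 nt overlap, strand-agnostic,
and independent of feature record order.

## Known miRNAs

A tag is assigned to a catalog mature miRNA when positions 1–18 agree
exactly and the lengths differ by at most 2 nt. The 5′ end is held fixed
because it defines the seed; 3′-end variation is the dominant isomiR mode.
Ambiguity resolves to the longest exact match, then lexicographically first
name. miRNAs with raw count below 10 in *all* libraries are removed.

## Folding model and the randomization test

Hairpins are folded by dynamic programming minimizing total **stack
energy**: each stack of adjacent base pairs contributes one energy keyed by
its 5′-side pair (Watson–Crick plus G:U; table in
`inst/extdata/stack_energies.tsv`), isolated pairs contribute nothing, and
hairpin loops are ≥3 nt. This is deliberately *not* a Turner-parameter
reimplementation: the workflow only consumes an MFE threshold, and
correctness is checked against exhaustive enumeration of all structures for
short sequences rather than against published energies. Numerics: energies
are integers in units of 0.1 kcal/mol, so co-optimality comparisons are
exact; among co-optimal structures the fold maximizes pair count and the
traceback prefers 5′-most closing pairs, making the output deterministic.

`randfold_test()` compares the observed MFE with dinucleotide-preserving
(Altschul–Erickson Euler-path) shuffles:
`p = (1 + #{MFE_shuffle ≤ MFE_obs}) / (1 + n_shuffles)`, bounded below by
`1/(n_shuffles+1)`. On i.i.d. sequences p is approximately uniform, which
the acceptance suite checks with a Kolmogorov–Smirnov test.

## Novel miRNA discovery

For each unannotated mapped tag with ≥10 reads, two excisions are folded —
tag as 5p arm (15 nt near flank, 70 nt far flank) and tag as 3p arm — and
the better-folding one is kept. The candidate is trimmed to the span
pairing with the mature arm and refolded; the *simplified score* is
`log2(tag count) + 1` if ≥60% of mature positions are paired (a plausible
star arm) and `log2(tag count) − 1` otherwise. Acceptance requires score
> 1, randomization p < 0.05 and MFE < −19 kcal/mol, all strict.

Two numerical choices matter here. First, the randomization p is computed
on the two *untrimmed* windows and Bonferroni-combined
(`min(1, 2·min(p))`): keeping the better of two windows, or shuffling a
structure-selected subsequence, is a selection step that otherwise inflates
the false-positive rate (shuffling the trimmed span gave ≈17% of
unstructured loci p < 0.05). Second, the pipeline uses 99 shuffles per
window (floor 0.01, comfortably below the 0.05 gate); the standalone
`randfold_test()` default is 199.

## Differential expression: the exact count test

Expression is normalized to transcripts per million,
`TPM = count / library clean total × 10⁶`; exact zeros become 0.01 so
ratios stay finite, and miRNAs below 1 TPM in all libraries are ignored.
The fold-change is `log2(TPM_treatment / TPM_control)`.

With `x` the miRNA's count in the control library (total `N1`) and `y` in a
treatment library (total `N2`), the probability of `y` given `x` is

$$p(y\mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!}\,
\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

a proper distribution over `y` for fixed `x`. The lower tail is
$C=\sum_{y'\le y} p(y'\mid x)$, the upper tail
$D=\sum_{y'\ge y} p(y'\mid x) = 1 - C + p(y\mid x)$ (the observed point
mass belongs to both tails), and the two-sided p doubles the smaller tail:
`p = min(1, 2·min(C, D))` — the conventional rule where only the tails are
defined. Implementation is in log space via `lgamma`, safe for counts up to
10⁷, and is checked against direct rational summation and against the
negative-binomial identity `C = pnbinom(y, x+1, 1/(1+N2/N1))`.

Two interface readings deserve a note. `N1`/`N2` are taken as the
*library clean-read totals*; reading them as the miRNA's own normalized
expression would make the ratio self-referential. And the doubled-tail p is
exactly symmetric in `(x, y)` only asymptotically: at small counts the two
orderings can differ by up to twice the shared point mass (at `x=0, y=1`,
equal totals: 1 vs ½), which the property tests assert instead of exact
symmetry.

Multiple testing uses Bonferroni with `m` = miRNAs tested in that
comparison; calls are **up** if corrected p < 0.05 and log2FC ≥ 1, **down**
if ≤ −1, else **ns**. Both cutoffs are configurable
(`pipeline_params()`) and logged.

## Target prediction and the consensus

Three deliberately independent predictors run over every miRNA × UTR pair:

* **Seed scan** — exact matches to the reverse complement of miRNA
  positions 2–8 classified as 8mer / 7mer-m8 / 7mer-A1 / 6mer; 7mer and
  better reported by default.
* **Alignment scan** — Smith–Waterman local alignment of the miRNA reverse
  complement: +5 Watson–Crick, +1 G:U, −4 mismatch, gaps 8 + 2/nt,
  substitution scores doubled at seed positions; threshold 80. A perfect
  22-mer scores 22·5 + 7·5 = 145.
* **Duplex scan** — intermolecular-only hybridization with the same stack
  table, 3 kcal/mol per bulged nt (the order of magnitude real internal
  loops cost), bulges ≤4 nt, threshold −20 kcal/mol, and a reported site
  must engage ≥12 base pairs of the miRNA. The pair floor reflects what a
  −20 kcal/mol threshold is meant to certify — extensive complementarity —
  because under any plausible stack table a chance GC-rich seed helix alone
  approaches −20.

Calls merge into a "spot" when the same miRNA, same transcript and
intervals overlap by ≥1 nt; a spot is **consensus** when all three
predictors contribute. Because pairwise and triple counts are computed on
the same merged components, the triple Venn count can never exceed a
pairwise count. Gene-level aggregation is provided alongside the site-level
table.

## Enrichment and qPCR

Consensus target genes are tested per term with the hypergeometric upper
tail `P(X ≥ k)` against the whole gene set as background (`stats::phyper`;
exact enumeration is the test oracle). Correction defaults to Bonferroni for
consistency with the expression stage; Benjamini–Hochberg is selectable;
significance is corrected p ≤ 0.05.

Relative expression from Ct tables uses 2^−ΔΔCt with a U6-style reference:
ΔCt per replicate, ΔΔCt against the calibrator-group mean, per-replicate RQ
so the SEM is defined on RQ. Group comparisons are one-way ANOVA with
Tukey's HSD; compact letter displays are built by insert-and-absorb at the
0.05 (lowercase) and 0.01 (uppercase) levels, ordered by decreasing group
mean. Letters at the stricter level never separate groups merged at the
looser one.

## The synthetic study: what it emulates, and what it does not

Defaults (`sim_config()`): 4 libraries × 20,000 reads of 50 nt on a
200 kb single-contig genome carrying 60 catalogued and 8 unannotated
precursor loci plus rRNA/tRNA/snRNA/snoRNA/repeat/exon/intron features; 80
UTRs of 200–400 nt; 12 DE miRNAs with |log2FC| = 2 in every treatment;
cleaning failures at 1% (quality), 0.5% (no 3′ adapter), 0.3% (5′
contaminant), 0.7% (short). These sizes are chosen so the full pipeline and
its validation complete in minutes on one core while every filter and test
still has material to act on.

Design features worth knowing:

* **Length structure.** 30% of clean mass is miRNA (mature lengths 21–23,
  mode 22) and 25% piRNA-like 28-mers, so the insert histogram is bimodal
  at 22 and 28 nt as in real insect libraries.
* **Abundance.** Log-uniform expected counts across the catalog, so both
  high-TPM miRNAs and sub-threshold ones (exercising the count-10 filter)
  exist. Counts are multinomial given expected proportions — no
  overdispersion, as there is one library per condition.
* **Mass-balanced DE.** Down-regulated DE miRNAs carry 4× the baseline of
  up-regulated ones, so with the default ±2 design the total miRNA mass is
  equal across libraries and planted per-miRNA fold-changes are not
  confounded by compositional renormalization. Custom unbalanced designs
  incur the usual composition bias.
* **Exact failure planting.** Failure reads are constructed to fail exactly
  their intended filter (and every insert is rejection-checked against the
  adapter-match definition), so cleaning counters equal the ledger exactly,
  not just in expectation.
* **Hairpin realism.** Precursors are mature arm + loop + near-complement
  star *plus a 12-bp lower stem*, as in real pre-miRNAs; without the lower
  stem a hairpin's MFE does not reliably dominate shuffles of its excision
  window.
* **Certified negatives.** Decoy tag loci are resampled until their
  excision windows are unexceptional against their own shuffles, and decoy
  UTR backgrounds until they show no chance strong complementarity to any
  DE miRNA. Without certification a few percent of "negatives" are, in
  truth, chance hairpins or chance strong sites — the labels in the ledger
  must be true for recovery rates to mean anything.

Not emulated: sequencing error and quality-score realism beyond the planted
low-quality class, 5′/3′ isomiR diversity (tags are exact matures),
multi-mapping ambiguity, overdispersion between biological replicates,
repeat-driven mapping artifacts, and any real transcriptome. Passing the
suite therefore demonstrates the *correctness of the computations and
filters against their definitions and planted truth* — not that the
pipeline's biological conclusions on real libraries would be robust to
those phenomena.

## Determinism and seeds

One master seed drives everything; each stage derives an independent
substream (`derive_seed(seed, label)`), so changing one stage's internals
never perturbs another's randomness, and the randomization test derives a
seed per candidate window. Two runs with the same configuration produce
byte-identical report files; the manifest records the seed, a config hash
and per-stage row counts.

## Known limitations

* The exact test has one library per condition by design; with biological
  replicates a dispersion-aware model (e.g. a negative-binomial GLM) is the
  right tool, and this package deliberately does not provide one.
* The simplified candidate score is not a probabilistic read-signature
  model; star-arm reads are neither simulated nor required.
* Exact-match mapping understates mapping rates on divergent or
  polymorphic genomes.
* The predictors are desk-scale simplifications of seed, alignment and
  hybridization approaches; their thresholds are calibrated to the
  simulation's signal/decoy design, not to any organism's validated target
  set.
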