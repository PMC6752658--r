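---
title: "Classifying tandem gene duplicates and measuring their divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tandem gene duplicates and measuring their divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemdiv)
```

## The problem

Plant transcription-factor families — the AP2/ERF family is a canonical
example — expand largely through tandem duplication: unequal crossing-over
leaves near-identical gene copies side by side on a chromosome. When a focal
genome (say, woodland strawberry) is compared with a distant outgroup (say,
*Arabidopsis*), two kinds of tandem duplicates must be distinguished, because
they have had very different amounts of time to diverge:

* **ancestral** tandem duplicates arose before the two lineages split; each
  copy travels with its own outgroup ortholog in the gene tree;
* **lineage-specific** tandem duplicates arose after the split; the copies
  form a focal-species-only clade (a "cluster").

`tandemdiv` implements this classification from standard inputs (GFF3 gene
models, a Newick gene tree with a species map, CDS/protein FASTA, an RPKM
expression matrix, a motif-architecture table, qPCR Ct tables) and then
quantifies how the two classes differ in sequence (Pi, Ka, Ks), structure
(introns, motif arrangements), and expression (detection calls, pair
correlations, ΔΔCt response profiles).

## Tandem detection

Two family genes form a *tandem pair* when they lie on the same chromosome
within `max_pair_distance_bp` (default 100 kb) of each other and are separated
by at most `max_intervening` (default 10) non-family genes. Distance is
measured as the inner gap between the two gene spans (zero when they overlap);
this is conservative and unambiguous for long genes, and a start-to-start
("anchor") mode is available through `analysis_config(distance_mode =
"anchor")` since the convention is not standardized. Strand is ignored —
tandem arrays routinely mix orientations.

Pairs are chained into *repeats* by single linkage: a repeat is a connected
component of the qualifying-pair graph. Single linkage is the weakest
defensible rule and the only one that reproduces observed multi-gene repeats
in which the outermost members are not themselves within pair range. The
detector is validated against a quadratic brute-force implementation on
hundreds of random layouts (up to 200 genes each) in the test suite.

## Duplicate classification

The gene tree is used as a topology only. A *focal cluster* is a maximal
clade whose tips are all focal-species genes, with at least two of them;
genes in clusters are **type I** (lineage-specific expansion), all other
focal genes **type II**. Support values are carried through but not used as a
filter, since no support cutoff is part of the definition; a polytomy mixing
the two species is not a cluster; unrooted input is midpoint-rooted with a
warning because clade maximality depends on the root.

A tandem gene is then classified by its *direct* partners — co-members of its
repeat with which it satisfies the pair rule itself, not merely by chaining:

* **lineage_specific** if some direct partner belongs to its own cluster;
* **ancestral** if it is a type II gene in a repeat, or if some direct
  partner lies outside its cluster;
* **both** when the two conditions hold simultaneously (a cluster gene
  arrayed in tandem with an older neighbour).

Type II membership in a repeat suffices for "ancestral" without requiring the
outgroup orthologs to be arrayed in tandem: outgroup genomes (particularly
post-polyploid ones) are heavily rearranged, so absent ortholog adjacency is
not counter-evidence. `outgroup_tandem_evidence()` applies the same pair rule
to the nearest outgroup orthologs extracted from the tree and attaches the
result as corroborating metadata only.

Gene-level tallies follow inclusion–exclusion (`|LS| + |ANC| − |both|` equals
the number of tandem genes) and the summary reports both gene-level and
repeat-level counts, because reported tallies use both conventions and they
need not agree; the package does not reconcile them silently.

## Sequence divergence: NG86 with Jukes–Cantor correction

Ka/Ks is computed by the Nei–Gojobori (1986) counting method rather than a
maximum-likelihood estimator. The classification analysis uses Ka/Ks only
ordinally (younger lineage-specific pairs versus older ancestral pairs), and
NG86 is exactly specifiable, which lets the test suite verify every count
against an exhaustive independent oracle. The steps:

* per codon, the synonymous site count is one third of the synonymous
  single-nucleotide changes (changes to stop codons count as nonsynonymous);
  synonymous + nonsynonymous sites = 3 exactly, and sites are averaged over
  the two sequences;
* per differing codon pair, synonymous/nonsynonymous differences are averaged
  over all minimal mutational pathways with equal weights (no
  transition/transversion weighting, the classic formulation); pathways
  through stop codons are excluded, and a codon pair whose pathways are all
  blocked is skipped with a log message;
* codon columns containing a gap or ambiguity character in either sequence
  are pairwise-deleted, not globally deleted;
* the proportions `pS = Sd/S`, `pN = Nd/N` receive the Jukes–Cantor
  correction `d = −(3/4)·ln(1 − 4p/3)`; a proportion at or above 3/4 is
  saturated and yields `NA`, as does Ka/Ks when Ks = 0.

Codon alignments are produced by `backtranslate_alignment()`, which maps each
amino-acid column of a protein alignment to the corresponding codon of the
unaligned CDS (protein gaps become `---`), after verifying that the CDS
translates exactly to the ungapped protein row under the standard genetic
code (a terminal stop codon is stripped; translation uses the plain codon
table, with no special-casing of alternative initiator codons). The genetic
code table comes from Biostrings and is injected through one internal chokepoint,
so an alternative code would be a one-line extension.

Pi is the proportion of differing nucleotide sites among sites where neither
row has a gap. Because the reporting convention for "Pi among paralogs" is
ambiguous between per-pair and group-average values, both a per-pair value
(in every divergence row) and class-level means (in the report) are emitted.

## Expression divergence

The detection rule is strict on the stated side: a gene with RPKM *lower
than* 0.3 is not expressed, so detection is `RPKM >= 0.3` and boundary values
are detected. A gene is *expressed* when detected in at least 2 stages, and
*lowly expressed* when RPKM < 1 in at least `ceiling(2/3 × n_stages)` stages
(9 of 13 — ceiling because the rule says "at least two thirds").

Pair correlations are Pearson by default (Spearman via config; the motivating
analyses say only "correlation coefficients", and Pearson is the common
default for RPKM profiles), computed over the stages where **both** genes are
detected, so values in undetected stages can never influence the result (a
property test mutates them arbitrarily and asserts invariance). With fewer
than `min_shared_stages = 3` shared stages the correlation is undefined
rather than spuriously ±1 from two points; this threshold is a package choice
where the source analyses are silent. The correlated flag is `r > 0.5`,
strictly.

Group comparisons are two-sided Welch t-tests; two constant equal groups
return p = 1 with a warning instead of an error. qPCR data are reduced by the
ΔΔCt method: `dCt = Ct_target − Ct_reference` per replicate, `ddCt` against
the control-condition mean, fold change `2^(−ddCt)`, significance from the
replicate-level dCt values. Heatmap export uses `log2(RPKM + 1)`: the +1
offset keeps zeros finite and is stated here because "log2 relative RPKM"
conventions vary; raw RPKM values are never transformed before thresholding
or correlation.

RPKM values are used as supplied, with no re-normalization before the log2
display transform; the thresholds operate on the raw scale, so any
re-normalization belongs upstream of this package.

## The simulator and what passing tests mean

`simulate_family()` generates the full study design forward in time — a
duplication history on a two-species tree rather than a draw from a
birth–death prior, because the ancestral/lineage-specific counts must be
controllable directly. Ancestral tandem pairs are planted before the split
and inherited adjacently by both genomes; lineage-specific pairs duplicate
adjacently on the focal branch; dispersed duplicates move to distant
positions; filler genes appear between tandem copies (0–3, inside a gap drawn
uniformly from 200–20,000 bp, which guarantees the pair rule at default
thresholds) and across the genome at
`intervening_density_per_10kb`. Family loci are spaced at least 300 kb apart
so unrelated loci can never chain into one repeat — without this the
clean-simulation recovery property would fail for accidental reasons
unrelated to the method.

Sequence evolution runs a per-codon continuous-time process: synonymous
single-nucleotide changes at rate 1, nonsynonymous at rate ω, stop-creating
changes rejected. Because each codon's synonymous site count is exactly one
third of its synonymous changes, synonymous divergence accrues at rate 3 per
unit time, so running for `target_ks / 3` gives an expected NG86 Ks equal to
the target — the calibration is analytic, not fitted. Defaults: orthologs at
Ks 0.8, ancestral pairs at 1.2, lineage-specific pairs at 0.2, ω 0.2
throughout — a deep eudicot-scale split with strongly purifying selection,
young within-lineage duplicates, and no positive selection.

Expression profiles default to 13 stages, mirroring a full reproductive
developmental series. Correlated pairs mix log-scale deviations
(`z2 = r·z1 + sqrt(1−r²)·ε`, sd 0.2) around a flat per-locus baseline; with a
flat baseline the expected Pearson correlation equals the target, whereas a
stage-varying shared baseline would add common signal and push the realized
correlation above it — recovery tests therefore use flat baselines, and the
class targets default to 0.5 for both classes (about half of tandem pairs
correlated above 0.5, with no class difference, matching the observed pattern
in reproductive tissues).

What the simulator deliberately omits: indels in coding sequence (so
back-translation alignment recovery is exact by construction),
transition/transversion bias and codon-usage bias (NG86 assumes neither),
RNA-seq read-level noise (expression is lognormal around the baseline), and
intergenic re-annotation (intervening genes come solely from the supplied
annotation). Passing recovery tests therefore demonstrates correctness of the
implementation under the model's own assumptions, not robustness to
real-data violations of them — on real data, alignment error, rate variation
and annotation gaps all add error the tests do not measure.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (GFF3 convention); strand `.`
  is accepted as unknown; unanchored scaffolds are ingested like chromosomes.
* The species map is a required sidecar table rather than parsed from tip
  labels — label-parsing conventions are too fragile to bake in.
* Ka/Ks is `NA` when Ks = 0 (identical or purely nonsynonymously diverged
  pairs), and saturation (`p ≥ 3/4`) yields `NA` rather than infinity.
* Motif "arrangement" differences are multiset symmetric differences:
  presence/absence and copy number count, order does not (an order-only
  rearrangement without content change scores 0; none is attested in the
  motivating data).
* `percent()` rounds to one decimal; empty denominators give `NA`, never 0 or
  an error, so empty classes propagate visibly through reports.
* Repeat and cluster identifiers are assigned in deterministic sorted order,
  making reports byte-identical across reruns and invariant to input
  shuffling and tree ladderization.

## Problem sizes used in validation

The shipped test-suite checks run at: 500 random layouts (10–200 genes) for the
detector-versus-oracle equivalence; 1,000 random 20-codon pairs for the NG86
pathway counts; 200 replicate 500-codon pairs for Ks/ω recovery (tolerance
±0.05 around Ks 0.3 and ω 0.2); one clean 50-locus simulation for exact
label recovery; 500 simulated pairs for correlation recovery (±0.05 around
0.8). These sizes give stable means at comfortable margins while keeping the
default test run fast.

## Limitations

* NG86 underestimates divergence when transition/transversion bias is strong;
  for publication-grade absolute Ka/Ks on real data, cross-check with a
  likelihood method (an external yn00/codeml result table can be joined
  against `divergence_table()` output by gene pair).
* Classification inherits all error in the input tree; there is no support
  filtering by default, so poorly resolved clusters propagate as-is.
* Ortholog assignment is nearest-outgroup-tip extraction from the tree, not a
  full orthology inference.
* The expression rules assume RPKM-like abundance units; the 0.3/1.0
  thresholds are not meaningful for raw counts or TPM without rescaling.
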