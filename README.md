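# tandemdiv

Divergence analysis of tandem gene-family duplicates in R.

Gene families in plant genomes — transcription-factor families such as
AP2/ERF especially — expand largely by tandem duplication. Given gene models
for a focal genome and an outgroup, plus a gene tree of the family,
`tandemdiv` answers three questions a molecular evolutionist asks of such a
family:

1. **Which family genes sit in tandem arrays?** Two family genes are a tandem
   pair when they lie within 100 kb on one chromosome with at most 10
   non-family genes between them; qualifying pairs are chained by single
   linkage into maximal repeats.
2. **Which duplicates are old and which are young?** Using the gene tree,
   genes in maximal focal-species-only clades are *type I* (lineage-specific
   expansion), the rest *type II*. A tandem gene is **lineage-specific** when
   a direct tandem partner shares its clade, **ancestral** when it is type II
   in a repeat or arrayed with a gene outside its clade, and **both** when
   both hold — with tandem arrangement of the outgroup orthologs attached as
   corroborating evidence.
3. **How far have the copies diverged?** Per duplicate pair: nucleotide
   divergence Pi; Ka and Ks by the Nei–Gojobori (1986) counting method —
   fractional synonymous/nonsynonymous site counts, equal-weight averaging of
   minimal mutational pathways for the difference counts, Jukes–Cantor
   correction d = −(3/4)·ln(1 − 4p/3), with Ka/Ks > 1 indicating positive and
   < 1 purifying selection; intron-count and motif-architecture differences;
   expression calls (detected at RPKM ≥ 0.3, lowly expressed below 1 in ≥ 2/3
   of stages), detection-masked Pearson pair correlations (correlated when
   r > 0.5), Welch t-tests between classes, and 2^(−ΔΔCt) qPCR fold changes.

A forward-in-time two-species simulator (`simulate_family()`) with fully
known duplication history, sequence divergence, and expression correlations
makes every stage testable without any external data.

## Worked example

Simulate a family with known history, run the whole pipeline, and print the
report:

```r
library(tandemdiv)

sim <- simulate_family(simulation_params(n_ancestral_genes = 20, rng_seed = 7))
report <- run_pipeline(list(
  gff_focal         = sim$genes_focal,
  family_ids        = sim$genes_focal$gene_id[sim$genes_focal$is_family_member],
  tree              = sim$tree,
  species_map       = sim$species_map,
  expression        = sim$expression,
  gff_outgroup      = sim$genes_outgroup,
  motifs            = sim$motifs,
  cds               = sim$cds,
  protein_alignment = sim$proteins
))
report
#> <tandemdiv_report>
#>   family genes: 37; tandem: 29 (78.4%) in 13 repeats (mean size 2.23)
#>   type I: 18 in 9 clusters (48.6% of family); type II: 19
#>   lineage-specific: 16; ancestral: 19; both: 6 (inclusion-exclusion: 29)
#>   low expression [tandem_or_clustered]: 1/30 (3.3%)
#>   low expression [other]: 0/7 (0.0%)
#>   low expression [lineage_specific_tandem]: 0/16 (0.0%)
#>   low expression [ancestral_tandem]: 1/19 (5.3%)
#>   low-expression fold (tandem/clustered vs other): NA
#>   divergence [ancestral]: n=12, Pi=0.3010, Ka=0.2341, Ks=1.2267, Ka/Ks=0.194
#>   divergence [lineage_specific]: n=8, Pi=0.0663, Ka=0.0384, Ks=0.1719, Ka/Ks=0.231
#>   correlated pairs [ancestral]: 3/12 (25.0%)
#>   correlated pairs [lineage_specific]: 3/8 (37.5%)
```

Reading the report: 29 of the 37 family genes sit in tandem repeats; the
classifier splits them into 16 lineage-specific and 19 ancestral tandem genes
(6 belonging to both, so 16 + 19 − 6 = 29). The divergence rows show the
expected age contrast — lineage-specific pairs were simulated at Ks 0.2 and
measure 0.17, ancestral pairs at Ks 1.2 measure 1.23, with Ka/Ks near the
simulated ω = 0.2 for both. The low-expression fold is `NA` here because the
"other" group has a 0% rate (empty denominators are reported as NA, never
silently dropped).

Every element is a tibble you can work with directly — `report$labels`,
`report$divergence`, `report$correlations` — plus broom-style accessors
(`tidy(report)` for the per-gene table, `glance(report)` for one-row
headline numbers) and plots (`autoplot(report)` for per-class divergence
boxplots, `autoplot(report, type = "expression")` or
`plot_expression_heatmap()` for a log2(RPKM+1) heatmap).

All inputs can equally be file paths (GFF3, Newick, TSV, FASTA) or a single
YAML config file; `run_pipeline()` reads whichever it is given and records a
manifest with input checksums and per-stage status.

Individual stages are exported on their own: `detect_tandem_repeats()`,
`find_focal_clusters()`, `assign_gene_types()`, `classify_tandem_genes()`,
`backtranslate_alignment()`, `ng86_ka_ks()`, `pairwise_pi()`,
`call_expression()`, `pair_correlation()`, `ddct_fold_change()`, and friends.

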