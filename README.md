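# kleptoscreen

Screening and expression-analysis toolkit for draft genomes of
kleptoplastic sea slugs (Sacoglossa) — animals that sequester algal
chloroplasts and keep them photosynthetically active. Assemblies of such
genomes mix nuclear contigs with bacterial contamination, mitochondrial
and kleptoplast DNA, and occasionally genuinely horizontally acquired
genes; their annotation and expression analyses feed a hunt for genes
behind long-term kleptoplast retention. `kleptoscreen` implements that
analysis chain as tested, reusable R functions, plus a deterministic
synthetic-study generator with recorded ground truth so the whole
pipeline can be validated without any external data.

## What it computes

**Alien Index screen.** For each predicted protein, hits are scored by
the normalized bitscore *nbs* = bitscore(best HSP to subject) /
bitscore(query vs itself), clamped to [0, 1], and

> AI = nbs<sub>O</sub> − nbs<sub>M</sub> ∈ [−1, 1],

where *nbs<sub>O</sub>* is the best hit outside Metazoa and
*nbs<sub>M</sub>* the best metazoan hit, skipping Placobranchoidea (the
query's own sublineage). Contigs are flagged as bacterial contamination
when min AI > 0 over their genes or ≥ half their genes have AI > 0.1;
HGT candidates need AI > 0.1, ≥ 50 database subjects, and a clean home
contig. Organelle contigs are flagged independently (≥ 2 hits at
e ≤ 1e−5 to organellar proteins).

**Gene-model curation.** Masked/unmasked annotation-run merge under
explicit rescue rules (zero overlap with masked genes and classified
repeats, BLASTp e < 1e−3, no exon > 50% simple repeats), evidence tables
(expression / orthology / functional annotation), the ≥ 2-sources
high-confidence gene set, and summary statistics with half-up rounded
percentages.

**Differential expression.** Length-scaled TPM, an expression filter on
per-stage means, TMM normalization, a negative-binomial conditional
exact test with a double-tail reject region (juvenile vs pooled unfed
stages), trended moment dispersion, BH FDR, and DEG calls at
log<sub>2</sub>FC > 2 and FDR < 0.01.

**Comparative candidates.** Orthogroup presence/absence classes across
four kleptoplastic species and an outgroup, candidate genes =
kleptoplast-specific orthogroup members ∩ DEGs, hypergeometric term
enrichment with BH, longest-isoform selection, and domain-span
extraction (350–650 aa window over required profiles).

**Tree utilities.** Support-annotated Newick IO, midpoint rooting,
collapsing of branches with support < 95, and an automated donor-clade
check for HGT candidates.

## Worked example

```r
library(kleptoscreen)

fx  <- simulateStudy(fixtureConfig(seed = 1))   # synthetic study + truth
res <- runAll(fx)                               # five-stage pipeline

res$screen$ai
#> AlienIndexResults with 246 genes
#>   recipient: Metazoa  skip: Placobranchoidea
#>   AI range: [-0.950, 0.987]; 16 gene(s) with AI > 0

res$screen$contaminant_contigs
#> [1] "contig_0041" "contig_0042" "contig_0043" "contig_0044" "contig_0045"

res$screen$hgt_candidates
#>          gene_id nbsO      nbsM        AI n_hits  top_outgroup_subject
#> 1 Ecla0008g00500 0.76 0.2615385 0.4984615     68 vir_Ecla0008g00500_01

res$trees$verdicts
#>          gene_id supported                                          reason
#> 1 Ecla0008g00500      TRUE query nests within donor-lineage leaves with...

length(res$express$degs)
#> [1] 48

head(res$compare$enrichment, 1)
#>         term k  K n   N       pvalue          fdr
#> 1 GO:0002376 9 10 9 196 1.024249e-14 3.072746e-14
```

Reading: the AI screen recovered all five spiked contaminant contigs
(their genes have near-1 normalized bitscores to bacteria and no real
metazoan support); the one spiked HGT gene passes the candidate filter
(AI ≈ 0.50 with 68 subjects) and its phylogeny check (it nests inside a
viral clade after midpoint rooting and support collapsing); 48 of the 50
spiked fed-stage genes are called differentially expressed; and the
immune-like term planted in the kleptoplast-specific candidates comes
out as the top enriched category.

Every threshold above is a `runConfig()` parameter, and real inputs can
replace the synthetic ones through the readers (`readHomologyHits`,
`readGeneModels`, `readCountMatrix`, `readOrthogroups`,
`readSupportTree`, ...). A thin CLI (`exec/kleptoscreen`) wraps
`simulate` and `run-all` for shell use.

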