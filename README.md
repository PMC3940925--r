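# paralomiR

Many microRNA genes occur as *paralogous families*: two or more hairpin
precursors at distinct genomic loci whose **major mature form is identical
in sequence**. Small-RNA reads from that shared mature form map equally
well to every family member, so standard read counting cannot say *which*
precursor is actually transcribed in a given tissue — a real obstacle for
anyone studying the transcriptional regulation of an individual miRNA gene
(e.g. miR-128-1 vs miR-128-2, or miR-194-1 vs miR-194-2 in mouse).

paralomiR discriminates the members of such families from miRBase-style
read-mapping tables (precursor, read start position within the hairpin,
read count, tissue), exploiting the fact that each hairpin is processed
into a major/minor duplex and the **minor (passenger) form is
member-specific** even when the major form is shared. The evidence that a
particular member drives expression in a tissue is that its major and its
own minor form are *jointly* enriched there. Corroborating screens use
host-gene and genomic-cluster co-expression, tissue-pattern metrics and
qPCR statistics.

## The statistics at the core

For an entity-by-tissue read-count matrix, with `M_ij` the reads of miRNA
*i* in tissue *j*, `T_i = Σ_j M_ij`, and `Q_j` the fraction of all reads
falling in tissue *j*, the tissue specificity of *i* in *j* is the
standardised excess over proportional allocation (binomial sampling null):

    Z_ij = (M_ij − T_i·Q_j) / sqrt(T_i·Q_j·(1 − Q_j)),   clamped at 0,
    Z_ij = 0 whenever M_ij = 0

and the **tissue coexpression score** of a major/minor pair in tissue *j*
is the product `S_j = Z(major)_j · Z(minor)_j`, which is exactly 0 for any
pair whose minor form has no reads. Pairs are filtered to majors with more
than 50 reads, the top 10 % of all pair-by-tissue scores are flagged, and
sibling minors within a family are screened with the two-sided Fisher
exact test (tissue-j vs elsewhere, minor A vs minor B, p < 0.05). The
member passing both filters is called the family's contributing precursor
in that tissue.

Supporting modules: guide/passenger arm assignment by read-pileup argmax;
reads-per-million normalisation and GenePattern GCT export; arm-usage
ratios and arm-switch detection; genomic clusters at inter-precursor
distance < 5000 bp; Pearson R with exact t-transform p-values (pair,
cluster and host-gene screens); SPM/CTM tissue-pattern calls
(specific: SPM > 0.9; selective: ≥2 tissues with SPM > 0.5 and joint
CTM > 0.9); comparative-CT (ΔΔCt) qPCR quantification with ANOVA + Tukey
HSD preferential-tissue calls; and a seed-reproducible synthetic study
generator with planted ground truth.

## Worked example

Simulate a 15-tissue study (six two-member families, planted
contributors), run the discrimination pipeline, and inspect the calls:

```r
library(paralomiR)
sim  <- simulateReads(simulationConfig(), seed = 42)
sim$reads
#> ReadMappingTable: 581 records, 44 precursors, 15 tissues
#> total reads: 4515077

prof <- assignArms(sim$reads, sim$annotations)
fams <- findFamilies(sim$annotations, prof)
maj  <- quantifyExpression(sim$reads, prof, "major")
mino <- quantifyExpression(sim$reads, prof, "minor")
prec <- quantifyExpression(sim$reads, prof, "precursor")
rpt  <- discriminationReport(fams, maj, mino, universe = prec)

top <- rpt[rpt$passes, c("family_id", "precursor_id", "tissue",
                         "Z_major", "Z_minor", "score")]
head(top[order(-top$score), ], 3)
#>         family_id precursor_id tissue  Z_major  Z_minor    score
#> 157 sim-miR-F6-3p sim-mir-F6-1   lung 171.9018 57.11028 9817.359
#> 146 sim-miR-F5-5p sim-mir-F5-2   skin 168.7827 55.12253 9303.729
#> 179 sim-miR-F6-3p sim-mir-F6-2 testis 182.8294 49.56166 9061.328

subset(contributorCalls(rpt), !unresolved & family_id == "sim-miR-F1-5p")
#>       family_id      tissue  contributor unresolved reason
#> 1 sim-miR-F1-5p bone_marrow sim-mir-F1-1      FALSE
#> 5 sim-miR-F1-5p       heart sim-mir-F1-2      FALSE
```

Reading the output: the shared mature `sim-miR-F1-5p` is produced by both
family members, but the joint major/minor enrichment attributes its bone
marrow expression to `sim-mir-F1-1` and its heart expression to
`sim-mir-F1-2` — which matches the generator's planted truth
(`sim$truth$contributors`). `Z_major ≈ 170` and `Z_minor ≈ 50` say major
and minor reads are both far above their proportional-allocation
expectation in that tissue; the score is their product.

A shell front end over the same functions is provided in
`inst/cli/paralomir.R` (subcommands `simulate`, `quantify`, `arm-ratios`,
`families`, `clusters`, `discriminate`, `correlate`, `pattern`, `qpcr`).

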