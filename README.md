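# ttnenrich

Regional enrichment analysis of titin-truncating variants (TTNtv) in dilated
cardiomyopathy (DCM), with nonsense-mediated decay (NMD) efficiency and
phenotype batteries.

## The problem

TTNtv — nonsense and frameshift variants in the giant sarcomere gene *TTN* —
are the most common genetic cause of DCM, yet they also occur in ~1% of the
general population. Where a truncation falls matters: variants in exons
constitutively spliced into the cardiac transcript (percent-spliced-in,
PSI > 0.9) are the pathogenic ones, and the A-band region is reportedly
enriched. But the A-band also contains exon 327, by far the longest *TTN*
exon (17,106 bp of the 107,976 bp coding sequence), so raw variant counts
confound regional biology with sheer coding length.

`ttnenrich` answers "where do disease variants *really* cluster?" by
length-normalized enrichment. For each region *r* of the meta-transcript
(Z-disk, proximal/distal I-band, A-band split around exon 327, M-band),
restricted to high-PSI exons:

- expected count  b_r = N · L_r / L_total   (L_r = high-PSI coding length)
- enrichment degree  c_r = a_r / b_r        (a_r = observed count)
- exact two-sided binomial test of a_r against p₀ = L_r / L_total
- case/control comparison: ratio of degrees c_case / c_control, with a
  two-proportion test of a_case/N_case vs a_control/N_control

The NMD module quantifies decay escape from RNA-seq allelic imbalance:
AI deviation = max(0, 0.5 − altered-allele frequency), 0 meaning no decay and
0.5 complete decay of the mutant allele, and relates it to the PTC-to-intron
distance (nucleotides from a premature termination codon to the next
downstream junction — long distances hinder NMD). A phenotype module compares
clinical indicators between exon-327 and other carriers with a
normality-gated test battery, and a seeded synthetic-cohort generator makes
every stage testable without any download.

## Worked example

The packaged inputs (a synthetic exon table with exact regional lengths, the
titin partition, and the published per-region counts: 570 DCM probands, 957
gnomAD carriers) reproduce the full reference analysis:

```r
library(ttnenrich)
tab <- reproduce_enrichment_table()
render_enrichment_table(tab)[c(1, 6, 10), c("region", "observed_dcm",
    "expected_dcm", "degree_dcm", "p_dcm", "degree_gnomad", "ratio", "p_ratio")]
#>      region observed_dcm expected_dcm degree_dcm p_dcm degree_gnomad ratio p_ratio
#> 1    Z-disk           17        44.22        .38 <.001           .44   .86    .729
#> 6  Exon 327          166       121.39       1.37 <.001           .50  2.76   <.001
#> 10   M-band           34        51.17        .66  .010          1.29   .51   <.001
```

Reading the exon-327 row: 166 DCM truncating variants were observed where
length share alone predicts 121.39 — a 1.37-fold enrichment (exact binomial
p < .001). The same region is depleted in gnomAD (degree .50), so the
case/control enrichment ratio is 2.76. The Z-disk and M-band are
significantly *under*-represented in DCM.

Annotating your own variants:

```r
ttn <- ttn_model()
ann <- annotate_variants(
  data.frame(study_id = "demo", protein_hgvs = "p.Ser4228LeufsTer23"),
  ttn, ttn_partition())
ann[c("ptc_residue", "exon_number", "region", "ptc_to_intron_distance")]
#>   ptc_residue exon_number          region ptc_to_intron_distance
#> 1        4250          49 Proximal I-band                     82
```

(The frameshift's stop sits at residue 4228 + 23 − 1 = 4250; exon and
distance here reflect the packaged *synthetic* per-exon boundaries — regional
aggregates are exact, individual exon borders are not published.)

A full synthetic study (cohort → annotation → enrichment → NMD → phenotype)
runs end to end with:

```r
study <- simulate_study(sim_config(n_probands = 570), ttn, ttn_partition(), seed = 1)
res <- run_pipeline(variants = study$variants, expression = study$expression,
                    phenotypes = study$phenotypes, out_dir = "out")
```

or from a shell via `inst/cli/ttn-enrich.R run|simulate`.

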