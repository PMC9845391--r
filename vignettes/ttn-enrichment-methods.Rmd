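---
title: "Methods: length-normalized TTNtv enrichment, NMD efficiency, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: length-normalized TTNtv enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttnenrich)
```

This vignette is the package's account of its statistical model, the
conventions it had to fix where the field's practice is ambiguous, and what
the synthetic-data generator does and does not emulate.

## The enrichment model

The unit of analysis is a truncating variant's premature termination codon
(PTC) placed on the *TTN* meta-transcript, the inferred transcript containing
all 363 exons, in 1-based coding (cDNA) coordinates. Genomic coordinates and
strand never enter: every quantity of interest — PTC position, exon length,
PTC-to-intron distance — is cDNA-level, so exon tables are consumed already
projected to coding space.

Because exons differentially spliced out of the adult left-ventricle
transcript cannot cause disease through that transcript, both the variant
counts and the coding lengths are restricted to *constitutive* exons,
percent-spliced-in (PSI) strictly greater than 0.9 (exons with PSI ≤ 0.9 are
removed; the threshold is an argument everywhere it is used). On the packaged
model this leaves 80,325 of 107,976 coding nucleotides.

For a cohort of $N$ variants and a region $r$ with high-PSI coding length
$L_r$ out of $L$ total:

$$b_r = N \frac{L_r}{L}, \qquad c_r = \frac{a_r}{b_r},$$

where $a_r$ is the observed count and $c_r$ the *enrichment degree* — 1 under
uniform placement per coding nucleotide. Two conservation laws hold by
construction and are property-tested: $\sum_r b_r = N$ over the disjoint
partition, and the length-weighted mean degree $\sum_r (L_r/L)\,c_r = 1$
exactly. Roll-up regions (I-band, A-band, A-band-minus-exon-327) are always
recomputed from summed counts and lengths, never by averaging member degrees.

Each region's count is tested against its length share with the exact
two-sided binomial test under the minimum-likelihood convention (sum of all
outcome probabilities not exceeding the observed outcome's). The suite checks
this against an exhaustive enumeration oracle on every instance with
$n \le 12$.

### Case versus control

Both cohorts share the same length normalization, so the ratio of degrees
equals the ratio of per-cohort proportions,
$(a_\text{case}/N_\text{case})/(a_\text{ctrl}/N_\text{ctrl})$, and is always
computed from unrounded degrees. The accompanying p-value is a
continuity-corrected two-proportion chi-square test (`prop.test`). This is a
deliberate, isolated choice: it is the procedure that reproduces the
published reference values for every region (e.g., Z-disk .729, I-band .021,
A-band .442), where a one-sample binomial of the case count against the
control proportion does not (.646, .002, .317). The comparison sits behind
`compare_cohorts()` so an alternative can be swapped in.

### Per-study intervals

Forest-plot intervals for a single region use the exact Clopper–Pearson
binomial interval on the study's observed proportion, divided by the region's
length fraction. The interval method is a package choice — exactness matters
at per-study counts of a handful — not a reproduction of any published
procedure.

## PTC resolution and distances

HGVS protein changes are parsed for the truncating grammar only: nonsense
(`p.Arg5Ter`) resolves to the anchor residue; frameshift `p.XnYfsTerK`
resolves to residue $n + K - 1$, since the first changed residue counts as
position 1 of the shifted frame. This counting convention is *validated*, not
assumed: the suite reconstructs descriptions from random coding sequences
carrying random 1–2 nt deletions/duplications and checks the resolved stop
against a translate-and-scan oracle. Frameshifts without a stated `TerK`
cannot pin the PTC and are excluded with a machine-readable reason, as are
splice-class descriptions (kept only in the NMD stage, where published
allelic-imbalance values cannot always be tied to a parseable description).

Two conventions the printed medians cannot disambiguate were fixed as
defaults and made configurable:

- **PTC anchor.** The PTC position is the *first* nucleotide of the stop
  codon, `3(r-1)+1`, because the stalled ribosome is positioned at the
  codon start; `distance_anchor = "last"` gives the 2-nt-shorter variant and
  the choice is recorded in the annotation's metadata.
- **Junction straddle.** A stop codon spanning an exon junction belongs to
  the exon containing its first nucleotide.

PTC-to-intron distance is `cds_end(exon) − ptc_position`. A PTC in the final
coding exon has no downstream junction: the distance is `NA`, an NMD-escape
flag is set, and such variants drop out of distance correlations rather than
receiving an arbitrary large value.

## NMD efficiency from allelic imbalance

For a heterozygous carrier, the altered-allele frequency (AF) in RNA-seq
reads is ~0.5 without decay and falls toward 0 under efficient NMD. The AI
deviation is $\max(0, 0.5 - \text{AF})$ — clamped because sampling noise can
push AF above 0.5, and a negative "deviation" has no decay interpretation.
Group comparisons of AI deviation are rank-based by design (the quantity is
bounded and zero-inflated): a Mann–Whitney U test, exact at small samples —
via the exact distribution without ties, or full enumeration of group
assignments with midranks when ties are present — and the tie-corrected
normal approximation with continuity correction when either group exceeds 20.

Correlations (distance vs deviation, deviation vs outcome age) are
*normality-gated*: Shapiro–Wilk on each vector at $\alpha_\text{gate} = 0.05$
(a package default; the gate level is configurable), Pearson when both pass,
Spearman otherwise, with the branch taken recorded in the result. The same
gate drives the phenotype battery's t-test/Mann–Whitney choice. The classic
equal-variance t-test is the default (Welch optional) to match conventional
clinical reporting. Quartiles use the linear-interpolation definition
(R type 7); the quantile method is stated because published medians (IQR)
never say which was used. NYHA class is handled numerically — fractional
published medians such as 3.25 imply numeric treatment — and family history
by Fisher's exact test, checked in the suite against hypergeometric
enumeration for all tables with totals ≤ 40.

## The packaged reference inputs

The meta-transcript's exact per-exon boundaries live in supplements that are
not reproduced here, so the packaged exon table
(`ttn_exon_fixture_path()`, *synthetic* in name and content) encodes what is
published exactly and distributes the rest evenly: 363 exons; total coding
length 107,976 nt; exon 327 = 17,106 nt; high-PSI regional lengths 6,232 /
6,912 / 6,171 / 22,749 / 17,106 / 13,944 / 7,211 nt (total 80,325); and the
27,651 nt of differentially spliced sequence placed as PSI-0.2 exons in the
middle I-band (exons 51–219), between the proximal (29–50) and distal
(220–252) I-band regions. Region aggregates, fractions, expected counts,
degrees and all tests computed from this table are exact; *individual* exon
assignments of a user variant are not, and a user-supplied full exon table is
accepted anywhere the packaged one is used. The packaged per-region counts
(570 DCM probands, 957 gnomAD carriers) complete the reference analysis of
`reproduce_enrichment_table()`.

Report rendering follows the reference table's style: degrees and ratios to
two decimals without a leading zero, p-values to three decimals, printing
`"<.001"` for anything below .001 (this threshold reproduces the published
cells, including two between .0002 and .001).

## What the simulator emulates

`simulate_study()` generates the three tables the analysis consumes, under a
single seed, with full determinism (base R's generator; identical seeds give
identical tables).

**Cohort placement.** Each proband's PTC lands on a codon start drawn
region-by-region. `region_multipliers` are *target enrichment degrees*: a
named region receives probability mass equal to its length share times the
configured degree, and unnamed regions share the remaining mass in
proportion to length. With this parameterization the generator's true degree
in a named region equals the configured value exactly — the property the
recovery studies check (a plain "weight × length, renormalize" rule would
make the realized degree depend on the region's length share: a weight of
1.37 on exon 327 would realize only ≈1.27). Configurations whose named mass
reaches 1 are rejected. Sampling is uniform over codons within a region, so
exon boundaries falling mid-codon cost at most one codon of weight per exon
— negligible against the recovery tolerances.

**Expression.** True AI deviation follows a logistic decay in PTC-to-intron
distance $d$: $0.5\,\mathrm{logit}^{-1}((d_0 - d)/s)$ with defaults
$d_0 = 500$ nt and $s = 300$ nt — the simplest monotone bounded link
consistent with distance-hindered NMD, chosen (not fitted: no published
values exist) so that exon-327-scale distances (~10⁴ nt) give essentially no
decay while typical short-exon distances (~10² nt) give substantial decay.
Observed AF is $0.5 - \text{truth}$ plus Gaussian noise (sd 0.05, a
moderate-coverage read-sampling scale), clamped to $[0,1]$. Final-exon PTCs
escape decay entirely.

**Phenotypes.** Indicators are drawn from fixed distributions typical of a
TTNtv-DCM cohort (diagnosis ≈ 40 y, LVEF ≈ 20%, LVEDD ≈ 65 mm, NYHA skewed
III–IV), with an optional linear effect of true deviation on endpoint age
and per-field missingness. With all effects zero the groups are exchangeable
— the null under which the suite calibrates the gated battery's type-I error
to [0.03, 0.07] at α = 0.05.

**What it does not emulate.** Raw reads and allele-specific read counts
(inputs are per-variant frequencies); coverage- or purity-dependent AF bias;
between-study heterogeneity in variant ascertainment; real per-case RNA-seq
values. Passing the simulation-based checks therefore demonstrates that the
*pipeline* recovers known structure, not that real-data statistics computed
from unpublished per-case tables are reproduced — those are out of reach at
package scale and are deliberately not asserted.

## Problem sizes and numerical choices

The recovery studies run at the analysis's own scale: 500 seeded cohorts of
570 probands for degree recovery (mean within 0.05 of truth), 100 cohorts of
500 for the distance–deviation correlation (negative at p < .01 in ≥ 95% of
replicates), 1,000 null replicates for type-I calibration. Exact-test oracles
enumerate every instance up to n = 12 (binomial) and margins totalling 40
(Fisher). Degenerate inputs are first-class: empty cohorts flow through with
zero counts, a zero control degree flags the ratio as undefined rather than
dividing, constant vectors refuse correlation, and groups under two
observations report summaries without p-values.

## Known limitations

- Variants must already be described on the meta-transcript; cross-transcript
  conversion is out of scope.
- The HGVS grammar covered is the truncating subset (nonsense, `fsTerK`,
  splice flagging); delins/extension/intronic notation is not parsed.
- Odds ratios are not estimable from the packaged inputs (per-study totals
  without TTNtv are unavailable) and are not attempted.
- Per-exon boundaries other than exon 327's are synthetic placements; any
  analysis hinging on exact single-exon borders needs a user-supplied table.
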