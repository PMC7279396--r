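# ampedit

Genotyping of CRISPR/Cas9 editing outcomes in diploid transformants from
Sanger-sequenced amplicon subclones — built for the dual-guide hairy-root
setting (e.g. *Eucalyptus grandis* roots transformed with a Cas9 + two-sgRNA
construct), where each transgenic root carries an unknown mixture of edited
alleles and the questions are: *which edits, which alleles, knock-out or
knock-down, and what mutation spectrum?*

It is aimed at plant molecular biologists genotyping T0 transformants by PCR
subcloning (and/or direct degenerate sequencing) and phenotyping edited
lines by FTIR spectroscopy.

## What it does

* **Locus model** — wild-type amplicon + CDS + two guide sites, anchored by
  protospacer/NGG-PAM match; the SpCas9 blunt cut sits 3 bp 5′ of the PAM.
  Guides overlapped by known SNPs are flagged (editing may fail on that
  haplotype).
* **Edit calling** — global Needleman–Wunsch alignment with affine gaps
  (match +2, mismatch −3, open −10, extend −1) of each subclone read;
  gap/mismatch runs become deletion, insertion and substitution events,
  left-aligned (VCF convention) and attributed to guides by a ±10 bp window
  around each cut; reads with identical normalized event sets collapse into
  alleles with summed support.
* **Consequences & genotypes** — mutant CDS translation: frameshift
  (net coding indel ∤ 3), premature stop, amino-acid change; significance
  hierarchy *frameshift > ≥15 bp in-frame indel > less significant*. Plant
  classes: WT/WT, homozygous (A1/A1), biallelic (A1/A2), monoallelic
  (WT/A1), chimera (A1/A2/A3…, with or without WT); putative knock-out iff
  no WT allele remains.
* **Tables** — editing rates (edited subclones / total; per-guide and
  dual-guide rates; expected large inter-guide deletions), mutation spectra
  (small ≤15 bp vs large >15 bp × deletion/insertion/substitution),
  prevalent edition types, consequence classes — one-decimal percentages
  over the denominators these tables conventionally use.
* **Simulator** — ground-truthed Cas9 outcome generator (per-guide events,
  inter-guide dropout, plant-class composition, multinomial subclone
  sampling, off-window Sanger/PCR noise) plus a two-group FTIR spectrum
  generator with planted discriminant bands.
* **Degenerate-trace decoder** — inverts the two-allele superposition of a
  direct-sequencing read (IUPAC consensus) for single-indel alleles anchored
  at the cuts; ≥3-base positions are rejected as chimeric; concordance with
  subcloning is tabulated per plant.
* **FTIR / PLS-DA** — baseline correction (iterative polynomial or
  rubberband), unit-area normalization, offset; two-group PLS-DA by NIPALS
  with per-component explained X-variance; discriminant wavenumbers from
  loading quantiles, annotated against a bundled cell-wall band table.

## Worked example

The package bundles two fully synthetic subclone cohorts
(`example_cohort("CCR1")`, `example_cohort("IAA9A")`) whose compositions
match the published outcome tables of its two demonstration genes. The full
pipeline in three lines:

```r
library(ampedit)
cc  <- example_cohort("CCR1")                     # 24 plants, 278 subclones
res <- genotype_cohort(cc$reads_by_plant, cc$locus)
res$rates
#>  total_subclones edited_n edited_pct sg1_n sg1_pct sg2_n sg2_pct sg12_n sg12_pct dropout_n dropout_pct
#>              278       89         32    46    51.7    65      73     22     24.7        19        21.3
res$prevalent
#>        signature  n pct    description
#>  del:221-302(82) 14  16 82 bp deletion
#>   del:295-295(1) 11  12  1 bp deletion
res$genotypes$per_class
#>             g_class  n pct_total pct_edited
#>               WT_WT  0       0.0         NA
#>          homozygous  0       0.0        0.0
#>           biallelic  0       0.0        0.0
#>         monoallelic 10      41.7       41.7
#>  chimera_all_edited  1       4.2        4.2
#>     chimera_with_WT 13      54.2       54.2
```

Reading: 89 of 278 sequenced subclones (32.0%) carry edits; 51.7% of edited
subclones are edited at the sgRNA1 position, 73.0% at sgRNA2, 24.7% at
both, and 21.3% carry the expected large deletion spanning both cut sites.
The most prevalent edition type is an 82 bp inter-guide deletion (14
subclones, 16%). All 24 plants are edited, but every plant except one
chimera retains a WT allele — so this cohort is dominated by putative
knock-downs, not knock-outs.

The numbered scripts under `analysis/` run the same workflow end to end
(simulate → genotype → decode → FTIR) and write their tables under
`results/`.

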