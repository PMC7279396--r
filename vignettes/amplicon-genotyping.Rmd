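---
title: "Genotyping CRISPR editing outcomes from amplicon subclones"
author: "ampedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping CRISPR editing outcomes from amplicon subclones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## The problem

Dual-guide CRISPR/Cas9 editing of a diploid transformant (for instance an
*Agrobacterium rhizogenes* hairy root of a tree species, where each root
derives from one transformed cell) produces a mixture of allele sequences at
the target locus: unedited wild type, small NHEJ indels and substitutions at
either cut site, and large deletions dropping the whole inter-guide
interval. Because Cas9 keeps cutting across cell lineages, a single root can
carry three or more distinct alleles (a chimera). The practical genotyping
questions are: which edits does each subclone carry, which alleles does each
plant carry, is the plant a putative knock-out (no wild-type allele left) or
only a knock-down, and what does the mutation spectrum look like across the
cohort. `ampedit` implements that pipeline end to end, together with a
ground-truthed simulator, a decoder for degenerate direct-sequencing traces,
and an FTIR/PLS-DA chemotype screen for phenotyping edited lines.

## The locus model

A `target_locus` holds the wild-type amplicon, its CDS geometry and two
guide sites. Guides are anchored by exact protospacer match on their stated
strand with a canonical SpCas9 NGG PAM immediately 3'; the blunt cut sits
3 bp 5' of the PAM, so a sense guide starting at 0-based position $s$ cuts
at bond $s + 17$ and an antisense site at $s$ cuts at bond $s + 3$.
Internally all coordinates are 0-based half-open; reports are 1-based
closed. Each guide carries an *attribution window* of ±10 bp around its cut
(configurable): an event is attributed to a guide when it overlaps that
window. No window is dictated by the underlying chemistry; ±10 bp covers
the placement uncertainty of left-normalized NHEJ indels at a blunt cut
while keeping the two guides' windows disjoint down to 21 bp spacing.
`flag_guide_snps()` reports guides whose protospacer or PAM is hit by a
known polymorphism — on such a haplotype editing may simply not occur.

## The simulator defines the study conditions

`simulate_allele()` draws one editing outcome per guide (small/large
deletion, small/large insertion, small substitution run, or nothing), or —
with probability `p_dropout`, default 0.20 — a single deletion spanning both
cut sites plus 0–5 bp of flanking jitter. Small event sizes are
geometric(0.5) truncated at 15 bp; large events are uniform on 16–100 bp;
substitutions are 1–3 bp mismatch runs at the cut. These defaults populate
every class the tabulators distinguish and reflect a deletion-dominated NHEJ
spectrum with roughly a fifth to a quarter of edited alleles being
inter-guide dropouts, as dual-guide designs spaced 50–100 bp are built to
produce. `simulate_plant()` realizes a genotype class (wild type,
homozygous, biallelic, monoallelic, chimera with or without WT) as distinct
allele sequences; `sample_subclones()` draws reads with optional per-base
substitution noise, injected only at positions mapping outside the guide
windows so that planted truth stays unambiguous inside them — the
false-positive behaviour of the caller *outside* windows is then cleanly
attributable to the noise channel. Randomness is stream-split per plant
(a per-plant seed derived from the cohort seed), so a plant's data does not
depend on cohort ordering; a fixed seed makes whole cohorts bit-reproducible.

What the simulator does not emulate: chromatogram waveforms and quality
decay, PCR chimeras and polymerase slippage, and microhomology-biased
repair. Passing round-trip tests therefore demonstrates the caller inverts
the simulator's generative model exactly, not that every artifact of real
Sanger data is handled; the noise channel covers the dominant one
(isolated miscalls/PCR substitutions), which the off-window filter absorbs.

## Edit calling

Reads are aligned to the amplicon by global Needleman–Wunsch with affine
gaps (match +2, mismatch −3, open −10, extend −1) — appropriate because
subclones are near-full-length amplicon copies. Unrelated sequences are
rejected by an identity floor of 60% computed *outside the edit zone* (the
guide-window span padded by 120 bp, the largest event extent handled): there
an amplicon clone is essentially identical to the reference, while a random
sequence scores ~25–45% once gap columns count against identity. Computing
identity only over aligned columns would let an unrelated sequence buy
spurious identity with scattered micro-gaps, which is why the zone-masked
definition is used.

Gap runs become deletion/insertion events, maximal mismatch runs become
single substitution events (one event regardless of run length), and indels
are left-aligned to their 5'-most equivalent placement — the VCF convention,
chosen so that alternative gap placements of the same physical edit collapse
to one canonical event. Events outside both windows are diverted to a
diagnostics channel rather than the allele definition (they are
Sanger/PCR-attributable); reads with identical normalized event sets merge
into alleles with summed support. `min_support` defaults to 1 — singleton
alleles are counted, as is conventional when up to ~22 colonies are
sequenced per plant — but can be raised to guard against PCR artifacts.

## Protein consequences and genotype classes

The mutant CDS is rebuilt by applying events while tracking coding bases
(insertions strictly inside a segment count as coding; event portions
outside the CDS are excluded from `net_indel` and flagged `partial_cds`),
then translated with the standard code. Frameshift means net coding indel
not divisible by 3; a premature stop is a stop codon earlier than the
wild-type stop. Significance follows the hierarchy frameshift > large
in-frame indel > less significant. Two size constants coexist deliberately:
the spectrum's size classes split at ≤15/>15 bp while the consequence
table's "large indel" uses ≥15 bp, so a 15-bp deletion is a *small*
spectrum event yet a *significant* protein-level indel; both conventions
are kept as independent constants because published outcome tables use both.

Plant classification is a total function of the allele inventory: chimera
(≥3 distinct alleles, with or without WT), biallelic (exactly two edited,
no WT), monoallelic (one edited + WT), homozygous (one edited, no WT),
wild type. Homozygosity is only asserted when the single edited allele has
at least `homozygote_min = 5` subclones; below that the call keeps the
homozygous shape but is annotated `homozygous_unconfirmed`, because an
under-sampled biallelic or monoallelic plant is observationally identical —
subclone counts are the only evidence available. Knock-out status is purely
WT-presence: any remaining WT allele makes the plant at best a knock-down.

Tables report percentages at one decimal, rounding half away from zero, and
give class percentages over both denominators in use (all transgenic
plants, and edited plants only). Spectrum and consequence tables weight
allele rows by subclone support, since published editing-outcome tables
count sequenced clones; an allele carrying several event kinds increments
several spectrum categories, so category percentages may sum above 100.

## Degenerate-trace decoding

Direct sequencing of a two-allele amplicon superposes both traces; after
the first length-discordant edit the frames drift apart and base calls
become IUPAC codes. `make_degenerate()` models exactly that (position-wise
superposition on each allele's own coordinate walk), and
`decode_degenerate()` inverts it for the tractable regime of at most one
indel per allele anchored near a cut site: positions needing three or more
superposed bases mark a chimera (undecodable); otherwise the consensus
length pins the longer allele's net shift, candidate indels (size ≤ 120 bp,
interval overlapping a guide window) are pruned by a vectorized base-set
containment test, insertion content is inferred from the partner allele,
and a surviving pair must re-superpose to the consensus *exactly* and be
unique. Two honest limitations: pairs in which both alleles carry
insertions leave the inserted bases under-determined and return
undecodable; and a three-allele mixture in which two alleles share a net
shift can be exactly consistent with a two-allele interpretation — no
decoder can flag those from the trace alone, which is the deep reason
subcloning outperforms direct-sequence decoding on chimeras. Reverse-primer
traces anchor at the amplicon's 3' end and are decoded against the mirrored
locus, then mapped back. `compare_methods()` tabulates per-plant concordance
with subcloning (same / partial / different / not compared).

## FTIR preprocessing and PLS-DA

Spectra live on the 400–4000 cm⁻¹ grid at 4 cm⁻¹ steps (901 points);
analysis is restricted to 800–4000 cm⁻¹. Preprocessing per spectrum:
baseline correction, normalization to unit integrated absorbance (so
between-sample comparisons are scale-free), then offset correction to zero
minimum. The default baseline is an iterative order-2 polynomial that
refits on points at or below the running fit: measured on simulated
cohorts, the convex-hull rubberband (also available) follows genuine
negative-going group differences wherever they fall near the envelope's
minima and absorbed roughly 60% of a planted band's between-group contrast,
which directly degrades discriminant-band recovery; the polynomial removes
only broad curvature and preserves band contrasts.

`fit_plsda()` is a NIPALS PLS2 of the column-centered absorbance matrix on
centered one-hot group indicators, deflating X and Y per component
(tolerance 1e-10, 500-iteration cap), reporting per-component X-variance.
Discriminant wavenumbers are those whose absolute loading on component 1 or
2 exceeds the 0.95 quantile of that component's loading magnitudes,
contiguous runs merged to their extremum; direction is the sign of the
group-median spectral difference, and bands falling in the bundled
cell-wall assignment table (lignin aromatic skeleton near 1510 and
1595 cm⁻¹, polysaccharide C–O near 1030 cm⁻¹, and so on) are annotated. A
quantile rule always selects its top fraction, even on noise; what
distinguishes real bands is reproducibility, so `stable_bands()` reports
wavenumbers selected in *every* reseeded cohort — empty for null cohorts.
Explained-variance figures from real root spectra are not reproducible from
simulation, so the FTIR claims validated here are property-based: planted
bands at five times the noise SD are recovered within two grid steps, null
cohorts yield no reseed-stable bands.

## Validation scale and bundled cohorts

`example_cohort()` builds two fully synthetic subclone cohorts whose
composition matches the published outcome tables for the package's two
demonstration genes (278 subclones / 24 plants with 43 edition types;
95 subclones / 13 plants with 20 types), constructed as designed event sets
applied to synthetic loci with 64 bp and 54 bp guide spacing. Running the
pipeline on them reproduces the published percentages at one-decimal
rounding, which pins every tabulation convention above. The validation
suite additionally uses 1,000 simulated reads for the caller round trip,
500 plants × 15 subclones for genotype-class recovery (misses are checked
against the inclusion–exclusion probability of never sampling some allele),
200 WT × single-indel pairs for the decoder, and 20 reseeded spectral
cohorts (10 vs 10 samples) for band recovery — sizes at which every check
runs comfortably on a laptop while the binomial error on each rate is well
inside its acceptance margin.

The numbered scripts under `analysis/` narrate the same workflow on the
bundled and simulated data and write their tables under `results/`; the
package functions are the interface for anything programmatic.

## Known limitations

Base qualities and AB1 chromatograms are not parsed; NGS amplicon modes are
out of scope. The decoder handles two-allele, single-indel traces only.
The consequence model does not predict protein function or NMD. The FTIR
module assumes two groups and a common wavenumber grid, and cross-validated
classification error is deliberately not reported — band recovery and
reproducibility are the claims the simulator can support.
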