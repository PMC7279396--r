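Package: ampedit
Title: CRISPR Amplicon Editing Outcome Analysis for Diploid Transformants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotyping of CRISPR/Cas9 editing outcomes in diploid
    transformants from Sanger-sequenced amplicon subclones. Models a dual-guide
    target locus, calls and left-normalizes indel/substitution events against
    the wild-type amplicon by global affine-gap alignment, collapses subclones
    into alleles, classifies protein consequences (frameshift, premature stop,
    large in-frame indels) and plant-level genotypes (homozygous, biallelic,
    monoallelic, chimera; putative knock-out vs knock-down), and tabulates
    editing rates and mutation spectra. Includes a ground-truthed simulator of
    Cas9 editing outcomes and two-group FTIR spectra, a decoder for degenerate
    direct-sequencing consensus reads of two-allele amplicons, and a NIPALS
    PLS-DA with discriminant-wavenumber selection for chemotype screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
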