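#!/usr/bin/env Rscript
# Compare direct-sequencing degenerate-trace decoding with subcloning:
# simulate plants of each genotype class, superpose their alleles into
# degenerate consensus reads, decode, and tabulate concordance.

library(ampedit)

loc <- synthetic_locus(seed = 42L)
set.seed(20260103L)
params <- edit_params(p_dropout = 0.25, p_small_sub = 0)

classes <- rep(c("WT_WT", "homozygous", "biallelic", "monoallelic",
                 "chimera_all_edited"), times = c(4, 8, 16, 8, 4))
decoded <- list(); subcloning <- list(); truth_class <- character()
for (i in seq_along(classes)) {
  pid <- sprintf("plant%02d", i)
  pl <- simulate_plant(loc, classes[i], params)
  # the trace superposes whatever templates the plant carries (a homozygous
  # or WT/WT plant contributes the same template twice)
  templates <- if (length(pl$alleles) == 1) rep(pl$alleles, 2) else unname(pl$alleles)
  decoded[[pid]] <- decode_degenerate(make_degenerate(templates), loc)
  subcloning[[pid]] <- unname(pl$alleles)
  truth_class[pid] <- classes[i]
}

cmp <- compare_methods(decoded, subcloning)
cmp$per_plant$class <- truth_class[cmp$per_plant$plant]
dir.create("results", showWarnings = FALSE)
write.table(cmp$per_plant, "results/decoding_concordance.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

message("Decoding vs subcloning over ", nrow(cmp$per_plant), " plants:")
print(cmp$summary)
print(table(cmp$per_plant$class, cmp$per_plant$concordance))
message("Chimera traces are rejected (not compared); one- and two-allele ",
        "plants mostly decode (pairs where both alleles carry insertions ",
        "stay undecodable); concordance written to ",
        "results/decoding_concordance.tsv.")
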