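#!/usr/bin/env Rscript
# Run the full genotyping pipeline (align -> call -> collapse -> classify ->
# tabulate) on the two bundled table-matched cohorts and on the simulated
# cohort from 01_simulate_cohort.R; write the rate, spectrum, consequence
# and genotype-class tables under results/.

library(ampedit)

dir.create("results", showWarnings = FALSE)

for (gene in c("CCR1", "IAA9A")) {
  cc <- example_cohort(gene)
  res <- genotype_cohort(cc$reads_by_plant, cc$locus)
  write_genotype_tables(res, "results", prefix = tolower(gene))
  message(gene, ": ", res$rates$edited_n, "/", res$rates$total_subclones,
          " subclones edited (", res$rates$edited_pct, "%), ",
          res$spectrum$n_types, " edition types; most prevalent: ",
          res$prevalent$description[1], " (", res$prevalent$pct[1], "%); ",
          res$genotypes$edited_n, "/", res$genotypes$total_n,
          " plants edited, ", res$genotypes$ko_n, " putative knock-out / ",
          res$genotypes$kd_n, " knock-down.")
}

# simulated cohort: recovery against truth
if (dir.exists("results/simulated_cohort/reads")) {
  files <- list.files("results/simulated_cohort/reads", full.names = TRUE)
  reads <- lapply(files, read_subclone_fasta)
  names(reads) <- sub("\\.fasta$", "", basename(files))
  loc <- load_locus("results/synthetic_locus.fasta", "results/synthetic_locus.yaml")
  res <- genotype_cohort(reads, loc)
  write_genotype_tables(res, "results", prefix = "simulated")
  truth <- read.delim("results/simulated_cohort/plants.tsv")
  acc <- mean(res$plants$g_class ==
                truth$intended_class[match(res$plants$plant, truth$plant)])
  message("Simulated cohort: genotype class recovered for ",
          round(100 * acc, 1), "% of plants.")
} else {
  message("(run analysis/01_simulate_cohort.R first for the simulated-cohort tables)")
}
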