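#' Run the full genotyping pipeline over one gene's cohort
#'
#' For each plant: align subclone reads, extract and normalize events,
#' collapse into alleles, classify protein consequences and the plant
#' genotype; then aggregate the gene-level editing-rate, mutation-spectrum,
#' consequence and genotype tables.
#'
#' @param reads_by_plant named list (plant id -> data.frame with `read_id`,
#'   `seq`), e.g. from a `sim_cohort` or [read_subclone_fasta()].
#' @param locus a `target_locus`.
#' @param min_support minimum subclone support per allele (default 1).
#' @param homozygote_min support needed to assert homozygosity (default 5).
#' @param filter_outside drop off-window events from allele definitions
#'   (default TRUE).
#' @return list with `calls` (per-subclone), `alleles` (gene-level, with
#'   consequences), `per_plant_alleles`, `plants`, `rates`, `spectrum`,
#'   `consequences`, `genotypes`, `prevalent`, `rejected`.
#' @export
genotype_cohort <- function(reads_by_plant, locus, min_support = 1L,
                            homozygote_min = 5L, filter_outside = TRUE) {
  stopifnot(length(reads_by_plant) > 0, !is.null(names(reads_by_plant)))
  per_plant <- list(); plant_rows <- list(); call_rows <- list()
  rejected <- character(0)
  for (pid in names(reads_by_plant)) {
    called <- call_reads(reads_by_plant[[pid]], locus,
                         filter_outside = filter_outside)
    rejected <- c(rejected, called$rejected)
    al <- collapse_alleles(called, min_support = min_support)
    al <- classify_alleles(al, locus)
    per_plant[[pid]] <- al
    plant_rows[[pid]] <- classify_plant(al, homozygote_min = homozygote_min,
                                        plant_id = pid)
    call_rows[[pid]] <- cbind(plant = pid, called$calls, stringsAsFactors = FALSE)
  }
  alleles <- bind_alleles(per_plant)
  calls <- do.call(rbind, call_rows); rownames(calls) <- NULL
  plants <- do.call(rbind, plant_rows); rownames(plants) <- NULL
  list(calls = calls, alleles = alleles, per_plant_alleles = per_plant,
       plants = plants,
       rates = editing_rates(calls),
       spectrum = mutation_spectrum(alleles),
       consequences = consequence_table(list(gene = alleles)),
       genotypes = genotype_table(plants),
       prevalent = prevalent_types(alleles),
       rejected = rejected)
}

#' Extract reads-by-plant from a simulated cohort
#' @param cohort a `sim_cohort`.
#' @return named list of read data.frames, suitable for [genotype_cohort()].
#' @export
cohort_reads <- function(cohort) {
  out <- lapply(cohort$plants, `[[`, "reads")
  names(out) <- vapply(cohort$plants, `[[`, character(1), "id")
  out
}

#' Write the pipeline's result tables as TSV files
#'
#' @param result a [genotype_cohort()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (e.g. the gene name).
#' @return invisibly, the written paths.
#' @export
write_genotype_tables <- function(result, dir, prefix = "gene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(dir, paste0(prefix, "_", name, ".tsv"))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }
  p1 <- w(result$alleles[, setdiff(names(result$alleles), "low_support")], "alleles")
  p2 <- w(result$plants, "plants")
  p3 <- w(result$rates, "editing_rates")
  p4 <- w(result$consequences, "consequences")
  spec <- data.frame(category = names(result$spectrum$counts),
                     n = unname(result$spectrum$counts),
                     pct = unname(result$spectrum$pct))
  p5 <- w(spec, "mutation_spectrum")
  p6 <- w(result$genotypes$per_class, "genotype_classes")
  invisible(c(p1, p2, p3, p4, p5, p6))
}
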