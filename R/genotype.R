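#' Classify a plant's allele inventory into a genotype class
#'
#' Maps the alleles recovered among one transformant's subclones onto the
#' diploid editing taxonomy:
#' \itemize{
#'   \item `WT_WT`: only the wild-type allele;
#'   \item `homozygous`: one edited allele, no WT (both chromosomes carry the
#'     same edit);
#'   \item `biallelic`: exactly two distinct edited alleles, no WT;
#'   \item `monoallelic`: one edited allele plus WT;
#'   \item `chimera_all_edited`: three or more distinct alleles, all edited;
#'   \item `chimera_with_WT`: three or more distinct alleles including WT.
#' }
#' The knock-out call follows WT presence: `putative_knock_out` when every
#' allele is edited (no WT remains), `putative_knock_down` when a WT allele
#' persists alongside edited ones, `wild_type` otherwise.
#'
#' A single edited allele without WT is only confidently homozygous when its
#' subclone support reaches `homozygote_min`; below that the call keeps the
#' homozygous shape but is annotated `homozygous_unconfirmed`, since an
#' under-sampled biallelic or monoallelic plant looks identical.
#'
#' @param alleles a [collapse_alleles()] result for one plant.
#' @param homozygote_min minimum support to assert homozygosity (default 5).
#' @param plant_id optional plant label.
#' @return one-row data.frame: `plant`, `n_distinct_alleles`, `has_WT`,
#'   `g_class`, `annotation`, `ko_status`, `n_subclones`.
#' @export
classify_plant <- function(alleles, homozygote_min = 5L, plant_id = "plant") {
  if (nrow(alleles) == 0) stop("no subclones: empty allele inventory")
  has_wt <- any(!alleles$edited)
  n_ed <- sum(alleles$edited)
  n <- nrow(alleles)
  annotation <- ""
  g_class <- if (n_ed == 0) "WT_WT"
    else if (n >= 3) { if (has_wt) "chimera_with_WT" else "chimera_all_edited" }
    else if (has_wt) "monoallelic"
    else if (n_ed == 2) "biallelic"
    else {  # single edited allele, no WT observed
      if (alleles$support[alleles$edited] >= homozygote_min) "homozygous"
      else { annotation <- "homozygous_unconfirmed"; "homozygous" }
    }
  ko_status <- if (n_ed == 0) "wild_type"
    else if (has_wt) "putative_knock_down" else "putative_knock_out"
  data.frame(plant = plant_id, n_distinct_alleles = n, has_WT = has_wt,
             g_class = g_class, annotation = annotation, ko_status = ko_status,
             n_subclones = sum(alleles$support), stringsAsFactors = FALSE)
}

#' Genotype-class summary over a cohort of plants
#'
#' Counts plants per genotype class and knock-out status, with two
#' percentage views: over all transgenic plants (the conventional table
#' denominator) and over edited plants (the in-text convention). The
#' edited-plant rate is plants with at least one edited allele over total.
#'
#' @param plants data.frame of [classify_plant()] rows.
#' @return list with `per_class` (data.frame: class, n, pct_total,
#'   pct_edited), `edited_n`, `total_n`, `edited_pct`, `ko_n`, `kd_n`.
#' @export
genotype_table <- function(plants) {
  total <- nrow(plants)
  edited <- sum(plants$g_class != "WT_WT")
  per_class <- do.call(rbind, lapply(PLANT_CLASSES, function(cl) {
    n <- sum(plants$g_class == cl)
    data.frame(g_class = cl, n = n,
               pct_total = pct(n, total),
               pct_edited = if (cl == "WT_WT") NA_real_ else pct(n, edited),
               stringsAsFactors = FALSE)
  }))
  list(per_class = per_class,
       total_n = total, edited_n = edited, edited_pct = pct(edited, total),
       ko_n = sum(plants$ko_status == "putative_knock_out"),
       kd_n = sum(plants$ko_status == "putative_knock_down"))
}
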