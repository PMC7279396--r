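#' Construct a synthetic dual-guide target locus
#'
#' Builds a random amplicon with two planted, validated guide sites (sense
#' sgRNA1, antisense sgRNA2, canonical NGG PAMs) separated by a chosen
#' cut-to-cut span, and a single CDS segment spanning both guides. Used by
#' the simulator, the examples and the test suite as a stand-in reference
#' locus; deterministic for a given seed.
#'
#' @param name locus label.
#' @param amp_len amplicon length in bp.
#' @param span cut-to-cut distance in bp between the two guides.
#' @param cut1 0-based cut position of the first guide.
#' @param seed integer seed (local to this constructor).
#' @param window attribution window half-width in bp.
#' @return a `target_locus`.
#' @export
synthetic_locus <- function(name = "synthLocus", amp_len = 600L, span = 64L,
                            cut1 = 230L, seed = 42L, window = 10L) {
  stopifnot(cut1 > 60, cut1 + span < amp_len - 120)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (attempt in 1:50) {
    ch <- sample(DNA_BASES, amp_len, replace = TRUE)
    s1 <- cut1 - 17L                 # sense guide: cut = site_start + 17
    ch[s1 + 22L] <- "G"; ch[s1 + 23L] <- "G"   # NGG PAM (1-based 22,23 after site)
    s2 <- cut1 + span - 3L           # antisense guide: cut = site_start + 3
    ch[s2 - 2L] <- "C"; ch[s2 - 1L] <- "C"     # CCN on amplicon = NGG on antisense
    # the CDS (0-based 30..570) must be an open reading frame: patch away
    # in-frame stop codons, avoiding the guide-site + PAM footprints
    footprint <- c((s1 + 1L):(s1 + 23L), (s2 - 2L):(s2 + 20L))
    ch <- .purge_stops(ch, cds0 = 30L, cds1 = 570L, footprint = footprint)
    if (is.null(ch)) { ch <- sample(DNA_BASES, amp_len, replace = TRUE); next }
    amp <- paste(ch, collapse = "")
    proto1 <- substr(amp, s1 + 1L, s1 + 20L)
    proto2 <- revcomp(substr(amp, s2 + 1L, s2 + 20L))
    loc <- tryCatch(target_locus(
      name = name, amplicon = amp,
      cds_segments = list(c(30L, 570L)),
      guides = list(list(name = "sg1", protospacer = proto1, strand = "sense"),
                    list(name = "sg2", protospacer = proto2, strand = "antisense")),
      phase = 0L, window = window), error = function(e) NULL)
    if (!is.null(loc)) return(loc)
  }
  stop("failed to construct a valid synthetic locus")
}

# Replace in-frame stop codons in ch[cds0+1 .. cds1] (1-based codon frame
# from cds0) by a single-base change outside `footprint` (1-based positions
# that must not be touched). NULL when a stop codon is locked in place.
.purge_stops <- function(ch, cds0, cds1, footprint) {
  stops <- c("TAA", "TAG", "TGA")
  is_stop <- function(cod) paste(cod, collapse = "") %in% stops
  for (c0 in seq(cds0 + 1L, cds1 - 2L, by = 3L)) {  # 1-based codon starts
    idx <- c0:(c0 + 2L)
    if (!is_stop(ch[idx])) next
    fixed <- FALSE
    for (p in setdiff(idx, footprint)) {
      for (b in setdiff(DNA_BASES, ch[p])) {
        cand <- ch[idx]; cand[match(p, idx)] <- b
        if (!is_stop(cand)) { ch[p] <- b; fixed <- TRUE; break }
      }
      if (fixed) break
    }
    if (!fixed) return(NULL)
  }
  ch
}

#' Simulate a cohort of transformants with known ground truth
#'
#' Draws a genotype class per plant from `class_mix`, realizes each plant's
#' allele set with [simulate_plant()] and samples its subclone reads with
#' [sample_subclones()]. Randomness is stream-split per plant: each plant's
#' alleles and reads are generated under a seed derived from `seed` and the
#' plant index, so a plant's data does not depend on how many plants precede
#' it.
#'
#' @param locus a `target_locus`.
#' @param n_plants number of transformants.
#' @param class_mix named numeric vector of class proportions over
#'   [PLANT_CLASSES] (normalized internally).
#' @param n_subclones subclones sequenced per plant (scalar).
#' @param params an [edit_params()] list.
#' @param noise per-base read error rate outside guide windows.
#' @param chimera_alleles allele count used for chimera classes.
#' @param seed integer cohort seed.
#' @return a `sim_cohort`: list of plants, each with `id`, `intended_class`,
#'   `alleles`, `truth`, `reads`.
#' @export
simulate_cohort <- function(locus, n_plants, class_mix = c(
                              WT_WT = 0.02, homozygous = 0.05, biallelic = 0.25,
                              monoallelic = 0.25, chimera_all_edited = 0.13,
                              chimera_with_WT = 0.30),
                            n_subclones = 15L, params = edit_params(),
                            noise = 0, chimera_alleles = 3L, seed = 1L) {
  stopifnot(all(names(class_mix) %in% PLANT_CLASSES))
  set.seed(seed)
  classes <- sample(names(class_mix), n_plants, replace = TRUE,
                    prob = class_mix / sum(class_mix))
  plants <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    set.seed((seed + i * 10007L) %% 2147483647L)
    pl <- simulate_plant(locus, classes[i], params, n_alleles = chimera_alleles)
    reads <- sample_subclones(pl, n_subclones, locus = locus, noise = noise)
    reads$read_id <- sprintf("plant%03d_sc%02d", i, seq_len(nrow(reads)))
    plants[[i]] <- list(id = sprintf("plant%03d", i), intended_class = classes[i],
                        alleles = pl$alleles, truth = pl$truth, reads = reads)
  }
  structure(list(plants = plants, locus_name = locus$name, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cls <- table(vapply(x$plants, `[[`, character(1), "intended_class"))
  cat("<sim_cohort> ", length(x$plants), " plants (seed ", x$seed, ")\n", sep = "")
  print(cls)
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One subclone FASTA per plant under `dir/reads/`, a ground-truth allele
#' table (`truth.tsv`, one row per planted allele with its event signature)
#' and a plant table (`plants.tsv`).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  truth <- list(); plants <- list()
  for (pl in cohort$plants) {
    seqs <- Biostrings::DNAStringSet(pl$reads$seq)
    names(seqs) <- pl$reads$read_id
    Biostrings::writeXStringSet(seqs, file.path(dir, "reads", paste0(pl$id, ".fasta")))
    truth[[pl$id]] <- data.frame(
      plant = pl$id, allele = names(pl$alleles),
      signature = vapply(pl$truth, event_signature, character(1)),
      stringsAsFactors = FALSE)
    plants[[pl$id]] <- data.frame(plant = pl$id,
                                  intended_class = pl$intended_class,
                                  n_subclones = nrow(pl$reads),
                                  stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, truth), file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, plants), file.path(dir, "plants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read one plant's subclone FASTA
#' @param path FASTA of subclone reads.
#' @return data.frame with `read_id`, `seq`.
#' @export
read_subclone_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  data.frame(read_id = names(seqs), seq = as.character(seqs),
             stringsAsFactors = FALSE, row.names = NULL)
}
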