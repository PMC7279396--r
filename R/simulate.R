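#' Editing-outcome simulation parameters
#'
#' Per-allele generative model of Cas9 outcomes at a dual-guide locus. With
#' probability `p_dropout` the repair joins the two cut ends, deleting the
#' inter-guide interval plus flanking jitter. Otherwise each guide
#' independently acquires one outcome from {small deletion, large deletion,
#' small insertion, large insertion, small substitution, none}. Small event
#' sizes are geometric(`geom_p`) truncated at `small_max`; large sizes are
#' uniform on `large_range`. Substitutions are 1-3 bp mismatch runs at the
#' cut site.
#'
#' Probabilities may be scalars (shared by both guides) or length-2 vectors
#' (per guide). Per-guide probabilities must sum to <= 1.
#'
#' @param p_small_del,p_large_del,p_small_ins,p_large_ins,p_small_sub
#'   per-guide outcome probabilities.
#' @param p_dropout probability of an inter-guide dropout deletion.
#' @param geom_p geometric size parameter for small events.
#' @param small_max small/large class boundary in bp (default 15).
#' @param large_range inclusive size range of large events.
#' @param dropout_jitter max extra bases deleted on each flank of a dropout.
#' @return an `edit_params` list.
#' @export
edit_params <- function(p_small_del = 0.30, p_large_del = 0.04,
                        p_small_ins = 0.06, p_large_ins = 0.02,
                        p_small_sub = 0.08, p_dropout = 0.20,
                        geom_p = 0.5, small_max = 15L,
                        large_range = c(16L, 100L), dropout_jitter = 5L) {
  two <- function(x) if (length(x) == 1) rep(x, 2) else x
  p <- rbind(small_del = two(p_small_del), large_del = two(p_large_del),
             small_ins = two(p_small_ins), large_ins = two(p_large_ins),
             small_sub = two(p_small_sub))
  if (any(p < 0) || any(p > 1) || p_dropout < 0 || p_dropout > 1)
    stop("probabilities must lie in [0, 1]")
  if (any(colSums(p) > 1)) stop("per-guide outcome probabilities must sum to <= 1")
  if (large_range[1] <= small_max) stop("large_range must start above small_max")
  list(p = p, p_dropout = p_dropout, geom_p = geom_p,
       small_max = as.integer(small_max),
       large_range = as.integer(large_range),
       dropout_jitter = as.integer(dropout_jitter))
}

rsize_small <- function(params) {
  min(stats::rgeom(1, params$geom_p) + 1L, params$small_max)
}
rsize_large <- function(params) {
  sample(seq(params$large_range[1], params$large_range[2]), 1L)
}

# One substitution run: 1-3 bases at `start`, each forced different from ref.
rsub_run <- function(ref, start) {
  len <- sample(1:3, 1L)
  orig <- str_chars(substr(ref, start + 1L, start + len))
  alt <- vapply(orig, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  events_df("substitution", start, len, paste(alt, collapse = ""))
}

#' Simulate one edited allele
#'
#' Draws editing outcomes under `params`, applies them at the guide cut
#' positions and returns the edited sequence together with the ground-truth
#' events (left-aligned, reference coordinates, annotated). Large per-guide
#' deletions extend away from the other guide so that simultaneous events at
#' both guides never overlap; the inter-guide dropout is the only event class
#' spanning both cut sites.
#'
#' @param locus a `target_locus`.
#' @param params an [edit_params()] list.
#' @return list with `seq` (character) and `truth` (annotated event
#'   data.frame; zero rows for an unedited allele).
#' @export
simulate_allele <- function(locus, params = edit_params()) {
  ref <- locus$amplicon
  cut1 <- locus$guides[[1]]$cut_pos
  cut2 <- locus$guides[[2]]$cut_pos

  if (stats::runif(1) < params$p_dropout) {
    jl <- if (params$dropout_jitter > 0) sample(0:params$dropout_jitter, 1L) else 0L
    jr <- if (params$dropout_jitter > 0) sample(0:params$dropout_jitter, 1L) else 0L
    s <- max(0L, cut1 - jl)
    e <- min(nchar(ref), cut2 + jr)
    ev <- events_df("deletion", s, e - s, "")
  } else {
    ev <- empty_events()
    for (gi in 1:2) {
      cut <- if (gi == 1) cut1 else cut2
      pr <- params$p[, gi]
      u <- stats::runif(1)
      outcome <- names(pr)[findInterval(u, cumsum(pr)) + 1][1]
      if (is.na(outcome)) next  # no edit at this guide
      e1 <- switch(outcome,
        small_del = {
          k <- rsize_small(params)
          s <- max(0L, cut - k %/% 2L)
          events_df("deletion", s, k, "")
        },
        large_del = {
          k <- rsize_large(params)
          if (gi == 1) {
            s <- max(0L, cut - k)
            events_df("deletion", s, cut - s, "")
          } else {
            k <- min(k, nchar(ref) - cut - 1L)
            events_df("deletion", cut, k, "")
          }
        },
        small_ins = events_df("insertion", cut, 0L, random_dna(rsize_small(params))),
        large_ins = events_df("insertion", cut, 0L, random_dna(rsize_large(params))),
        small_sub = rsub_run(ref, cut)
      )
      ev <- rbind(ev, e1)
    }
  }
  ev <- normalize_events(ev, ref)
  ev <- annotate_events(ev, locus, small_max = params$small_max)
  list(seq = apply_events(ref, ev), truth = ev)
}

#' The six plant genotype classes
#' @format character vector of class labels.
#' @export
PLANT_CLASSES <- c("WT_WT", "homozygous", "biallelic", "monoallelic",
                   "chimera_all_edited", "chimera_with_WT")

#' Simulate the allele composition of one transformant
#'
#' Realizes a requested plant genotype class as a set of distinct allele
#' sequences: `WT_WT` (wild type only), `homozygous` (one edited allele on
#' both chromosomes), `biallelic` (two distinct edited, no WT),
#' `monoallelic` (one edited + WT), `chimera_all_edited` (>= 3 distinct
#' edited, no WT), `chimera_with_WT` (WT + >= 2 distinct edited). Chimeras
#' arise from ongoing editing across cell lineages of a hairy root.
#' Distinctness is enforced by resampling; a class unreachable under `params`
#' (e.g. biallelic with all edit probabilities zero) fails after bounded
#' retries.
#'
#' @param locus a `target_locus`.
#' @param class_spec one of [PLANT_CLASSES].
#' @param params an [edit_params()] list.
#' @param n_alleles allele count for chimera classes (>= 3 including WT when
#'   present; default 3 for `chimera_all_edited`, 3 for `chimera_with_WT`).
#' @param max_tries resampling bound per allele.
#' @return list with `class_spec`, `alleles` (character vector; element names
#'   `"WT"` or `"A1"`, `"A2"`, ...) and `truth` (list of event data.frames,
#'   parallel to `alleles`).
#' @export
simulate_plant <- function(locus, class_spec, params = edit_params(),
                           n_alleles = NULL, max_tries = 200L) {
  class_spec <- match.arg(class_spec, PLANT_CLASSES)
  n_ed <- switch(class_spec,
    WT_WT = 0L, homozygous = 1L, biallelic = 2L, monoallelic = 1L,
    chimera_all_edited = max(3L, n_alleles %||% 3L),
    chimera_with_WT = max(3L, n_alleles %||% 3L) - 1L)
  has_wt <- class_spec %in% c("WT_WT", "monoallelic", "chimera_with_WT")

  seqs <- character(0); truths <- list()
  if (has_wt) { seqs <- c(WT = locus$amplicon); truths <- list(empty_events()) }
  for (k in seq_len(n_ed)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a <- simulate_allele(locus, params)
      if (nrow(a$truth) > 0 && !a$seq %in% seqs) {
        seqs <- c(seqs, stats::setNames(a$seq, paste0("A", k)))
        truths <- c(truths, list(a$truth))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("class '", class_spec, "' unreachable under these edit ",
                  "parameters (", max_tries, " resampling attempts)")
  }
  names(truths) <- names(seqs)
  list(class_spec = class_spec, alleles = seqs, truth = truths)
}

# Piecewise map from edited-sequence coordinates (0-based) to reference
# coordinates; NA for inserted bases. Used to place sequencing noise outside
# the guide windows.
read_to_ref_map <- function(events, ref_len) {
  if (nrow(events) == 0) return(seq_len(ref_len) - 1L)
  ev <- events[order(events$start), , drop = FALSE]
  map <- integer(0); pos <- 0L
  for (i in seq_len(nrow(ev))) {
    if (ev$start[i] > pos) map <- c(map, pos:(ev$start[i] - 1L))
    if (ev$kind[i] == "insertion") map <- c(map, rep(NA_integer_, nchar(ev$alt_seq[i])))
    if (ev$kind[i] == "substitution") map <- c(map, ev$start[i]:(ev$start[i] + ev$ref_span[i] - 1L))
    pos <- ev$start[i] + ev$ref_span[i]
  }
  if (pos < ref_len) map <- c(map, pos:(ref_len - 1L))
  map
}

#' Sample Sanger-sequenced subclone reads from a plant's alleles
#'
#' Each subclone (one cloned PCR amplicon molecule) carries exactly one
#' allele. Reads are drawn with the stated weights (uniform by default). With
#' `noise > 0`, per-base substitution errors emulating Sanger/PCR noise are
#' injected, but only at read positions mapping outside both guide
#' attribution windows so that ground-truth edit attribution stays
#' unambiguous.
#'
#' @param plant a [simulate_plant()] result.
#' @param n number of subclones (>= 1).
#' @param locus the `target_locus` (needed when `noise > 0`).
#' @param weights sampling weight per allele (recycled/normalized).
#' @param noise per-base substitution error rate (default 0).
#' @return data.frame with `read_id`, `allele` (source allele name), `seq`,
#'   `n_errors`, `n_eligible` (bases eligible for noise).
#' @export
sample_subclones <- function(plant, n, locus = NULL, weights = NULL, noise = 0) {
  stopifnot(n >= 1)
  k <- length(plant$alleles)
  w <- if (is.null(weights)) rep(1, k) else rep_len(weights, k)
  idx <- if (k == 1) rep(1L, n) else sample.int(k, n, replace = TRUE, prob = w)
  seqs <- unname(plant$alleles[idx])
  n_err <- integer(n); n_elig <- integer(n)
  if (noise > 0) {
    if (is.null(locus)) stop("locus required to place noise outside guide windows")
    w1 <- guide_window(locus, 1); w2 <- guide_window(locus, 2)
    for (i in seq_len(n)) {
      map <- read_to_ref_map(plant$truth[[idx[i]]], nchar(locus$amplicon))
      eligible <- which(!is.na(map) & !(map >= w1[1] & map < w1[2]) &
                          !(map >= w2[1] & map < w2[2]))
      n_elig[i] <- length(eligible)
      hit <- eligible[stats::runif(length(eligible)) < noise]
      n_err[i] <- length(hit)
      if (length(hit) > 0) {
        ch <- str_chars(seqs[i])
        ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                          character(1))
        seqs[i] <- paste(ch, collapse = "")
      }
    }
  }
  data.frame(read_id = sprintf("%s_sc%02d", plant$class_spec, seq_len(n)),
             allele = names(plant$alleles)[idx], seq = seqs,
             n_errors = n_err, n_eligible = n_elig, stringsAsFactors = FALSE)
}

#' Superpose alleles into a degenerate direct-sequencing consensus
#'
#' Direct Sanger sequencing of a mixed amplicon superposes the traces of all
#' template alleles. Anchored at the read start, each position emits the
#' plain base where all templates agree and the IUPAC code of the base set
#' where they differ; after the first length-discordant event the
#' superposition runs on each allele's own coordinate walk, emulating the
#' frame-shifted double trace. Templates shorter than the consensus stop
#' contributing at their end.
#'
#' @param alleles character vector of >= 2 allele sequences (a homozygous
#'   plant passes the same sequence twice).
#' @param orientation `"forward"` or `"reverse"`; reverse emulates sequencing
#'   from the 3' primer (all templates reverse-complemented first).
#' @return IUPAC consensus string, in read orientation.
#' @export
make_degenerate <- function(alleles, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (length(alleles) < 2) stop("need at least two allele templates")
  if (orientation == "reverse") alleles <- vapply(alleles, revcomp, character(1))
  lens <- nchar(alleles)
  L <- max(lens)
  bits <- integer(L)
  for (a in alleles) {
    b <- base_to_bits(str_chars(a))
    bits[seq_along(b)] <- bitwOr(bits[seq_along(b)], b)
  }
  paste(bits_to_base(bits), collapse = "")
}
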