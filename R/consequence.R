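#' Protein consequence of one allele's events
#'
#' Applies the allele's events to the amplicon while tracking which bases are
#' coding, rebuilds and translates the mutant CDS with the standard genetic
#' code, and classifies the consequence:
#' \itemize{
#'   \item `frameshift`: net coding indel not divisible by 3;
#'   \item `premature_stop`: a stop codon appears in the mutant translation
#'     before the wild-type stop position;
#'   \item `aa_changed`: mutant protein differs from wild type;
#'   \item `significance`: `"significant_frameshift"` >
#'     `"significant_large_indel"` (any indel event of
#'     `large_indel_min` bp or more without a frameshift) >
#'     `"less_significant"` (small in-frame indels, substitutions without a
#'     shift).
#' }
#' `net_indel` counts only the CDS-overlapping portions of each event;
#' alleles with events partly outside the CDS are flagged `partial_cds`.
#' Inserted bases count as coding when the insertion point lies strictly
#' inside a CDS segment. Substitution runs contribute 0 to `net_indel`.
#'
#' The `large_indel_min` threshold (default 15, i.e. ">= 15 bp" counts as
#' large) is deliberately a constant separate from the simulator's
#' small/large size-class boundary (<= 15 small / > 15 large): consequence
#' tables and mutation-spectrum tables conventionally use these two slightly
#' different conventions, so a 15-bp indel is a "small" spectrum event yet a
#' significant large indel at the protein level.
#'
#' @param events event data.frame (may be empty = wild-type allele).
#' @param locus a `target_locus`.
#' @param large_indel_min minimum indel size for the large-indel significance
#'   class (default 15).
#' @return one-row data.frame: `frameshift`, `premature_stop`, `aa_changed`,
#'   `net_indel`, `partial_cds`, `significance`.
#' @export
classify_consequence <- function(events, locus, large_indel_min = 15L) {
  ref <- locus$amplicon
  if (nrow(events) > 0 && any(events$start + events$ref_span > nchar(ref)))
    stop("event extends past the amplicon")

  cds_flag <- logical(nchar(ref))
  for (seg in locus$cds_segments) cds_flag[(seg[1] + 1L):seg[2]] <- TRUE
  in_cds_point <- function(p) {  # 0-based point strictly inside a segment
    any(vapply(locus$cds_segments, function(seg) p > seg[1] && p < seg[2], logical(1)))
  }

  ref_ch <- str_chars(ref)
  mut_ch <- ref_ch; mut_flag <- cds_flag
  net <- 0L; partial <- FALSE
  ev <- events[order(-events$start), , drop = FALSE]  # right-to-left: stable coords
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; L <- ev$ref_span[i]
    if (ev$kind[i] == "substitution") {
      mut_ch[(s + 1L):(s + L)] <- str_chars(ev$alt_seq[i])
      ov <- sum(cds_flag[(s + 1L):(s + L)])
      if (ov > 0 && ov < L) partial <- TRUE
    } else if (ev$kind[i] == "deletion") {
      ov <- sum(cds_flag[(s + 1L):(s + L)])
      net <- net - ov
      if (ov > 0 && ov < L) partial <- TRUE
      keep <- setdiff(seq_along(mut_ch), (s + 1L):(s + L))
      mut_ch <- mut_ch[keep]; mut_flag <- mut_flag[keep]
    } else {  # insertion at point s
      ins <- str_chars(ev$alt_seq[i])
      coding <- in_cds_point(s)
      if (coding) net <- net + length(ins)
      mut_ch <- append(mut_ch, ins, after = s)
      mut_flag <- append(mut_flag, rep(coding, length(ins)), after = s)
    }
  }

  wt_prot <- .translate_cds(ref_ch[cds_flag], locus$phase)
  mut_prot <- .translate_cds(mut_ch[mut_flag], locus$phase)
  wt_stop <- regexpr("*", wt_prot, fixed = TRUE)
  mut_stop <- regexpr("*", mut_prot, fixed = TRUE)
  wt_stop <- if (wt_stop > 0) wt_stop else Inf
  mut_stop <- if (mut_stop > 0) mut_stop else Inf

  frameshift <- (net %% 3L) != 0L
  has_large_indel <- nrow(events) > 0 &&
    any(events$kind %in% c("deletion", "insertion") & events$size >= large_indel_min)
  significance <- if (nrow(events) == 0) "none"
    else if (frameshift) "significant_frameshift"
    else if (has_large_indel) "significant_large_indel"
    else "less_significant"

  data.frame(
    frameshift = frameshift,
    premature_stop = is.finite(mut_stop) && mut_stop < wt_stop,
    aa_changed = !identical(wt_prot, mut_prot),
    net_indel = net,
    partial_cds = partial,
    significance = significance,
    stringsAsFactors = FALSE)
}

.translate_cds <- function(chars, phase) {
  if (phase > 0) chars <- chars[-seq_len(phase)]
  n <- length(chars) - length(chars) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(paste(chars[seq_len(n)], collapse = "")),
    no.init.codon = TRUE))
}

#' Annotate an allele table with protein consequences
#'
#' @param alleles a [collapse_alleles()] result (rows + `events` attribute),
#'   or any data.frame with a `signature` column plus an `events` attribute.
#' @param locus a `target_locus`.
#' @param large_indel_min see [classify_consequence()].
#' @return `alleles` with consequence columns bound on.
#' @export
classify_alleles <- function(alleles, locus, large_indel_min = 15L) {
  ev_map <- attr(alleles, "events")
  cons <- lapply(alleles$signature, function(sig) {
    ev <- if (sig == "WT") empty_events() else ev_map[[sig]]
    if (is.null(ev)) stop("no events recorded for signature ", sig)
    classify_consequence(ev, locus, large_indel_min)
  })
  out <- cbind(alleles, do.call(rbind, cons))
  attr(out, "events") <- ev_map
  out
}

#' Consequence class counts over edited alleles
#'
#' Tabulates, over the edited subclones of a gene (allele rows weighted by
#' their subclone support), the frameshift class, the large in-frame indel
#' class, their union (presumed significant modifications) and the remainder
#' (presumed less significant: small in-frame indels, substitutions without
#' a shift). Percentages are one-decimal, denominated on edited subclones.
#'
#' @param alleles a [classify_alleles()] result (or a list of them, one per
#'   gene, named).
#' @return data.frame with one row per gene.
#' @export
consequence_table <- function(alleles) {
  if (is.data.frame(alleles)) alleles <- list(gene = alleles)
  rows <- lapply(names(alleles), function(gn) {
    al <- alleles[[gn]]
    ed <- al[al$edited, , drop = FALSE]
    n <- sum(ed$support)
    fs <- sum(ed$support[ed$frameshift])
    li_any <- sum(ed$support[vapply(ed$signature, function(sig) {
      ev <- attr(al, "events")[[sig]]
      any(ev$kind %in% c("deletion", "insertion") & ev$size >= 15L)
    }, logical(1))])
    sig <- sum(ed$support[ed$significance %in%
                            c("significant_frameshift", "significant_large_indel")])
    data.frame(
      gene = gn, edited_clones = n,
      frameshift_n = fs, frameshift_pct = pct(fs, n),
      ge15_indel_n = li_any, ge15_indel_pct = pct(li_any, n),
      significant_n = sig, significant_pct = pct(sig, n),
      less_significant_n = n - sig, less_significant_pct = pct(n - sig, n),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
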