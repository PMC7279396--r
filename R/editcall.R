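#' Align a subclone read globally to the wild-type amplicon
#'
#' Needleman-Wunsch global alignment with affine gap penalties (match +2,
#' mismatch -3, gap open -10, gap extend -1), suited to Sanger reads that are
#' near-full-length clones of the amplicon. Reads are screened by their
#' identity outside the edit zone -- the region around and between the two
#' guide windows (padded by `zone_margin`) where Cas9 events live: outside
#' that zone an amplicon clone must match the reference near-perfectly
#' (gap columns count against identity, so an unrelated sequence cannot buy
#' identity with scattered micro-gaps). Reads below `min_identity` there are
#' rejected as unalignable; reads far from the amplicon length are rejected
#' up front.
#'
#' @param read read sequence (DNA string).
#' @param locus a `target_locus`.
#' @param min_identity identity floor outside the edit zone (default 0.6).
#' @param zone_margin bp added on each side of the guide-window span when
#'   masking the edit zone (default 120, the largest event extent handled).
#' @return list with `status` (`"aligned"` or `"unalignable"`), aligned
#'   strings `read_aln`/`ref_aln` (with `-` gaps), `score` and `identity`.
#' @export
align_read <- function(read, locus, min_identity = 0.6, zone_margin = 120L) {
  ref <- locus$amplicon
  if (nchar(read) < 0.3 * nchar(ref) || nchar(read) > 2.0 * nchar(ref))
    return(list(status = "unalignable", reason = "length out of range",
                identity = NA_real_))
  aln <- Biostrings::pairwiseAlignment(
    read, ref, type = "global",
    substitutionMatrix = .sub_matrix(), gapOpening = 10, gapExtension = 1)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- str_chars(p); sc <- str_chars(s)
  # reference coordinate (0-based) of each column (insertions inherit the
  # coordinate of the next reference base)
  ref_at <- cumsum(sc != "-") - as.integer(sc != "-")
  zone <- c(guide_window(locus, 1)[1] - zone_margin,
            guide_window(locus, 2)[2] + zone_margin)
  outside <- ref_at < zone[1] | ref_at >= zone[2]
  ident <- if (any(outside)) sum((pc == sc)[outside]) / sum(outside) else 1
  if (ident < min_identity)
    return(list(status = "unalignable", reason = "below identity floor",
                identity = ident))
  list(status = "aligned", read_aln = p, ref_aln = s,
       score = Biostrings::score(aln), identity = ident)
}

.sub_matrix_cache <- new.env(parent = emptyenv())
.sub_matrix <- function() {
  if (is.null(.sub_matrix_cache$m))
    .sub_matrix_cache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE)
  .sub_matrix_cache$m
}

#' Extract normalized edit events from an alignment
#'
#' Gap runs in the reference become insertions, gap runs in the read become
#' deletions, and maximal runs of adjacent mismatches become single
#' substitution events. Indels are left-aligned against the reference and
#' events are annotated with size class, guide attribution and inter-guide
#' dropout status. Events outside both guide attribution windows are
#' attributable to Sanger/PCR noise rather than Cas9: with
#' `filter_outside = TRUE` (default) they are moved to a `diagnostics`
#' attribute instead of the returned event set.
#'
#' @param aln an [align_read()] result with status `"aligned"`.
#' @param locus a `target_locus`.
#' @param filter_outside drop events not touching a guide window (kept as the
#'   `diagnostics` attribute).
#' @param small_max small/large size-class boundary (default 15).
#' @return annotated event data.frame; attribute `diagnostics` holds the
#'   filtered off-window events.
#' @export
extract_events <- function(aln, locus, filter_outside = TRUE, small_max = 15L) {
  stopifnot(aln$status == "aligned")
  pc <- str_chars(aln$read_aln)
  sc <- str_chars(aln$ref_aln)
  n <- length(pc)
  # column state: 0 match, 1 mismatch, 2 deletion (gap in read), 3 insertion
  state <- integer(n)
  state[pc == "-"] <- 2L
  state[sc == "-"] <- 3L
  state[state == 0L & pc != sc] <- 1L
  # reference coordinate (0-based) consumed before each column
  ref_before <- cumsum(sc != "-") - as.integer(sc != "-")

  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts_col <- ends - runs$lengths + 1L
  ev <- empty_events()
  for (r in seq_along(runs$values)) {
    st <- runs$values[r]
    if (st == 0L) next
    i0 <- starts_col[r]; i1 <- ends[r]
    rs <- ref_before[i0]
    ev <- rbind(ev, switch(as.character(st),
      "1" = events_df("substitution", rs, i1 - i0 + 1L,
                      paste(pc[i0:i1], collapse = "")),
      "2" = events_df("deletion", rs, i1 - i0 + 1L, ""),
      "3" = events_df("insertion", rs, 0L, paste(pc[i0:i1], collapse = ""))
    ))
  }
  ev <- normalize_events(ev, locus$amplicon)
  ev <- annotate_events(ev, locus, small_max = small_max)
  if (filter_outside) {
    keep <- ev$guide_hit != "none"
    diag <- ev[!keep, , drop = FALSE]
    ev <- ev[keep, , drop = FALSE]
    attr(ev, "diagnostics") <- diag
  } else {
    attr(ev, "diagnostics") <- ev[0, , drop = FALSE]
  }
  ev
}

#' Call events for every subclone read of a plant
#'
#' Aligns each read (deduplicating identical sequences), extracts normalized
#' events and returns a per-read call table. Unalignable reads are logged
#' and excluded from allele calling.
#'
#' @param reads data.frame with `read_id` and `seq` columns.
#' @param locus a `target_locus`.
#' @param filter_outside see [extract_events()].
#' @param min_identity see [align_read()].
#' @return list with `calls` (per aligned read: `read_id`, `signature`,
#'   `edited`, `guide_hit`, `dropout`, `n_offwindow`), `events` (named list of
#'   event data.frames keyed by signature) and `rejected` (read ids).
#' @export
call_reads <- function(reads, locus, filter_outside = TRUE, min_identity = 0.6) {
  uniq <- unique(reads$seq)
  by_seq <- vector("list", length(uniq))
  names(by_seq) <- uniq
  for (s in uniq) {
    a <- align_read(s, locus, min_identity = min_identity)
    if (a$status != "aligned") { by_seq[[s]] <- list(rejected = TRUE); next }
    ev <- extract_events(a, locus, filter_outside = filter_outside)
    by_seq[[s]] <- list(rejected = FALSE, events = ev,
                        n_offwindow = nrow(attr(ev, "diagnostics")))
  }
  rejected <- character(0)
  rows <- list(); ev_by_sig <- list()
  for (i in seq_len(nrow(reads))) {
    r <- by_seq[[reads$seq[i]]]
    if (isTRUE(r$rejected)) { rejected <- c(rejected, reads$read_id[i]); next }
    ev <- r$events
    sig <- event_signature(ev)
    if (is.null(ev_by_sig[[sig]])) ev_by_sig[[sig]] <- ev
    gh <- unique(ev$guide_hit)
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = reads$read_id[i], signature = sig,
      edited = nrow(ev) > 0,
      hit_sg1 = any(ev$guide_hit %in% c("sg1", "both")),
      hit_sg2 = any(ev$guide_hit %in% c("sg2", "both")),
      dropout = any(ev$inter_guide_dropout),
      n_offwindow = r$n_offwindow,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), signature = character(),
               edited = logical(), hit_sg1 = logical(), hit_sg2 = logical(),
               dropout = logical(), n_offwindow = integer())
  list(calls = calls, events = ev_by_sig, rejected = rejected)
}

#' Collapse per-read event calls into alleles
#'
#' Reads with identical normalized event sets merge into one allele with
#' summed subclone support; the wild-type allele is the empty event set.
#' Alleles below `min_support` are retained but flagged low-support (the
#' default of 1 keeps singletons, matching how single-subclone alleles are
#' conventionally counted; raise it to guard against PCR-introduced
#' artifacts).
#'
#' @param called a [call_reads()] result.
#' @param min_support minimum subclone support (default 1).
#' @return data.frame of `allele_call` rows: `allele`, `signature`,
#'   `support`, `edited`, `low_support`, `hit_sg1`, `hit_sg2`, `dropout`;
#'   attribute `events` maps signature -> event data.frame.
#' @export
collapse_alleles <- function(called, min_support = 1L) {
  calls <- called$calls
  if (nrow(calls) == 0)
    stop("no subclones: no aligned reads to collapse")
  agg <- stats::aggregate(list(support = calls$read_id),
                          by = list(signature = calls$signature), FUN = length)
  first <- calls[!duplicated(calls$signature), ]
  agg <- merge(agg, first[, c("signature", "edited", "hit_sg1", "hit_sg2", "dropout")],
               by = "signature")
  agg <- agg[order(-agg$support, agg$signature), , drop = FALSE]
  wt <- agg$signature == "WT"
  ids <- character(nrow(agg))
  ids[wt] <- "WT"
  ids[!wt] <- paste0("A", seq_len(sum(!wt)))
  out <- data.frame(allele = ids, signature = agg$signature,
                    support = agg$support, edited = agg$edited,
                    low_support = agg$support < min_support,
                    hit_sg1 = agg$hit_sg1, hit_sg2 = agg$hit_sg2,
                    dropout = agg$dropout,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "events") <- called$events
  out
}

#' Reconstruct an allele sequence from its called events
#'
#' @param allele_sig signature present in `events` of a [collapse_alleles()]
#'   result (or an event data.frame).
#' @param alleles a [collapse_alleles()] result (used for its events map),
#'   or NULL when `allele_sig` is already an event data.frame.
#' @param locus a `target_locus`.
#' @return the reconstructed sequence string.
#' @export
reconstruct_allele <- function(allele_sig, alleles = NULL, locus) {
  ev <- if (is.data.frame(allele_sig)) allele_sig
        else attr(alleles, "events")[[allele_sig]]
  if (is.null(ev)) stop("unknown allele signature: ", allele_sig)
  apply_events(locus$amplicon, ev)
}
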