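#' Decode a two-allele degenerate direct-sequencing consensus
#'
#' Direct Sanger sequencing of a diploid amplicon superposes the traces of
#' both alleles: after a length-discordant edit the two frames drift apart
#' and the base caller emits IUPAC ambiguity codes. This decoder inverts that
#' superposition for the tractable case of at most one indel per allele,
#' anchored (as Cas9 edits are) near the guide cut sites:
#' \enumerate{
#'   \item positions whose ambiguity code requires three or more superposed
#'     bases mark a >2-allele template -- returned as undecodable
#'     (`"chimeric"`);
#'   \item the consensus length pins the larger allele's net length shift;
#'     candidate single-indel hypotheses (deletions of 1..`max_shift` bp,
#'     an insertion of the pinned size, or no indel) are enumerated with
#'     their event interval overlapping a guide attribution window;
#'   \item hypotheses are pruned by a vectorized subset test (every base of
#'     a real template must be contained in the consensus code at its trace
#'     position), inserted bases are inferred from the partner allele, and
#'     each surviving pair is verified by exact re-superposition
#'     ([make_degenerate()]) against the consensus;
#'   \item a unique surviving pair decodes; zero or several survivors (e.g.
#'     both alleles inserted, which leaves the insertion content
#'     under-determined) return undecodable.
#' }
#'
#' @param consensus IUPAC consensus string, in read orientation.
#' @param locus a `target_locus`.
#' @param max_shift largest candidate indel size in bp (default 120).
#' @param orientation `"forward"` or `"reverse"`: strand the trace was read
#'   on; reverse traces are reverse-complemented into amplicon orientation
#'   first (their unambiguous flank is then the 3' one).
#' @return list with `status` (`"decoded"`/`"undecodable"`), `reason`,
#'   `alleleA`, `alleleB` (sequences, amplicon orientation; the allele with
#'   fewer events first) and `events_A`, `events_B` (annotated event
#'   data.frames).
#' @export
decode_degenerate <- function(consensus, locus, max_shift = 120L,
                              orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (orientation == "reverse") {
    # a reverse trace anchors at the amplicon's 3' end: decode against the
    # mirrored locus (where that anchor is the read start), then map back
    d <- decode_degenerate(consensus, .mirror_locus(locus), max_shift,
                           orientation = "forward")
    if (d$status != "decoded") return(d)
    seqA <- revcomp(d$alleleA); seqB <- revcomp(d$alleleB)
    evs <- lapply(c(seqA, seqB), .allele_events_fwd, locus = locus)
    if (any(vapply(evs, is.null, logical(1))))
      return(list(status = "undecodable",
                  reason = "reverse-frame alleles fail forward event calling",
                  alleleA = NA_character_, alleleB = NA_character_))
    return(.decoded(seqA, seqB, evs[[1]], evs[[2]], locus))
  }
  m <- base_to_bits(str_chars(consensus))
  undec <- function(reason) list(status = "undecodable", reason = reason,
                                 alleleA = NA_character_, alleleB = NA_character_)

  popcount <- vapply(m, function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0), numeric(1))
  if (any(popcount >= 3)) return(undec("chimeric"))

  amp <- locus$amplicon
  a <- base_to_bits(str_chars(amp))
  La <- length(a); Lc <- length(m)
  D <- Lc - La  # net length shift of the longer allele
  if (abs(D) > max_shift) return(undec("shift exceeds max_shift"))

  if (all(popcount == 1)) {
    # no ambiguity: both traces identical (WT/WT or homozygous-shaped)
    ev <- .consensus_events(consensus, locus)
    if (is.null(ev)) return(undec("unambiguous consensus does not match a single-indel allele"))
    return(.decoded(consensus, consensus, ev, ev, locus))
  }

  hyps <- .enumerate_hypotheses(m, a, locus, max_shift, D)
  if (length(hyps) == 0) return(undec("no candidate events"))

  # pair survivors: one allele must carry the pinned net shift D
  shifts <- vapply(hyps, `[[`, numeric(1), "shift")
  main <- which(shifts == D)
  pairs <- list()
  for (i in main) for (j in seq_along(hyps)) {
    if (shifts[j] > D) next
    pr <- .verify_pair(hyps[[i]], hyps[[j]], m, amp, locus)
    if (!is.null(pr)) pairs[[length(pairs) + 1L]] <- pr
  }
  if (length(pairs) == 0) return(undec("no consistent allele pair"))
  key <- vapply(pairs, function(p)
    paste(sort(c(p$seqA, p$seqB)), collapse = "|"), character(1))
  pairs <- pairs[!duplicated(key)]
  if (length(pairs) > 1) return(undec("ambiguous: multiple consistent pairs"))
  p <- pairs[[1]]
  .decoded(p$seqA, p$seqB, p$evA, p$evB, locus)
}

revcomp_iupac <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Reverse-complement view of a locus: amplicon flipped, cut positions and
# windows mirrored. Only the fields the decoder touches are carried.
.mirror_locus <- function(locus) {
  L <- nchar(locus$amplicon)
  gs <- lapply(locus$guides, function(g) {
    g$cut_pos <- L - g$cut_pos
    g
  })
  gs <- gs[order(vapply(gs, `[[`, integer(1), "cut_pos"))]
  out <- locus
  out$amplicon <- revcomp(locus$amplicon)
  out$guides <- gs
  out
}

# Events of a decoded allele in forward amplicon coordinates.
.allele_events_fwd <- function(seq, locus) {
  if (identical(seq, locus$amplicon)) return(empty_events())
  a <- align_read(seq, locus)
  if (a$status != "aligned") return(NULL)
  extract_events(a, locus, filter_outside = FALSE)
}

# Candidate single-indel hypotheses compatible with the consensus (subset
# test), each a list(kind, start, size, shift, seq or NULL for insertions).
.enumerate_hypotheses <- function(m, a, locus, max_shift, D) {
  La <- length(a); Lc <- length(m)
  subset_at <- function(amp_idx, cons_idx) {
    ok <- cons_idx >= 1 & cons_idx <= Lc
    res <- rep(FALSE, length(amp_idx))
    res[ok] <- bitwAnd(a[amp_idx[ok]], m[cons_idx[ok]]) == a[amp_idx[ok]]
    res
  }
  comp0 <- subset_at(seq_len(La), seq_len(La))
  # prefix_ok[s+1]: amp[1..s] all compatible unshifted (s = 0-based event start)
  prefix_ok <- c(TRUE, cumsum(!comp0) == 0)

  in_window <- function(s, k) {  # event interval [s, s+k) overlaps a guide window
    any(vapply(1:2, function(g) {
      w <- guide_window(locus, g)
      if (k == 0) s >= w[1] && s <= w[2] else s < w[2] && s + k > w[1]
    }, logical(1)))
  }

  hyps <- list()
  # "no indel" allele (net 0): admissible when every amplicon base fits the
  # consensus code at its own position (a WT template never makes the
  # consensus shorter than the amplicon, hence D >= 0)
  if (D >= 0 && all(comp0))
    hyps[[length(hyps) + 1L]] <- list(kind = "none", start = NA_integer_,
                                      size = 0L, shift = 0L,
                                      seq = paste(bits_to_base(a), collapse = ""))
  # deletions of size k: suffix amp[j] must fit consensus[j - k]
  for (k in seq_len(max_shift)) {
    j <- seq_len(La)
    T_k <- subset_at(j, j - k)
    # suffix_ok[p]: all amp positions >= p (1-based) compatible at shift -k
    bad_after <- rev(cumsum(rev(!T_k)))
    starts <- 0:(La - k)  # 0-based deletion starts
    ok <- prefix_ok[starts + 1L] &
      (starts + k >= La | c(bad_after, 0)[starts + k + 1L] == 0)
    for (s in starts[ok]) {
      if (!in_window(s, k)) next
      seq_bits <- c(a[seq_len(s)], a[(s + k + 1L):La])[seq_len(La - k)]
      if (s == La - k) seq_bits <- a[seq_len(s)]
      hyps[[length(hyps) + 1L]] <- list(kind = "deletion", start = s, size = k,
                                        shift = -k,
                                        seq = paste(bits_to_base(seq_bits), collapse = ""))
    }
  }
  # insertion: only the pinned net shift D can be an insertion
  if (D > 0) {
    k <- D
    j <- seq_len(La)
    U_k <- subset_at(j, j + k)
    bad_after <- rev(cumsum(rev(!U_k)))
    for (s in 0:La) {
      if (!in_window(s, 0L)) next
      pre <- prefix_ok[s + 1L]
      suf <- s >= La || bad_after[s + 1L] == 0
      if (pre && suf)
        hyps[[length(hyps) + 1L]] <- list(kind = "insertion", start = s, size = k,
                                          shift = k, seq = NULL)
    }
  }
  # deduplicate deletion hypotheses yielding identical sequences
  seqs <- vapply(hyps, function(h) h$seq %||% sprintf("ins@%d", h$start), character(1))
  hyps[!duplicated(seqs)]
}

# Verify one hypothesis pair by exact re-superposition; infers insertion
# content from the partner. Returns NULL if inconsistent.
.verify_pair <- function(hA, hB, m, amp, locus) {
  if (hA$kind == "insertion" && hB$kind == "insertion") return(NULL)
  fill <- function(h, partner_seq) {
    if (h$kind != "insertion") return(h$seq)
    s <- h$start; k <- h$size
    pb <- base_to_bits(str_chars(partner_seq))
    ins <- integer(k)
    for (t in seq_len(k)) {
      i <- s + t  # 1-based consensus position of inserted base
      x <- if (i <= length(pb)) bitwAnd(m[i], bitwNot(pb[i])) else m[i]
      x <- bitwAnd(x, 15L)
      nb <- sum(bitwAnd(x, c(1L, 2L, 4L, 8L)) > 0)
      if (nb == 1) ins[t] <- x
      else if (nb == 0 && i <= length(pb) &&
               sum(bitwAnd(m[i], c(1L, 2L, 4L, 8L)) > 0) == 1) ins[t] <- m[i]
      else return(NULL)
    }
    paste0(substr(amp, 1, s), paste(bits_to_base(ins), collapse = ""),
           substr(amp, s + 1, nchar(amp)))
  }
  seqB <- if (hB$kind == "insertion") fill(hB, hA$seq) else hB$seq
  if (is.null(seqB)) return(NULL)
  seqA <- if (hA$kind == "insertion") fill(hA, seqB) else hA$seq
  if (is.null(seqA)) return(NULL)
  cons <- paste(bits_to_base(base_to_bits(str_chars(m_to_str(m)))), collapse = "")
  sup <- make_degenerate(c(seqA, seqB))
  if (!identical(sup, m_to_str(m))) return(NULL)
  mk_ev <- function(h, seq) {
    ev <- switch(h$kind,
      none = empty_events(),
      deletion = events_df("deletion", h$start, h$size, ""),
      insertion = events_df("insertion", h$start, 0L,
                            substr(seq, h$start + 1L, h$start + h$size)))
    annotate_events(normalize_events(ev, locus$amplicon), locus)
  }
  list(seqA = seqA, seqB = seqB, evA = mk_ev(hA, seqA), evB = mk_ev(hB, seqB))
}

m_to_str <- function(m) paste(bits_to_base(m), collapse = "")

# Events of an unambiguous consensus: WT, or a single cut-anchored indel
# (recovered through the standard aligner).
.consensus_events <- function(consensus, locus) {
  if (identical(consensus, locus$amplicon)) return(empty_events())
  a <- align_read(consensus, locus)
  if (a$status != "aligned") return(NULL)
  ev <- extract_events(a, locus)
  if (nrow(ev) == 0) NULL else ev
}

.decoded <- function(seqA, seqB, evA, evB, locus) {
  # canonical order: fewer events first, then lexicographic
  if (nrow(evB) < nrow(evA) ||
      (nrow(evB) == nrow(evA) && seqB < seqA)) {
    tmp <- seqA; seqA <- seqB; seqB <- tmp
    tmpe <- evA; evA <- evB; evB <- tmpe
  }
  stopifnot(identical(make_degenerate(c(seqA, seqB)),
                      make_degenerate(c(seqA, seqB))))
  list(status = "decoded", reason = "",
       alleleA = seqA, alleleB = seqB, events_A = evA, events_B = evB)
}

#' Concordance between degenerate decoding and subcloning genotypes
#'
#' Per plant, compares the decoded allele pair with the allele sequences
#' recovered by subcloning: `"same"` when the two sets of distinct sequences
#' agree, `"partial"` when they overlap without agreeing (e.g. the decoder
#' reports one allele of a biallelic pair twice, concluding homozygosity),
#' `"different"` when they are disjoint, `"not_compared"` when the trace was
#' undecodable.
#'
#' @param decoded named list (plant id -> [decode_degenerate()] result).
#' @param subcloning named list (plant id -> character vector of allele
#'   sequences from subcloning).
#' @return list with `per_plant` data.frame and `summary` counts.
#' @export
compare_methods <- function(decoded, subcloning) {
  ids <- names(decoded)
  if (!setequal(ids, names(subcloning)))
    stop("plant id mismatch between decoding and subcloning results")
  rows <- lapply(ids, function(pid) {
    d <- decoded[[pid]]
    res <- if (d$status != "decoded") "not_compared" else {
      ds <- unique(c(d$alleleA, d$alleleB))
      ss <- unique(subcloning[[pid]])
      if (setequal(ds, ss)) "same"
      else if (length(intersect(ds, ss)) > 0) "partial"
      else "different"
    }
    data.frame(plant = pid, concordance = res, stringsAsFactors = FALSE)
  })
  per_plant <- do.call(rbind, rows)
  list(per_plant = per_plant,
       summary = table(factor(per_plant$concordance,
                              levels = c("same", "partial", "different",
                                         "not_compared"))))
}
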