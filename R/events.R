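#' Edit events
#'
#' An edit event is one normalized mutation in reference (amplicon)
#' coordinates. Events are kept in a data.frame with columns:
#' \describe{
#'   \item{kind}{`"deletion"`, `"insertion"` or `"substitution"`.}
#'   \item{start}{0-based reference coordinate. For insertions, the point
#'     before which bases are inserted.}
#'   \item{ref_span}{reference bases removed/replaced (0 for insertions).}
#'   \item{alt_seq}{inserted or replacement bases (`""` for pure deletions).}
#'   \item{size}{event size in bp (bases deleted, inserted, or length of the
#'     substituted run).}
#' }
#' Indels are stored left-aligned (shifted to their 5'-most equivalent
#' placement), the canonical form used throughout.
#'
#' @name edit_events
NULL

#' Construct an event table
#' @param kind,start,ref_span,alt_seq parallel vectors (see [edit_events]).
#' @return event data.frame with a derived `size` column.
#' @export
events_df <- function(kind = character(), start = integer(),
                      ref_span = integer(), alt_seq = character()) {
  kind <- as.character(kind)
  stopifnot(all(kind %in% c("deletion", "insertion", "substitution")))
  size <- ifelse(kind == "insertion", nchar(alt_seq), as.integer(ref_span))
  df <- data.frame(kind = kind, start = as.integer(start),
                   ref_span = as.integer(ref_span),
                   alt_seq = as.character(alt_seq),
                   size = as.integer(size), stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(df$size < 1)) stop("event size must be >= 1")
  df[order(df$start, df$kind), , drop = FALSE]
}

empty_events <- function() events_df()

#' Apply events to a reference sequence
#'
#' Rebuilds the mutated sequence from the wild-type amplicon and a set of
#' non-overlapping events. This is the simulator's forward operation and the
#' edit caller's reconstruction check.
#'
#' @param ref reference DNA string.
#' @param events event data.frame ([events_df()]).
#' @return mutated sequence string.
#' @export
apply_events <- function(ref, events) {
  if (nrow(events) == 0) return(ref)
  ev <- events[order(events$start), , drop = FALSE]
  ends <- ev$start + ev$ref_span
  if (any(ev$start[-1] < ends[-length(ends)])) stop("events overlap")
  if (any(ends > nchar(ref))) stop("event extends past the amplicon")
  out <- character(2 * nrow(ev) + 1)
  pos <- 0L  # 0-based consumed prefix of ref
  for (i in seq_len(nrow(ev))) {
    out[2 * i - 1] <- substr(ref, pos + 1L, ev$start[i])
    out[2 * i] <- ev$alt_seq[i]
    pos <- ev$start[i] + ev$ref_span[i]
  }
  out[2 * nrow(ev) + 1] <- substr(ref, pos + 1L, nchar(ref))
  paste(out, collapse = "")
}

#' Left-align indels against the reference
#'
#' Shifts each deletion/insertion to its 5'-most equivalent placement (the
#' VCF convention): a deletion slides left while the base preceding it equals
#' the last deleted base; an insertion rotates analogously. Substitution runs
#' are not moved. Returns events sorted by start.
#'
#' @param events event data.frame.
#' @param ref reference DNA string.
#' @return normalized event data.frame.
#' @export
normalize_events <- function(events, ref) {
  if (nrow(events) == 0) return(events)
  rc <- str_chars(ref)
  for (i in seq_len(nrow(events))) {
    s <- events$start[i]
    if (events$kind[i] == "deletion") {
      L <- events$ref_span[i]
      while (s > 0 && rc[s] == rc[s + L]) s <- s - 1L
      events$start[i] <- s
    } else if (events$kind[i] == "insertion") {
      ins <- str_chars(events$alt_seq[i])
      L <- length(ins)
      while (s > 0 && rc[s] == ins[L]) {
        ins <- c(rc[s], ins[-L])
        s <- s - 1L
      }
      events$start[i] <- s
      events$alt_seq[i] <- paste(ins, collapse = "")
    }
  }
  events[order(events$start, events$kind), , drop = FALSE]
}

#' Annotate events with size class, guide attribution and dropout status
#'
#' Adds columns `size_class` (`"small"` for <= 15 bp, `"large"` for > 15 bp),
#' `guide_hit` (`"sg1"`, `"sg2"`, `"both"`, `"none"`, by overlap with each
#' guide's attribution window) and `inter_guide_dropout` (deletion whose
#' interval contains both cut positions -- the large deletion expected when
#' both guides cut simultaneously).
#'
#' @param events event data.frame.
#' @param locus a `target_locus`.
#' @param small_max largest size still called "small" (default 15).
#' @return annotated event data.frame.
#' @export
annotate_events <- function(events, locus, small_max = 15L) {
  n <- nrow(events)
  if (n == 0) {
    events$size_class <- character(0)
    events$guide_hit <- character(0)
    events$inter_guide_dropout <- logical(0)
    return(events)
  }
  w1 <- guide_window(locus, 1)
  w2 <- guide_window(locus, 2)
  cut1 <- locus$guides[[1]]$cut_pos
  cut2 <- locus$guides[[2]]$cut_pos

  hit_win <- function(ev_start, ev_span, w) {
    if (ev_span == 0) ev_start >= w[1] && ev_start <= w[2]
    else ev_start < w[2] && ev_start + ev_span > w[1]
  }
  events$size_class <- ifelse(events$size <= small_max, "small", "large")
  events$guide_hit <- vapply(seq_len(n), function(i) {
    h1 <- hit_win(events$start[i], events$ref_span[i], w1)
    h2 <- hit_win(events$start[i], events$ref_span[i], w2)
    if (h1 && h2) "both" else if (h1) "sg1" else if (h2) "sg2" else "none"
  }, character(1))
  events$inter_guide_dropout <- events$kind == "deletion" &
    events$start <= cut1 & (events$start + events$ref_span) >= cut2
  events
}

#' Compact human-readable event signature
#'
#' One string per event set, e.g. `"del:121-202(82)"`,
#' `"ins:130(+ACG);sub:140-141(GT)"`. Coordinates are 1-based closed; an
#' insertion is reported at the 1-based position of the base it follows.
#' Identical (normalized) event sets map to identical signatures, so the
#' signature keys allele collapse and edition-type counting. The wild-type
#' (empty) event set has signature `"WT"`.
#'
#' @param events event data.frame (normalized).
#' @return character scalar.
#' @export
event_signature <- function(events) {
  if (nrow(events) == 0) return("WT")
  ev <- events[order(events$start, events$kind), , drop = FALSE]
  parts <- vapply(seq_len(nrow(ev)), function(i) {
    s1 <- ev$start[i] + 1L
    switch(ev$kind[i],
      deletion = sprintf("del:%d-%d(%d)", s1, ev$start[i] + ev$ref_span[i], ev$size[i]),
      insertion = sprintf("ins:%d(+%s)", ev$start[i], ev$alt_seq[i]),
      substitution = sprintf("sub:%d-%d(%s)", s1, ev$start[i] + ev$ref_span[i], ev$alt_seq[i])
    )
  }, character(1))
  paste(parts, collapse = ";")
}
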