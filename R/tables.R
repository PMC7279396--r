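#' Combine per-plant allele tables into one gene-level table
#'
#' @param per_plant named list of [collapse_alleles()] (or
#'   [classify_alleles()]) results, one per plant.
#' @return one data.frame with a `plant` column; `events` attribute is the
#'   union of the per-plant signature maps.
#' @export
bind_alleles <- function(per_plant) {
  ev <- list()
  rows <- lapply(names(per_plant), function(pid) {
    al <- per_plant[[pid]]
    for (sig in names(attr(al, "events"))) ev[[sig]] <<- attr(al, "events")[[sig]]
    cbind(plant = pid, al, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "events") <- ev
  out
}

#' Editing frequency and guide-position rates
#'
#' Per-subclone rates for one gene: the allele edition rate (edited subclones
#' over total sequenced subclones) and, denominated on edited subclones, the
#' fraction carrying edits at the sgRNA1 position, at the sgRNA2 position, at
#' both, and the fraction with the expected large deletion (a single deletion
#' spanning both cut sites). Percentages are one-decimal.
#'
#' @param calls per-subclone call table ([call_reads()]`$calls`, concatenated
#'   over a gene's plants).
#' @return one-row data.frame.
#' @export
editing_rates <- function(calls) {
  total <- nrow(calls)
  if (total == 0) stop("no sequenced subclones")
  ed <- calls[calls$edited, , drop = FALSE]
  n_ed <- nrow(ed)
  data.frame(
    total_subclones = total,
    edited_n = n_ed, edited_pct = pct(n_ed, total),
    sg1_n = sum(ed$hit_sg1), sg1_pct = pct(sum(ed$hit_sg1), n_ed),
    sg2_n = sum(ed$hit_sg2), sg2_pct = pct(sum(ed$hit_sg2), n_ed),
    sg12_n = sum(ed$hit_sg1 & ed$hit_sg2),
    sg12_pct = pct(sum(ed$hit_sg1 & ed$hit_sg2), n_ed),
    dropout_n = sum(ed$dropout), dropout_pct = pct(sum(ed$dropout), n_ed),
    stringsAsFactors = FALSE)
}

# Per-allele kind/size-class membership flags, from the events map.
.allele_memberships <- function(alleles) {
  ev_map <- attr(alleles, "events")
  kinds <- c(deletion = "del", insertion = "ins", substitution = "sub")
  flags <- lapply(alleles$signature, function(sig) {
    ev <- if (sig == "WT") empty_events() else ev_map[[sig]]
    out <- c(small_del = FALSE, large_del = FALSE, small_ins = FALSE,
             large_ins = FALSE, small_sub = FALSE, large_sub = FALSE,
             any_del = FALSE, any_ins = FALSE, any_sub = FALSE)
    for (i in seq_len(nrow(ev))) {
      key <- paste0(ev$size_class[i], "_", kinds[[ev$kind[i]]])
      out[key] <- TRUE
      out[paste0("any_", kinds[[ev$kind[i]]])] <- TRUE
    }
    out
  })
  as.data.frame(do.call(rbind, flags))
}

#' Mutation-spectrum table
#'
#' Tabulates, over the edited subclones of a gene (allele rows weighted by
#' support), membership in each size-class x kind category (small <= 15 bp,
#' large > 15 bp; deletion / insertion / substitution), the per-kind totals,
#' the expected-large-deletion count (deletions spanning both cut sites) and
#' the number of distinct edition types (unique normalized event sets). A
#' subclone whose allele carries several event kinds increments several
#' categories, so category percentages can sum above 100.
#'
#' @param alleles gene-level allele table ([bind_alleles()] of
#'   [collapse_alleles()] results).
#' @return list with `counts` (named category counts), `pct` (one-decimal
#'   percentages over edited subclones), `edited_clones`, `n_types`,
#'   `dropout_n`, `dropout_pct`.
#' @export
mutation_spectrum <- function(alleles) {
  mem <- .allele_memberships(alleles)
  ed <- alleles$edited
  w <- alleles$support
  n_ed <- sum(w[ed])
  cats <- c("small_del", "large_del", "small_ins", "large_ins",
            "small_sub", "large_sub", "any_del", "any_ins", "any_sub")
  counts <- vapply(cats, function(cl) sum(w[ed & mem[[cl]]]), numeric(1))
  dropout_n <- sum(w[ed & alleles$dropout])
  list(counts = counts,
       pct = vapply(counts, pct, numeric(1), d = n_ed),
       edited_clones = n_ed,
       n_types = length(unique(alleles$signature[ed])),
       dropout_n = dropout_n, dropout_pct = pct(dropout_n, n_ed))
}

#' Most prevalent edition types
#'
#' Edition types are keyed by the normalized event signature; counts are
#' subclone-weighted over edited alleles and percentages are whole-number
#' (the convention for headline edit types). Ties are broken by smaller
#' total event size, then leftmost position, then signature.
#'
#' @param alleles gene-level allele table ([bind_alleles()]).
#' @param k number of types to return (default 2).
#' @return data.frame: `signature`, `n`, `pct`, `description`.
#' @export
prevalent_types <- function(alleles, k = 2L) {
  ed <- alleles[alleles$edited, , drop = FALSE]
  if (nrow(ed) == 0) return(data.frame(signature = character(), n = integer(),
                                       pct = numeric(), description = character()))
  agg <- stats::aggregate(list(n = ed$support),
                          by = list(signature = ed$signature), FUN = sum)
  ev_map <- attr(alleles, "events")
  key <- t(vapply(agg$signature, function(sig) {
    ev <- ev_map[[sig]]
    c(size = sum(ev$size), start = min(ev$start))
  }, numeric(2)))
  ord <- order(-agg$n, key[, "size"], key[, "start"], agg$signature)
  agg <- agg[ord, , drop = FALSE]
  n_ed <- sum(ed$support)
  out <- utils::head(agg, k)
  out$pct <- round_half_up(100 * out$n / n_ed, 0)
  out$description <- vapply(out$signature, function(sig) {
    ev <- ev_map[[sig]]
    if (nrow(ev) == 1)
      sprintf("%d bp %s", ev$size, ev$kind)
    else sprintf("%d events", nrow(ev))
  }, character(1))
  rownames(out) <- NULL
  out
}
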