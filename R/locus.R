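#' Model a dual-guide CRISPR target locus
#'
#' A `target_locus` holds the wild-type amplicon, its coding (CDS) geometry
#' and two registered single-guide RNA sites, and supplies the coordinate
#' frame used by every other stage (simulation, edit calling, consequence
#' classification, degenerate decoding).
#'
#' All internal coordinates are 0-based half-open; human-readable reports are
#' 1-based closed. A guide's `cut_pos` is the 0-based index of the bond at
#' which SpCas9 cuts, i.e. the number of amplicon bases 5' of the blunt cut:
#' 3 bp 5' of the PAM on the protospacer strand.
#'
#' @param name locus label.
#' @param amplicon wild-type amplicon sequence (uppercase DNA string).
#' @param cds_segments list of `c(start, end)` 0-based half-open intervals of
#'   the amplicon that are coding, in order.
#' @param guides list of exactly two guide specifications, each a list with
#'   `name`, `protospacer` (20-nt DNA) and `strand` (`"sense"` or
#'   `"antisense"` relative to the amplicon); an optional `cut_pos` overrides
#'   the canonical blunt-cut position.
#' @param phase reading-frame phase of the first CDS segment (0, 1 or 2).
#' @param window half-width in bp of the edit-attribution window around each
#'   cut position (default 10).
#' @return an object of class `target_locus`.
#' @export
target_locus <- function(name, amplicon, cds_segments, guides, phase = 0L,
                         window = 10L) {
  amplicon <- toupper(amplicon)
  if (!grepl("^[ACGT]+$", amplicon)) stop("amplicon must be uppercase ACGT DNA")
  if (window < 1L) stop("window must be >= 1")
  if (length(guides) != 2L) stop("exactly two guides are required")

  gs <- lapply(guides, anchor_guide, amplicon = amplicon, window = window)

  # guides sorted by cut position; the 5'-most cut is sg1's by construction
  ord <- order(vapply(gs, `[[`, integer(1), "cut_pos"))
  gs <- gs[ord]
  span <- gs[[2]]$cut_pos - gs[[1]]$cut_pos
  if (span <= 0L) stop("guide cut positions must be distinct")

  cds_segments <- lapply(cds_segments, as.integer)
  starts <- vapply(cds_segments, `[`, integer(1), 1)
  ends <- vapply(cds_segments, `[`, integer(1), 2)
  if (any(diff(starts) <= 0) && length(starts) > 1)
    stop("cds_segments must be ordered")
  if (any(starts < 0) || any(ends > nchar(amplicon)) || any(ends <= starts))
    stop("cds_segments out of amplicon bounds")
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("cds_segments must not overlap")
  if (sum(ends - starts) < 3L) stop("total CDS length must be >= 3")

  structure(list(
    name = name,
    amplicon = amplicon,
    cds_segments = cds_segments,
    phase = as.integer(phase),
    guides = gs,
    window = as.integer(window),
    inter_guide_span = span
  ), class = "target_locus")
}

# Locate one protospacer on its stated strand, validate the NGG PAM and
# derive the blunt-cut coordinate. Fails if the guide is absent or ambiguous.
anchor_guide <- function(g, amplicon, window) {
  proto <- toupper(g$protospacer)
  if (nchar(proto) != 20L || !grepl("^[ACGT]+$", proto))
    stop("protospacer must be 20-nt ACGT DNA: ", g$name)
  strand <- match.arg(g$strand, c("sense", "antisense"))

  site <- if (strand == "sense") proto else revcomp(proto)
  hits <- gregexpr(site, amplicon, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) != 1L)
    stop("guide not anchored: protospacer of '", g$name, "' found ",
         length(hits), " times on the ", strand, " strand")
  s0 <- hits[1] - 1L  # 0-based start of the site on the amplicon

  if (strand == "sense") {
    if (s0 + 23L > nchar(amplicon))
      stop("PAM of '", g$name, "' extends past the amplicon")
    pam <- substr(amplicon, s0 + 21L, s0 + 23L)
    if (substr(pam, 2, 3) != "GG")
      stop("PAM mismatch for '", g$name, "': expected NGG, found ", pam)
    cut <- s0 + 17L
  } else {
    if (s0 < 3L) stop("PAM of '", g$name, "' extends past the amplicon")
    pam_on_amp <- substr(amplicon, s0 - 2L, s0)
    pam <- revcomp(pam_on_amp)
    if (substr(pam, 2, 3) != "GG")
      stop("PAM mismatch for '", g$name, "': expected NGG, found ", pam)
    cut <- s0 + 3L
  }
  if (!is.null(g$cut_pos)) cut <- as.integer(g$cut_pos)
  if (cut <= 0L || cut >= nchar(amplicon))
    stop("cut position of '", g$name, "' lies outside the amplicon")

  list(name = g$name, protospacer = proto, strand = strand, pam = pam,
       site_start = s0, cut_pos = cut, window = as.integer(window))
}

#' @export
print.target_locus <- function(x, ...) {
  cat("<target_locus> ", x$name, ": ", nchar(x$amplicon), " bp amplicon, ",
      length(x$cds_segments), " CDS segment(s)\n", sep = "")
  for (g in x$guides)
    cat(sprintf("  %s [%s] cut at %d (1-based %d|%d), window +/-%d bp\n",
                g$name, g$strand, g$cut_pos, g$cut_pos, g$cut_pos + 1L,
                g$window))
  cat("  inter-guide span:", x$inter_guide_span, "bp\n")
  invisible(x)
}

#' Attribution window of a guide, as a 0-based half-open interval
#' @param locus a `target_locus`.
#' @param i guide index (1 or 2).
#' @return integer vector `c(start, end)`.
#' @export
guide_window <- function(locus, i) {
  g <- locus$guides[[i]]
  c(max(0L, g$cut_pos - g$window), min(nchar(locus$amplicon), g$cut_pos + g$window))
}

#' Load a target locus from a FASTA reference and a flat YAML config
#'
#' The FASTA must contain a single record (the wild-type amplicon). The
#' config names the locus and its two guides (protospacer + strand), the CDS
#' segments (1-based closed, as humans annotate them) with the phase of the
#' first segment, and optionally the attribution `window`.
#'
#' @param fasta_path path to a single-record FASTA.
#' @param config_path path to a YAML locus config.
#' @return a `target_locus`.
#' @export
load_locus <- function(fasta_path, config_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("reference FASTA must contain exactly one record")
  cfg <- yaml::read_yaml(config_path)
  cds <- lapply(cfg$cds_segments, function(seg) {
    seg <- as.integer(seg)
    c(seg[1] - 1L, seg[2])  # 1-based closed in config -> 0-based half-open
  })
  target_locus(
    name = cfg$name %||% names(seqs)[1],
    amplicon = as.character(seqs[[1]]),
    cds_segments = cds,
    guides = cfg$guides,
    phase = cfg$phase %||% 0L,
    window = cfg$window %||% 10L
  )
}

#' Write a locus back to FASTA + YAML config
#'
#' Round-trips with [load_locus()]: reloading a saved locus reproduces
#' identical coordinates.
#'
#' @param locus a `target_locus`.
#' @param fasta_path,config_path output paths.
#' @return invisibly, the two paths.
#' @export
save_locus <- function(locus, fasta_path, config_path) {
  seq <- Biostrings::DNAStringSet(locus$amplicon)
  names(seq) <- locus$name
  Biostrings::writeXStringSet(seq, fasta_path)
  cfg <- list(
    name = locus$name,
    phase = locus$phase,
    window = locus$window,
    cds_segments = lapply(locus$cds_segments, function(s) c(s[1] + 1L, s[2])),
    guides = lapply(locus$guides, function(g)
      list(name = g$name, protospacer = g$protospacer, strand = g$strand))
  )
  yaml::write_yaml(cfg, config_path)
  invisible(c(fasta_path, config_path))
}

#' Flag guides overlapped by known sequence variants
#'
#' Heterozygous SNPs inside a protospacer or its PAM can abolish Cas9
#' recognition on the variant haplotype, so editing may be ineffective there.
#' Each variant is checked against both guides' protospacer + PAM intervals.
#'
#' @param locus a `target_locus`.
#' @param variants data.frame with columns `pos` (1-based amplicon
#'   coordinate), `ref`, `alt`. May have zero rows.
#' @return data.frame with one row per guide: `guide`, `flagged`, `n_variants`
#'   and a human-readable `note`.
#' @export
flag_guide_snps <- function(locus, variants) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) > 0) {
    ref_at <- substring(locus$amplicon, variants$pos, variants$pos)
    bad <- ref_at != toupper(variants$ref)
    if (any(bad))
      stop("variant ref mismatch at position ", variants$pos[which(bad)[1]],
           ": amplicon has ", ref_at[which(bad)[1]], ", variant says ",
           variants$ref[which(bad)[1]])
  }
  res <- lapply(seq_along(locus$guides), function(i) {
    g <- locus$guides[[i]]
    # protospacer site + PAM, 0-based half-open on the amplicon
    iv <- if (g$strand == "sense") c(g$site_start, g$site_start + 23L)
          else c(g$site_start - 3L, g$site_start + 20L)
    hit <- if (nrow(variants) == 0) logical(0) else
      (variants$pos - 1L) >= iv[1] & (variants$pos - 1L) < iv[2]
    data.frame(
      guide = g$name,
      flagged = any(hit),
      n_variants = sum(hit),
      note = if (any(hit)) "editing may be ineffective on the variant haplotype" else "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}
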