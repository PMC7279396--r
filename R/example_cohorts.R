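#' Bundled example cohorts with table-matched editing-outcome compositions
#'
#' Two fully synthetic subclone cohorts whose per-category compositions match
#' the published editing outcome tables for the two demonstration target
#' genes of this package:
#' \itemize{
#'   \item `"CCR1"`: 24 transformants, 278 sequenced subclones of which 89
#'     are edited (32.0%), 43 distinct edition types, deletion-dominated
#'     spectrum with 19 inter-guide dropouts, plant classes 1 chimera (all
#'     alleles edited, 7 alleles, one a synonymous 1-bp substitution),
#'     10 monoallelic, 13 chimera with WT;
#'   \item `"IAA9A"`: 13 transformants, 95 subclones of which 88 are edited
#'     (92.6%), 20 edition types, 27 dropouts, 7 biallelic plants, 4 chimera
#'     (all edited), 1 monoallelic, 1 WT/WT.
#' }
#' Sequences are generated on a synthetic dual-guide locus (guide spacing 64
#' bp for CCR1-like, 54 bp for IAA9A-like); every subclone read is built by
#' applying a designed event set to the wild-type amplicon, so running the
#' genotyping pipeline on the cohort reproduces the published rate,
#' spectrum, consequence and genotype-class tables. Used by the worked
#' examples, the validation suite and the analysis scripts.
#'
#' @param gene `"CCR1"` or `"IAA9A"`.
#' @return list with `locus` (a `target_locus`), `reads_by_plant` (named
#'   list of read data.frames for [genotype_cohort()]), `types` (the
#'   designed edition-type table: `type`, `n`, `signature`) and
#'   `assignment` (plant x type support table).
#' @export
example_cohort <- function(gene = c("CCR1", "IAA9A")) {
  gene <- match.arg(gene)
  if (gene == "CCR1") .cohort_ccr1() else .cohort_iaa9a()
}

# ---- event descriptor helpers -------------------------------------------

.cut <- function(locus, g) locus$guides[[g]]$cut_pos

# small deletion roughly centered on the cut
.d_small <- function(locus, g, k, v = 0L)
  events_df("deletion", .cut(locus, g) - k %/% 2L + v, k, "")
# large deletion extending 5' (away from the partner guide) from the cut
.d_left <- function(locus, g, k)
  events_df("deletion", .cut(locus, g) - k, k, "")
# large deletion centered on guide 2's cut (not reaching guide 1)
.d_cent <- function(locus, g, k, v = 0L)
  events_df("deletion", .cut(locus, g) - k %/% 2L + v, k, "")
# dropout: deletion spanning both cut sites
.d_span <- function(locus, k) {
  span <- locus$inter_guide_span
  stopifnot(k >= span + 2L)
  events_df("deletion", .cut(locus, 1) - (k - span) %/% 2L, k, "")
}
.i_at <- function(locus, g, seqstr, v = 0L)
  events_df("insertion", .cut(locus, g) + v, 0L, seqstr)
# substitution run: each base replaced by the next base in A>C>G>T>A order
.s_run <- function(locus, g, k, v = 0L) {
  s <- .cut(locus, g) + v
  orig <- str_chars(substr(locus$amplicon, s + 1L, s + k))
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  events_df("substitution", s, k, paste(nxt[orig], collapse = ""))
}
# synonymous 1-bp substitution at a codon wobble position inside guide 2's
# attribution window (searched on the actual sequence)
.s_syn <- function(locus) {
  w <- guide_window(locus, 2)
  seg <- locus$cds_segments[[1]]
  aa_of <- function(codon) as.character(Biostrings::translate(
    Biostrings::DNAString(codon), no.init.codon = TRUE))
  for (p in w[1]:(w[2] - 1L)) {
    if (p < seg[1] || p >= seg[2]) next
    if ((p - seg[1] - locus$phase) %% 3L != 2L) next  # wobble position only
    c0 <- p - 2L
    codon <- substr(locus$amplicon, c0 + 1L, c0 + 3L)
    ref <- substr(locus$amplicon, p + 1L, p + 1L)
    for (b in setdiff(DNA_BASES, ref)) {
      mut <- paste0(substr(codon, 1, 2), b)
      if (aa_of(mut) == aa_of(codon))
        return(events_df("substitution", p, 1L, b))
    }
  }
  stop("no synonymous wobble substitution available in guide 2's window")
}

# Build allele table from a type list: list(id = list(n, ev_fun)).
.build_types <- function(locus, types) {
  rows <- lapply(names(types), function(id) {
    ev <- do.call(rbind, lapply(types[[id]]$ev, function(f) f(locus)))
    ev <- annotate_events(normalize_events(ev, locus$amplicon), locus)
    list(type = id, n = types[[id]]$n, events = ev,
         seq = apply_events(locus$amplicon, ev),
         signature = event_signature(ev))
  })
  names(rows) <- names(types)
  sigs <- vapply(rows, `[[`, character(1), "signature")
  if (anyDuplicated(sigs))
    stop("designed edition types collide after normalization: ",
         paste(sigs[duplicated(sigs)], collapse = "; "))
  rows
}

# Deal remaining type instances into k plants, no type twice per plant,
# balancing plant sizes. Deterministic.
.deal <- function(counts, k) {
  plants <- replicate(k, character(0), simplify = FALSE)
  fill <- integer(k)
  for (ty in names(sort(counts, decreasing = TRUE))) {
    for (j in seq_len(counts[[ty]])) {
      ok <- which(!vapply(plants, function(p) ty %in% p, logical(1)))
      pick <- ok[which.min(fill[ok])]
      plants[[pick]] <- c(plants[[pick]], ty)
      fill[pick] <- fill[pick] + 1L
    }
  }
  plants
}

.assemble_reads <- function(locus, built, assignment) {
  # assignment: data.frame plant, type ("WT" allowed), support
  reads <- list()
  for (pid in unique(assignment$plant)) {
    rows <- assignment[assignment$plant == pid, , drop = FALSE]
    seqs <- unlist(lapply(seq_len(nrow(rows)), function(i) {
      s <- if (rows$type[i] == "WT") locus$amplicon else built[[rows$type[i]]]$seq
      rep(s, rows$support[i])
    }))
    reads[[pid]] <- data.frame(
      read_id = sprintf("%s_sc%02d", pid, seq_along(seqs)),
      seq = seqs, stringsAsFactors = FALSE)
  }
  reads
}

# ---- CCR1-like cohort ----------------------------------------------------

.cohort_ccr1 <- function() {
  locus <- synthetic_locus("CCR1like", span = 64L, seed = 101L)
  L <- function(...) list(...)
  types <- list(
    # inter-guide dropouts (19) and other events at both guides (3)
    t01 = L(n = 14L, ev = L(function(l) .d_span(l, 82L))),
    t02 = L(n = 1L, ev = L(function(l) .d_span(l, 66L))),
    t03 = L(n = 1L, ev = L(function(l) .d_span(l, 70L))),
    t04 = L(n = 1L, ev = L(function(l) .d_span(l, 74L))),
    t05 = L(n = 1L, ev = L(function(l) .d_span(l, 77L))),
    t06 = L(n = 1L, ev = L(function(l) .d_span(l, 80L))),
    t07 = L(n = 1L, ev = L(function(l) .d_small(l, 1, 1L), function(l) .d_small(l, 2, 1L))),
    t08 = L(n = 1L, ev = L(function(l) .d_small(l, 1, 2L), function(l) .d_small(l, 2, 2L))),
    t09 = L(n = 1L, ev = L(function(l) .d_small(l, 1, 1L), function(l) .d_small(l, 2, 4L))),
    # sgRNA1-only (24)
    t10 = L(n = 1L, ev = L(function(l) .d_left(l, 1, 20L))),
    t11 = L(n = 1L, ev = L(function(l) .d_left(l, 1, 23L))),
    t12 = L(n = 1L, ev = L(function(l) .i_at(l, 1, "A"))),
    t13 = L(n = 1L, ev = L(function(l) .i_at(l, 1, "AC"))),
    t14 = L(n = 1L, ev = L(function(l) .i_at(l, 1, "GT"))),
    t15 = L(n = 1L, ev = L(function(l) .i_at(l, 1, "T"))),
    t16 = L(n = 1L, ev = L(function(l) .s_run(l, 1, 1L))),
    t17 = L(n = 2L, ev = L(function(l) .s_run(l, 1, 2L))),
    t18 = L(n = 2L, ev = L(function(l) .s_run(l, 1, 3L))),
    t19 = L(n = 3L, ev = L(function(l) .d_small(l, 1, 1L), function(l) .s_run(l, 1, 2L, 4L))),
    t20 = L(n = 2L, ev = L(function(l) .d_small(l, 1, 1L, -3L), function(l) .s_run(l, 1, 1L, 3L))),
    t21 = L(n = 2L, ev = L(function(l) .d_small(l, 1, 3L), function(l) .s_run(l, 1, 2L, 5L))),
    t22 = L(n = 1L, ev = L(function(l) .d_small(l, 1, 3L, -4L), function(l) .s_run(l, 1, 1L, 4L))),
    t23 = L(n = 5L, ev = L(function(l) .d_small(l, 1, 1L))),
    # sgRNA2-only (43)
    t25 = L(n = 11L, ev = L(function(l) .d_small(l, 2, 1L))),
    t26 = L(n = 4L, ev = L(function(l) .d_small(l, 2, 2L))),
    t27 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 2L, -3L))),
    t28 = L(n = 4L, ev = L(function(l) .d_small(l, 2, 3L))),
    t29 = L(n = 2L, ev = L(function(l) .d_small(l, 2, 6L))),
    t30 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 6L, -4L))),
    t31 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 9L))),
    t32 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 15L))),
    t33 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 12L))),
    t34 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 9L, -5L))),
    t35 = L(n = 3L, ev = L(function(l) .s_run(l, 2, 2L))),
    t36 = L(n = 2L, ev = L(function(l) .s_run(l, 2, 1L))),
    t37 = L(n = 1L, ev = L(function(l) .s_run(l, 2, 4L))),
    t38 = L(n = 1L, ev = L(function(l) .s_syn(l))),
    t39 = L(n = 3L, ev = L(function(l) .d_small(l, 2, 1L), function(l) .s_run(l, 2, 2L, 4L))),
    t40 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 1L, -3L), function(l) .s_run(l, 2, 1L, 3L))),
    t41 = L(n = 2L, ev = L(function(l) .d_small(l, 2, 2L), function(l) .s_run(l, 2, 2L, 4L))),
    t42 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 2L, -4L), function(l) .s_run(l, 2, 3L, 3L))),
    t43 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 3L), function(l) .s_run(l, 2, 2L, 5L))),
    t44 = L(n = 1L, ev = L(function(l) .d_small(l, 2, 3L, -4L), function(l) .s_run(l, 2, 1L, 4L)))
  )
  built <- .build_types(locus, types)

  # plant composition: 1 chimera (all edited, 7 alleles), 10 monoallelic,
  # 13 chimera with WT
  asg <- list()
  add <- function(plant, type, support = 1L)
    asg[[length(asg) + 1L]] <<- data.frame(plant = plant, type = type,
                                           support = support,
                                           stringsAsFactors = FALSE)
  for (ty in c("t38", "t01", "t25", "t23", "t16", "t35", "t28"))
    add("CCR1_01", ty)
  mono <- c("t01", "t25", "t02", "t03", "t10", "t12", "t17", "t21", "t29", "t32")
  for (i in seq_along(mono)) {
    pid <- sprintf("CCR1_%02d", i + 1L)
    add(pid, mono[i]); add(pid, "WT", 9L)
  }
  counts <- vapply(built, `[[`, integer(1), "n")
  used <- table(c("t38", "t01", "t25", "t23", "t16", "t35", "t28", mono))
  rem <- counts
  rem[names(used)] <- rem[names(used)] - as.integer(used)
  rem <- rem[rem > 0]
  dealt <- .deal(rem, 13L)
  for (j in seq_len(13L)) {
    pid <- sprintf("CCR1_%02d", j + 11L)
    for (ty in dealt[[j]]) add(pid, ty)
    add(pid, "WT", if (j <= 8) 8L else 7L)
  }
  assignment <- do.call(rbind, asg)
  list(locus = locus,
       reads_by_plant = .assemble_reads(locus, built, assignment),
       types = data.frame(type = names(built),
                          n = counts,
                          signature = vapply(built, `[[`, character(1), "signature"),
                          row.names = NULL, stringsAsFactors = FALSE),
       assignment = assignment)
}

# ---- IAA9A-like cohort ---------------------------------------------------

.cohort_iaa9a <- function() {
  locus <- synthetic_locus("IAA9Alike", span = 54L, seed = 202L)
  L <- function(...) list(...)
  types <- list(
    u01 = L(n = 26L, ev = L(function(l) .d_span(l, 73L))),
    u02 = L(n = 1L, ev = L(function(l) .d_span(l, 70L))),
    u03 = L(n = 8L, ev = L(function(l) .d_small(l, 1, 1L))),
    u04 = L(n = 3L, ev = L(function(l) .d_small(l, 1, 2L), function(l) .i_at(l, 2, "A"))),
    u05 = L(n = 3L, ev = L(function(l) .d_small(l, 1, 2L), function(l) .i_at(l, 2, "T"))),
    u06 = L(n = 3L, ev = L(function(l) .d_small(l, 1, 4L), function(l) .i_at(l, 2, "AC"))),
    u07 = L(n = 3L, ev = L(function(l) .d_small(l, 1, 4L, -3L), function(l) .i_at(l, 2, "AC"))),
    u08 = L(n = 4L, ev = L(function(l) .d_small(l, 1, 1L), function(l) .i_at(l, 2, "G"))),
    u09 = L(n = 7L, ev = L(function(l) .d_small(l, 2, 2L),
                           function(l) .i_at(l, 1, "ACGTACGTACGTACGTAC"))),
    u10 = L(n = 5L, ev = L(function(l) .d_small(l, 2, 4L),
                           function(l) .i_at(l, 1, "GTCAGTCAGTCAGTCAGTCA"))),
    u11 = L(n = 4L, ev = L(function(l) .d_cent(l, 2, 22L), function(l) .s_run(l, 1, 2L))),
    u12 = L(n = 3L, ev = L(function(l) .d_cent(l, 2, 22L, -3L), function(l) .s_run(l, 1, 2L, 3L))),
    u13 = L(n = 3L, ev = L(function(l) .d_left(l, 1, 19L), function(l) .s_run(l, 2, 1L))),
    u14 = L(n = 1L, ev = L(function(l) .d_left(l, 1, 18L))),
    u15 = L(n = 3L, ev = L(function(l) .d_small(l, 2, 1L), function(l) .s_run(l, 1, 3L))),
    u16 = L(n = 1L, ev = L(function(l) .s_run(l, 2, 2L))),
    u17 = L(n = 4L, ev = L(function(l) .d_small(l, 1, 3L), function(l) .d_small(l, 2, 3L))),
    u18 = L(n = 3L, ev = L(function(l) .d_small(l, 2, 3L, -4L))),
    u19 = L(n = 2L, ev = L(function(l) .d_small(l, 1, 2L), function(l) .d_small(l, 2, 2L))),
    u20 = L(n = 1L, ev = L(function(l) .d_small(l, 1, 2L, -3L), function(l) .d_small(l, 2, 2L)))
  )
  built <- .build_types(locus, types)

  asg <- list()
  add <- function(plant, type, support = 1L)
    asg[[length(asg) + 1L]] <<- data.frame(plant = plant, type = type,
                                           support = support,
                                           stringsAsFactors = FALSE)
  bi <- list(c("u01", 3L, "u03", 2L), c("u01", 3L, "u03", 2L),
             c("u01", 3L, "u03", 2L), c("u01", 3L, "u03", 2L),
             c("u01", 2L, "u11", 4L), c("u01", 2L, "u13", 3L),
             c("u01", 2L, "u15", 3L))
  for (i in seq_along(bi)) {
    pid <- sprintf("IAA9A_%02d", i)
    add(pid, bi[[i]][1], as.integer(bi[[i]][2]))
    add(pid, bi[[i]][3], as.integer(bi[[i]][4]))
  }
  chim <- list(
    list(c(u01 = 2L, u04 = 3L, u05 = 3L, u09 = 7L)),
    list(c(u01 = 2L, u06 = 3L, u07 = 3L, u10 = 5L)),
    list(c(u01 = 2L, u08 = 4L, u12 = 3L, u17 = 4L)),
    list(c(u01 = 2L, u16 = 1L, u14 = 1L, u18 = 3L, u19 = 2L, u20 = 1L)))
  for (i in seq_along(chim)) {
    pid <- sprintf("IAA9A_%02d", i + 7L)
    v <- chim[[i]][[1]]
    for (ty in names(v)) add(pid, ty, v[[ty]])
  }
  add("IAA9A_12", "u02", 1L); add("IAA9A_12", "WT", 4L)
  add("IAA9A_13", "WT", 3L)
  assignment <- do.call(rbind, asg)
  counts <- vapply(built, `[[`, integer(1), "n")
  list(locus = locus,
       reads_by_plant = .assemble_reads(locus, built, assignment),
       types = data.frame(type = names(built), n = counts,
                          signature = vapply(built, `[[`, character(1), "signature"),
                          row.names = NULL, stringsAsFactors = FALSE),
       assignment = assignment)
}
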