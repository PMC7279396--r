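test_that("editing rates use the documented denominators", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:10),
    signature = c(rep("WT", 6), "d1", "d1", "d2", "d3"),
    edited = c(rep(FALSE, 6), rep(TRUE, 4)),
    hit_sg1 = c(rep(FALSE, 6), TRUE, TRUE, FALSE, TRUE),
    hit_sg2 = c(rep(FALSE, 6), FALSE, FALSE, TRUE, TRUE),
    dropout = c(rep(FALSE, 9), TRUE))
  r <- editing_rates(calls)
  expect_equal(r$total_subclones, 10L)
  expect_equal(r$edited_pct, 40)
  expect_equal(r$sg1_pct, 75)      # 3 of 4 edited
  expect_equal(r$sg2_pct, 50)      # 2 of 4
  expect_equal(r$sg12_pct, 25)     # 1 of 4
  expect_equal(r$dropout_pct, 25)
  expect_error(editing_rates(calls[0, ]), "no sequenced subclones")

  # all-WT cohort: 0 everywhere
  wt <- calls[1:6, ]
  r0 <- editing_rates(wt)
  expect_equal(r0$edited_pct, 0)
  expect_equal(r0$sg1_pct, 0)
})

test_that("mutation spectrum counts per-kind memberships, support-weighted", {
  loc <- test_locus()
  cut1 <- loc$guides[[1]]$cut_pos
  # one allele with del+sub (two kinds), one small-deletion-only allele
  reads <- list(p1 = data.frame(
    read_id = c("a", "b", "c"),
    seq = c(rep(apply_events(loc$amplicon, events_df(
      c("deletion", "substitution"), c(cut1, cut1 + 4L), c(2L, 1L),
      c("", if (substr(loc$amplicon, cut1 + 5, cut1 + 5) == "A") "C" else "A"))), 2),
      apply_events(loc$amplicon, events_df("deletion", cut1, 1L, "")))))
  res <- genotype_cohort(reads, loc)
  sp <- res$spectrum
  expect_equal(sp$edited_clones, 3)
  expect_equal(unname(sp$counts["small_del"]), 3)
  expect_equal(unname(sp$counts["small_sub"]), 2)
  # membership sum exceeds the clone count (multi-kind alleles)
  expect_gte(sum(sp$counts[c("any_del", "any_ins", "any_sub")]), sp$edited_clones)
  expect_equal(sp$n_types, 2)

  # single allele with one 1-bp deletion: 100% small deletion, 1 type
  reads1 <- list(p1 = data.frame(read_id = "a", seq = apply_events(
    loc$amplicon, events_df("deletion", cut1, 1L, ""))))
  sp1 <- genotype_cohort(reads1, loc)$spectrum
  expect_equal(unname(sp1$pct["small_del"]), 100)
  expect_equal(sp1$n_types, 1)
})

test_that("prevalent types rank by count with deterministic tie-breaking", {
  cc <- example_cohort("CCR1")
  res <- genotype_cohort(cc$reads_by_plant, cc$locus)
  pv <- prevalent_types(res$alleles, k = 3)
  expect_equal(pv$n[1], 14L)
  expect_equal(pv$pct[1], 16)
  expect_match(pv$description[1], "82 bp deletion")
  expect_equal(pv$n[2], 11L)
  expect_equal(pv$pct[2], 12)
  expect_match(pv$description[2], "1 bp deletion")

  # all-unique alleles: every count 1, order deterministic under shuffling
  al <- res$alleles
  singles <- al[!duplicated(al$signature) & al$edited, ][1:6, ]
  singles$support <- 1L
  attr(singles, "events") <- attr(al, "events")
  p1 <- prevalent_types(singles, k = 6)
  shuffled <- singles[c(4, 2, 6, 1, 3, 5), ]
  attr(shuffled, "events") <- attr(al, "events")
  p2 <- prevalent_types(shuffled, k = 6)
  expect_identical(p1$signature, p2$signature)
  expect_true(all(p1$n == 1L))
})

test_that("table regeneration is idempotent and input-order independent", {
  cc <- example_cohort("IAA9A")
  res <- genotype_cohort(cc$reads_by_plant, cc$locus)
  rev_reads <- rev(cc$reads_by_plant)
  res2 <- genotype_cohort(rev_reads, cc$locus)
  expect_equal(res2$rates, res$rates)
  expect_equal(res2$spectrum$counts, res$spectrum$counts)
  expect_equal(res2$spectrum$n_types, res$spectrum$n_types)
  expect_equal(res2$genotypes$per_class$n, res$genotypes$per_class$n)
  # each membership bounded by the edited clone count
  expect_true(all(res$spectrum$counts <= res$spectrum$edited_clones))
})

test_that("pipeline tables write to TSV", {
  cc <- example_cohort("IAA9A")
  res <- genotype_cohort(cc$reads_by_plant, cc$locus)
  d <- tempfile()
  paths <- write_genotype_tables(res, d, prefix = "iaa9a")
  expect_true(all(file.exists(paths)))
  rt <- utils::read.delim(file.path(d, "iaa9a_editing_rates.tsv"))
  expect_equal(rt$edited_pct, 92.6)
})
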