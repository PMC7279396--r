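test_that("unambiguous consensus decodes as WT/WT or homozygous shape", {
  loc <- test_locus()
  d_wt <- decode_degenerate(loc$amplicon, loc)
  expect_equal(d_wt$status, "decoded")
  expect_identical(d_wt$alleleA, loc$amplicon)
  expect_identical(d_wt$alleleB, loc$amplicon)

  hom <- apply_events(loc$amplicon,
                      events_df("deletion", loc$guides[[2]]$cut_pos, 1L, ""))
  d_hom <- decode_degenerate(hom, loc)
  expect_equal(d_hom$status, "decoded")
  expect_identical(d_hom$alleleA, hom)
  expect_identical(d_hom$alleleB, hom)
  expect_equal(nrow(d_hom$events_A), 1L)
})

test_that("WT x single-indel superpositions decode exactly (round trip)", {
  loc <- test_locus()
  set.seed(41)
  cases <- list(
    events_df("deletion", loc$guides[[1]]$cut_pos, 1L, ""),
    events_df("deletion", loc$guides[[2]]$cut_pos - 3L, 7L, ""),
    events_df("deletion", loc$guides[[1]]$cut_pos - 5L, 82L, ""),
    events_df("insertion", loc$guides[[1]]$cut_pos, 0L, "T"),
    events_df("insertion", loc$guides[[2]]$cut_pos, 0L, "GATTACA"))
  for (ev in cases) {
    mut <- apply_events(loc$amplicon, ev)
    cons <- make_degenerate(c(loc$amplicon, mut))
    d <- decode_degenerate(cons, loc)
    expect_equal(d$status, "decoded")
    expect_setequal(c(d$alleleA, d$alleleB), c(loc$amplicon, mut))
    # decoded result re-superposes to the input exactly
    expect_identical(make_degenerate(c(d$alleleA, d$alleleB)), cons)
    # canonical order: the WT-like allele (fewer events) first
    expect_identical(d$alleleA, loc$amplicon)
  }
})

test_that("reverse-orientation traces decode after strand normalization", {
  loc <- test_locus()
  mut <- apply_events(loc$amplicon,
                      events_df("deletion", loc$guides[[2]]$cut_pos - 2L, 5L, ""))
  cons_rev <- make_degenerate(c(loc$amplicon, mut), orientation = "reverse")
  # a reverse trace anchors at the 3' end, so its unambiguous flank is the
  # one downstream of the edits; it is not the reverse complement of the
  # forward trace
  expect_true(grepl("[RYSWKM]", cons_rev))
  d <- decode_degenerate(cons_rev, loc, orientation = "reverse")
  expect_equal(d$status, "decoded")
  expect_setequal(c(d$alleleA, d$alleleB), c(loc$amplicon, mut))
})

test_that("three-allele superpositions are rejected as chimeric", {
  loc <- test_locus()
  a1 <- apply_events(loc$amplicon, events_df("deletion", loc$guides[[1]]$cut_pos, 5L, ""))
  a2 <- apply_events(loc$amplicon, events_df("deletion", loc$guides[[1]]$cut_pos - 2L, 11L, ""))
  tri <- make_degenerate(c(loc$amplicon, a1, a2))
  d <- decode_degenerate(tri, loc)
  expect_equal(d$status, "undecodable")
  expect_equal(d$reason, "chimeric")
})

test_that("the decoder never returns a pair that fails re-superposition", {
  loc <- test_locus()
  set.seed(42)
  params <- edit_params(p_dropout = 0.3)
  for (i in 1:40) {
    repeat {
      a <- simulate_allele(loc, params)
      if (nrow(a$truth) == 1 && a$truth$kind[1] != "substitution") break
    }
    cons <- make_degenerate(c(loc$amplicon, a$seq))
    d <- decode_degenerate(cons, loc)
    if (d$status == "decoded")
      expect_identical(make_degenerate(c(d$alleleA, d$alleleB)), cons)
  }
})

test_that("method comparison classifies same / partial / not_compared", {
  loc <- test_locus()
  bi_a <- apply_events(loc$amplicon, events_df("deletion", loc$guides[[1]]$cut_pos - 5L, 73L, ""))
  bi_b <- apply_events(loc$amplicon, events_df("deletion", loc$guides[[2]]$cut_pos - 3L, 6L, ""))
  decoded <- list(
    p_same = decode_degenerate(make_degenerate(c(loc$amplicon, bi_a)), loc),
    p_partial = list(status = "decoded", alleleA = bi_a, alleleB = bi_a),
    p_undec = list(status = "undecodable", reason = "chimeric"))
  subcloning <- list(
    p_same = c(loc$amplicon, bi_a),
    p_partial = c(bi_a, bi_b),    # subcloning saw biallelic; decoder saw homozygous
    p_undec = c(bi_a, bi_b, loc$amplicon))
  cmp <- compare_methods(decoded, subcloning)
  got <- setNames(cmp$per_plant$concordance, cmp$per_plant$plant)
  expect_equal(unname(got["p_same"]), "same")
  expect_equal(unname(got["p_partial"]), "partial")
  expect_equal(unname(got["p_undec"]), "not_compared")
  expect_error(compare_methods(decoded, subcloning[1:2]), "mismatch")
})
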