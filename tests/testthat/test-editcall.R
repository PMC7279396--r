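test_that("self-alignment is perfect and random DNA is unalignable", {
  loc <- test_locus()
  a <- align_read(loc$amplicon, loc)
  expect_equal(a$status, "aligned")
  expect_equal(a$identity, 1)
  expect_equal(a$score, 2 * nchar(loc$amplicon))
  expect_equal(nrow(extract_events(a, loc)), 0L)

  set.seed(21)
  rnd <- paste(sample(c("A", "C", "G", "T"), nchar(loc$amplicon), TRUE),
               collapse = "")
  expect_equal(align_read(rnd, loc)$status, "unalignable")
  # length guard
  expect_equal(align_read(substr(loc$amplicon, 1, 100), loc)$status,
               "unalignable")
})

test_that("a large deletion is recovered as a single spanning gap", {
  loc <- test_locus()
  ev <- events_df("deletion", loc$guides[[1]]$cut_pos - 9L, 82L, "")
  ev <- normalize_events(ev, loc$amplicon)
  read <- apply_events(loc$amplicon, ev)
  got <- extract_events(align_read(read, loc), loc)
  expect_equal(nrow(got), 1L)
  expect_equal(got$kind, "deletion")
  expect_equal(got$size, 82L)
  expect_equal(got$start, ev$start)
  expect_equal(got$guide_hit, "both")
  expect_true(got$inter_guide_dropout)
})

test_that("a 1-bp deletion in a homopolymer is reported at its leftmost position", {
  loc <- test_locus()
  amp <- loc$amplicon
  # engineer a homopolymer run just after guide 1's cut
  cut <- loc$guides[[1]]$cut_pos
  amp2 <- paste0(substr(amp, 1, cut), "AAAAA", substr(amp, cut + 6, nchar(amp)))
  loc2 <- loc; loc2$amplicon <- amp2
  read <- apply_events(amp2, events_df("deletion", cut + 3L, 1L, ""))  # mid-run
  got <- extract_events(align_read(read, loc2), loc2)
  del <- got[got$kind == "deletion", ]
  expect_equal(nrow(del), 1L)
  # leftmost equivalent position: start of the A-run (or further left if the
  # reference base before the run is also A)
  s <- del$start
  ref_ch <- strsplit(amp2, "")[[1]]
  expect_true(s == 0L || ref_ch[s] != ref_ch[s + del$ref_span])
})

test_that("off-window mismatches go to diagnostics, not allele definition", {
  loc <- test_locus()
  far <- loc$guides[[1]]$cut_pos - 100L
  read <- apply_events(loc$amplicon, events_df("substitution", far, 1L, "A"))
  if (substr(loc$amplicon, far + 1, far + 1) == "A")
    read <- apply_events(loc$amplicon, events_df("substitution", far, 1L, "C"))
  got <- extract_events(align_read(read, loc), loc)
  expect_equal(nrow(got), 0L)
  expect_equal(nrow(attr(got, "diagnostics")), 1L)
  # with filtering off the event is retained
  got2 <- extract_events(align_read(read, loc), loc, filter_outside = FALSE)
  expect_equal(nrow(got2), 1L)
})

test_that("reads collapse into alleles with summed support (8:1 example)", {
  loc <- test_locus()
  d73 <- apply_events(loc$amplicon,
                      events_df("deletion", loc$guides[[1]]$cut_pos - 5L, 73L, ""))
  d6 <- apply_events(loc$amplicon,
                     events_df("deletion", loc$guides[[2]]$cut_pos - 3L, 6L, ""))
  reads <- data.frame(read_id = sprintf("r%02d", 1:9),
                      seq = c(rep(d73, 8), d6), stringsAsFactors = FALSE)
  al <- collapse_alleles(call_reads(reads, loc))
  expect_equal(nrow(al), 2L)
  expect_equal(sort(al$support, decreasing = TRUE), c(8L, 1L))
  expect_true(all(al$edited))

  # all-WT reads give the single WT allele
  wt_reads <- data.frame(read_id = c("a", "b"), seq = rep(loc$amplicon, 2))
  al_wt <- collapse_alleles(call_reads(wt_reads, loc))
  expect_equal(al_wt$allele, "WT")
  expect_false(al_wt$edited)
  expect_equal(al_wt$support, 2L)

  # min_support flags singletons without dropping them
  al2 <- collapse_alleles(call_reads(reads, loc), min_support = 2L)
  expect_equal(sum(al2$low_support), 1L)
  expect_equal(nrow(al2), 2L)
})

test_that("the same deletion at different gap placements is one allele", {
  loc <- test_locus()
  cut <- loc$guides[[2]]$cut_pos
  amp2 <- paste0(substr(loc$amplicon, 1, cut), "AAAA",
                 substr(loc$amplicon, cut + 5, nchar(loc$amplicon)))
  loc2 <- loc; loc2$amplicon <- amp2
  # two placements of the same 1-bp A deletion
  r1 <- apply_events(amp2, events_df("deletion", cut + 0L, 1L, ""))
  r2 <- apply_events(amp2, events_df("deletion", cut + 3L, 1L, ""))
  expect_identical(r1, r2)
  al <- collapse_alleles(call_reads(data.frame(read_id = c("x", "y"),
                                               seq = c(r1, r2)), loc2))
  expect_equal(nrow(al), 1L)
  expect_equal(al$support, 2L)
})

test_that("called events reconstruct each read exactly (noise-free)", {
  loc <- test_locus()
  set.seed(22)
  for (i in 1:40) {
    a <- simulate_allele(loc)
    got <- extract_events(align_read(a$seq, loc), loc)
    expect_identical(apply_events(loc$amplicon, got), a$seq)
    expect_true(all(diff(got$start) >= 0))
  }
})
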