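test_that("degenerate parameters give an unedited allele; dropout is exact without jitter", {
  loc <- test_locus()
  p0 <- edit_params(p_small_del = 0, p_large_del = 0, p_small_ins = 0,
                    p_large_ins = 0, p_small_sub = 0, p_dropout = 0)
  set.seed(1)
  a <- simulate_allele(loc, p0)
  expect_identical(a$seq, loc$amplicon)
  expect_equal(nrow(a$truth), 0L)

  pd <- edit_params(p_small_del = 0, p_large_del = 0, p_small_ins = 0,
                    p_large_ins = 0, p_small_sub = 0, p_dropout = 1,
                    dropout_jitter = 0L)
  set.seed(2)
  d <- simulate_allele(loc, pd)
  expect_equal(nrow(d$truth), 1L)
  expect_equal(d$truth$size, loc$inter_guide_span)
  expect_true(d$truth$inter_guide_dropout)
  expect_equal(nchar(d$seq), nchar(loc$amplicon) - loc$inter_guide_span)
})

test_that("edited length obeys the deletion/insertion bookkeeping for every allele", {
  loc <- test_locus()
  set.seed(3)
  for (i in 1:200) {
    a <- simulate_allele(loc)
    tr <- a$truth
    net <- sum(tr$size[tr$kind == "insertion"]) - sum(tr$size[tr$kind == "deletion"])
    expect_equal(nchar(a$seq), nchar(loc$amplicon) + net)
    expect_identical(apply_events(loc$amplicon, tr), a$seq)
    # every planted event touches a guide window or spans both cuts
    if (nrow(tr) > 0) expect_true(all(tr$guide_hit != "none"))
  }
})

test_that("plant classes realize the requested allele structure", {
  loc <- test_locus()
  set.seed(4)
  wt <- simulate_plant(loc, "WT_WT")
  expect_identical(unname(wt$alleles), loc$amplicon)

  mono <- simulate_plant(loc, "monoallelic")
  expect_equal(length(mono$alleles), 2L)
  expect_true("WT" %in% names(mono$alleles))
  expect_false(mono$alleles[["A1"]] == loc$amplicon)

  chi7 <- simulate_plant(loc, "chimera_all_edited", n_alleles = 7L)
  expect_equal(length(chi7$alleles), 7L)
  expect_equal(anyDuplicated(chi7$alleles), 0L)
  expect_false(any(chi7$alleles == loc$amplicon))

  p0 <- edit_params(p_small_del = 0, p_large_del = 0, p_small_ins = 0,
                    p_large_ins = 0, p_small_sub = 0, p_dropout = 0)
  expect_error(simulate_plant(loc, "biallelic", p0, max_tries = 5L),
               "unreachable")
})

test_that("subclone sampling follows allele weights and places noise outside windows", {
  loc <- test_locus()
  set.seed(5)
  bi <- simulate_plant(loc, "biallelic")
  # 8:1 weighting over many draws concentrates on the first allele
  reads <- sample_subclones(bi, 900L, weights = c(8, 1))
  frac <- mean(reads$allele == "A1")
  expect_gt(frac, 8 / 9 - 3 * sqrt((8 / 9) * (1 / 9) / 900))
  expect_lt(frac, 8 / 9 + 3 * sqrt((8 / 9) * (1 / 9) / 900))

  wt <- simulate_plant(loc, "WT_WT")
  r5 <- sample_subclones(wt, 5L)
  expect_true(all(r5$seq == loc$amplicon))

  # error fraction over eligible bases within 3 binomial SDs of the rate
  noisy <- sample_subclones(wt, 1000L, locus = loc, noise = 0.01)
  rate <- sum(noisy$n_errors) / sum(noisy$n_eligible)
  se <- sqrt(0.01 * 0.99 / sum(noisy$n_eligible))
  expect_lt(abs(rate - 0.01), 3 * se)
  # no injected error inside a guide window
  w1 <- guide_window(loc, 1); w2 <- guide_window(loc, 2)
  same_win <- vapply(noisy$seq, function(s)
    substr(s, w1[1] + 1, w1[2]) == substr(loc$amplicon, w1[1] + 1, w1[2]) &&
      substr(s, w2[1] + 1, w2[2]) == substr(loc$amplicon, w2[1] + 1, w2[2]),
    logical(1))
  expect_true(all(same_win))
})

test_that("degenerate superposition matches the positional IUPAC oracle", {
  loc <- test_locus()
  amp <- loc$amplicon
  # identical templates: no ambiguity codes
  expect_identical(make_degenerate(c(amp, amp)), amp)

  # WT + 1-bp deletion: clean prefix, ambiguity-bearing suffix
  del1 <- apply_events(amp, events_df("deletion", loc$guides[[2]]$cut_pos, 1L, ""))
  cons <- make_degenerate(c(amp, del1))
  expect_identical(cons, oracle_superpose(amp, del1))
  pre <- substr(cons, 1, loc$guides[[2]]$cut_pos)
  expect_identical(pre, substr(amp, 1, loc$guides[[2]]$cut_pos))
  expect_true(grepl("[RYSWKM]", substr(cons, loc$guides[[2]]$cut_pos + 1, nchar(cons))))

  # WT + inter-guide dropout: ambiguity onset at the upstream cut site
  drop <- apply_events(amp, events_df("deletion", loc$guides[[1]]$cut_pos,
                                      loc$inter_guide_span, ""))
  cons2 <- make_degenerate(c(amp, drop))
  expect_identical(cons2, oracle_superpose(amp, drop))
  first_amb <- regexpr("[RYSWKMBDHVN]", cons2)
  expect_gte(as.integer(first_amb), loc$guides[[1]]$cut_pos - 5L)
  expect_lte(as.integer(first_amb), loc$guides[[1]]$cut_pos + loc$inter_guide_span + 5L)
})

test_that("cohort simulation is seed-reproducible and order-independent per plant", {
  loc <- test_locus()
  c1 <- simulate_cohort(loc, 6L, n_subclones = 5L, seed = 99L)
  c2 <- simulate_cohort(loc, 6L, n_subclones = 5L, seed = 99L)
  expect_identical(lapply(c1$plants, `[[`, "reads"),
                   lapply(c2$plants, `[[`, "reads"))
  # writing twice gives byte-identical outputs
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # FASTA round trip
  rd <- read_subclone_fasta(file.path(d1, "reads", paste0(c1$plants[[1]]$id, ".fasta")))
  expect_identical(rd$seq, c1$plants[[1]]$reads$seq)
})

test_that("simulated class frequencies follow the mixture within binomial error", {
  loc <- test_locus()
  mix <- c(biallelic = 0.5, monoallelic = 0.5)
  cls <- local({
    co <- simulate_cohort(loc, 200L, class_mix = mix, n_subclones = 1L, seed = 7L)
    vapply(co$plants, `[[`, character(1), "intended_class")
  })
  p_hat <- mean(cls == "biallelic")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("spectra simulator covers the default grid and plants detectable effects", {
  set.seed(6)
  ss <- simulate_spectra()
  expect_equal(length(ss$wavenumbers), 901L)  # (4000 - 400) / 4 + 1
  expect_equal(dim(ss$absorbance), c(20L, 901L))

  # planted band at 5x noise SD: group-mean difference exceeds 3x pooled SE
  b <- data.frame(center = 1510, width = 10, effect = 0.05)
  ss2 <- simulate_spectra(bands = b, noise_sd = 0.01)
  i <- which.min(abs(ss2$wavenumbers - 1510))
  g <- ss2$groups
  d <- mean(ss2$absorbance[g == "edited", i]) - mean(ss2$absorbance[g == "control", i])
  se <- sqrt(stats::var(ss2$absorbance[g == "edited", i]) / sum(g == "edited") +
               stats::var(ss2$absorbance[g == "control", i]) / sum(g == "control"))
  expect_gt(abs(d) / se, 3)

  # zero effect: difference at the same band is noise-level
  b0 <- data.frame(center = 1510, width = 10, effect = 0)
  ss3 <- simulate_spectra(bands = b0, noise_sd = 0.01)
  d0 <- mean(ss3$absorbance[ss3$groups == "edited", i]) -
    mean(ss3$absorbance[ss3$groups == "control", i])
  expect_lt(abs(d0), 5 * 0.01)

  expect_error(simulate_spectra(bands = data.frame(center = 9000, width = 5,
                                                   effect = 1)),
               "outside")
})
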