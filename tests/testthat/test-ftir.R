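test_that("preprocessing removes a known baseline and normalizes area", {
  grid <- seq(400, 4000, by = 4)
  peak <- 0.8 * exp(-(grid - 1600)^2 / (2 * 30^2))
  lin <- 0.1 + 0.00005 * grid
  X <- rbind(lin + peak, lin + peak)
  ss <- spectra_set(grid, X, c("a", "a", "b", "b")[1:2])
  pp <- preprocess_spectra(ss, baseline = "polynomial")
  keep <- grid >= 800
  i_peak <- which.min(abs(pp$wavenumbers - 1600))
  # baseline residual away from the peak is < 1% of peak height (scaled)
  far <- which(abs(pp$wavenumbers - 1600) > 400)
  expect_lt(max(pp$absorbance[1, far]) / pp$absorbance[1, i_peak], 0.02)
  # unit area, zero minimum
  y <- pp$absorbance[1, ]
  x <- pp$wavenumbers
  area <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  expect_equal(min(y), 0)
  # the final offset step lifts the curve by |min|, so the integral sits
  # slightly above the unit normalization
  expect_lt(abs(area - 1), 0.1)

  # flat constant spectrum -> all zeros; all-zero input is fatal
  flat <- spectra_set(grid, rbind(rep(2, length(grid)), rep(2, length(grid))),
                      c("a", "b"))
  pf <- preprocess_spectra(flat, baseline = "rubberband")
  expect_true(all(abs(pf$absorbance) < 1e-10))
  zero <- spectra_set(grid, matrix(0, 2, length(grid)), c("a", "b"))
  expect_error(preprocess_spectra(zero), "degenerate spectrum")
})

test_that("replicate averaging reduces to one spectrum per sample", {
  set.seed(51)
  ss <- simulate_spectra(n_per_group = c(4L, 4L))
  ids <- rep(c("s1", "s2", "s3", "s4"), each = 2)
  avg <- average_replicates(ss, ids)
  expect_equal(nrow(avg$absorbance), 4L)
  expect_equal(avg$absorbance[1, ],
               colMeans(ss$absorbance[1:2, ]), ignore_attr = TRUE)
  expect_error(average_replicates(ss, rep(c("x", "y"), 4)), "several groups")
})

test_that("NIPALS satisfies score orthogonality and deflation monotonicity", {
  set.seed(52)
  ss <- simulate_spectra(noise_sd = 0.01)
  pp <- preprocess_spectra(ss)
  fit <- fit_plsda(pp, ncomp = 3L)
  S <- fit$scores
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(sum(S[, i] * S[, j])),
              1e-8 * sqrt(sum(S[, i]^2) * sum(S[, j]^2)))
  expect_true(all(fit$expl_var >= 0))
  expect_lte(sum(fit$expl_var), 100 + 1e-8)
  # residual SS strictly decreases with each component
  rs <- vapply(1:3, function(k) fit_plsda(pp, ncomp = k)$residual_ss, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_lt(rs[1], fit$total_ss)
})

test_that("fit is invariant to sample order and global positive scaling", {
  set.seed(53)
  ss <- simulate_spectra(n_per_group = c(5L, 5L))
  pp <- preprocess_spectra(ss)
  fit <- fit_plsda(pp, 2L)
  perm <- sample(nrow(pp$absorbance))
  ssp <- spectra_set(pp$wavenumbers, pp$absorbance[perm, ], pp$groups[perm])
  fitp <- fit_plsda(ssp, 2L)
  expect_equal(abs(fitp$loadings), abs(fit$loadings), tolerance = 1e-6)
  ss2 <- spectra_set(pp$wavenumbers, 3.7 * pp$absorbance, pp$groups)
  fit2 <- fit_plsda(ss2, 2L)
  expect_equal(fit2$expl_var, fit$expl_var, tolerance = 1e-8)
  cor12 <- abs(stats::cor(fit2$scores[, 1], fit$scores[, 1]))
  expect_gt(cor12, 1 - 1e-10)
})

test_that("a strong planted band separates groups on component 1", {
  set.seed(54)
  ss <- simulate_spectra(bands = data.frame(center = 1510, width = 10,
                                            effect = 0.1),  # 10x noise SD
                         noise_sd = 0.01)
  pp <- preprocess_spectra(ss)
  fit <- fit_plsda(pp, 2L)
  t1 <- fit$scores[, 1]
  r1 <- range(t1[pp$groups == "control"])
  r2 <- range(t1[pp$groups == "edited"])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])  # zero overlap
})

test_that("duplicated columns receive identical loadings", {
  set.seed(55)
  ss <- simulate_spectra(n_per_group = c(4L, 4L), grid = seq(1000, 1400, 4),
                         bands = data.frame(center = 1200, width = 10,
                                            effect = 0.05))
  X <- ss$absorbance
  X[, 51] <- X[, 50]
  ss2 <- spectra_set(ss$wavenumbers, X, ss$groups)
  fit <- fit_plsda(ss2, 2L)
  expect_equal(fit$loadings[50, ], fit$loadings[51, ], tolerance = 1e-10)
})

test_that("scores agree with the mixOmics PLS-DA up to sign", {
  skip_if_not_installed("mixOmics")
  set.seed(56)
  ss <- simulate_spectra(n_per_group = c(6L, 6L), grid = seq(1000, 1800, 4))
  pp <- preprocess_spectra(ss)
  fit <- fit_plsda(pp, 2L)
  mo <- mixOmics::plsda(pp$absorbance, pp$groups, ncomp = 2, scale = FALSE)
  for (h in 1:2) {
    r <- abs(stats::cor(fit$scores[, h], mo$variates$X[, h]))
    expect_gt(r, 0.99)
  }
})

test_that("permuted labels give no component-1 separation (null case)", {
  set.seed(57)
  ss <- simulate_spectra(bands = data.frame(center = 1510, width = 10,
                                            effect = 0),
                         noise_sd = 0.01)
  pp <- preprocess_spectra(ss)
  seps <- replicate(60, {
    g <- sample(pp$groups)
    f <- fit_plsda(spectra_set(pp$wavenumbers, pp$absorbance, g), 1L)
    diff(f$group_means[, 1])
  })
  f0 <- fit_plsda(pp, 1L)
  sep0 <- abs(diff(f0$group_means[, 1]))
  # the observed separation sits inside the permutation null distribution
  expect_gt(mean(abs(seps) >= sep0), 0.05)
})

test_that("planted bands are recovered and annotated; direction follows the effect", {
  set.seed(58)
  bands <- data.frame(center = c(1035, 1510, 1595), width = c(12, 10, 14),
                      effect = c(0.05, -0.05, -0.05))
  ss <- simulate_spectra(bands = bands, noise_sd = 0.01)
  pp <- preprocess_spectra(ss)
  fit <- fit_plsda(pp, 2L)
  sel <- select_bands(fit, pp)
  rec <- band_recovery(sel, bands$center)
  expect_true(all(rec))
  # the 1510 band (lignin aromatic skeleton) is lower in the edited group
  hit <- sel[abs(sel$wavenumber - 1510) <= 8, ]
  expect_true(any(hit$direction == "lower"))
  lign <- sel[abs(sel$wavenumber - 1510) <= 8 & sel$annotation != "", ]
  if (nrow(lign) > 0) expect_match(lign$annotation[1], "lignin")
})
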