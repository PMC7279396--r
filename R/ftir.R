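#' Labeled FTIR spectra set
#'
#' Container for an absorbance matrix on a common wavenumber grid with a
#' group label per sample.
#'
#' @param wavenumbers strictly monotone grid in cm^-1.
#' @param absorbance numeric matrix, samples x wavenumbers.
#' @param groups factor (or coercible) of length `nrow(absorbance)`.
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, absorbance, groups) {
  absorbance <- as.matrix(absorbance)
  d <- diff(wavenumbers)
  if (length(wavenumbers) < 2 || !(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotone")
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance columns must match the wavenumber grid")
  groups <- factor(groups)
  if (length(groups) != nrow(absorbance))
    stop("one group label per sample is required")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 absorbance = absorbance, groups = groups),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " spectra x ",
      length(x$wavenumbers), " wavenumbers (",
      min(x$wavenumbers), "-", max(x$wavenumbers), " cm-1); groups: ",
      paste(levels(x$groups), table(x$groups), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate two-group FTIR spectra with planted discriminant bands
#'
#' Each spectrum is a smooth low-order polynomial baseline (random
#' coefficients per spectrum) plus a set of Gaussian peaks shared by all
#' samples, plus, for the second group, amplitude shifts at the planted
#' discriminant bands, plus white noise. Emulates attenuated-total-reflection
#' absorbance spectra of milled root cell-wall material on the standard
#' 400-4000 cm^-1 grid at 4 cm^-1 resolution (901 points).
#'
#' @param n_per_group samples per group (length-2).
#' @param grid wavenumber grid (default `seq(400, 4000, by = 4)`).
#' @param bands data.frame with `center` (cm^-1), `width` (Gaussian sd,
#'   cm^-1) and `effect` (absorbance shift in the second group; negative =
#'   lower absorbance in the edited group).
#' @param noise_sd white-noise standard deviation (absorbance units).
#' @param n_shared_peaks number of shared background peaks.
#' @param group_names two group labels.
#' @return a `spectra_set`; the planted band table is kept as attribute
#'   `"truth_bands"`.
#' @export
simulate_spectra <- function(n_per_group = c(10L, 10L),
                             grid = seq(400, 4000, by = 4),
                             bands = data.frame(center = c(1035, 1510, 1595),
                                                width = c(12, 10, 14),
                                                effect = c(0.05, -0.05, -0.05)),
                             noise_sd = 0.01, n_shared_peaks = 8L,
                             group_names = c("control", "edited")) {
  if (nrow(bands) > 0 &&
      (any(bands$center < min(grid)) || any(bands$center > max(grid))))
    stop("planted band center outside the wavenumber grid")
  n <- sum(n_per_group)
  groups <- factor(rep(group_names, n_per_group), levels = group_names)
  gauss <- function(c0, w) exp(-(grid - c0)^2 / (2 * w^2))

  centers <- stats::runif(n_shared_peaks, min(grid) + 150, max(grid) - 150)
  widths <- stats::runif(n_shared_peaks, 20, 80)
  amps <- stats::runif(n_shared_peaks, 0.2, 1.0)
  shared <- Reduce(`+`, Map(function(c0, w, a) a * gauss(c0, w),
                            centers, widths, amps))

  u <- (grid - mean(grid)) / (diff(range(grid)) / 2)
  X <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    coefs <- stats::runif(3, -0.1, 0.1)
    baseline <- coefs[1] + coefs[2] * u + coefs[3] * u^2 + 0.2
    eff <- if (groups[i] == group_names[2] && nrow(bands) > 0)
      Reduce(`+`, Map(function(c0, w, a) a * gauss(c0, w),
                      bands$center, bands$width, bands$effect))
      else 0
    X[i, ] <- baseline + shared + eff + stats::rnorm(length(grid), 0, noise_sd)
  }
  ss <- spectra_set(grid, X, groups)
  attr(ss, "truth_bands") <- bands
  ss
}

# Lower convex hull baseline (rubberband), Andrew monotone chain.
.rubberband <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      # drop b if it lies above segment a-i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  stats::approx(x[hull], y[hull], xout = x)$y
}

# Iterative polynomial baseline (order 2): refit on the points at or below
# the running fit (plus a noise allowance), so peaks are excluded rather
# than clamped and the fit converges to the true background.
.polybaseline <- function(x, y, order = 2L, iter = 10L) {
  xs <- (x - mean(x)) / stats::sd(x)
  M <- outer(xs, 0:order, `^`)
  sel <- rep(TRUE, length(y))
  base <- y
  for (k in seq_len(iter)) {
    fit <- qr.coef(qr(M[sel, , drop = FALSE]), y[sel])
    base <- as.numeric(M %*% fit)
    resid <- y - base
    tol <- 2 * sqrt(mean(pmin(resid, 0)^2)) + 1e-12
    sel_new <- resid <= tol
    if (sum(sel_new) < order + 2L) break
    if (identical(sel_new, sel)) break
    sel <- sel_new
  }
  base
}

#' Preprocess FTIR spectra
#'
#' Per spectrum, in order: baseline correction (iterative order-2 polynomial
#' by default, or convex-hull rubberband), normalization to unit integrated
#' absorbance over the analysis range, and offset correction subtracting the
#' per-spectrum minimum. The analysis range defaults to 800-4000 cm^-1 (the
#' low-wavenumber end is dominated by ATR artifacts).
#'
#' The polynomial baseline is the default for discriminant analysis: the
#' rubberband's convex lower hull follows genuine negative-going group
#' differences wherever they fall near the spectral envelope's minima and
#' can absorb a substantial part of a band's between-group contrast, whereas
#' the low-order polynomial removes only broad curvature. The rubberband
#' remains available for strongly curved backgrounds.
#'
#' A constant spectrum baseline-corrects to all zeros and is passed through
#' unnormalized; an all-zero input spectrum is an error.
#'
#' @param ss a `spectra_set`.
#' @param baseline `"polynomial"` or `"rubberband"`.
#' @param range analysis range `c(lo, hi)` in cm^-1.
#' @return a preprocessed `spectra_set` cropped to `range`.
#' @export
preprocess_spectra <- function(ss, baseline = c("polynomial", "rubberband"),
                               range = c(800, 4000)) {
  baseline <- match.arg(baseline)
  keep <- ss$wavenumbers >= range[1] & ss$wavenumbers <= range[2]
  x <- ss$wavenumbers[keep]
  if (any(diff(x) < 0)) { ord <- order(x) } else ord <- seq_along(x)
  X <- ss$absorbance[, keep, drop = FALSE][, ord, drop = FALSE]
  xg <- x[ord]
  out <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    y <- X[i, ]
    if (all(y == 0)) stop("degenerate spectrum: all-zero absorbance (sample ", i, ")")
    y <- y - switch(baseline,
                    polynomial = .polybaseline(xg, y),
                    rubberband = .rubberband(xg, y))
    area <- sum(diff(xg) * (y[-1] + y[-length(y)]) / 2)
    if (abs(area) > 1e-12) y <- y / area
    out[i, ] <- y - min(y)
  }
  res <- spectra_set(xg, out, ss$groups)
  attr(res, "truth_bands") <- attr(ss, "truth_bands")
  res
}

#' Average replicate spectra per biological sample
#'
#' @param ss a `spectra_set`.
#' @param sample_ids one id per spectrum; replicates share an id.
#' @return a `spectra_set` with one mean spectrum per id (group taken from
#'   the replicates, which must agree).
#' @export
average_replicates <- function(ss, sample_ids) {
  ids <- unique(sample_ids)
  X <- t(vapply(ids, function(id)
    colMeans(ss$absorbance[sample_ids == id, , drop = FALSE]),
    numeric(ncol(ss$absorbance))))
  grp <- vapply(ids, function(id) {
    g <- unique(as.character(ss$groups[sample_ids == id]))
    if (length(g) != 1) stop("replicates of '", id, "' span several groups")
    g
  }, character(1))
  res <- spectra_set(ss$wavenumbers, X, factor(grp, levels = levels(ss$groups)))
  attr(res, "truth_bands") <- attr(ss, "truth_bands")
  res
}

#' Fit a two-group PLS-DA by NIPALS
#'
#' Partial least squares discriminant analysis: PLS2 regression of the
#' column-centered absorbance matrix X on centered one-hot group indicators
#' Y, computed component-by-component with the iterative NIPALS algorithm
#' and deflation of X (and Y) after each component. Reported per component:
#' X-scores, X-loadings, weights and the percentage of X variance explained.
#'
#' @param ss a (preprocessed) `spectra_set` with exactly two groups and at
#'   least two samples per group.
#' @param ncomp number of latent components (default 2).
#' @param max_iter,tol NIPALS iteration cap and convergence tolerance.
#' @return object of class `plsda_fit`: `scores` (n x ncomp), `loadings`
#'   (p x ncomp), `weights`, `y_loadings`, `expl_var` (% X variance per
#'   component), `group_means` (in score space), `groups`, `wavenumbers`,
#'   `x_mean`.
#' @export
fit_plsda <- function(ss, ncomp = 2L, max_iter = 500L, tol = 1e-10) {
  X0 <- ss$absorbance
  grp <- ss$groups
  if (nlevels(grp) != 2) stop("PLS-DA here is two-group: got ", nlevels(grp))
  if (any(table(grp) < 2)) stop("need at least 2 samples per group")
  if (ncomp > min(nrow(X0) - 1L, ncol(X0)))
    stop("ncomp exceeds min(samples - 1, wavenumbers)")
  x_mean <- colMeans(X0)
  X <- sweep(X0, 2, x_mean)
  Y <- stats::model.matrix(~ grp - 1)
  Y <- sweep(Y, 2, colMeans(Y))
  ss_tot <- sum(X^2)

  n <- nrow(X); p <- ncol(X)
  Tm <- matrix(0, n, ncomp); P <- matrix(0, p, ncomp)
  W <- matrix(0, p, ncomp); Q <- matrix(0, ncol(Y), ncomp)
  expl <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    u <- Y[, 1]
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_vec <- X %*% w
      q <- crossprod(Y, t_vec)[, 1] / sum(t_vec^2)
      u <- (Y %*% q)[, 1] / sum(q^2)
      if (sqrt(sum((t_vec - t_old)^2)) < tol * sqrt(sum(t_vec^2))) {
        converged <- TRUE
        break
      }
      t_old <- t_vec
    }
    if (!converged)
      stop("NIPALS did not converge for component ", h, " after ",
           max_iter, " iterations (last score delta ",
           format(sqrt(sum((t_vec - t_old)^2))), ")")
    t_vec <- as.numeric(t_vec)
    pvec <- crossprod(X, t_vec)[, 1] / sum(t_vec^2)
    X <- X - tcrossprod(t_vec, pvec)
    Y <- Y - tcrossprod(t_vec, q)
    Tm[, h] <- t_vec; P[, h] <- pvec; W[, h] <- w; Q[, h] <- q
    expl[h] <- 100 * sum(t_vec^2) * sum(pvec^2) / ss_tot
  }
  gm <- apply(Tm, 2, function(tc) tapply(tc, grp, mean))
  structure(list(ncomp = ncomp, scores = Tm, loadings = P, weights = W,
                 y_loadings = Q, expl_var = expl, group_means = gm,
                 groups = grp, wavenumbers = ss$wavenumbers, x_mean = x_mean,
                 residual_ss = sum(X^2), total_ss = ss_tot),
            class = "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat("<plsda_fit> ", x$ncomp, " components; explained X variance: ",
      paste(sprintf("%.1f%%", x$expl_var), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select discriminant wavenumbers from PLS-DA loadings
#'
#' Wavenumbers whose absolute loading on component 1 or 2 exceeds the
#' `threshold_quantile` of that component's absolute-loading distribution
#' are selected; contiguous selections merge to the position of their
#' loading extremum. Direction is the sign of the difference of the group
#' median spectra at that wavenumber (second group minus first). Bands are
#' annotated from the bundled cell-wall band-assignment table when their
#' wavenumber falls in an annotated range.
#'
#' @param model a `plsda_fit`.
#' @param ss the `spectra_set` the model was fitted on.
#' @param threshold_quantile loading-magnitude quantile (default 0.95).
#' @param components components to scan (default `1:min(2, ncomp)`).
#' @return data.frame: `wavenumber`, `component`, `loading`, `direction`
#'   (`"higher"`/`"lower"` in the second group), `annotation`.
#' @export
select_bands <- function(model, ss, threshold_quantile = 0.95,
                         components = seq_len(min(2L, model$ncomp))) {
  grid <- model$wavenumbers
  med <- apply(ss$absorbance, 2, function(col) tapply(col, ss$groups, stats::median))
  dmed <- med[2, ] - med[1, ]
  ann <- .band_annotations()
  rows <- list()
  for (h in components) {
    lo <- model$loadings[, h]
    thr <- stats::quantile(abs(lo), threshold_quantile)
    sel <- abs(lo) > thr
    if (!any(sel)) next
    runs <- rle(sel)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      idx <- starts[r]:ends[r]
      peak <- idx[which.max(abs(lo[idx]))]
      wn <- grid[peak]
      hit <- ann[ann$from <= wn & ann$to >= wn, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        wavenumber = wn, component = h, loading = lo[peak],
        direction = if (dmed[peak] < 0) "lower" else "higher",
        annotation = if (nrow(hit) > 0) hit$assignment[1] else "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(wavenumber = numeric(), component = integer(),
                      loading = numeric(), direction = character(),
                      annotation = character()))
  out <- do.call(rbind, rows)
  out[order(out$component, out$wavenumber), , drop = FALSE]
}

.band_annotations <- function() {
  path <- system.file("extdata", "ftir_band_annotations.tsv", package = "ampedit")
  if (path == "") return(data.frame(from = numeric(), to = numeric(),
                                    assignment = character()))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Bands reproducible across reseeded cohorts
#'
#' A quantile-threshold loading rule always selects its top fraction of
#' wavenumbers, even on pure noise; what distinguishes real discriminant
#' bands is reproducibility. A wavenumber is reseed-stable when every run's
#' selection contains a band within `tol_cm` of it.
#'
#' @param band_list list of [select_bands()] results (or wavenumber vectors)
#'   from independently reseeded cohorts.
#' @param tol_cm matching tolerance in cm^-1 (default 8).
#' @return numeric vector of stable wavenumbers (positions from the first
#'   run; empty when nothing reproduces).
#' @export
stable_bands <- function(band_list, tol_cm = 8) {
  wns <- lapply(band_list, function(b) if (is.data.frame(b)) b$wavenumber else b)
  if (length(wns) == 0) return(numeric(0))
  Reduce(function(acc, w) acc[vapply(acc, function(x) any(abs(w - x) <= tol_cm),
                                     logical(1))], wns[-1], wns[[1]])
}

#' Match selected bands against planted truth bands
#'
#' @param bands a [select_bands()] result.
#' @param truth_centers planted band centers (cm^-1).
#' @param tol_cm matching tolerance in cm^-1 (default 8 = two 4 cm^-1 grid
#'   steps).
#' @return logical vector, one per truth center: recovered or not.
#' @export
band_recovery <- function(bands, truth_centers, tol_cm = 8) {
  vapply(truth_centers, function(c0)
    any(abs(bands$wavenumber - c0) <= tol_cm), logical(1))
}
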