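makePeakVector <- function(frag, basis, areas, halfWidth = 0.3) {
  new("PeakVector", fragment = frag, centers = mz(basis[[1]]),
      areas = areas, halfWidth = halfWidth)
}

test_that("noiseless mixtures are recovered exactly from the basis", {
  frag <- angiotensin()
  basis <- basisEnvelopes(frag)
  A <- sapply(basis, abundance)

  fstar <- c(0, 0.5, 0.5, 0, 0, 0, 0)
  pv <- makePeakVector(frag, basis, as.numeric(A %*% fstar))
  prof <- fitComposition(pv, basis)
  expect_lt(max(abs(fractions(prof) - fstar)), 1e-6)
  expect_false(prof@degenerate)

  # a single basis column yields a delta profile
  pv1 <- makePeakVector(frag, basis, abundance(basis[[4]]))
  prof1 <- fitComposition(pv1, basis)
  expect_lt(max(abs(fractions(prof1) - c(0, 0, 0, 1, 0, 0, 0))), 1e-6)

  expect_error(fitComposition(makePeakVector(frag, basis, rep(0, nrow(A))),
                              basis), "zero")
})

test_that("two-population envelope is deconvoluted to the printed fractions", {
  # 6-amide peptide carrying 5 D in 6.3% and 6 D in 93.7% of molecules
  frag <- angiotensin()
  sp <- renderSpectrum(frag, angiotensinProfile(), noiseSd = 0)
  res <- deconvoluteSpectrum(sp, frag)
  f <- fractions(res)
  expect_lt(abs(f[["f5"]] - 0.063), 0.005)
  expect_lt(abs(f[["f6"]] - 0.937), 0.005)
  expect_lt(max(abs(f[c("f0", "f1", "f2", "f3", "f4")])), 0.005)
})

test_that("profile summaries match their definitions", {
  p <- angiotensinProfile()
  expect_equal(averageExchanged(p), 5.937, tolerance = 1e-9)
  expect_equal(deuterationRatio(p), 98.95, tolerance = 1e-9)

  delta0 <- compositionProfile(c(1, rep(0, 6)))
  expect_identical(averageExchanged(delta0), 0)
  expect_identical(deuterationRatio(delta0), 0)

  deltaN <- compositionProfile(c(rep(0, 6), 1))
  expect_identical(deuterationRatio(deltaN), 100)

  unif <- compositionProfile(rep(0.1, 10))
  expect_equal(averageExchanged(unif), 4.5, tolerance = 1e-12)

  # the two summaries are exactly consistent
  set.seed(11)
  for (i in 1:20) {
    p <- compositionProfile(randomProfile(8))
    expect_identical(deuterationRatio(p),
                     100 * averageExchanged(p) / nAmide(p))
  }

  noAmide <- compositionProfile(1, nAmide = 0L)
  expect_error(deuterationRatio(noAmide), "undefined")
})

test_that("fitted peak vectors decompose into their components", {
  frag <- angiotensin()
  basis <- basisEnvelopes(frag)

  delta <- compositionProfile(c(0, 0, 0, 0, 1, 0, 0))
  fv <- fittedPeakVector(delta, basis, scale = 12, fragment = frag)
  expect_equal(peakAreas(fv), 12 * abundance(basis[[5]]), tolerance = 1e-12)

  sp <- renderSpectrum(frag, angiotensinProfile(), noiseSd = 0)
  res <- deconvoluteSpectrum(sp, frag)
  comp <- attr(res@fitted, "components")
  expect_equal(rowSums(comp), peakAreas(res@fitted), tolerance = 1e-12)

  # mixture fit beats the best single-component fit
  obs <- extractPeakVector(sp, frag, basis)
  y <- peakAreas(obs) / sum(peakAreas(obs))
  singleResiduals <- vapply(seq_along(basis), function(k) {
    a <- abundance(basis[[k]])
    coef <- max(0, sum(a * y) / sum(a * a))
    sqrt(sum((coef * a - y)^2))
  }, numeric(1))
  expect_lte(res@residualNorm, min(singleResiduals) + 1e-12)
})

test_that("the NNLS solution beats random feasible profiles", {
  frag <- peptideFragment("GKSTFVE")
  basis <- basisEnvelopes(frag)
  A <- sapply(basis, abundance)
  set.seed(99)
  truth <- randomProfile(length(basis))
  y <- as.numeric(A %*% truth) + abs(rnorm(nrow(A), sd = 0.01))
  pv <- makePeakVector(frag, basis, y)
  prof <- fitComposition(pv, basis)
  yn <- y / sum(y)
  fitRes <- attr(prof, "residualNorm")
  for (i in 1:100) {
    cand <- randomProfile(length(basis))
    # allow candidates the same overall scale freedom the fit has
    sc <- max(0, sum((A %*% cand) * yn) / sum((A %*% cand)^2))
    candRes <- sqrt(sum((sc * A %*% cand - yn)^2))
    expect_lte(fitRes, candRes + 1e-9)
  }
})

test_that("average uptake is recovered within 0.1 atoms at high SNR", {
  frag <- angiotensin()
  basis <- basisEnvelopes(frag)
  set.seed(2020)
  errs <- replicate(100, {
    truth <- compositionProfile(randomProfile(length(basis)))
    sp <- renderSpectrum(frag, truth, noiseSd = 0.02,
                         seed = sample.int(1e6, 1))
    res <- deconvoluteSpectrum(sp, frag, basis = basis)
    abs(averageExchanged(res) - averageExchanged(truth))
  })
  # recovered within 0.1 atoms across the 100 random profiles
  expect_lt(mean(errs), 0.1)
})

test_that("batch processing crosses spectra with fragments deterministically", {
  dir <- withr::local_tempdir()
  frag1 <- angiotensin()
  frag2 <- peptideFragment("GKSTFVE", name = "frag2")
  # each spectrum carries the envelopes of both digestion fragments
  writeDigest <- function(path, p1, p2, seed) {
    spA <- renderSpectrum(frag1, compositionProfile(p1), noiseSd = 0.002,
                          seed = seed)
    spB <- renderSpectrum(frag2, compositionProfile(p2), noiseSd = 0.002,
                          seed = seed + 1L)
    df <- rbind(data.frame(x = mz(spA), y = intensity(spA)),
                data.frame(x = mz(spB), y = intensity(spB)))
    df <- df[order(df$x), ]
    write.table(df, path, row.names = FALSE, col.names = FALSE)
  }
  writeDigest(file.path(dir, "a_t1min.txt"),
              c(0, 0, 0, 0, 0, 0.063, 0.937),
              c(0.1, 0.2, 0.3, 0.2, 0.1, 0.05, 0.05), 3L)
  writeDigest(file.path(dir, "b_t5min.txt"),
              c(0, 0, 0.2, 0.3, 0.5, 0, 0),
              c(0, 0.5, 0.5, 0, 0, 0, 0), 5L)
  writeDigest(file.path(dir, "c_t40min.txt"),
              c(0.2, 0.2, 0.2, 0.2, 0.1, 0.05, 0.05),
              c(0, 0, 0, 0, 0, 0.5, 0.5), 7L)

  res <- batchProcess(dir, list(frag1, frag2))
  expect_equal(nrow(res), 6L)  # 3 spectra x 2 fragments
  expect_equal(res$time_min, rep(c(1, 5, 40), each = 2))
  expect_equal(res$fragment, rep(c("angiotensin II", "frag2"), 3))
  expect_true(all(res$n_amide == rep(c(6L, 6L), 3)))

  # one corrupt file: its pairs are skipped, the rest survive
  writeLines("not a spectrum at all", file.path(dir, "broken.txt"))
  expect_warning(res2 <- batchProcess(dir, list(frag1, frag2)),
                 "skipping unreadable")
  expect_equal(nrow(res2), 6L)

  # determinism: byte-identical CSV on rerun
  f1 <- file.path(dir, "r1.csv"); f2 <- file.path(dir, "r2.csv")
  write.csv(res, f1, row.names = FALSE)
  res3 <- batchProcess(dir, list(frag1, frag2),
                       pattern = "^[abc]_.*\\.txt$")
  write.csv(res3, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(batchProcess(withr::local_tempdir(), list(frag1)), "no spectrum")
})
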