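test_that("elemental composition sums residue formulas plus water", {
  gg <- compositionFromSequence(peptideFragment("GG"))
  expect_identical(gg, c(C = 4L, H = 8L, N = 2L, O = 3L, S = 0L))
  # frozen independent oracle (pyteomics): GG neutral monoisotopic mass
  expect_equal(monoisotopicMass(peptideFragment("GG")), 132.05349212,
               tolerance = 1e-4 / 132)

  g <- compositionFromSequence(peptideFragment("G"))
  expect_identical(g, c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))

  # frozen independent oracle (pyteomics): FERRIGQPTLL [M+H]+ and composition
  frag <- peptideFragment("FERRIGQPTLL")
  expect_identical(compositionFromSequence(frag),
                   c(C = 60L, H = 100L, N = 18L, O = 16L, S = 0L))
  expect_equal(monoisotopicMass(frag, protonated = TRUE), 1329.76374567,
               tolerance = 1e-4 / 1329)
})

test_that("unknown residues are rejected naming the offender", {
  expect_error(peptideFragment("GZG"), "Z.*position 2")
  expect_error(peptideFragment(""), "non-empty|unknown")
})

test_that("fragment range must match sequence length and charge is fixed", {
  expect_error(peptideFragment("DRVYIHPF", start = 1, end = 9),
               "rangeEnd")
  f <- peptideFragment("DRVYIHPF", start = 1, end = 8)
  expect_identical(f@charge, 1L)
})

test_that("exchangeable-site counting follows the amide and labile rules", {
  # angiotensin II: six backbone amide hydrogens
  ang <- countExchangeSites(peptideFragment("DRVYIHPF"))
  expect_identical(ang[["n_amide"]], 6L)
  # AK1 107-117: deuterium incorporations run 0 to 9
  ak <- countExchangeSites(peptideFragment("FERRIGQPTLL"))
  expect_identical(ak[["n_amide"]], 9L)
  # single residue: no peptide bond, no amide
  expect_identical(countExchangeSites(peptideFragment("A"))[["n_amide"]], 0L)
})

test_that("site classes partition the hydrogens for random sequences", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(2:25, 1)
    sq <- randomSequence(L)
    frag <- peptideFragment(sq)
    sites <- countExchangeSites(frag)
    res <- strsplit(sq, "")[[1]]
    expect_identical(sites[["n_amide"]],
                     L - 1L - as.integer(sum(res[-1] == "P")))
    expect_identical(sum(sites),
                     compositionFromSequence(frag)[["H"]])
    expect_true(all(sites >= 0))
  }
})

test_that("single-carbon and C100 envelopes match closed forms", {
  e <- naturalIsotopicDistribution(c(C = 1L), protonated = FALSE)
  expect_equal(mz(e), c(12.0000000, 13.0033548378), tolerance = 1e-9)
  expect_equal(abundance(e), c(0.9893, 0.0107), tolerance = 1e-12)

  e100 <- naturalIsotopicDistribution(c(C = 100L), protonated = FALSE,
                                      pruneThreshold = 0)
  expect_equal(abundance(e100)[1], 0.9893^100, tolerance = 1e-10)
  # binomial closed form for the +1 peak
  expect_equal(abundance(e100)[2], 100 * 0.9893^99 * 0.0107,
               tolerance = 1e-10)
})

test_that("envelopes are normalized, ordered, and start at the light peak", {
  for (sq in c("G", "DRVYIHPF", "FERRIGQPTLL", "CWM")) {
    comp <- compositionFromSequence(peptideFragment(sq))
    e <- naturalIsotopicDistribution(comp)
    expect_equal(sum(abundance(e)), 1, tolerance = 1e-12)
    expect_true(all(diff(mz(e)) > 0))
    expect_equal(mz(e)[1], monoisotopicMass(comp, protonated = TRUE),
                 tolerance = 1e-9)
    expect_equal(which.max(mz(e) == mz(e)[1]), 1L)
  }
  expect_error(naturalIsotopicDistribution(c(C = 0L)), "empty")
  expect_error(naturalIsotopicDistribution(c(C = 5L), pruneThreshold = 1e-3))
})

test_that("convolution equals exhaustive isotopologue enumeration", {
  formulas <- list(c(C = 2L, H = 3L, N = 1L, O = 1L),  # glycyl residue
                   c(C = 1L, H = 4L),
                   c(H = 2L, O = 1L, S = 1L),
                   c(C = 3L, O = 2L, S = 1L),
                   c(N = 2L, O = 2L, S = 2L),
                   c(C = 2L, H = 2L, N = 2L, O = 1L, S = 1L))
  for (fm in formulas) {
    oracle <- enumerateEnvelope(fm)
    p <- maldiHDX:::.compositionPattern(fm)
    for (i in seq_along(oracle$offset)) {
      got <- patternAbundance(p, oracle$offset[i])
      expect_lt(abs(got - oracle$abundance[i]), 1e-10)
      if (got > 1e-12)
        expect_lt(abs(patternMass(p, oracle$offset[i]) - oracle$mass[i]), 1e-6)
    }
    # no probability outside the enumerated bins
    expect_equal(sum(p$ab), 1, tolerance = 1e-12)
  }
})

test_that("deuterated envelopes shift rigidly and mix binomially", {
  frag <- peptideFragment("DRVYIHPF")
  sites <- countExchangeSites(frag)
  base <- naturalIsotopicDistribution(compositionFromSequence(frag))
  noSide <- c(n_amide = sites[["n_amide"]], n_side = 0L, n_fixed = 0L)

  # identity at k = 0 with no side chains
  e0 <- deuteratedEnvelope(base, 0, noSide)
  expect_equal(mz(e0), mz(base))
  expect_equal(abundance(e0), abundance(base))

  # rigid shift of the centroid by k * 1.006277 Da
  e2 <- deuteratedEnvelope(base, 2, noSide)
  expect_equal(envelopeCentroid(e2) - envelopeCentroid(base), 2 * 1.006277,
               tolerance = 1e-12)

  # binomial n = 1: mixture of shifted and unshifted
  oneSide <- c(n_amide = sites[["n_amide"]], n_side = 1L, n_fixed = 0L)
  e1 <- deuteratedEnvelope(base, 0, oneSide, solventDFraction = 0.9)
  expect_equal(envelopeCentroid(e1),
               0.1 * envelopeCentroid(base) +
                 0.9 * (envelopeCentroid(base) + 1.006277),
               tolerance = 1e-9)

  expect_error(deuteratedEnvelope(base, 7, noSide), "kAmideD")
  expect_error(deuteratedEnvelope(base, -1, noSide), "kAmideD")
  expect_error(deuteratedEnvelope(base, 0, sites, solventDFraction = 0))
})

test_that("mass conservation: centroid spacing is exactly k * (mD - mH)", {
  frag <- peptideFragment("FERRIGQPTLL")
  sites <- countExchangeSites(frag)
  base <- naturalIsotopicDistribution(compositionFromSequence(frag))
  c0 <- envelopeCentroid(deuteratedEnvelope(base, 0, sites))
  for (k in 1:sites[["n_amide"]]) {
    ck <- envelopeCentroid(deuteratedEnvelope(base, k, sites))
    expect_equal(ck - c0, k * 1.006277, tolerance = 1e-6)
  }
})

test_that("centroid mass is monotone in the solvent deuterium fraction", {
  frag <- peptideFragment("DRVYIHPF")
  sites <- countExchangeSites(frag)
  base <- naturalIsotopicDistribution(compositionFromSequence(frag))
  for (k in c(0L, 3L)) {
    cents <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0), function(p)
      envelopeCentroid(deuteratedEnvelope(base, k, sites, p)), numeric(1))
    expect_true(all(diff(cents) > 0))
  }
})

test_that("basis envelopes share a grid and cover 0..n_amide", {
  basis <- basisEnvelopes(peptideFragment("FERRIGQPTLL"))
  expect_length(basis, 10L)
  grid <- mz(basis[[1]])
  for (e in basis) {
    expect_equal(mz(e), grid)
    expect_equal(sum(abundance(e)), 1, tolerance = 1e-9)
  }
  expect_true(all(diff(grid) > 0.99 & diff(grid) < 1.01))

  # no amides: a single envelope
  basisA <- basisEnvelopes(peptideFragment("A"))
  expect_length(basisA, 1L)
})
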