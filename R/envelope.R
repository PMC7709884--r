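#' @include constants.R AllClasses.R
NULL

## ---- internal isotope-pattern engine -------------------------------------
##
## A pattern is a list(ab, msum) of equal-length vectors indexed by neutron
## offset 0, 1, 2, ... relative to the all-light isotopologue: ab[i] is the
## total probability of carrying (i - 1) extra neutrons and msum[i] the
## probability-weighted sum of the exact masses in that nominal bin. The
## bin's reported mass is msum/ab, i.e. the abundance-weighted mean mass.
## Aggregating by neutron count is exact for total mass and probability and
## matches what a reflectron TOF resolves: fine structure within a nominal
## bin (13C vs 15N vs 2H substitutions) is never separated.

.elementPattern <- function(element) {
  iso <- .ISOTOPES[[element]]
  off <- round(iso$mass - iso$mass[1])
  ab <- numeric(max(off) + 1L)
  msum <- numeric(max(off) + 1L)
  ab[off + 1L] <- iso$abundance
  msum[off + 1L] <- iso$abundance * iso$mass
  list(ab = ab, msum = msum)
}

.convolvePatterns <- function(a, b) {
  na <- length(a$ab); nb <- length(b$ab)
  ab <- numeric(na + nb - 1L)
  msum <- numeric(na + nb - 1L)
  for (i in seq_len(na)) {
    if (a$ab[i] == 0 && a$msum[i] == 0) next
    idx <- i:(i + nb - 1L)
    ab[idx] <- ab[idx] + a$ab[i] * b$ab
    msum[idx] <- msum[idx] + a$ab[i] * b$msum + a$msum[i] * b$ab
  }
  .trimPattern(list(ab = ab, msum = msum))
}

## drop negligible trailing bins so repeated convolution stays small; leading
## bins are kept so array position i always means neutron offset i - 1
.trimPattern <- function(p, floor = 1e-15) {
  keep <- which(p$ab > floor)
  if (!length(keep)) return(p)
  sub <- seq_len(max(keep))
  list(ab = p$ab[sub], msum = p$msum[sub])
}

.patternPower <- function(p, n) {
  ## exponentiation by squaring
  stopifnot(n >= 1)
  out <- NULL
  sq <- p
  while (n > 0) {
    if (n %% 2 == 1) out <- if (is.null(out)) sq else .convolvePatterns(out, sq)
    n <- n %/% 2
    if (n > 0) sq <- .convolvePatterns(sq, sq)
  }
  out
}

## pattern of a whole composition (named counts of C/H/N/O/S)
.compositionPattern <- function(composition) {
  composition <- composition[composition > 0]
  if (!length(composition)) stop("empty elemental composition")
  pats <- lapply(names(composition), function(el) {
    if (is.null(.ISOTOPES[[el]])) stop("unknown element: ", el)
    .patternPower(.elementPattern(el), composition[[el]])
  })
  Reduce(.convolvePatterns, pats)
}

## ---- exported envelope operations ----------------------------------------

#' Theoretical isotopic envelope of a composition
#'
#' Computes the natural-abundance isotopic envelope by iterative convolution
#' of the elemental isotope patterns (standard IUPAC abundances), aggregated
#' into nominal-mass bins whose reported m/z is the abundance-weighted mean
#' mass of the bin. Peaks below \code{pruneThreshold} are removed and the
#' envelope renormalized to unit sum.
#'
#' @param composition Named integer vector of C/H/N/O/S counts (e.g. from
#'   \code{\link{compositionFromSequence}}).
#' @param pruneThreshold Abundance below which peaks are pruned
#'   (must be < 1e-3).
#' @param protonated If TRUE (default), report the singly protonated ion
#'   [M+H]+: the proton is added as a fixed mass of 1.007276 Da. Use FALSE
#'   for the neutral/bare envelope.
#' @param label Species label stored in the envelope.
#' @return An \linkS4class{IsotopicEnvelope}.
#' @examples
#' frag <- peptideFragment("DRVYIHPF")
#' naturalIsotopicDistribution(compositionFromSequence(frag))
#' @export
naturalIsotopicDistribution <- function(composition, pruneThreshold = 1e-6,
                                        protonated = TRUE, label = "") {
  stopifnot(pruneThreshold >= 0, pruneThreshold < 1e-3)
  if (!length(composition) || all(composition == 0))
    stop("empty elemental composition")
  p <- .compositionPattern(composition)
  ab <- p$ab
  mass <- ifelse(ab > 0, p$msum / ab, NA_real_)
  keep <- which(ab > pruneThreshold & ab > 0)
  if (!length(keep)) stop("pruneThreshold removed every peak")
  keep <- min(keep):max(keep)         # keep bins contiguous
  keep <- keep[ab[keep] > 0]
  ab <- ab[keep]; mass <- mass[keep]
  if (protonated) mass <- mass + .PROTON_MASS
  new("IsotopicEnvelope", mz = mass, abundance = ab / sum(ab), label = label)
}

#' Envelope of a species carrying k backbone-amide deuteriums
#'
#' Shifts a base envelope rigidly by \code{kAmideD} times the D-H mass
#' difference (1.006277 Da) and convolves it with a binomial occupancy
#' distribution over the \code{n_side} fast-exchanging side-chain/terminal
#' sites, each deuterated independently with probability
#' \code{solventDFraction} (the quench-solvent D fraction). The component
#' index k therefore counts only backbone amide deuteriums; the side-chain
#' contribution is identical across components and is what the fit removes
#' computationally.
#'
#' @param base An \linkS4class{IsotopicEnvelope}: the all-protium envelope
#'   of the ion (see \code{\link{basisEnvelopes}} for its construction).
#' @param kAmideD Number of amide deuteriums, 0 <= k <= n_amide.
#' @param sites Named vector from \code{\link{countExchangeSites}}.
#' @param solventDFraction Deuterium fraction of the quench solvent, in
#'   (0, 1]; default 0.9 (the H:D = 1:9 exchange condition).
#' @return An \linkS4class{IsotopicEnvelope} on nominal-mass bins.
#' @export
deuteratedEnvelope <- function(base, kAmideD, sites, solventDFraction = 0.9) {
  stopifnot(is(base, "IsotopicEnvelope"))
  nAmide <- sites[["n_amide"]]; nSide <- sites[["n_side"]]
  if (kAmideD < 0 || kAmideD > nAmide)
    stop(sprintf("kAmideD must lie in [0, %d], got %s", nAmide, kAmideD))
  if (solventDFraction <= 0 || solventDFraction > 1)
    stop("solventDFraction must lie in (0, 1]")
  shift <- kAmideD * .DELTA_DH
  if (nSide == 0) {
    return(new("IsotopicEnvelope", mz = base@mz + shift,
               abundance = base@abundance,
               label = sprintf("k=%d", kAmideD)))
  }
  j <- 0:nSide
  w <- stats::dbinom(j, nSide, solventDFraction)
  ## all (mass, abundance) pairs, then aggregate by nominal bin
  mass <- as.vector(outer(base@mz + shift, j * .DELTA_DH, `+`))
  ab <- as.vector(outer(base@abundance, w, `*`))
  idx <- round(mass - min(mass))
  ab2 <- tapply(ab, idx, sum)
  m2 <- tapply(ab * mass, idx, sum) / ab2
  keep <- ab2 > 0
  ord <- order(as.numeric(names(ab2)))
  ab2 <- ab2[ord][keep[ord]]; m2 <- m2[ord][keep[ord]]
  new("IsotopicEnvelope", mz = as.numeric(m2),
      abundance = as.numeric(ab2) / sum(ab2),
      label = sprintf("k=%d", kAmideD))
}

#' Basis envelopes for every deuterium incorporation count
#'
#' Builds the n_amide + 1 theoretical envelopes (k = 0 .. n_amide amide
#' deuteriums) of a fragment's [M+H]+ ion, aligned on a common nominal-mass
#' grid with zero padding so they can serve as columns of the mixture-fit
#' design matrix.
#'
#' The all-protium base envelope is computed on the elemental formula with
#' the n_side labile hydrogens removed from the natural-abundance
#' convolution and re-added as fixed protium mass; their deuterium occupancy
#' is then modeled explicitly by \code{\link{deuteratedEnvelope}}.
#'
#' @param fragment A \linkS4class{PeptideFragment}.
#' @param solventDFraction Quench-solvent deuterium fraction, default 0.9.
#' @param pruneThreshold Abundance pruning threshold for the base envelope.
#' @return List of \linkS4class{IsotopicEnvelope}, length n_amide + 1, all
#'   sharing the same \code{mz} grid.
#' @examples
#' basis <- basisEnvelopes(peptideFragment("FERRIGQPTLL"))
#' length(basis)  # 10 envelopes: 0 to 9 deuteriums
#' @export
basisEnvelopes <- function(fragment, solventDFraction = 0.9,
                           pruneThreshold = 1e-6) {
  sites <- countExchangeSites(fragment)
  comp <- compositionFromSequence(fragment)
  reduced <- comp
  reduced["H"] <- reduced["H"] - sites[["n_side"]]
  stopifnot(reduced["H"] > 0)
  base <- naturalIsotopicDistribution(reduced, pruneThreshold,
                                      protonated = TRUE)
  base@mz <- base@mz + sites[["n_side"]] * .H1_MASS
  envs <- lapply(0:sites[["n_amide"]], function(k)
    deuteratedEnvelope(base, k, sites, solventDFraction))
  ## align on the union nominal grid, anchored at the k=0 monoisotopic peak
  mono0 <- envs[[1]]@mz[1]
  idxs <- lapply(envs, function(e) as.integer(round(e@mz - mono0)))
  grid <- sort(unique(unlist(idxs)))
  ## grid center = abundance-weighted mean m/z over all components
  num <- den <- numeric(length(grid))
  for (i in seq_along(envs)) {
    pos <- match(idxs[[i]], grid)
    num[pos] <- num[pos] + envs[[i]]@abundance * envs[[i]]@mz
    den[pos] <- den[pos] + envs[[i]]@abundance
  }
  centers <- num / den
  lapply(seq_along(envs), function(i) {
    ab <- numeric(length(grid))
    ab[match(idxs[[i]], grid)] <- envs[[i]]@abundance
    new("IsotopicEnvelope", mz = centers, abundance = ab,
        label = envs[[i]]@label)
  })
}

#' Intensity-weighted centroid of an envelope
#'
#' @param envelope An \linkS4class{IsotopicEnvelope}.
#' @return Abundance-weighted mean m/z (Da).
#' @export
envelopeCentroid <- function(envelope) {
  sum(envelope@mz * envelope@abundance) / sum(envelope@abundance)
}
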