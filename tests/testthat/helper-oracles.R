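# Independent oracles and fixture builders shared across tests.

# Exhaustive isotopologue enumeration: every assignment of an isotope to every
# atom, aggregated into nominal (neutron-count) bins. Independent of the
# package's convolution engine; tractable only for tiny formulas.
enumerateEnvelope <- function(composition) {
  iso <- list(
    C = list(mass = c(12.0000000, 13.0033548378), ab = c(0.9893, 0.0107)),
    H = list(mass = c(1.0078250319, 2.0141017780), ab = c(0.999885, 0.000115)),
    N = list(mass = c(14.0030740052, 15.0001088984), ab = c(0.99636, 0.00364)),
    O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
             ab = c(0.99757, 0.00038, 0.00205)),
    S = list(mass = c(31.97207069, 32.9714585, 33.96786683, 35.96708088),
             ab = c(0.9499, 0.0075, 0.0425, 0.0001)))
  atoms <- rep(names(composition), composition)
  stopifnot(length(atoms) <= 8)
  choices <- expand.grid(lapply(atoms, function(el)
    seq_along(iso[[el]]$mass)), KEEP.OUT.ATTRS = FALSE)
  mass <- prob <- off <- numeric(nrow(choices))
  prob[] <- 1
  for (j in seq_along(atoms)) {
    el <- iso[[atoms[j]]]
    idx <- choices[[j]]
    mass <- mass + el$mass[idx]
    prob <- prob * el$ab[idx]
    off <- off + round(el$mass[idx] - el$mass[1])
  }
  ab <- tapply(prob, off, sum)
  m <- tapply(prob * mass, off, sum) / ab
  ord <- order(as.numeric(names(ab)))
  list(offset = as.numeric(names(ab))[ord], abundance = as.numeric(ab)[ord],
       mass = as.numeric(m)[ord])
}

# abundance of a pattern bin, treating bins beyond the stored (trimmed)
# range as zero
patternAbundance <- function(p, offset) {
  idx <- offset + 1L
  ifelse(idx <= length(p$ab), p$ab[idx], 0)
}

patternMass <- function(p, offset) {
  idx <- offset + 1L
  if (idx > length(p$ab) || p$ab[idx] == 0) return(NA_real_)
  p$msum[idx] / p$ab[idx]
}

# random valid peptide sequence
randomSequence <- function(len, letters = rownames(maldiHDX:::.RESIDUE_FORMULAS)) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# random point on the simplex (Dirichlet(1,...,1))
randomProfile <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

angiotensin <- function() peptideFragment("DRVYIHPF", name = "angiotensin II")

angiotensinProfile <- function() compositionProfile(c(0, 0, 0, 0, 0, 0.063, 0.937))
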