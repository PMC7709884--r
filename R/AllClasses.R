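#' PeptideFragment: a singly charged peptic peptide
#'
#' Holds the one-letter sequence of a peptic fragment together with its
#' residue range in the parent protein. The analysis is restricted to singly
#' protonated MALDI ions, so \code{charge} is fixed at 1.
#'
#' @slot name Character label.
#' @slot sequence One-letter amino-acid string (20 standard residues).
#' @slot rangeStart,rangeEnd 1-based inclusive residue indices in the parent
#'   protein; \code{NA} when the fragment is not mapped to a parent.
#' @slot charge Integer, always 1.
#' @exportClass PeptideFragment
setClass("PeptideFragment",
  representation(name = "character", sequence = "character",
                 rangeStart = "integer", rangeEnd = "integer",
                 charge = "integer"),
  prototype(name = "", rangeStart = NA_integer_, rangeEnd = NA_integer_,
            charge = 1L))

setValidity("PeptideFragment", function(object) {
  msgs <- character()
  seqchars <- strsplit(object@sequence, "")[[1]]
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    msgs <- c(msgs, "sequence must be a single non-empty string")
  else {
    bad <- which(!seqchars %in% .AA_ALPHABET)
    if (length(bad))
      msgs <- c(msgs, sprintf("unknown residue '%s' at position %d",
                              seqchars[bad[1]], bad[1]))
  }
  if (!is.na(object@rangeStart) && !is.na(object@rangeEnd) &&
      length(seqchars) > 0 &&
      object@rangeEnd - object@rangeStart + 1L != nchar(object@sequence))
    msgs <- c(msgs, "rangeEnd - rangeStart + 1 must equal sequence length")
  if (!identical(object@charge, 1L))
    msgs <- c(msgs, "charge must be 1 (singly protonated MALDI ions only)")
  if (length(msgs)) msgs else TRUE
})

#' IsotopicEnvelope: normalized isotope pattern of one species
#'
#' An ordered list of (m/z, relative abundance) pairs at approximately 1 Da
#' spacing, normalized to unit total abundance. Peaks are nominal-mass bins:
#' isotopologues are aggregated by neutron count and each bin's m/z is the
#' abundance-weighted mean mass of its members.
#'
#' @slot mz Numeric, strictly increasing peak m/z (Da).
#' @slot abundance Numeric fractions summing to 1.
#' @slot label Character species label (e.g. \code{"k=3"}).
#' @exportClass IsotopicEnvelope
setClass("IsotopicEnvelope",
  representation(mz = "numeric", abundance = "numeric", label = "character"),
  prototype(label = ""))

setValidity("IsotopicEnvelope", function(object) {
  msgs <- character()
  if (length(object@mz) != length(object@abundance))
    msgs <- c(msgs, "mz and abundance must have equal length")
  if (length(object@mz) == 0L)
    msgs <- c(msgs, "envelope must contain at least one peak")
  if (any(object@abundance < 0))
    msgs <- c(msgs, "abundances must be non-negative")
  if (length(object@abundance) && abs(sum(object@abundance) - 1) > 1e-9)
    msgs <- c(msgs, "abundances must sum to 1 within 1e-9")
  if (length(object@mz) > 1L) {
    d <- diff(object@mz)
    if (any(d <= 0)) msgs <- c(msgs, "mz must be strictly increasing")
    else if (any(d < 0.99 | d > 1.01))
      msgs <- c(msgs, "consecutive peak spacing must lie within [0.99, 1.01] Da")
  }
  if (length(msgs)) msgs else TRUE
})

#' Spectrum: an ASCII mass spectrum
#'
#' @slot mz Numeric, strictly increasing m/z values (Da).
#' @slot intensity Numeric, non-negative finite intensities (arbitrary units).
#' @slot sourcePath Path the spectrum was read from ("" if in-memory).
#' @slot label Character label.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(mz = "numeric", intensity = "numeric",
                 sourcePath = "character", label = "character"),
  prototype(sourcePath = "", label = ""))

setValidity("Spectrum", function(object) {
  msgs <- character()
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have equal length")
  if (length(object@mz) < 2L)
    msgs <- c(msgs, "a spectrum needs at least 2 points")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msgs <- c(msgs, "mz must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    msgs <- c(msgs, "intensities must be finite")
  if (any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' PeakVector: areas of the theoretical isotopic peaks in one spectrum
#'
#' The quantified observation for a fragment: one integrated peak area per
#' theoretical peak center, using a fixed +/- \code{halfWidth} window.
#'
#' @slot fragment The \linkS4class{PeptideFragment} the centers belong to.
#' @slot centers Numeric, strictly increasing theoretical peak m/z (Da).
#' @slot areas Numeric, non-negative integrated areas.
#' @slot halfWidth Integration window half-width (Da).
#' @exportClass PeakVector
setClass("PeakVector",
  representation(fragment = "PeptideFragment", centers = "numeric",
                 areas = "numeric", halfWidth = "numeric"))

setValidity("PeakVector", function(object) {
  msgs <- character()
  if (length(object@centers) != length(object@areas))
    msgs <- c(msgs, "centers and areas must have equal length")
  if (length(object@centers) > 1L && any(diff(object@centers) <= 0))
    msgs <- c(msgs, "centers must be strictly increasing")
  if (any(object@areas < 0))
    msgs <- c(msgs, "areas must be non-negative")
  if (length(object@halfWidth) != 1L || object@halfWidth <= 0)
    msgs <- c(msgs, "halfWidth must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' CompositionProfile: fractions of molecules with exactly k deuteriums
#'
#' The deconvolution result: \code{fractions[k + 1]} is the fraction of
#' molecules carrying exactly k backbone-amide deuteriums, k = 0..nAmide.
#'
#' @slot fractions Numeric vector of length nAmide + 1, non-negative, unit sum.
#' @slot nAmide Integer, number of exchangeable backbone amide hydrogens.
#' @slot degenerate Logical; TRUE when the basis was rank-deficient and the
#'   fitted profile is therefore not unique.
#' @exportClass CompositionProfile
setClass("CompositionProfile",
  representation(fractions = "numeric", nAmide = "integer",
                 degenerate = "logical"),
  prototype(degenerate = FALSE))

setValidity("CompositionProfile", function(object) {
  msgs <- character()
  if (length(object@fractions) != object@nAmide + 1L)
    msgs <- c(msgs, "fractions must have length nAmide + 1")
  if (any(object@fractions < 0))
    msgs <- c(msgs, "fractions must be non-negative")
  if (abs(sum(object@fractions) - 1) > 1e-9)
    msgs <- c(msgs, "fractions must sum to 1 within 1e-9")
  if (length(msgs)) msgs else TRUE
})

#' HDXResult: per-spectrum deconvolution output
#'
#' @slot profile The fitted \linkS4class{CompositionProfile}.
#' @slot avgExchanged Average number of exchanged amide hydrogens (atoms).
#' @slot deutRatio Average deuteration ratio (percent of exchangeable amides).
#' @slot residualNorm Euclidean norm of the fit residual on the unit-sum scale.
#' @slot fitted The model-predicted \linkS4class{PeakVector}.
#' @slot spectrumLabel Label of the spectrum that was fitted.
#' @slot timePoint Exchange time (minutes), NA when unknown.
#' @exportClass HDXResult
setClass("HDXResult",
  representation(profile = "CompositionProfile", avgExchanged = "numeric",
                 deutRatio = "numeric", residualNorm = "numeric",
                 fitted = "PeakVector", spectrumLabel = "character",
                 timePoint = "numeric"),
  prototype(spectrumLabel = "", timePoint = NA_real_))

setValidity("HDXResult", function(object) {
  msgs <- character()
  n <- object@profile@nAmide
  if (object@avgExchanged < -1e-9 || object@avgExchanged > n + 1e-9)
    msgs <- c(msgs, "avgExchanged must lie in [0, nAmide]")
  if (object@deutRatio < -1e-9 || object@deutRatio > 100 + 1e-9)
    msgs <- c(msgs, "deutRatio must lie in [0, 100]")
  expAvg <- sum(seq(0, n) * object@profile@fractions)
  if (abs(object@avgExchanged - expAvg) > 1e-9)
    msgs <- c(msgs, "avgExchanged must equal sum(k * f_k)")
  if (length(msgs)) msgs else TRUE
})

#' UptakeTimeSeries: deuteration ratio as a function of exchange time
#'
#' @slot fragment Character label of the fragment or region (e.g. "14-45").
#' @slot state Character state label (e.g. "apo", "bound").
#' @slot times Numeric, strictly increasing exchange times (minutes, > 0).
#' @slot D Numeric, percent deuteration at each time.
#' @slot sd Numeric, per-point standard deviation (percent); length 0 when
#'   unavailable.
#' @exportClass UptakeTimeSeries
setClass("UptakeTimeSeries",
  representation(fragment = "character", state = "character",
                 times = "numeric", D = "numeric", sd = "numeric"),
  prototype(fragment = "", state = "", sd = numeric()))

setValidity("UptakeTimeSeries", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@D))
    msgs <- c(msgs, "times and D must have equal length")
  if (length(object@times) && (any(object@times <= 0) ||
      any(diff(object@times) <= 0)))
    msgs <- c(msgs, "times must be strictly increasing and positive")
  ## [-5, 105] rather than [0, 100]: nested-fragment subtraction of noisy data
  ## can legitimately push points slightly past the physical bounds.
  if (any(object@D < -5 | object@D > 105))
    msgs <- c(msgs, "D must lie within [-5, 105] percent")
  if (length(object@sd) && length(object@sd) != length(object@times))
    msgs <- c(msgs, "sd must be empty or match times in length")
  if (any(object@sd < 0)) msgs <- c(msgs, "sd must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' KineticsFit: parameters of the single-exponential uptake model
#'
#' Parameters of D(t) = Dinf - A * exp(-kObs * t): asymptotic uptake
#' \code{dInf}, amplitude \code{amplitude} (A), apparent first-order rate
#' constant \code{kObs}, and the derived zero-time uptake D0 = Dinf - A.
#' When the best fit drives A to zero the rate is unidentifiable and
#' \code{kObs} is NA.
#'
#' @slot dInf,amplitude,kObs Fitted parameters (percent, percent, 1/min).
#' @slot dInfSE,amplitudeSE,kObsSE Standard errors from the fit covariance.
#' @slot converged Logical convergence flag.
#' @slot fragment,state Labels carried over from the input series.
#' @exportClass KineticsFit
setClass("KineticsFit",
  representation(dInf = "numeric", amplitude = "numeric", kObs = "numeric",
                 dInfSE = "numeric", amplitudeSE = "numeric",
                 kObsSE = "numeric", converged = "logical",
                 fragment = "character", state = "character"),
  prototype(fragment = "", state = ""))

setValidity("KineticsFit", function(object) {
  msgs <- character()
  if (object@converged) {
    if (object@dInf < 0 || object@dInf > 100)
      msgs <- c(msgs, "dInf must lie in [0, 100]")
    if (object@amplitude < 0) msgs <- c(msgs, "amplitude must be >= 0")
    if (!is.na(object@kObs) && object@kObs < 0)
      msgs <- c(msgs, "kObs must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})
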