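#' @include AllClasses.R
NULL

#' @title Accessor generics
#' @description Accessors for the package's S4 classes. Use these rather than
#'   reaching into slots.
#' @param object An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))

#' @rdname accessors
#' @export
setGeneric("fragmentSequence", function(object) standardGeneric("fragmentSequence"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("nAmide", function(object) standardGeneric("nAmide"))

#' @rdname accessors
#' @export
setGeneric("peakCenters", function(object) standardGeneric("peakCenters"))

#' @rdname accessors
#' @export
setGeneric("peakAreas", function(object) standardGeneric("peakAreas"))

#' Average number of exchanged amide hydrogens
#'
#' The mean of the deuterium-count distribution, \eqn{\sum_k k f_k}.
#'
#' @param object A \linkS4class{CompositionProfile} or \linkS4class{HDXResult}.
#' @return Average number of incorporated backbone-amide deuteriums (atoms).
#' @examples
#' p <- compositionProfile(c(rep(0, 5), 0.063, 0.937))
#' averageExchanged(p)  # 5.937
#' @export
setGeneric("averageExchanged", function(object) standardGeneric("averageExchanged"))

#' Average deuteration ratio (percent)
#'
#' \code{100 * averageExchanged / nAmide}: the percentage of exchangeable
#' backbone amide hydrogens that carry deuterium on average.
#'
#' @param object A \linkS4class{CompositionProfile} or \linkS4class{HDXResult}.
#' @return Percent deuteration in [0, 100].
#' @examples
#' p <- compositionProfile(c(rep(0, 5), 0.063, 0.937))
#' deuterationRatio(p)  # 98.95
#' @export
setGeneric("deuterationRatio", function(object) standardGeneric("deuterationRatio"))

#' Zero-time uptake of the exponential uptake model
#'
#' For the model D(t) = Dinf - A exp(-k t), the value at t = 0 is
#' D0 = Dinf - A: the uptake already present at the first instant, governed by
#' sites exchanging faster than the earliest measurable time.
#'
#' @param object A \linkS4class{KineticsFit}.
#' @return D0 in percent.
#' @examples
#' fit <- fitHdxKinetics(renderTimeSeries("14-45", dInf = 89.6, amplitude = 5.5,
#'   kObs = 0.07, times = c(1, 3, 5, 7, 10, 20, 40)))
#' d0(fit)  # 84.1
#' @export
setGeneric("d0", function(object) standardGeneric("d0"))
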