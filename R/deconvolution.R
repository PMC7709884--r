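#' @include AllClasses.R AllGenerics.R
NULL

#' Deconvolute an observed peak vector into deuterium-count fractions
#'
#' Solves the non-negative least-squares problem
#' \deqn{\min_{f \ge 0} \| A f - y \|^2}
#' where column k of A is the theoretical envelope with exactly k amide
#' deuteriums sampled on the common peak grid, and y is the observed area
#' vector scaled to unit sum. The solution is renormalized to unit sum, so
#' f_k is the fraction of molecules carrying exactly k backbone amide
#' deuteriums. Non-negativity is what makes the mixture physically
#' interpretable; exact zeros arise naturally from the active set.
#'
#' @param observed A \linkS4class{PeakVector} on the same grid as the basis.
#' @param basis Basis envelopes from \code{\link{basisEnvelopes}}.
#' @return A \linkS4class{CompositionProfile} with attribute
#'   \code{"residualNorm"} (residual Euclidean norm on the unit-sum scale).
#'   If the basis matrix is numerically rank-deficient the profile's
#'   \code{degenerate} flag is set (the fit is still returned).
#' @export
fitComposition <- function(observed, basis) {
  y <- observed@areas
  if (all(y <= 0)) stop("all observed peak areas are zero; nothing to fit")
  A <- vapply(basis, function(e) e@abundance, numeric(length(basis[[1]]@mz)))
  if (nrow(A) != length(y))
    stop("observed peak vector and basis are on different grids")
  y <- y / sum(y)
  sol <- pracma::lsqnonneg(A, y)
  f <- sol$x
  if (sum(f) <= 0) stop("degenerate fit: all mixture weights zero")
  prof <- new("CompositionProfile", fractions = f / sum(f),
              nAmide = length(basis) - 1L,
              degenerate = qr(A)$rank < ncol(A))
  attr(prof, "residualNorm") <- sqrt(sum((A %*% f - y)^2))
  prof
}

#' @rdname averageExchanged
#' @export
setMethod("averageExchanged", "CompositionProfile", function(object) {
  sum(seq(0L, object@nAmide) * object@fractions)
})

#' @rdname averageExchanged
#' @export
setMethod("averageExchanged", "HDXResult", function(object)
  averageExchanged(object@profile))

#' @rdname deuterationRatio
#' @export
setMethod("deuterationRatio", "CompositionProfile", function(object) {
  if (object@nAmide == 0L)
    stop("deuteration ratio undefined for a peptide with no exchangeable amides")
  100 * averageExchanged(object) / object@nAmide
})

#' @rdname deuterationRatio
#' @export
setMethod("deuterationRatio", "HDXResult", function(object)
  deuterationRatio(object@profile))

#' Model-predicted peak vector of a fitted profile
#'
#' Reconstructs A f on the basis grid and rescales it to a given total
#' area, with the per-component contributions attached for display of the
#' individual fitted populations on the observed spectrum.
#'
#' @param profile A \linkS4class{CompositionProfile}.
#' @param basis The basis envelopes the profile was fitted against.
#' @param scale Total area of the returned vector (e.g. the observed total
#'   area); default 1.
#' @param fragment The fragment, stored in the result.
#' @param halfWidth Window half-width recorded in the result (Da).
#' @return A \linkS4class{PeakVector} with attribute \code{"components"}, a
#'   matrix whose column k + 1 is the contribution of the k-deuterium
#'   population; columns sum to the fitted vector exactly.
#' @export
fittedPeakVector <- function(profile, basis, scale = 1, fragment = NULL,
                             halfWidth = 0.3) {
  A <- vapply(basis, function(e) e@abundance, numeric(length(basis[[1]]@mz)))
  comp <- sweep(A, 2, profile@fractions, `*`) * scale
  fit <- rowSums(comp)
  if (!is(fragment, "PeptideFragment"))
    fragment <- new("PeptideFragment", sequence = "G", charge = 1L)
  pv <- new("PeakVector", fragment = fragment, centers = basis[[1]]@mz,
            areas = fit, halfWidth = halfWidth)
  colnames(comp) <- paste0("k", seq_along(basis) - 1L)
  attr(pv, "components") <- comp
  pv
}

#' Deconvolute one spectrum for one fragment
#'
#' Convenience pipeline: build the basis, quantify the peaks, fit the
#' mixture and assemble an \linkS4class{HDXResult}.
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param fragment A \linkS4class{PeptideFragment}.
#' @param solventDFraction Quench-solvent D fraction, default 0.9.
#' @param halfWidth Peak integration half-width (Da), default 0.3.
#' @param timePoint Exchange time in minutes (NA when unknown).
#' @param basis Optional precomputed basis (from
#'   \code{\link{basisEnvelopes}}) to avoid recomputation in batch runs.
#' @return An \linkS4class{HDXResult}.
#' @examples
#' frag <- peptideFragment("DRVYIHPF", name = "angiotensin II")
#' truth <- compositionProfile(c(0, 0, 0, 0, 0, 0.063, 0.937))
#' sp <- renderSpectrum(frag, truth, noiseSd = 0)
#' res <- deconvoluteSpectrum(sp, frag)
#' averageExchanged(res)
#' @export
deconvoluteSpectrum <- function(spectrum, fragment, solventDFraction = 0.9,
                                halfWidth = 0.3, timePoint = NA_real_,
                                basis = NULL) {
  if (is.null(basis)) basis <- basisEnvelopes(fragment, solventDFraction)
  obs <- extractPeakVector(spectrum, fragment, basis, halfWidth)
  prof <- fitComposition(obs, basis)
  fit <- fittedPeakVector(prof, basis, scale = sum(obs@areas),
                          fragment = fragment, halfWidth = halfWidth)
  new("HDXResult", profile = prof,
      avgExchanged = averageExchanged(prof),
      deutRatio = deuterationRatio(prof),
      residualNorm = attr(prof, "residualNorm"),
      fitted = fit, spectrumLabel = spectrum@label, timePoint = timePoint)
}

#' Batch-process a folder of ASCII spectra
#'
#' Runs the deconvolution for every (spectrum, fragment) pair: all readable
#' ASCII spectra in \code{folder} (sorted by path) crossed with the rows of
#' the fragment table. A failure on one pair is logged as a warning and the
#' batch continues; output ordering is deterministic (spectrum path, then
#' fragment order).
#'
#' An exchange time in minutes is parsed from spectrum file names containing
#' \code{"t<number>min"} (e.g. \code{apo_t5min.txt}); otherwise it is NA.
#'
#' @param folder Directory containing ASCII spectra.
#' @param fragments List of \linkS4class{PeptideFragment} (e.g. from
#'   \code{\link{readFragmentTable}}).
#' @param solventDFraction Quench-solvent D fraction, default 0.9.
#' @param halfWidth Peak integration half-width (Da), default 0.3.
#' @param pattern Regular expression selecting spectrum files,
#'   default \code{"\\\\.(txt|asc|csv|dat|xy)$"}.
#' @return A \code{data.frame} with one row per successful pair: columns
#'   \code{spectrum}, \code{fragment}, \code{time_min}, \code{n_amide},
#'   \code{f_0 .. f_N} (percent; NA beyond a fragment's own N),
#'   \code{avg_exchanged}, \code{deut_ratio_pct}, \code{residual_norm}. The
#'   \linkS4class{HDXResult} objects are attached as attribute
#'   \code{"results"}.
#' @export
batchProcess <- function(folder, fragments, solventDFraction = 0.9,
                         halfWidth = 0.3,
                         pattern = "\\.(txt|asc|csv|dat|xy)$") {
  if (!dir.exists(folder)) stop("spectrum folder not found: ", folder)
  files <- sort(list.files(folder, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no spectrum files in folder: ", folder)
  if (!length(fragments)) stop("no fragments to process")
  bases <- lapply(fragments, basisEnvelopes,
                  solventDFraction = solventDFraction)
  nMax <- max(vapply(bases, length, integer(1))) - 1L
  rows <- list(); results <- list()
  for (f in files) {
    sp <- tryCatch(readAsciiSpectrum(f), error = function(e) {
      warning(sprintf("skipping unreadable spectrum %s: %s", f,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(sp)) next
    tmin <- .parseTimeMin(basename(f))
    for (i in seq_along(fragments)) {
      res <- tryCatch(
        deconvoluteSpectrum(sp, fragments[[i]], solventDFraction, halfWidth,
                            timePoint = tmin, basis = bases[[i]]),
        error = function(e) {
          warning(sprintf("fit failed for %s / %s: %s", basename(f),
                          fragments[[i]]@name, conditionMessage(e)))
          NULL
        })
      if (is.null(res)) next
      fr <- rep(NA_real_, nMax + 1L)
      fr[seq_along(res@profile@fractions)] <- 100 * res@profile@fractions
      row <- data.frame(spectrum = basename(f),
                        fragment = fragments[[i]]@name,
                        time_min = tmin,
                        n_amide = res@profile@nAmide,
                        stringsAsFactors = FALSE)
      row[paste0("f_", 0:nMax)] <- as.list(fr)
      row$avg_exchanged <- res@avgExchanged
      row$deut_ratio_pct <- res@deutRatio
      row$residual_norm <- res@residualNorm
      rows[[length(rows) + 1L]] <- row
      results[[length(results) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("no (spectrum, fragment) pair could be processed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

.parseTimeMin <- function(filename) {
  m <- regmatches(filename,
                  regexpr("t([0-9]+(\\.[0-9]+)?)min", filename))
  if (!length(m)) return(NA_real_)
  as.numeric(sub("^t", "", sub("min$", "", m)))
}
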