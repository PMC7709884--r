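#' @include AllClasses.R envelope.R
NULL

#' Simulate a MALDI HDX spectrum with known ground truth
#'
#' Renders the mixture of deuterium-incorporation components as a profile
#' spectrum: each nominal-mass peak of each component becomes a Gaussian
#' whose full width at half maximum is \code{mz / resolution}, weighted by
#' the component fraction times the peak abundance, sampled on a regular
#' m/z axis, with optional additive Gaussian noise (seeded, clipped at 0 so
#' the result is a valid spectrum).
#'
#' @param fragment A \linkS4class{PeptideFragment}.
#' @param profile The true \linkS4class{CompositionProfile} (length must
#'   match the fragment's n_amide + 1).
#' @param resolution Mass resolving power m/dm (FWHM), default 10000
#'   (reflectron-TOF scale).
#' @param noiseSd Noise standard deviation as a fraction of the maximum
#'   signal, default 0.
#' @param solventDFraction Quench-solvent D fraction, default 0.9.
#' @param mzStep Sampling step (Da), default 0.01.
#' @param seed Integer seed for the noise; ignored when \code{noiseSd = 0}.
#' @param pad m/z padding below/above the envelope (Da), default 3.
#' @return A \linkS4class{Spectrum} with the true profile attached as
#'   attribute \code{"truth"} and the seed as attribute \code{"seed"}.
#' @examples
#' frag <- peptideFragment("DRVYIHPF")
#' truth <- compositionProfile(c(0, 0, 0, 0, 0, 0.063, 0.937))
#' sp <- renderSpectrum(frag, truth, noiseSd = 0.002, seed = 7)
#' @export
renderSpectrum <- function(fragment, profile, resolution = 10000,
                           noiseSd = 0, solventDFraction = 0.9,
                           mzStep = 0.01, seed = 1L, pad = 3) {
  stopifnot(resolution > 0, noiseSd >= 0, mzStep > 0)
  basis <- basisEnvelopes(fragment, solventDFraction)
  if (length(basis) != profile@nAmide + 1L)
    stop("profile length does not match the fragment's amide count")
  grid <- basis[[1]]@mz
  axis <- seq(min(grid) - pad, max(grid) + pad, by = mzStep)
  signal <- numeric(length(axis))
  for (k in seq_along(basis)) {
    fk <- profile@fractions[k]
    if (fk == 0) next
    env <- basis[[k]]
    for (i in seq_along(env@mz)) {
      a <- fk * env@abundance[i]
      if (a == 0) next
      sigma <- env@mz[i] / resolution / (2 * sqrt(2 * log(2)))
      signal <- signal + a * stats::dnorm(axis, env@mz[i], sigma)
    }
  }
  if (noiseSd > 0) {
    rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv()))
    set.seed(seed)
    signal <- signal + stats::rnorm(length(signal), sd = noiseSd * max(signal))
    signal[signal < 0] <- 0
  }
  sp <- newSpectrum(axis, signal,
                    label = sprintf("simulated %s", fragment@name))
  attr(sp, "truth") <- profile
  attr(sp, "seed") <- if (noiseSd > 0) seed else NA_integer_
  sp
}

#' Simulate an uptake time course from the exponential model
#'
#' Evaluates \eqn{D(t) = D_\infty - A e^{-k_{obs} t}} at the given times and
#' adds seeded Gaussian noise, clipped to [0, 100] so the series remains a
#' valid percent-deuteration course.
#'
#' @param fragment Fragment/region label.
#' @param dInf Asymptotic uptake (percent).
#' @param amplitude Exchangeable amplitude A (percent).
#' @param kObs Apparent rate constant (1/min).
#' @param times Exchange times (minutes); default the conventional
#'   1, 3, 5, 7, 10, 20, 40 min sampling.
#' @param noiseSd Noise standard deviation (percentage points), default 0.
#' @param seed Integer seed, used only when \code{noiseSd > 0}.
#' @param state State label, default "apo".
#' @return An \linkS4class{UptakeTimeSeries}; when noise is added, the
#'   per-point \code{sd} slot is set to \code{noiseSd}.
#' @export
renderTimeSeries <- function(fragment, dInf, amplitude, kObs,
                             times = c(1, 3, 5, 7, 10, 20, 40),
                             noiseSd = 0, seed = 1L, state = "apo") {
  stopifnot(dInf >= 0, dInf <= 100, amplitude >= 0, kObs >= 0, noiseSd >= 0)
  D <- .uptakeModel(times, dInf, amplitude, kObs)
  sd <- numeric()
  if (noiseSd > 0) {
    rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv()))
    set.seed(seed)
    D <- pmin(100, pmax(0, D + stats::rnorm(length(times), sd = noiseSd)))
    sd <- rep(noiseSd, length(times))
  }
  uptakeTimeSeries(times, D, sd, fragment = fragment, state = state)
}
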