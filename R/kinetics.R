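#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an uptake time series
#'
#' @param times Exchange times in minutes, strictly increasing, > 0.
#' @param D Percent deuteration at each time.
#' @param sd Optional per-point standard deviation (percent).
#' @param fragment,state Labels.
#' @return An \linkS4class{UptakeTimeSeries}.
#' @export
uptakeTimeSeries <- function(times, D, sd = numeric(), fragment = "",
                             state = "") {
  new("UptakeTimeSeries", fragment = fragment, state = state,
      times = as.numeric(times), D = as.numeric(D), sd = as.numeric(sd))
}

## single-exponential uptake model
.uptakeModel <- function(t, dInf, A, k) dInf - A * exp(-k * t)

#' Fit the single-exponential HDX uptake model
#'
#' Fits \deqn{D(t) = D_\infty - A e^{-k_{obs} t}} to an uptake time course
#' by bounded nonlinear least squares (Levenberg-Marquardt), weighted by
#' 1/sd^2 when per-point standard deviations are available.
#' \eqn{D_\infty} is the asymptotic uptake, \eqn{A} the amplitude of the
#' observable exchanging fraction, and \eqn{k_{obs}} the apparent
#' first-order rate constant averaging the individual amide exchange rates.
#' The zero-time uptake is the derived \eqn{D_0 = D_\infty - A}.
#'
#' Initialization uses \code{dInf = max(D)}, \code{A = max(D) - min(D)},
#' \code{k = 1/median(t)}, plus \code{nStarts} multiplicatively jittered
#' restarts (internal fixed seed, so the fit is deterministic); the lowest
#' weighted residual sum of squares wins. When the best fit drives the
#' amplitude to (numerically) zero the rate constant is unidentifiable and
#' the fit is reported with \code{amplitude = 0} and \code{kObs = NA}.
#'
#' @param series An \linkS4class{UptakeTimeSeries} with at least 4 points.
#' @param nStarts Number of jittered restarts, default 10.
#' @return A \linkS4class{KineticsFit}. If no start converges the fit is
#'   returned with \code{converged = FALSE} and NA parameters.
#' @examples
#' ts <- renderTimeSeries("14-45", dInf = 89.6, amplitude = 5.5, kObs = 0.07,
#'                        times = c(1, 3, 5, 7, 10, 20, 40))
#' fitHdxKinetics(ts)
#' @export
fitHdxKinetics <- function(series, nStarts = 10L) {
  t <- series@times; D <- series@D
  if (length(t) < 4L)
    stop("at least 4 time points are required to fit 3 parameters")
  w <- if (length(series@sd) && all(series@sd > 0)) 1 / series@sd^2
       else rep(1, length(t))

  ## flat series: the model degenerates to a constant
  if (diff(range(D)) < 1e-9) {
    return(new("KineticsFit", dInf = stats::weighted.mean(D, w), amplitude = 0,
               kObs = NA_real_, dInfSE = 0, amplitudeSE = 0, kObsSE = NA_real_,
               converged = TRUE, fragment = series@fragment,
               state = series@state))
  }

  base <- c(dInf = max(D), A = max(1e-3, max(D) - min(D)),
            k = 1 / stats::median(t))
  jit <- local({
    ## private RNG stream so fitting never disturbs the caller's seed
    rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(20200214L)
    matrix(exp(stats::rnorm(3L * nStarts, sd = 0.5)), ncol = 3L)
  })
  starts <- rbind(rep(1, 3), jit)

  resfun <- function(par) sqrt(w) * (.uptakeModel(t, par[1], par[2], par[3]) - D)
  best <- NULL; bestRSS <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- base * starts[i, ]
    st["dInf"] <- min(st[["dInf"]], 100)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resfun,
                         lower = c(0, 0, 0), upper = c(100, 100, 1e6),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resfun(fit$par)^2)
    if (rss < bestRSS) { bestRSS <- rss; best <- fit }
  }
  if (is.null(best)) {
    return(new("KineticsFit", dInf = NA_real_, amplitude = NA_real_,
               kObs = NA_real_, dInfSE = NA_real_, amplitudeSE = NA_real_,
               kObsSE = NA_real_, converged = FALSE,
               fragment = series@fragment, state = series@state))
  }
  cf <- best$par
  se <- tryCatch({
    dof <- length(t) - 3L
    sigma2 <- bestRSS / max(dof, 1L)
    sqrt(diag(sigma2 * solve(best$hessian)))
  }, error = function(e) rep(NA_real_, 3))
  names(se) <- names(cf)
  if (cf[["A"]] < 1e-3) {
    ## amplitude at zero: rate constant unidentifiable (reported "A 0, k -")
    m <- stats::weighted.mean(D, w)
    dofA <- length(t) - 1L
    seA <- sqrt(sum(w * (D - m)^2) / dofA / sum(w))
    return(new("KineticsFit", dInf = m, amplitude = 0,
               kObs = NA_real_, dInfSE = seA, amplitudeSE = 0,
               kObsSE = NA_real_, converged = TRUE,
               fragment = series@fragment, state = series@state))
  }
  new("KineticsFit", dInf = unname(cf["dInf"]), amplitude = unname(cf["A"]),
      kObs = unname(cf["k"]), dInfSE = unname(se["dInf"]),
      amplitudeSE = unname(se["A"]), kObsSE = unname(se["k"]),
      converged = TRUE, fragment = series@fragment, state = series@state)
}

#' @rdname d0
#' @export
setMethod("d0", "KineticsFit", function(object) object@dInf - object@amplitude)

#' Predicted uptake of a fitted model
#'
#' @param fit A \linkS4class{KineticsFit}.
#' @param times Times (minutes) at which to evaluate the model.
#' @return Percent deuteration at each time.
#' @export
predictUptake <- function(fit, times) {
  if (fit@amplitude == 0 || is.na(fit@kObs))
    return(rep(fit@dInf, length(times)))
  .uptakeModel(times, fit@dInf, fit@amplitude, fit@kObs)
}

#' Region-specific uptake by nested-fragment subtraction
#'
#' Derives the uptake of the region covered by the parent fragment but not
#' by the nested child fragment. With \eqn{n_p} and \eqn{n_c} exchangeable
#' amides in parent and child, the region's deuteration ratio at each time
#' is the amide-weighted difference
#' \deqn{D_{region} = (D_p n_p - D_c n_c) / (n_p - n_c).}
#' Per-point standard deviations propagate in quadrature. Noise can push a
#' derived point slightly outside [0, 100]; such points are flagged with a
#' warning but are not clamped.
#'
#' @param parent,child \linkS4class{UptakeTimeSeries} on identical time
#'   grids; the child region must be contained in the parent region.
#' @param nParent,nChild Exchangeable amide counts; nParent > nChild > 0.
#' @return An \linkS4class{UptakeTimeSeries} for the difference region.
#' @export
subtractNestedFragment <- function(parent, child, nParent, nChild) {
  if (length(parent@times) != length(child@times) ||
      any(abs(parent@times - child@times) > 1e-9))
    stop("parent and child must share the same time grid")
  if (nChild <= 0) stop("child must contribute at least one exchangeable amide")
  if (nParent <= nChild) stop("parent must have more exchangeable amides than child")
  D <- (parent@D * nParent - child@D * nChild) / (nParent - nChild)
  out <- which(D < 0 | D > 100)
  if (length(out))
    warning(sprintf("%d subtracted point(s) outside [0, 100] (noise); not clamped",
                    length(out)))
  sd <- if (length(parent@sd) && length(child@sd))
    sqrt((parent@sd * nParent)^2 + (child@sd * nChild)^2) / (nParent - nChild)
  else numeric()
  uptakeTimeSeries(parent@times, D, sd,
                   fragment = sprintf("%s minus %s", parent@fragment,
                                      child@fragment),
                   state = parent@state)
}

#' Fit uptake kinetics for a whole table of time courses
#'
#' Reads a long-format table (columns \code{fragment}, \code{state},
#' \code{time_min}, \code{D_pct}, optional \code{sd_pct}), fits each
#' (fragment, state) series with \code{\link{fitHdxKinetics}} and returns a
#' parameter table in the conventional kinetics layout. Unfittable series
#' yield a row with \code{converged = FALSE}; the batch continues.
#'
#' @param tab A data.frame, or a path to a CSV with the columns above.
#' @return A \code{data.frame} with one row per (fragment, state):
#'   \code{fragment}, \code{state}, \code{D_inf}, \code{D_inf_se}, \code{A},
#'   \code{A_se}, \code{k_obs}, \code{k_obs_se}, \code{D_0},
#'   \code{converged}. The \linkS4class{KineticsFit} objects are attached as
#'   attribute \code{"fits"}.
#' @export
fitKineticsTable <- function(tab) {
  if (is.character(tab)) tab <- utils::read.csv(tab, stringsAsFactors = FALSE)
  need <- c("fragment", "state", "time_min", "D_pct")
  if (!all(need %in% names(tab)))
    stop("kinetics table needs columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("kinetics table is empty")
  keys <- unique(tab[, c("fragment", "state")])
  fits <- vector("list", nrow(keys))
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- tab[tab$fragment == keys$fragment[i] & tab$state == keys$state[i], ]
    sub <- sub[order(sub$time_min), ]
    sd <- if ("sd_pct" %in% names(sub) && !anyNA(sub$sd_pct)) sub$sd_pct
          else numeric()
    fit <- tryCatch(
      fitHdxKinetics(uptakeTimeSeries(sub$time_min, sub$D_pct, sd,
                                      fragment = keys$fragment[i],
                                      state = keys$state[i])),
      error = function(e) {
        warning(sprintf("kinetics fit failed for %s/%s: %s",
                        keys$fragment[i], keys$state[i], conditionMessage(e)))
        new("KineticsFit", dInf = NA_real_, amplitude = NA_real_,
            kObs = NA_real_, dInfSE = NA_real_, amplitudeSE = NA_real_,
            kObsSE = NA_real_, converged = FALSE,
            fragment = keys$fragment[i], state = keys$state[i])
      })
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      fragment = keys$fragment[i], state = keys$state[i],
      D_inf = fit@dInf, D_inf_se = fit@dInfSE,
      A = fit@amplitude, A_se = fit@amplitudeSE,
      k_obs = fit@kObs, k_obs_se = fit@kObsSE,
      D_0 = if (fit@converged) d0(fit) else NA_real_,
      converged = fit@converged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
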