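#' Normalize reporter intensities to the reference (lowest) temperature
#'
#' Converts per-channel reporter intensities into fold changes
#' FC(T) = I(T) / I(Tmin), the quantity the melting model is fitted to.
#' The fold change at the lowest temperature is exactly 1. Proteins whose
#' reference intensity is missing or not positive cannot be normalized and
#' are excluded with reason code \code{"no_reference"}.
#'
#' @param values numeric vector of reporter intensities, one per channel.
#' @param temperatures numeric vector of channel temperatures (degrees C).
#' @return A list with \code{fc} (fold-change vector, or \code{NULL} when
#'   excluded) and \code{reason} (\code{NA} or \code{"no_reference"}).
#' @examples
#' normalizeToReference(c(100, 50, 25), c(30, 50, 70))$fc
#' @export
normalizeToReference <- function(values, temperatures) {
  if (length(values) != length(temperatures))
    stop("'values' and 'temperatures' must have equal length")
  ref <- which.min(temperatures)
  i0 <- values[ref]
  if (!is.finite(i0) || i0 <= 0)
    return(list(fc = NULL, reason = "no_reference"))
  fc <- values / i0
  fc[ref] <- 1
  list(fc = fc, reason = NA_character_)
}

#' Fold-change matrix of a ProteomeQuant
#'
#' Applies [normalizeToReference()] row-wise. Excluded proteins (no usable
#' reference intensity) are returned as all-\code{NA} rows and listed in the
#' \code{"excluded"} attribute (named vector of reason codes).
#'
#' @param x a \linkS4class{ProteomeQuant}.
#' @return Numeric matrix of fold changes with an \code{"excluded"} attribute.
#' @export
foldChanges <- function(x) {
  stopifnot(is(x, "ProteomeQuant"))
  m <- intensities(x)
  tt <- temperatures(x)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  excl <- character()
  for (i in seq_len(nrow(m))) {
    z <- normalizeToReference(m[i, ], tt)
    if (is.null(z$fc)) excl[rownames(m)[i]] <- z$reason
    else out[i, ] <- z$fc
  }
  attr(out, "excluded") <- excl
  out
}

.meltEvalNum <- function(a, b, p, temperature) {
  (1 - p) / (1 + exp(b - a / temperature)) + p
}

#' Evaluate the sigmoid melting model
#'
#' Soluble fraction f(T) = (1 - p) / (1 + exp(b - a/T)) + p. The curve is
#' strictly decreasing in T for a > 0 and bounded in (p, 1).
#'
#' @param params a \linkS4class{MeltParams}.
#' @param temperature temperature(s) in degrees C, > 0.
#' @return Soluble fraction(s) in (plateau, 1).
#' @examples
#' meltEval(MeltParams(3000, 10, 0), 300)  # 0.5 at a/b
#' @export
meltEval <- function(params, temperature) {
  stopifnot(is(params, "MeltParams"))
  if (any(temperature <= 0))
    stop("temperature must be > 0 (model domain)")
  .meltEvalNum(params@a, params@b, params@plateau, temperature)
}

.meltingPointNum <- function(a, b, p) {
  if (!is.finite(a) || !is.finite(b) || !is.finite(p)) return(NA_real_)
  if (p >= 0.5) stop("melting point undefined: plateau >= 0.5 (curve never reaches soluble fraction 0.5)")
  den <- b + log(1 - 2 * p)
  if (den <= 0) stop("melting point undefined: b + log(1 - 2*plateau) <= 0")
  a / den
}

#' Melting point (Tm) of a melting model
#'
#' Closed-form temperature where the soluble fraction equals 0.5:
#' Tm = a / (b + log(1 - 2 p)). Defined only for plateau < 0.5 with
#' b + log(1 - 2 p) > 0.
#'
#' @param object a \linkS4class{MeltParams} or \linkS4class{MeltFit}.
#' @return Tm in degrees C.
#' @examples
#' meltingPoint(MeltParams(3000, 10, 0))  # 300
#' @rdname meltingPoint
#' @export
setMethod("meltingPoint", "MeltParams", function(object) {
  .meltingPointNum(object@a, object@b, object@plateau)
})

#' @rdname meltingPoint
setMethod("meltingPoint", "MeltFit", function(object) object@tm)

.meltSlopeNum <- function(a, b, p) {
  tm <- .meltingPointNum(a, b, p)
  if (!is.finite(tm)) return(NA_real_)
  e <- exp(b - a / tm)  # equals 0.5 / (0.5 - p)
  -(1 - p) * e * a / (tm^2 * (1 + e)^2)
}

#' Slope of the melting curve at Tm
#'
#' Analytic derivative df/dT evaluated at T = Tm; negative for a > 0.
#'
#' @inheritParams meltingPoint
#' @return Slope in soluble-fraction units per degree C.
#' @examples
#' meltSlope(MeltParams(3000, 10, 0))  # -a / (4 Tm^2)
#' @rdname meltSlope
#' @export
setMethod("meltSlope", "MeltParams", function(object) {
  .meltSlopeNum(object@a, object@b, object@plateau)
})

#' @rdname meltSlope
setMethod("meltSlope", "MeltFit", function(object) object@slope)

#' Fitting options for the melting model
#'
#' @param ftol relative least-squares convergence tolerance.
#' @param maxfev maximum number of function evaluations.
#' @return A list of options for [fitMeltCurve()].
#' @export
fitOptions <- function(ftol = 1e-8, maxfev = 5000) {
  stopifnot(ftol > 0, maxfev >= 1)
  list(ftol = ftol, maxfev = as.integer(maxfev))
}

#' Stringency QC criteria for melting-curve fits
#'
#' Defaults mirror the highest-stringency significance requirements of
#' established TPP curve analysis: coefficient of determination at least
#' \code{r2Min}, control-curve post-transition plateau below
#' \code{plateauMax}, and curve slope at Tm at most \code{slopeMax}
#' (i.e. at least that steep).
#'
#' @param r2Min minimum R-squared for both fits (default 0.8).
#' @param plateauMax maximum control plateau (default 0.3).
#' @param slopeMax maximum (least-negative admissible) slope (default -0.06).
#' @return A list of criteria for [passesQC()].
#' @export
qcCriteria <- function(r2Min = 0.8, plateauMax = 0.3, slopeMax = -0.06) {
  list(r2Min = r2Min, plateauMax = plateauMax, slopeMax = slopeMax)
}

.meltFit <- function(a = NA_real_, b = NA_real_, p = NA_real_,
                     tm = NA_real_, slope = NA_real_, r2 = NA_real_,
                     converged = FALSE, qcPass = NA) {
  new("MeltFit", params = MeltParams(a, b, p), tm = tm, slope = slope,
      r2 = r2, converged = converged, qcPass = qcPass)
}

.tryFitOnce <- function(fc, tt, start, control) {
  tryCatch({
    fit <- minpack.lm::nlsLM(
      fc ~ (1 - p) / (1 + exp(b - a / tt)) + p,
      data = data.frame(fc = fc, tt = tt),
      start = start,
      lower = c(a = 1e-6, b = 1e-6, p = 0),
      upper = c(a = Inf, b = Inf, p = 0.49),
      control = control)
    est <- stats::coef(fit)
    list(est = est, ssres = sum(stats::resid(fit)^2),
         converged = fit$convInfo$isConv)
  }, error = function(e) NULL)
}

#' Fit the melting model to one protein's fold-change curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the
#' three-parameter sigmoid to fold changes, with a deterministic start
#' (plateau from the lowest observed fold change, Tm from the temperature
#' whose fold change is nearest 0.5, b = 10) and a deterministic
#' multistart fallback grid (b in {5, 10, 15, 25, 40}, plateau in
#' {0, 0.1, 0.2}) whenever the first attempt fails to converge or leaves
#' more than 2 percent of the curve variance unexplained - steep
#' transitions need large-b starts. Curves with fewer than 5 finite points, or inputs
#' the optimizer cannot fit, yield a non-converged NaN fit rather than an
#' error, so proteome-wide loops never abort.
#'
#' The single-fit QC flag requires convergence, a defined Tm, r2 >= r2Min
#' and slope <= slopeMax; the plateau criterion is pair-level and applied
#' in [passesQC()].
#'
#' @param fc fold-change vector (reference channel = 1).
#' @param tt temperatures (degrees C), same length.
#' @param options see [fitOptions()].
#' @param criteria see [qcCriteria()].
#' @return A \linkS4class{MeltFit}.
#' @examples
#' tt <- defaultTemperatures
#' fc <- meltEval(MeltParams(1000, 19, 0.1), tt)
#' fitMeltCurve(fc, tt)
#' @export
fitMeltCurve <- function(fc, tt, options = fitOptions(),
                         criteria = qcCriteria()) {
  stopifnot(length(fc) == length(tt))
  keep <- is.finite(fc) & is.finite(tt)
  fc <- fc[keep]; tt <- tt[keep]
  if (length(fc) < 5L) return(.meltFit(qcPass = FALSE))
  control <- minpack.lm::nls.lm.control(
    ftol = options$ftol, ptol = options$ftol,
    maxfev = options$maxfev, maxiter = 500)
  p0 <- min(max(min(fc) - 0.01, 0), 0.3)
  tm0 <- if (any(abs(fc - 0.5) < 0.45)) tt[which.min(abs(fc - 0.5))]
         else stats::median(tt)
  sstot <- sum((fc - mean(fc))^2)
  best <- .tryFitOnce(fc, tt, c(a = 10 * tm0, b = 10, p = p0), control)
  # multistart rescue: steep transitions (large b) sit in a different basin
  # than the default start, so refine whenever the first attempt failed or
  # explains the curve poorly
  poor <- is.null(best) || !isTRUE(best$converged) ||
    (sstot > 0 && best$ssres / sstot > 0.02)
  if (poor) {
    for (b0 in c(5, 10, 15, 25, 40)) for (pp0 in c(0, 0.1, 0.2)) {
      cand <- .tryFitOnce(fc, tt, c(a = b0 * tm0, b = b0, p = pp0), control)
      if (!is.null(cand) && isTRUE(cand$converged) &&
          (is.null(best) || !isTRUE(best$converged) ||
           cand$ssres < best$ssres))
        best <- cand
    }
  }
  if (is.null(best)) return(.meltFit(qcPass = FALSE))
  est <- best$est
  r2 <- if (sstot > 0) 1 - best$ssres / sstot else NaN
  tm <- tryCatch(.meltingPointNum(est["a"], est["b"], est["p"]),
                 error = function(e) NA_real_)
  slope <- if (is.finite(tm)) .meltSlopeNum(est["a"], est["b"], est["p"])
           else NA_real_
  qc <- isTRUE(best$converged) && is.finite(tm) &&
    isTRUE(r2 >= criteria$r2Min) && isTRUE(slope <= criteria$slopeMax)
  .meltFit(unname(est["a"]), unname(est["b"]), unname(est["p"]),
           tm = unname(tm), slope = unname(slope), r2 = r2,
           converged = isTRUE(best$converged), qcPass = qc)
}

#' Pairwise stringency QC for a control/treatment fit pair
#'
#' Passes iff both fits converged with a defined melting point, both have
#' r2 >= r2Min, the control post-transition plateau is below plateauMax,
#' and both slopes are at most slopeMax. Reasons enumerate every failed
#' criterion (\code{"not_converged"}, \code{"r2"}, \code{"plateau"},
#' \code{"slope"}).
#'
#' @param fitControl,fitTreatment \linkS4class{MeltFit} objects.
#' @param criteria see [qcCriteria()].
#' @return list with \code{pass} (logical) and \code{reasons} (character).
#' @export
passesQC <- function(fitControl, fitTreatment, criteria = qcCriteria()) {
  stopifnot(is(fitControl, "MeltFit"), is(fitTreatment, "MeltFit"))
  reasons <- character()
  ok <- function(x) isTRUE(x)
  if (!ok(fitControl@converged) || !ok(fitTreatment@converged) ||
      !is.finite(fitControl@tm) || !is.finite(fitTreatment@tm))
    reasons <- c(reasons, "not_converged")
  if (!ok(fitControl@r2 >= criteria$r2Min) ||
      !ok(fitTreatment@r2 >= criteria$r2Min))
    reasons <- c(reasons, "r2")
  if (!ok(fitControl@params@plateau < criteria$plateauMax))
    reasons <- c(reasons, "plateau")
  if (!ok(fitControl@slope <= criteria$slopeMax) ||
      !ok(fitTreatment@slope <= criteria$slopeMax))
    reasons <- c(reasons, "slope")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Fit melting curves for every protein of one condition
#'
#' Normalizes to the reference temperature and fits each protein with
#' [fitMeltCurve()]. Proteins failing normalization are retained with
#' reason codes rather than dropped.
#'
#' @param x a \linkS4class{ProteomeQuant}.
#' @param options see [fitOptions()].
#' @param criteria see [qcCriteria()].
#' @return data.frame with one row per protein: \code{protein},
#'   \code{condition}, \code{a}, \code{b}, \code{plateau}, \code{tm},
#'   \code{slope}, \code{r2}, \code{converged}, \code{qc_pass},
#'   \code{reason}.
#' @export
fitProteome <- function(x, options = fitOptions(), criteria = qcCriteria()) {
  stopifnot(is(x, "ProteomeQuant"))
  fcm <- foldChanges(x)
  excl <- attr(fcm, "excluded")
  tt <- temperatures(x)
  ids <- rownames(fcm)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id %in% names(excl)) {
      rows[[i]] <- data.frame(
        protein = id, condition = condition(x), a = NA_real_, b = NA_real_,
        plateau = NA_real_, tm = NA_real_, slope = NA_real_, r2 = NA_real_,
        converged = FALSE, qc_pass = FALSE, reason = excl[[id]],
        stringsAsFactors = FALSE)
      next
    }
    f <- fitMeltCurve(fcm[i, ], tt, options, criteria)
    rows[[i]] <- data.frame(
      protein = id, condition = condition(x), a = f@params@a,
      b = f@params@b, plateau = f@params@plateau, tm = f@tm,
      slope = f@slope, r2 = f@r2, converged = f@converged,
      qc_pass = isTRUE(f@qcPass),
      reason = if (isTRUE(f@qcPass)) NA_character_ else "fit_qc",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
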