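#' SimConfig: design of a synthetic TPP crowding experiment
#'
#' Holds every knob of the synthetic experiment generator: proteome size,
#' the temperature gradient, number of crowder treatments, the fraction
#' of protein-crowder pairs with true stabilizing/destabilizing shifts,
#' the shift magnitude distribution, the control melting-parameter
#' distributions, the multiplicative log-normal intensity noise
#' (coefficient of variation), missingness, and the RNG seed.
#'
#' @slot nProteins number of proteins (default 300).
#' @slot temperatures gradient in degrees C (default the ten-point
#'   30-70 degree gradient).
#' @slot nCrowders number of crowder treatments (default 6).
#' @slot crowderNames treatment labels; defaults to the six classic
#'   reagents (two Ficolls, two dextrans, two PEGs) when nCrowders is 6.
#' @slot fractionStabilized,fractionDestabilized per-pair probabilities of
#'   a true positive/negative shift (defaults 0.03 each).
#' @slot shiftMean,shiftSd true |delta-Tm| distribution, degrees C
#'   (defaults 5 and 1).
#' @slot shiftMin smallest admissible true |delta-Tm| (degrees C, default
#'   3): shift draws below it are resampled, so every labelled class is
#'   separated from the null population and the truth classes stay
#'   consistent with the magnitude of the shift they label.
#' @slot tmMean,tmSd control Tm distribution, degrees C (defaults 52, 5).
#' @slot plateauRange uniform range of the post-transition plateau
#'   (default [0, 0.25]).
#' @slot slopeRange uniform range of the curve slope at Tm, per degree C
#'   (default [-0.12, -0.07]; steepened automatically for low-Tm proteins
#'   so curves are fully folded at the reference temperature).
#' @slot noiseCv multiplicative log-normal noise CV on intensities
#'   (default 0.05).
#' @slot missingRate fraction of intensities set missing (default 0).
#' @slot leftSkewBias extra probability mass added to destabilizing
#'   shifts, mimicking the slight excess of lowered melting temperatures
#'   seen in crowded lysates (default 0).
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", representation(
  nProteins = "integer", temperatures = "numeric", nCrowders = "integer",
  crowderNames = "character", fractionStabilized = "numeric",
  fractionDestabilized = "numeric", shiftMean = "numeric",
  shiftSd = "numeric", shiftMin = "numeric",
  tmMean = "numeric", tmSd = "numeric",
  plateauRange = "numeric", slopeRange = "numeric", noiseCv = "numeric",
  missingRate = "numeric", leftSkewBias = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nProteins < 1L) msg <- c(msg, "nProteins must be >= 1")
  tt <- object@temperatures
  if (length(tt) < 5L || any(diff(tt) <= 0) || any(tt <= 0))
    msg <- c(msg, "temperatures must be >= 5 positive strictly increasing values")
  fr <- object@fractionStabilized + object@fractionDestabilized +
    object@leftSkewBias
  if (object@fractionStabilized < 0 || object@fractionDestabilized < 0 ||
      object@leftSkewBias < 0 || fr >= 1)
    msg <- c(msg, "shift fractions must be non-negative and sum below 1")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (object@shiftMin < 0 || object@shiftMin > object@shiftMean)
    msg <- c(msg, "shiftMin must lie in [0, shiftMean]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  pr <- object@plateauRange
  if (length(pr) != 2L || pr[1] < 0 || pr[2] >= 0.5 || pr[1] > pr[2])
    msg <- c(msg, "plateauRange must be within [0, 0.5)")
  sr <- object@slopeRange
  if (length(sr) != 2L || any(sr >= 0) || sr[1] > sr[2])
    msg <- c(msg, "slopeRange must be two negative values, increasing")
  if (length(msg)) msg else TRUE
})

.defaultCrowders <- c("ficoll70", "ficoll400", "dextran40", "dextran86",
                      "peg1", "peg8")

#' @rdname SimConfig-class
#' @param nProteins,temperatures,nCrowders,crowderNames,fractionStabilized,fractionDestabilized,shiftMean,shiftSd,shiftMin,tmMean,tmSd,plateauRange,slopeRange,noiseCv,missingRate,leftSkewBias,seed see slot descriptions.
#' @return \code{SimConfig()} returns a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(nProteins = 50, seed = 7)
#' sim <- simulateTppExperiment(cfg)
#' names(sim$quants)
#' @export
SimConfig <- function(nProteins = 300, temperatures = defaultTemperatures,
                      nCrowders = 6, crowderNames = NULL,
                      fractionStabilized = 0.03,
                      fractionDestabilized = 0.03,
                      shiftMean = 5, shiftSd = 1, shiftMin = 3,
                      tmMean = 52, tmSd = 5,
                      plateauRange = c(0, 0.25),
                      slopeRange = c(-0.12, -0.07), noiseCv = 0.05,
                      missingRate = 0, leftSkewBias = 0, seed = 1) {
  if (is.null(crowderNames))
    crowderNames <- if (nCrowders == 6L) .defaultCrowders
                    else sprintf("crowder%d", seq_len(nCrowders))
  if (length(crowderNames) != nCrowders)
    stop("need one crowder name per treatment")
  new("SimConfig", nProteins = as.integer(nProteins),
      temperatures = as.numeric(temperatures),
      nCrowders = as.integer(nCrowders),
      crowderNames = as.character(crowderNames),
      fractionStabilized = fractionStabilized,
      fractionDestabilized = fractionDestabilized,
      shiftMean = shiftMean, shiftSd = shiftSd, shiftMin = shiftMin,
      tmMean = tmMean,
      tmSd = tmSd, plateauRange = as.numeric(plateauRange),
      slopeRange = as.numeric(slopeRange), noiseCv = noiseCv,
      missingRate = missingRate, leftSkewBias = leftSkewBias,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d proteins, %d temperatures, %d crowders, noise CV %.3f, seed %d\n",
    object@nProteins, length(object@temperatures), object@nCrowders,
    object@noiseCv, object@seed))
})

# Smallest admissible |slope| (at the control Tm) so that
# exp(b - a/Tref) <= eps even for the lowest melting point the protein can
# reach under shifting; keeps curves fully folded at Tref.
.minSlopeMagnitude <- function(tmLow, tmCtrl, p, tref, eps = 1e-6) {
  aReq <- (-log(eps) - log(1 - 2 * p)) * tref * tmLow / (tmLow - tref)
  aReq / (.slopeFactor(p) * tmCtrl^2)
}

# |slope| = a * (1 - p) * E / (Tm^2 (1+E)^2) with E = 0.5/(0.5-p);
# .slopeFactor is Tm^2 |slope| / a.
.slopeFactor <- function(p) {
  e <- 0.5 / (0.5 - p)
  1 / ((1 - p) * e / (1 + e)^2)
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a complete synthetic TPP crowding experiment
#'
#' Draws, per protein, a control melting curve (Tm normal, plateau and
#' slope uniform within the configured ranges); per protein-crowder pair,
#' a true class (stabilized / destabilized / null) and an exact true
#' delta-Tm, injected by re-solving the offset parameter b while holding
#' a and the plateau, so truth shifts are analytic, not approximate; and
#' reporter intensities abundance x f(T) x log-normal noise. Curves are
#' constrained to be fully folded (soluble fraction within ~1e-6 of 1) at
#' the reference temperature, so normalized fold changes coincide with
#' the model curve and true parameters are identifiable. Low-melting
#' proteins get correspondingly steeper transitions; infeasible shifts
#' (melting point pushed to the reference temperature or below) are
#' resampled with a warning. Fully reproducible from the config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{quants} (named list of
#'   \linkS4class{ProteomeQuant}: \code{control} plus one per crowder),
#'   \code{truth} (list: \code{params} per protein x condition with true
#'   a, b, plateau, tm; \code{calls} per protein x crowder with
#'   \code{true_delta_tm} and \code{true_class}) and \code{config}.
#' @export
simulateTppExperiment <- function(config) {
  stopifnot(is(config, "SimConfig"))
  .withSeed(config@seed, {
    n <- config@nProteins
    tt <- config@temperatures
    tref <- min(tt)
    ids <- sprintf("SYN%04d", seq_len(n))
    maxShift <- config@shiftMean + 4 * config@shiftSd
    tmFloor <- tref + 6  # keep transitions inside the gradient
    tm <- numeric(n); plate <- numeric(n); aa <- numeric(n); bb <- numeric(n)
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        tmi <- stats::rnorm(1, config@tmMean, config@tmSd)
        if (tmi >= tmFloor + maxShift && tmi <= max(tt) - 2) break
        tries <- tries + 1L
        if (tries > 10000L)
          stop("cannot draw a control Tm inside the gradient; ",
               "check tmMean/tmSd against the temperature range")
      }
      p <- stats::runif(1, config@plateauRange[1], config@plateauRange[2])
      sMag <- stats::runif(1, -config@slopeRange[2], -config@slopeRange[1])
      sMin <- .minSlopeMagnitude(tmi - maxShift, tmi, p, tref)
      sMag <- max(sMag, sMin * 1.02)
      a <- sMag * tmi^2 * .slopeFactor(p)  # a from the slope at Tm
      b <- a / tmi - log(1 - 2 * p)
      tm[i] <- tmi; plate[i] <- p; aa[i] <- a; bb[i] <- b
    }
    abund <- exp(stats::rnorm(n, log(1e7), 1))
    conds <- c("control", config@crowderNames)
    pS <- config@fractionStabilized
    pD <- config@fractionDestabilized + config@leftSkewBias
    callRows <- list(); paramRows <- list(); quants <- list()
    # truth per protein x crowder
    trueDelta <- matrix(0, n, config@nCrowders,
                        dimnames = list(ids, config@crowderNames))
    trueClass <- matrix("null", n, config@nCrowders,
                        dimnames = list(ids, config@crowderNames))
    for (j in seq_len(config@nCrowders)) {
      u <- stats::runif(n)
      cls <- ifelse(u < pS, "stabilized",
                    ifelse(u < pS + pD, "destabilized", "null"))
      for (i in seq_len(n)) {
        if (cls[i] == "null") next
        sgn <- if (cls[i] == "stabilized") 1 else -1
        tries <- 0L
        warned <- FALSE
        repeat {
          d <- sgn * stats::rnorm(1, config@shiftMean, config@shiftSd)
          inMagnitude <- abs(d) >= config@shiftMin && sign(d) == sgn
          inDomain <- tm[i] + d > tmFloor && tm[i] + d < max(tt) + 10
          if (inMagnitude && inDomain) break
          if (inMagnitude && !inDomain && !warned) {
            warning("infeasible shift resampled for ", ids[i], " / ",
                    config@crowderNames[j])
            warned <- TRUE
          }
          tries <- tries + 1L
          if (tries > 100L) { d <- 0; cls[i] <- "null"; break }
        }
        trueDelta[i, j] <- d
      }
      trueClass[, j] <- cls
    }
    sdlog <- if (config@noiseCv > 0) sqrt(log(1 + config@noiseCv^2)) else 0
    for (cond in conds) {
      j <- match(cond, config@crowderNames)
      tmC <- if (cond == "control") tm else tm + trueDelta[, j]
      bC <- aa / tmC - log(1 - 2 * plate)
      curve <- vapply(seq_along(tt), function(k)
        .meltEvalNum(aa, bC, plate, tt[k]), numeric(n))
      m <- abund * curve
      if (sdlog > 0)
        m <- m * exp(matrix(stats::rnorm(length(m), 0, sdlog), nrow = n))
      if (config@missingRate > 0)
        m[stats::runif(length(m)) < config@missingRate] <- NA_real_
      dimnames(m) <- list(ids, NULL)
      quants[[cond]] <- ProteomeQuant(m, tt, cond, abundance = abund)
      paramRows[[cond]] <- data.frame(
        protein = ids, condition = cond, a = aa, b = bC, plateau = plate,
        tm = tmC, stringsAsFactors = FALSE)
    }
    calls <- data.frame(
      protein = rep(ids, config@nCrowders),
      crowder = rep(config@crowderNames, each = n),
      true_delta_tm = as.vector(trueDelta),
      true_class = as.vector(trueClass), stringsAsFactors = FALSE)
    params <- do.call(rbind, paramRows)
    rownames(params) <- NULL
    list(quants = quants,
         truth = list(params = params, calls = calls),
         config = config)
  })
}

#' Score stability calls against the synthetic ground truth
#'
#' Confusion-matrix rates of the three-way classification plus sign
#' accuracy. Sensitivity is the fraction of truly shifted protein-crowder
#' pairs called as their true class; specificity the fraction of true
#' null pairs called null (excluded/\code{NA} calls count as misses);
#' sign accuracy is, over truly shifted pairs with a finite estimated
#' delta-Tm, the fraction whose estimated shift has the true sign.
#'
#' @param calls data.frame from [stabilityCalls()].
#' @param truth the \code{truth} element of [simulateTppExperiment()]
#'   output (or its \code{calls} data.frame).
#' @return list: \code{sensitivity}, \code{specificity},
#'   \code{sign_accuracy}, \code{n_true_shifted}, \code{n_true_null},
#'   \code{confusion} (table of true vs called class).
#' @export
truthEvaluation <- function(calls, truth) {
  tc <- if (is.data.frame(truth)) truth else truth$calls
  stopifnot(all(c("protein", "crowder", "true_class", "true_delta_tm")
                %in% colnames(tc)))
  key <- function(d) paste(d$protein, d$crowder, sep = "\r")
  idx <- match(key(calls), key(tc))
  if (anyNA(idx))
    stop("calls contain protein/crowder pairs absent from the truth")
  tr <- tc[idx, ]
  called <- ifelse(is.na(calls$call), "uncalled", calls$call)
  shifted <- tr$true_class != "null"
  sens <- if (any(shifted)) mean(called[shifted] == tr$true_class[shifted])
          else NA_real_
  spec <- if (any(!shifted)) mean(called[!shifted] == "null") else NA_real_
  okDelta <- shifted & is.finite(calls$delta_tm)
  signAcc <- if (any(okDelta))
    mean(sign(calls$delta_tm[okDelta]) == sign(tr$true_delta_tm[okDelta]))
  else NA_real_
  list(sensitivity = sens, specificity = spec, sign_accuracy = signAcc,
       n_true_shifted = sum(shifted), n_true_null = sum(!shifted),
       confusion = table(true = tr$true_class, called = called))
}
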