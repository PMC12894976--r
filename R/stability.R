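#' Melting-temperature shift of a treatment/control fit pair
#'
#' Delta-Tm = Tm(treatment) - Tm(control); positive means the crowder
#' stabilizes the protein. Pairs where either fit fails QC are excluded
#' with a reason code instead of contributing a value.
#'
#' @param fitTreatment,fitControl \linkS4class{MeltFit} objects whose
#'   \code{qcPass} flags have been set.
#' @return list with \code{value} (degrees C, or \code{NA}) and
#'   \code{reason} (\code{NA}, \code{"control_qc"} or \code{"treatment_qc"}).
#' @export
deltaTm <- function(fitTreatment, fitControl) {
  stopifnot(is(fitTreatment, "MeltFit"), is(fitControl, "MeltFit"))
  if (!isTRUE(fitControl@qcPass))
    return(list(value = NA_real_, reason = "control_qc"))
  if (!isTRUE(fitTreatment@qcPass))
    return(list(value = NA_real_, reason = "treatment_qc"))
  list(value = fitTreatment@tm - fitControl@tm, reason = NA_character_)
}

#' Standard scores of delta-Tm values within one treatment
#'
#' z_j = (x_j - mean(x)) / sd(x) with the sample (n - 1) standard
#' deviation, computed across all QC-passing proteins of a single
#' treatment. The result has mean 0 and sd 1 by construction.
#'
#' @param x numeric vector of delta-Tm values (degrees C).
#' @return numeric vector of z-scores.
#' @export
zScores <- function(x) {
  x <- as.numeric(x)
  if (sum(is.finite(x)) < 3L)
    stop("z-scores require at least 3 finite delta-Tm values")
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("degenerate delta-Tm distribution: zero standard deviation")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Classify z-scores into stability calls
#'
#' Three-way classification with inclusive boundaries: z >= zCrit is
#' \code{"stabilized"}, z <= -zCrit is \code{"destabilized"}, otherwise
#' \code{"null"}. The default threshold 1.96 corresponds to a two-sided
#' normal alpha of 0.05.
#'
#' @param z numeric vector of z-scores.
#' @param zCrit positive critical value (default 1.96).
#' @return character vector of calls; \code{NA} propagates.
#' @export
callStability <- function(z, zCrit = 1.96) {
  stopifnot(zCrit > 0)
  out <- rep(NA_character_, length(z))
  out[which(z >= zCrit)] <- "stabilized"
  out[which(z <= -zCrit)] <- "destabilized"
  out[which(abs(z) < zCrit)] <- "null"
  out
}

.pairQc <- function(ctrl, trt, criteria) {
  # vectorized pair-level stringency gate over fit-table rows
  ok <- function(x) !is.na(x) & x
  conv <- ok(ctrl$converged) & ok(trt$converged) &
    is.finite(ctrl$tm) & is.finite(trt$tm)
  r2 <- ok(ctrl$r2 >= criteria$r2Min) & ok(trt$r2 >= criteria$r2Min)
  plat <- ok(ctrl$plateau < criteria$plateauMax)
  slp <- ok(ctrl$slope <= criteria$slopeMax) &
    ok(trt$slope <= criteria$slopeMax)
  reasons <- mapply(function(a, b, c2, d) {
    paste(c(if (!a) "not_converged", if (!b) "r2",
            if (!c2) "plateau", if (!d) "slope"), collapse = ";")
  }, conv, r2, plat, slp)
  list(pass = conv & r2 & plat & slp,
       reasons = ifelse(nchar(reasons) == 0L, NA_character_, reasons))
}

#' Delta-Tm z-score stability calls across all crowder treatments
#'
#' For every treatment condition in a combined fit table (rows from
#' [fitProteome()] over control plus treatments), applies the pairwise
#' stringency gate against the control fits, computes delta-Tm for the
#' passing pairs, standardizes within the treatment ([zScores()]) and
#' classifies ([callStability()]). Excluded pairs are retained with reason
#' codes and \code{NA} calls.
#'
#' @param fits data.frame as returned by [fitProteome()], covering the
#'   control and at least one treatment condition.
#' @param control name of the control condition (default \code{"control"}).
#' @param zCrit z threshold (default 1.96).
#' @param criteria see [qcCriteria()].
#' @return data.frame with columns \code{protein}, \code{crowder},
#'   \code{delta_tm}, \code{z}, \code{call}, \code{qc_reason}.
#' @export
stabilityCalls <- function(fits, control = "control", zCrit = 1.96,
                           criteria = qcCriteria()) {
  stopifnot(all(c("protein", "condition", "tm", "r2", "plateau", "slope",
                  "converged") %in% colnames(fits)))
  if (!control %in% fits$condition)
    stop(sprintf("control condition '%s' not present in fits", control))
  ctrl <- fits[fits$condition == control, ]
  treatments <- setdiff(unique(fits$condition), control)
  if (!length(treatments)) stop("no treatment conditions in fits")
  out <- list()
  for (tr in treatments) {
    trt <- fits[fits$condition == tr, ]
    common <- intersect(ctrl$protein, trt$protein)
    c2 <- ctrl[match(common, ctrl$protein), ]
    t2 <- trt[match(common, trt$protein), ]
    qc <- .pairQc(c2, t2, criteria)
    dtm <- ifelse(qc$pass, t2$tm - c2$tm, NA_real_)
    z <- rep(NA_real_, length(dtm))
    z[qc$pass] <- zScores(dtm[qc$pass])
    out[[tr]] <- data.frame(
      protein = common, crowder = tr, delta_tm = dtm, z = z,
      call = callStability(z, zCrit), qc_reason = qc$reasons,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-crowder concordance of stability calls
#'
#' Counts, per protein, in how many treatments it was called significant
#' and whether the significant calls are all stabilizing, all
#' destabilizing, or mixed; and tabulates proteins by that count and
#' direction profile.
#'
#' @param calls data.frame with columns \code{protein}, \code{crowder},
#'   \code{call} (as from [stabilityCalls()]).
#' @return list with \code{perProtein} (protein, n_significant,
#'   direction_profile; only proteins with at least one significant call)
#'   and \code{histogram} (n_significant, direction_profile, count).
#' @export
concordanceSummary <- function(calls) {
  stopifnot(all(c("protein", "crowder", "call") %in% colnames(calls)))
  sig <- calls[!is.na(calls$call) & calls$call != "null", ]
  if (!nrow(sig)) {
    pp <- data.frame(protein = character(), n_significant = integer(),
                     direction_profile = character(),
                     stringsAsFactors = FALSE)
    return(list(perProtein = pp,
                histogram = data.frame(n_significant = integer(),
                                       direction_profile = character(),
                                       count = integer(),
                                       stringsAsFactors = FALSE)))
  }
  sp <- split(sig$call, sig$protein)
  pp <- data.frame(
    protein = names(sp),
    n_significant = vapply(sp, length, integer(1)),
    direction_profile = vapply(sp, function(v) {
      if (all(v == "stabilized")) "all-stabilized"
      else if (all(v == "destabilized")) "all-destabilized"
      else "mixed"
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(pp) <- NULL
  pp <- pp[order(pp$protein), ]
  h <- as.data.frame(table(n_significant = pp$n_significant,
                           direction_profile = pp$direction_profile),
                     stringsAsFactors = FALSE)
  h <- h[h$Freq > 0, ]
  histogram <- data.frame(
    n_significant = as.integer(h$n_significant),
    direction_profile = h$direction_profile,
    count = as.integer(h$Freq), stringsAsFactors = FALSE)
  histogram <- histogram[order(histogram$n_significant,
                               histogram$direction_profile), ]
  rownames(histogram) <- NULL
  list(perProtein = pp, histogram = histogram)
}

#' Recompute published-style call and concordance counts from exported fits
#'
#' Given a directory containing the study's exported melting-parameter
#' tables converted to this package's fit-table dialect (a tab-separated
#' \code{fits.tsv} with columns \code{protein}, \code{condition}, \code{a},
#' \code{b}, \code{plateau}, \code{tm}, \code{slope}, \code{r2},
#' \code{converged}; one control plus one condition per crowder), re-runs
#' the z-score calling and concordance summary and returns the headline
#' counts. This reproduces deposited-experiment numbers only when the
#' deposited tables are supplied; no data ship with the package.
#'
#' @param dir directory holding \code{fits.tsv}.
#' @param control control condition name.
#' @param zCrit z threshold (default 1.96).
#' @return list with \code{n_significant}, \code{n_stabilized},
#'   \code{n_destabilized}, and \code{concordance} (histogram of proteins
#'   by significant-crowder count).
#' @export
reproducePublishedCounts <- function(dir, control = "control",
                                     zCrit = 1.96) {
  path <- file.path(dir, "fits.tsv")
  if (!file.exists(path))
    stop("exported melting-parameter tables not found at ", path,
         " (supply the deposited experiment's fit tables; ",
         "they are not distributed with the package)")
  fits <- utils::read.delim(path, stringsAsFactors = FALSE)
  calls <- stabilityCalls(fits, control = control, zCrit = zCrit)
  conc <- concordanceSummary(calls)
  sig <- calls[!is.na(calls$call) & calls$call != "null", ]
  byN <- tapply(conc$perProtein$n_significant,
                conc$perProtein$n_significant, length)
  list(n_significant = nrow(sig),
       n_stabilized = sum(sig$call == "stabilized"),
       n_destabilized = sum(sig$call == "destabilized"),
       concordance = byN)
}
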