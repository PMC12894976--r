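#' Pairwise Spearman rank-correlation matrix of sample profiles
#'
#' Rank correlation between every pair of sample columns, using
#' pairwise-complete observations and average ranks for ties. Pairs with
#' fewer than 3 shared finite observations get \code{NA} with a warning.
#'
#' @param expr numeric matrix, proteins x samples (e.g. LFQ abundances or
#'   lowest-temperature reporter intensities per condition).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("at least 2 samples are required")
  n <- ncol(expr)
  out <- diag(1, n)
  dimnames(out) <- list(colnames(expr), colnames(expr))
  short <- character()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- is.finite(expr[, i]) & is.finite(expr[, j])
    if (sum(ok) < 3L) {
      out[i, j] <- out[j, i] <- NA_real_
      short <- c(short, sprintf("%s/%s", colnames(expr)[i],
                                colnames(expr)[j]))
    } else {
      out[i, j] <- out[j, i] <-
        stats::cor(expr[ok, i], expr[ok, j], method = "spearman")
    }
  }
  if (length(short))
    warning("fewer than 3 shared observations for pair(s): ",
            paste(short, collapse = ", "))
  out
}

#' PCA variance decomposition of expression profiles
#'
#' Principal component analysis with either samples (default; matches a
#' per-sample ordination of expression profiles) or proteins as the
#' observations. Rows with any missing value are dropped (complete case).
#' Signs are fixed so each component's largest-magnitude loading is
#' positive, making results deterministic across platforms.
#'
#' @param expr numeric matrix, proteins x samples.
#' @param observations \code{"samples"} or \code{"proteins"}.
#' @return list with \code{fractions} (variance-explained, sums to 1),
#'   \code{scores} (observations x components) and \code{loadings}.
#' @export
pcaVariance <- function(expr, observations = c("samples", "proteins")) {
  observations <- match.arg(observations)
  expr <- as.matrix(expr)
  expr[!is.finite(expr)] <- NA_real_
  expr <- expr[stats::complete.cases(expr), , drop = FALSE]
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("need >= 2 proteins and >= 2 samples after dropping missing rows")
  x <- if (observations == "samples") t(expr) else expr
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  fractions <- v / sum(v)
  rot <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(rot))) {
    s <- sign(rot[which.max(abs(rot[, k])), k])
    if (s < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(fractions = fractions, scores = scores, loadings = rot)
}

#' Mann-Whitney comparison of two parameter distributions
#'
#' Two-sided Mann-Whitney U test: exact enumeration for small samples
#' (both sizes at most 8, no ties), tie-corrected normal approximation
#' otherwise. U counts pairs won by the first sample (wins of \code{a}
#' over \code{b}, ties counted 1/2).
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exactMax largest per-group size for the exact path (default 8).
#' @return list with \code{U}, \code{p} (two-sided), \code{n1}, \code{n2},
#'   \code{method}.
#' @export
compareParamDistributions <- function(a, b, exactMax = 8) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= exactMax && length(b) <= exactMax && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(a), n2 = length(b),
       method = if (exact) "exact" else "normal-tie-corrected")
}

#' Mean aggregated-fraction profile across the thermal gradient
#'
#' Per-temperature mean of the aggregated (denatured) fraction 1 - FC,
#' with each protein's contribution clipped to [0, 1]; fold changes above
#' 1 (apparent over-recovery) therefore contribute 0 to the clipped mean,
#' and the raw (unclipped) mean is reported alongside. The reference
#' temperature has aggregated fraction 0 by construction.
#'
#' @param fcm fold-change matrix (proteins x temperatures, reference
#'   column equal to 1), e.g. from [foldChanges()].
#' @return data.frame with \code{channel}, \code{mean_aggregated}
#'   (clipped) and \code{mean_aggregated_raw}.
#' @export
aggregatedFractionProfile <- function(fcm) {
  fcm <- as.matrix(fcm)
  agg <- 1 - fcm
  clipped <- pmin(pmax(agg, 0), 1)
  data.frame(
    channel = if (!is.null(colnames(fcm))) colnames(fcm)
              else paste0("ch", seq_len(ncol(fcm))),
    mean_aggregated = colMeans(clipped, na.rm = TRUE),
    mean_aggregated_raw = colMeans(agg, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare fitted melting-parameter distributions between conditions
#'
#' Runs [compareParamDistributions()] for Tm, slope and plateau of every
#' treatment against the control, over QC-passing fits.
#'
#' @param fits combined fit table from [fitProteome()].
#' @param control control condition name.
#' @return data.frame: \code{condition}, \code{parameter}, \code{U},
#'   \code{p}, \code{n_treatment}, \code{n_control}.
#' @export
parameterDistributionTests <- function(fits, control = "control") {
  ok <- fits[!is.na(fits$qc_pass) & fits$qc_pass, ]
  ctrl <- ok[ok$condition == control, ]
  if (!nrow(ctrl)) stop("no QC-passing control fits")
  rows <- list()
  for (tr in setdiff(unique(ok$condition), control)) {
    trt <- ok[ok$condition == tr, ]
    for (par in c("tm", "slope", "plateau")) {
      r <- compareParamDistributions(trt[[par]], ctrl[[par]])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = tr, parameter = par, U = r$U, p = r$p,
        n_treatment = r$n1, n_control = r$n2, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
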