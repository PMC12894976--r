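#' Per-crowder stability summary over the common protein support
#'
#' Reduces QC-passing melting fits to one scalar per crowder so that
#' crowders can be regressed on their physico-chemical descriptors. All
#' summaries are computed over the intersection of proteins passing QC in
#' every condition, so crowders are compared on identical support.
#'
#' @param fits combined fit table from [fitProteome()] (control plus
#'   treatments, with \code{qc_pass}).
#' @param mode \code{"mean_tm"} (mean melting temperature per crowder),
#'   \code{"mean_delta_tm"} or \code{"median_delta_tm"} (shift against the
#'   control).
#' @param control control condition name.
#' @return named numeric vector, one value per treatment condition.
#' @export
stabilitySummaryPerCrowder <- function(fits,
                                       mode = c("mean_tm", "mean_delta_tm",
                                                "median_delta_tm"),
                                       control = "control") {
  mode <- match.arg(mode)
  ok <- fits[!is.na(fits$qc_pass) & fits$qc_pass & is.finite(fits$tm), ]
  conds <- unique(fits$condition)
  byCond <- lapply(conds, function(cc) ok$protein[ok$condition == cc])
  names(byCond) <- conds
  common <- Reduce(intersect, byCond)
  if (!length(common)) {
    worst <- names(byCond)[which.min(lengths(byCond))]
    stop("no protein passes QC in all conditions (smallest set: '",
         worst, "')")
  }
  tmOf <- function(cc) {
    sub <- ok[ok$condition == cc, ]
    sub$tm[match(common, sub$protein)]
  }
  treatments <- setdiff(conds, control)
  vals <- vapply(treatments, function(tr) {
    switch(mode,
           mean_tm = mean(tmOf(tr)),
           mean_delta_tm = mean(tmOf(tr) - tmOf(control)),
           median_delta_tm = stats::median(tmOf(tr) - tmOf(control)))
  }, numeric(1))
  attr(vals, "n_proteins") <- length(common)
  vals
}

#' Regress a per-crowder stability summary on a reagent descriptor
#'
#' Ordinary least squares of the stability summary on one
#' physico-chemical descriptor across crowders; the reported r-squared
#' equals the squared Pearson correlation of the two vectors.
#'
#' @param summaries named numeric vector (crowder -> summary), e.g. from
#'   [stabilitySummaryPerCrowder()].
#' @param properties a \linkS4class{CrowderPropertyTable}.
#' @param descriptor name of a numeric descriptor column.
#' @return data.frame row: \code{descriptor}, \code{slope}, \code{r2},
#'   \code{n}, \code{small_sample} (TRUE for n <= 6, flagging that the
#'   regression rests on very few points).
#' @export
propertyRegression <- function(summaries, properties, descriptor) {
  stopifnot(is(properties, "CrowderPropertyTable"))
  if (!descriptor %in% colnames(properties))
    stop("unknown descriptor: ", descriptor)
  idx <- match(names(summaries), properties$reagent)
  keep <- !is.na(idx)
  x <- as.numeric(properties[[descriptor]][idx[keep]])
  y <- as.numeric(summaries[keep])
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need >= 3 crowders with both descriptor and summary")
  if (stats::sd(x) == 0)
    stop("degenerate descriptor '", descriptor,
         "': zero variance across crowders")
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  data.frame(descriptor = descriptor,
             slope = unname(stats::coef(fit)[2]),
             r2 = r2,
             n = length(x), small_sample = length(x) <= 6L,
             stringsAsFactors = FALSE)
}

#' Mechanism screen: stability summaries vs all reagent descriptors
#'
#' Runs [propertyRegression()] for every numeric descriptor and every
#' summary mode, contrasting the crowding/viscosity account (molecular
#' weight, mass concentration, intrinsic viscosity) with the
#' preferential-exclusion account (polar atom fraction, hydrophobicity
#' index).
#'
#' @param fits combined fit table from [fitProteome()].
#' @param properties a \linkS4class{CrowderPropertyTable}.
#' @param modes summary modes to evaluate (default all three).
#' @param control control condition name.
#' @return data.frame: \code{mode}, \code{descriptor}, \code{slope},
#'   \code{r2}, \code{n}, \code{small_sample}.
#' @export
mechanismAnalysis <- function(fits, properties,
                              modes = c("mean_tm", "mean_delta_tm",
                                        "median_delta_tm"),
                              control = "control") {
  stopifnot(is(properties, "CrowderPropertyTable"))
  numCols <- colnames(properties)[vapply(seq_along(colnames(properties)),
    function(i) is.numeric(properties[[i]]), logical(1))]
  rows <- list()
  for (mode in modes) {
    s <- stabilitySummaryPerCrowder(fits, mode = mode, control = control)
    for (d in numCols) {
      r <- tryCatch(propertyRegression(s, properties, d),
                    error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- cbind(mode = mode, r,
                                         stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no descriptor could be regressed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
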