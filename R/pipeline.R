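#' Expression matrix across conditions
#'
#' Assembles the proteins x conditions matrix used by the dataset-level
#' QC analytics, taking either each condition's reference-temperature
#' (lowest channel) reporter intensities or its per-protein abundance
#' (LFQ-style) values, over the proteins shared by all conditions.
#'
#' @param quants named list of \linkS4class{ProteomeQuant} objects.
#' @param source \code{"reference"} (lowest-temperature channel, default)
#'   or \code{"abundance"}.
#' @return numeric matrix, proteins x conditions.
#' @export
expressionMatrix <- function(quants, source = c("reference", "abundance")) {
  source <- match.arg(source)
  stopifnot(length(quants) >= 2L)
  common <- Reduce(intersect, lapply(quants, rownames))
  if (length(common) < 2L) stop("fewer than 2 proteins shared by all conditions")
  cols <- lapply(quants, function(q) {
    if (source == "reference") intensities(q)[common, 1]
    else {
      ab <- abundance(q)
      if (is.null(ab)) stop("condition '", condition(q),
                            "' carries no abundance values")
      stats::setNames(ab, rownames(q))[common]
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(quants, condition, character(1))
  m
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full TPP crowding analysis pipeline
#'
#' Executes normalize -> fit -> QC -> delta-Tm -> z-score calling ->
#' concordance -> dataset QC analytics, plus the mechanism regression
#' when a crowder property table is supplied and the sequence-feature
#' analysis when sequences/annotations are supplied, and writes all
#' result tables plus a run manifest to \code{outputDir}. On any stage
#' error the partially written outputs are removed and the error names
#' the stage. Deterministic: identical inputs produce identical files.
#'
#' @param quants named list of \linkS4class{ProteomeQuant} objects, one
#'   per condition, including the control.
#' @param outputDir directory for the result bundle.
#' @param control control condition name (default \code{"control"}).
#' @param zCrit z threshold for stability calls (default 1.96).
#' @param options,criteria see [fitOptions()] and [qcCriteria()].
#' @param properties optional \linkS4class{CrowderPropertyTable}.
#' @param sequences optional named sequences (see [sequenceFeatures()]).
#' @param annotations optional annotation table (see
#'   [keywordEnrichment()]).
#' @param truth optional synthetic ground truth (from
#'   [simulateTppExperiment()]) to score the calls against.
#' @return invisibly, a list with all in-memory results (\code{fits},
#'   \code{calls}, \code{concordance}, \code{correlations}, \code{pca},
#'   \code{paramTests}, \code{aggregated}, and when applicable
#'   \code{mechanism}, \code{features}, \code{enrichment},
#'   \code{evaluation}).
#' @export
runPipeline <- function(quants, outputDir, control = "control",
                        zCrit = 1.96, options = fitOptions(),
                        criteria = qcCriteria(), properties = NULL,
                        sequences = NULL, annotations = NULL,
                        truth = NULL) {
  stopifnot(is.list(quants), length(quants) >= 2L)
  if (!control %in% names(quants))
    stop("control condition '", control, "' missing from quants")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on.exit(unlink(written), add = TRUE)
  emit <- function(d, name) {
    p <- file.path(outputDir, name)
    .writeTsv(d, p)
    written <<- c(written, p)
    p
  }

  fits <- .stage("fit", do.call(rbind, lapply(quants, fitProteome,
                                              options = options,
                                              criteria = criteria)))
  rownames(fits) <- NULL
  calls <- .stage("call", stabilityCalls(fits, control = control,
                                         zCrit = zCrit,
                                         criteria = criteria))
  conc <- .stage("concordance", concordanceSummary(calls))
  .stage("write", {
    written <- c(written, writeResults(fits, calls, outputDir))
    emit(conc$perProtein, "concordance.tsv")
    emit(conc$histogram, "concordance_histogram.tsv")
  })

  expr <- .stage("qc-analytics", expressionMatrix(quants))
  cors <- .stage("qc-analytics", spearmanMatrix(log2(expr)))
  pca <- .stage("qc-analytics", pcaVariance(log2(expr)))
  ptests <- .stage("qc-analytics", parameterDistributionTests(fits, control))
  agg <- .stage("qc-analytics",
                aggregatedFractionProfile(foldChanges(quants[[control]])))
  .stage("write", {
    emit(data.frame(condition = rownames(cors), as.data.frame(cors),
                    check.names = FALSE), "qc_correlations.tsv")
    emit(data.frame(component = seq_along(pca$fractions),
                    fraction = pca$fractions,
                    t(pca$scores), check.names = FALSE), "pca.tsv")
    emit(ptests, "param_tests.tsv")
    emit(agg, "aggregated_fraction.tsv")
  })

  out <- list(fits = fits, calls = calls, concordance = conc,
              correlations = cors, pca = pca, paramTests = ptests,
              aggregated = agg)

  if (!is.null(properties)) {
    mech <- .stage("mechanism", mechanismAnalysis(fits, properties,
                                                  control = control))
    emit(mech, "mechanism.tsv")
    out$mechanism <- mech
  }
  if (!is.null(sequences)) {
    feats <- .stage("features", sequenceFeatures(sequences))
    emit(feats, "biophysics.tsv")
    out$features <- feats
    if (!is.null(annotations)) {
      sig <- calls[!is.na(calls$call) & calls$call != "null", ]
      fg <- unique(sig$protein)
      bg <- unique(calls$protein[!is.na(calls$call)])
      if (length(fg)) {
        enr <- .stage("features", keywordEnrichment(fg, bg, annotations))
        emit(enr, "enrichment.tsv")
        out$enrichment <- enr
      }
    }
  }
  if (!is.null(truth)) {
    ev <- .stage("evaluate", truthEvaluation(calls, truth))
    emit(data.frame(metric = c("sensitivity", "specificity",
                               "sign_accuracy"),
                    value = c(ev$sensitivity, ev$specificity,
                              ev$sign_accuracy)), "evaluation.tsv")
    out$evaluation <- ev
  }

  sig <- calls[!is.na(calls$call) & calls$call != "null", ]
  manifest <- list(
    package = as.character(utils::packageVersion("crowdTPP")),
    control = control, conditions = names(quants), z_crit = zCrit,
    qc_criteria = criteria, fit_options = options,
    counts = list(
      proteins_per_condition = vapply(quants, nrow, integer(1)),
      qc_pass_per_condition = vapply(
        split(fits$qc_pass, fits$condition), sum, numeric(1)),
      significant_pairs = nrow(sig),
      stabilized = sum(sig$call == "stabilized"),
      destabilized = sum(sig$call == "destabilized")))
  yaml::write_yaml(manifest, file.path(outputDir, "manifest.yaml"))
  written <- c(written, file.path(outputDir, "manifest.yaml"))

  on.exit()  # success: keep outputs
  invisible(out)
}
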