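#' Read a channel-to-temperature map
#'
#' The map links reporter-intensity column names in a quantification table
#' to channel temperatures. Accepted formats: YAML (a flat mapping
#' \code{column name: temperature}) or a two-column TSV with header
#' \code{channel} and \code{temperature}.
#'
#' @param path file path (\code{.yml}/\code{.yaml} or TSV).
#' @return named numeric vector: column name -> temperature (degrees C).
#' @export
readChannelMap <- function(path) {
  if (!file.exists(path)) stop("channel map not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    out <- vapply(y, as.numeric, numeric(1))
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("channel", "temperature") %in% colnames(d)))
    out <- stats::setNames(as.numeric(d$temperature), d$channel)
  }
  if (anyDuplicated(out)) stop("channel temperatures must be distinct")
  out
}

.flagCol <- function(d, candidates) {
  hit <- intersect(candidates, colnames(d))
  if (length(hit)) trimws(as.character(d[[hit[1]]])) == "+" else
    rep(FALSE, nrow(d))
}

#' Read a protein-level quantification table into a ProteomeQuant
#'
#' Reads a tab-separated protein-level table in the MaxQuant
#' proteinGroups style: one row per protein, one reporter-intensity
#' column per TMT channel. Column naming is decoupled from the code via
#' \code{channelMap}. Rows flagged "+" in reverse-database or contaminant
#' columns (if present) are dropped and counted in the \code{"dropped"}
#' attribute; reporter-style columns present in the file but absent from
#' the map are ignored with a warning.
#'
#' @param path TSV file path.
#' @param channelMap named numeric vector (column name -> temperature),
#'   e.g. from [readChannelMap()].
#' @param condition condition label for the resulting object.
#' @param idColumn protein accession column; the first match among
#'   \code{"Protein IDs"}, \code{"Majority protein IDs"},
#'   \code{"protein"} is used by default.
#' @param abundanceColumn optional LFQ-style abundance column name.
#' @return a \linkS4class{ProteomeQuant} with attribute \code{"dropped"}
#'   (number of reverse/contaminant rows removed).
#' @export
readQuantTable <- function(path, channelMap, condition,
                           idColumn = NULL, abundanceColumn = NULL) {
  if (!file.exists(path)) stop("quantification table not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!nrow(d)) stop("empty quantification table: ", path)
  if (is.null(idColumn)) {
    cand <- c("Protein IDs", "Majority protein IDs", "protein", "Protein")
    idColumn <- intersect(cand, colnames(d))[1]
    if (is.na(idColumn)) stop("no protein accession column found")
  }
  miss <- setdiff(names(channelMap), colnames(d))
  if (length(miss))
    stop("channel column(s) missing from table: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(as.numeric(channelMap)))
    stop("channel temperatures must be distinct")
  unmapped <- setdiff(grep("^(Reporter intensity|reporter_)",
                           colnames(d), value = TRUE),
                      names(channelMap))
  if (length(unmapped))
    warning("reporter column(s) not in channel map ignored: ",
            paste(unmapped, collapse = ", "))
  drop <- .flagCol(d, c("Reverse")) |
    .flagCol(d, c("Potential contaminant", "Contaminant"))
  nDropped <- sum(drop)
  d <- d[!drop, , drop = FALSE]
  ids <- as.character(d[[idColumn]])
  if (anyDuplicated(ids))
    stop("duplicate protein accession(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(d[, names(channelMap), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  ab <- if (!is.null(abundanceColumn)) {
    if (!abundanceColumn %in% colnames(d))
      stop("abundance column missing: ", abundanceColumn)
    as.numeric(d[[abundanceColumn]])
  } else NULL
  pq <- ProteomeQuant(m, unname(as.numeric(channelMap)), condition,
                      abundance = ab)
  attr(pq, "dropped") <- nDropped
  pq
}

#' Read and validate a crowder property table
#'
#' @param path TSV with columns \code{reagent}, \code{molecular_weight}
#'   (kDa), \code{intrinsic_viscosity} (mL/g), \code{polar_atom_fraction}
#'   (in [0, 1]), \code{hydrophobicity_index}, \code{topology}
#'   (linear/branched); extra columns (e.g. \code{mass_concentration},
#'   mg/mL) are preserved.
#' @return a \linkS4class{CrowderPropertyTable}.
#' @export
readCrowderProperties <- function(path) {
  if (!file.exists(path)) stop("property table not found: ", path)
  d <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                error = function(e) stop("empty or unreadable property table: ",
                                         path))
  if (!nrow(d)) stop("empty property table: ", path)
  CrowderPropertyTable(d)
}

#' Read an annotation keyword table
#'
#' @param path TSV with columns \code{protein} and \code{keyword}
#'   (one row per protein-keyword pair).
#' @return data.frame with those two character columns.
#' @export
readAnnotationTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein", "keyword") %in% colnames(d)))
  d$protein <- as.character(d$protein)
  d$keyword <- as.character(d$keyword)
  if (any(!nzchar(d$keyword))) stop("keywords must be non-empty strings")
  d
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet()} that trims
#' FASTA headers to the first token so names match accession columns.
#'
#' @param path FASTA file path.
#' @return an \code{AAStringSet} named by accession.
#' @export
readProteinSequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  names(s) <- vapply(strsplit(names(s), "\\s+"), `[`, character(1), 1L)
  s
}

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Write fit and call tables to a results directory
#'
#' Writes \code{fits.tsv} (one row per protein x condition),
#' \code{calls.tsv} (one row per protein x crowder) and
#' \code{summary.tsv} (per-condition counts) with deterministic column
#' and row order; re-reading reproduces all numeric values to at least 6
#' significant digits.
#'
#' @param fits combined fit table from [fitProteome()].
#' @param calls call table from [stabilityCalls()] (may have zero rows).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeResults <- function(fits, calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  fitCols <- c("protein", "condition", "a", "b", "plateau", "tm", "slope",
               "r2", "converged", "qc_pass", "reason")
  callCols <- c("protein", "crowder", "delta_tm", "z", "call", "qc_reason")
  fits <- fits[order(fits$condition, fits$protein),
               intersect(fitCols, colnames(fits)), drop = FALSE]
  calls <- calls[order(calls$crowder, calls$protein),
                 intersect(callCols, colnames(calls)), drop = FALSE]
  if (nrow(calls) && !all(is.na(calls$call)) &&
      !all(stats::na.omit(calls$call) %in%
           c("stabilized", "destabilized", "null")))
    stop("calls contain classes outside {stabilized, destabilized, null}")
  sm <- if (nrow(fits)) {
    agg <- stats::aggregate(qc_pass ~ condition, data = fits,
                            FUN = function(v) sum(v, na.rm = TRUE))
    n <- stats::aggregate(protein ~ condition, data = fits, FUN = length)
    data.frame(condition = agg$condition, n_proteins = n$protein,
               n_qc_pass = agg$qc_pass, stringsAsFactors = FALSE)
  } else data.frame(condition = character(), n_proteins = integer(),
                    n_qc_pass = integer(), stringsAsFactors = FALSE)
  paths <- file.path(dir, c("fits.tsv", "calls.tsv", "summary.tsv"))
  .writeTsv(fits, paths[1])
  .writeTsv(calls, paths[2])
  .writeTsv(sm, paths[3])
  invisible(paths)
}
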