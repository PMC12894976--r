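# Kyte-Doolittle hydropathy scale (Kyte & Doolittle 1982, J Mol Biol 157).
.kdScale <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Residue masses (Da) for the 20 standard amino acids; average and
# monoisotopic values as tabulated by ExPASy. Water is added once per chain.
.avgResidueMass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.monoResidueMass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
.waterMass <- c(average = 18.01524, monoisotopic = 18.010565)

.residues <- function(sequence) {
  strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the counted residues of a protein
#' sequence. Non-standard residues (X, B, Z, U, ...) are skipped with a
#' warning; a sequence with no standard residue is an error.
#'
#' @param sequence amino-acid string (or anything coercible, e.g. one
#'   element of a \code{Biostrings::AAStringSet}).
#' @return numeric GRAVY score (positive = hydrophobic).
#' @examples
#' gravy("AAA")  # 1.8
#' @export
gravy <- function(sequence) {
  aa <- .residues(sequence)
  if (!length(aa)) stop("empty sequence")
  known <- aa %in% names(.kdScale)
  if (any(!known))
    warning(sum(!known), " non-standard residue(s) skipped")
  if (!any(known)) stop("sequence contains no standard residue")
  mean(.kdScale[aa[known]])
}

#' Protein molecular weight from sequence
#'
#' Sum of residue masses plus one water. Average masses by default;
#' monoisotopic available. Non-standard residues are an error unless
#' \code{skipUnknown = TRUE} (then skipped with a warning).
#'
#' @inheritParams gravy
#' @param type \code{"average"} (default) or \code{"monoisotopic"}.
#' @param skipUnknown skip non-standard residues instead of failing.
#' @return mass in Da.
#' @examples
#' proteinMw("G")  # glycine + water, 75.07 Da
#' @export
proteinMw <- function(sequence, type = c("average", "monoisotopic"),
                      skipUnknown = FALSE) {
  type <- match.arg(type)
  tab <- if (type == "average") .avgResidueMass else .monoResidueMass
  aa <- .residues(sequence)
  if (!length(aa)) stop("empty sequence")
  known <- aa %in% names(tab)
  if (any(!known)) {
    if (!skipUnknown)
      stop("non-standard residue(s): ",
           paste(unique(aa[!known]), collapse = ", "))
    warning(sum(!known), " non-standard residue(s) skipped")
  }
  if (!any(known)) stop("sequence contains no standard residue")
  sum(tab[aa[known]]) + .waterMass[[type]]
}

#' Sequence-derived biophysical features for a set of proteins
#'
#' GRAVY, molecular weight, length, aromaticity (fraction of F/W/Y) and
#' the aliphatic index (Ikai 1980) for each sequence.
#'
#' @param sequences a named character vector or
#'   \code{Biostrings::AAStringSet} (names are protein accessions).
#' @return data.frame: \code{protein}, \code{length}, \code{gravy},
#'   \code{mw}, \code{aromaticity}, \code{aliphatic_index}.
#' @export
sequenceFeatures <- function(sequences) {
  nm <- names(sequences)
  if (is.null(nm)) stop("sequences must be named by accession")
  seqs <- stats::setNames(as.character(sequences), nm)
  rows <- lapply(names(seqs), function(id) {
    aa <- .residues(seqs[[id]])
    aa <- aa[aa %in% names(.kdScale)]
    n <- length(aa)
    if (!n) return(NULL)
    frac <- function(x) sum(aa %in% x) / n
    data.frame(
      protein = id, length = n,
      gravy = mean(.kdScale[aa]),
      mw = sum(.avgResidueMass[aa]) + .waterMass[["average"]],
      aromaticity = frac(c("F", "W", "Y")),
      aliphatic_index = 100 * (frac("A") + 2.9 * frac("V") +
                               3.9 * frac(c("I", "L"))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.annotationList <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("protein", "keyword") %in% colnames(annotations)))
    split(as.character(annotations$keyword),
          as.character(annotations$protein))
  } else if (is.list(annotations)) {
    annotations
  } else stop("annotations must be a data.frame or a named list")
}

#' Keyword enrichment by Fisher's exact test with BH correction
#'
#' For every annotation keyword observed in the foreground, builds the
#' 2 x 2 table (in/out of foreground x has/lacks keyword, within the
#' background universe), computes a Fisher exact p-value and
#' Benjamini-Hochberg q-values across the tested keywords. This is a
#' self-contained replacement for hosted annotation-enrichment services.
#'
#' @param foreground character vector of accessions, a subset of
#'   \code{background} (e.g. the stabilized proteins).
#' @param background character vector of accessions (the analyzable
#'   universe, e.g. all QC-passing proteins).
#' @param annotations data.frame (\code{protein}, \code{keyword}) or named
#'   list accession -> keywords.
#' @param alternative passed to [stats::fisher.test()] (default
#'   two-sided; \code{"greater"} tests over-representation only).
#' @return data.frame sorted by p: \code{keyword}, \code{fg_count},
#'   \code{bg_count}, \code{odds_ratio}, \code{p}, \code{q}.
#' @export
keywordEnrichment <- function(foreground, background, annotations,
                              alternative = "two.sided") {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  ann <- .annotationList(annotations)
  ann <- ann[names(ann) %in% background]
  kw <- sort(unique(unlist(ann[names(ann) %in% foreground])))
  if (!length(kw))
    return(data.frame(keyword = character(), fg_count = integer(),
                      bg_count = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  has <- function(k) names(ann)[vapply(ann, function(v) k %in% v,
                                       logical(1))]
  rows <- lapply(kw, function(k) {
    withKw <- has(k)
    a <- sum(foreground %in% withKw)
    if (a == 0L) return(NULL)
    b <- length(foreground) - a
    c2 <- sum(!(withKw %in% foreground))
    d <- length(background) - length(foreground) - c2
    ft <- stats::fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE),
                             alternative = alternative)
    data.frame(keyword = k, fg_count = a, bg_count = length(withKw),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$keyword), ]
  rownames(out) <- NULL
  out
}

#' Compare a per-protein property between stability classes
#'
#' Pairwise Mann-Whitney comparisons (via
#' [compareParamDistributions()]) of a scalar property between the
#' stabilized, destabilized and null protein sets, with the difference of
#' medians as the effect direction. Empty sets skip their comparisons
#' with a warning.
#'
#' @param stabilized,destabilized,nullSet character vectors of accessions.
#' @param values named numeric vector of the property (e.g. GRAVY or MW).
#' @return data.frame: \code{comparison}, \code{n1}, \code{n2},
#'   \code{median_diff} (first minus second), \code{U}, \code{p}.
#' @export
compareSetsProperty <- function(stabilized, destabilized, nullSet, values) {
  sets <- list(stabilized = stabilized, destabilized = destabilized,
               null = nullSet)
  vals <- lapply(sets, function(s) {
    v <- values[names(values) %in% s]
    v[is.finite(v)]
  })
  combos <- list(c("stabilized", "destabilized"),
                 c("stabilized", "null"),
                 c("destabilized", "null"))
  rows <- list()
  for (cb in combos) {
    v1 <- vals[[cb[1]]]; v2 <- vals[[cb[2]]]
    if (!length(v1) || !length(v2)) {
      warning("empty set; skipping ", cb[1], " vs ", cb[2])
      next
    }
    r <- compareParamDistributions(v1, v2)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = paste(cb, collapse = "_vs_"),
      n1 = r$n1, n2 = r$n2,
      median_diff = stats::median(v1) - stats::median(v2),
      U = r$U, p = r$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
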