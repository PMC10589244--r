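#' @import methods
NULL

#' Directional catalog of positive and negative regulator genes
#'
#' Holds two disjoint gene sets: genes that positively regulate a process
#' (here, pyroptosis) and genes that negatively regulate it. The directional
#' single-sample enrichment index is the difference of the enrichment scores
#' of the two sets.
#'
#' @slot positive character vector of positive-regulator gene symbols.
#' @slot negative character vector of negative-regulator gene symbols.
#'
#' @seealso [prgCatalog()] for the packaged pyroptosis-regulator catalog,
#'   [computePpi()] for the index itself.
#' @export
setClass("DirectionalCatalog",
         slots = c(positive = "character", negative = "character"))

setValidity("DirectionalCatalog", function(object) {
  msgs <- character()
  for (dir in c("positive", "negative")) {
    g <- slot(object, dir)
    if (length(g) == 0L) msgs <- c(msgs, sprintf("%s set is empty", dir))
    if (anyDuplicated(g)) msgs <- c(msgs, sprintf("duplicate symbols in %s set", dir))
    if (any(!nzchar(g)) || any(g != trimws(g)))
      msgs <- c(msgs, sprintf("%s set contains blank or untrimmed symbols", dir))
  }
  if (length(intersect(object@positive, object@negative)) > 0L)
    msgs <- c(msgs, "positive and negative sets overlap")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DirectionalCatalog
#'
#' Symbols are whitespace-trimmed and matched case-sensitively; duplicates
#' within a direction are collapsed.
#'
#' @param positive character vector of positive-regulator gene symbols.
#' @param negative character vector of negative-regulator gene symbols.
#' @return A [DirectionalCatalog-class] object.
#' @examples
#' DirectionalCatalog(c("CASP1", "GSDMD"), c("EGFR", "NEK7"))
#' @export
DirectionalCatalog <- function(positive, negative) {
  new("DirectionalCatalog",
      positive = unique(trimws(as.character(positive))),
      negative = unique(trimws(as.character(negative))))
}

#' @describeIn DirectionalCatalog-class positive-regulator symbols.
#' @param x,object a `DirectionalCatalog`.
#' @export
setGeneric("positiveRegulators", function(x) standardGeneric("positiveRegulators"))

#' @rdname DirectionalCatalog-class
#' @export
setMethod("positiveRegulators", "DirectionalCatalog", function(x) x@positive)

#' @describeIn DirectionalCatalog-class negative-regulator symbols.
#' @export
setGeneric("negativeRegulators", function(x) standardGeneric("negativeRegulators"))

#' @rdname DirectionalCatalog-class
#' @export
setMethod("negativeRegulators", "DirectionalCatalog", function(x) x@negative)

#' @rdname DirectionalCatalog-class
#' @export
setMethod("show", "DirectionalCatalog", function(object) {
  cat("DirectionalCatalog\n")
  cat(sprintf("  positive: %d genes (%s, ...)\n", length(object@positive),
              paste(utils::head(object@positive, 4), collapse = ", ")))
  cat(sprintf("  negative: %d genes (%s, ...)\n", length(object@negative),
              paste(utils::head(object@negative, 4), collapse = ", ")))
})

#' Swap the directions of a catalog
#'
#' Exchanging positive and negative sets negates the raw directional index
#' exactly; this is used by the antisymmetry checks.
#'
#' @param catalog a [DirectionalCatalog-class].
#' @return A `DirectionalCatalog` with the two sets exchanged.
#' @export
swapDirections <- function(catalog) {
  stopifnot(is(catalog, "DirectionalCatalog"))
  new("DirectionalCatalog", positive = catalog@negative, negative = catalog@positive)
}

#' Per-sample table of directional enrichment scores
#'
#' A data.frame with columns `sample`, `es_positive`, `es_negative`, `ppi`
#' carrying, for every sample, the enrichment score of the positive set, of
#' the negative set, and their difference. The stored `es_*` columns are the
#' values actually subtracted (i.e. after range normalization when it is on),
#' so `ppi == es_positive - es_negative` holds row by row.
#'
#' @slot .Data the underlying data.frame (inherited).
#' @slot alpha the ssGSEA rank-weight exponent used.
#' @slot normalized whether per-direction range normalization was applied.
#' @export
setClass("PpiTable",
         contains = "data.frame",
         slots = c(alpha = "numeric", normalized = "logical"))

setValidity("PpiTable", function(object) {
  df <- S3Part(object, strictS3 = TRUE)
  need <- c("sample", "es_positive", "es_negative", "ppi")
  if (!all(need %in% names(df)))
    return(sprintf("missing columns: %s", paste(setdiff(need, names(df)), collapse = ", ")))
  if (anyDuplicated(df$sample)) return("duplicate sample identifiers")
  if (nrow(df) && max(abs(df$ppi - (df$es_positive - df$es_negative))) > 1e-8)
    return("ppi != es_positive - es_negative")
  TRUE
})

.PpiTable <- function(df, alpha, normalized) {
  new("PpiTable", df, alpha = alpha, normalized = normalized)
}

#' @describeIn PpiTable-class named numeric vector of per-sample index values.
#' @param x,object a `PpiTable`.
#' @export
setGeneric("ppiScores", function(x) standardGeneric("ppiScores"))

#' @rdname PpiTable-class
#' @export
setMethod("ppiScores", "PpiTable", function(x) {
  df <- S3Part(x, strictS3 = TRUE)
  stats::setNames(df$ppi, df$sample)
})

#' @rdname PpiTable-class
#' @export
setMethod("show", "PpiTable", function(object) {
  df <- S3Part(object, strictS3 = TRUE)
  cat(sprintf("PpiTable: %d samples (alpha = %g, normalized = %s)\n",
              nrow(df), object@alpha, object@normalized))
  print(utils::head(df, 5))
  if (nrow(df) > 5) cat(sprintf("  ... and %d more rows\n", nrow(df) - 5L))
})

#' Synthetic pan-cancer cohort
#'
#' Container for one simulated cohort: the expression matrix, clinical and
#' survival annotations, mutation table, per-sample annotation scores,
#' a cell-line panel (expression + per-drug responses), and the latent
#' per-sample activation that generated the data. The activation slot exists
#' for recovery tests only and is never consumed by analysis stages.
#'
#' @slot expression gene x sample numeric matrix, log2(FPKM+1)-like scale.
#' @slot annotations per-sample clinical table (see [simulateCohort()]).
#' @slot mutations MAF-like mutation table.
#' @slot scores per-sample annotation scores (immune/stromal/purity/...).
#' @slot cellLineExpression gene x cell-line numeric matrix.
#' @slot drugResponse drug x cell-line numeric matrix of IC50-like values.
#' @slot activation named numeric latent activation per sample.
#' @slot config the [simulationConfig()] list that generated the cohort.
#' @export
setClass("SyntheticCohort",
         slots = c(expression = "matrix",
                   annotations = "data.frame",
                   mutations = "data.frame",
                   scores = "data.frame",
                   cellLineExpression = "matrix",
                   drugResponse = "matrix",
                   activation = "numeric",
                   config = "list"))

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  ids <- colnames(object@expression)
  if (!identical(sort(ids), sort(object@annotations$sample)))
    msgs <- c(msgs, "expression columns and annotation samples disagree")
  if (!identical(sort(ids), sort(names(object@activation))))
    msgs <- c(msgs, "activation names and expression columns disagree")
  if (nrow(object@scores) && !all(object@scores$sample %in% ids))
    msgs <- c(msgs, "scores reference unknown samples")
  if (nrow(object@mutations) && !all(object@mutations$Tumor_Sample_Barcode %in% ids))
    msgs <- c(msgs, "mutations reference unknown samples")
  if (ncol(object@cellLineExpression) &&
      !identical(colnames(object@cellLineExpression), colnames(object@drugResponse)))
    msgs <- c(msgs, "cell-line identifiers differ between expression and drug tables")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SyntheticCohort-class the gene x sample expression matrix.
#' @param x,object a `SyntheticCohort`.
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("expressionMatrix", "SyntheticCohort", function(x) x@expression)

#' @describeIn SyntheticCohort-class the per-sample clinical table.
#' @export
setGeneric("cohortAnnotations", function(x) standardGeneric("cohortAnnotations"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortAnnotations", "SyntheticCohort", function(x) x@annotations)

#' @describeIn SyntheticCohort-class the MAF-like mutation table.
#' @export
setGeneric("mutationTable", function(x) standardGeneric("mutationTable"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("mutationTable", "SyntheticCohort", function(x) x@mutations)

#' @describeIn SyntheticCohort-class the per-sample annotation scores.
#' @export
setGeneric("annotationScores", function(x) standardGeneric("annotationScores"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("annotationScores", "SyntheticCohort", function(x) x@scores)

#' @describeIn SyntheticCohort-class list with elements `expression`
#'   (gene x line matrix) and `drugs` (drug x line matrix).
#' @export
setGeneric("cellLinePanel", function(x) standardGeneric("cellLinePanel"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("cellLinePanel", "SyntheticCohort", function(x)
  list(expression = x@cellLineExpression, drugs = x@drugResponse))

#' @describeIn SyntheticCohort-class latent activation (recovery tests only).
#' @export
setGeneric("trueActivation", function(x) standardGeneric("trueActivation"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("trueActivation", "SyntheticCohort", function(x) x@activation)

#' @rdname SyntheticCohort-class
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort\n")
  cat(sprintf("  expression : %d genes x %d samples\n",
              nrow(object@expression), ncol(object@expression)))
  cat(sprintf("  strata     : %s\n",
              paste(sort(unique(object@annotations$cancer_type)), collapse = ", ")))
  cat(sprintf("  tumors/normals: %d / %d\n",
              sum(object@annotations$tissue == "tumor"),
              sum(object@annotations$tissue == "normal")))
  cat(sprintf("  mutations  : %d rows; cell lines: %d; drugs: %d\n",
              nrow(object@mutations), ncol(object@cellLineExpression),
              nrow(object@drugResponse)))
})
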