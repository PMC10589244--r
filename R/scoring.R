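# Single-sample gene-set enrichment scoring and the directional index.
#
# The per-sample statistic is the ssGSEA running-sum: genes are ranked
# within a sample (1 = lowest expression, ties averaged), walked in
# decreasing rank order, and at every step the difference between the
# rank^alpha-weighted fraction of set genes seen so far and the unweighted
# fraction of non-set genes seen so far is accumulated. The sum over all
# positions (not the maximum deviation) is the enrichment score, following
# the single-sample convention. Because only within-sample ranks enter, the
# score is invariant under any strictly monotone transform of a sample's
# expression vector.

#' Within-sample expression ranks
#'
#' Ranks one sample's expression values across genes, with 1 = lowest
#' expression and ties receiving the average of their covered ranks.
#'
#' @param expr validated gene x sample numeric matrix.
#' @param sample sample identifier (must be a column of `expr`).
#' @return named numeric vector of ranks in `1..nrow(expr)`.
#' @export
rankWithinSample <- function(expr, sample) {
  validateExpression(expr)
  if (!sample %in% colnames(expr)) stop("unknown sample: ", sample)
  r <- rank(expr[, sample], ties.method = "average")
  names(r) <- rownames(expr)
  r
}

#' ssGSEA enrichment score for one sample
#'
#' @param ranks named numeric within-sample ranks (see [rankWithinSample()]).
#' @param members character vector of gene-set member symbols; must be a
#'   subset of `names(ranks)` and a proper subset of the genes.
#' @param alpha rank-weight exponent, >= 0 (default 0.25, the convention of
#'   the single-sample method this engine follows).
#' @return the enrichment score (dimensionless).
#' @details Genes tied on rank are walked in lexicographic symbol order so
#'   the score is deterministic. Walking order is decreasing rank.
#' @examples
#' r <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
#' ssgseaScore(r, c("g1", "g2"), alpha = 0.25)  # ~2.5139
#' @export
ssgseaScore <- function(ranks, members, alpha = 0.25) {
  stopifnot(is.numeric(ranks), !is.null(names(ranks)), alpha >= 0)
  N <- length(ranks)
  if (!all(members %in% names(ranks)))
    stop("gene set contains genes absent from the ranked list: ",
         paste(utils::head(setdiff(members, names(ranks)), 5), collapse = ", "))
  k <- length(unique(members))
  if (k == 0L || k >= N)
    stop("degenerate gene set: must cover some but not all ranked genes")
  ord <- order(-ranks, names(ranks))
  inset <- names(ranks)[ord] %in% members
  w <- ifelse(inset, ranks[ord]^alpha, 0)
  pin <- cumsum(w) / sum(w)
  pout <- cumsum(!inset) / (N - k)
  sum(pin - pout)
}

#' ssGSEA scores for a matrix of samples and a list of gene sets
#'
#' Computes [ssgseaScore()] independently per sample for every supplied
#' gene set. When `normalize` is `TRUE`, each set's column of scores is
#' divided by the range (max - min) of that set's scores across the
#' samples of the run (skipped when the range is zero), so scores from
#' different runs or sample subsets are not directly comparable.
#'
#' @param expr validated gene x sample numeric matrix.
#' @param geneSets named list of character vectors (or a single character
#'   vector, treated as one set).
#' @param alpha rank-weight exponent.
#' @param normalize apply per-set range normalization (default `TRUE`).
#' @return sample x set numeric matrix of enrichment scores.
#' @export
scoreMatrix <- function(expr, geneSets, alpha = 0.25, normalize = TRUE) {
  validateExpression(expr)
  if (is.character(geneSets)) geneSets <- list(set = geneSets)
  stopifnot(is.list(geneSets), !is.null(names(geneSets)))
  es <- matrix(NA_real_, ncol(expr), length(geneSets),
               dimnames = list(colnames(expr), names(geneSets)))
  for (s in colnames(expr)) {
    r <- rank(expr[, s], ties.method = "average")
    names(r) <- rownames(expr)
    for (g in names(geneSets)) es[s, g] <- ssgseaScore(r, geneSets[[g]], alpha)
  }
  if (normalize) {
    for (g in colnames(es)) {
      rng <- max(es[, g]) - min(es[, g])
      if (rng > 0) es[, g] <- es[, g] / rng
    }
  }
  es
}

#' Compute the directional pyroptosis potential index
#'
#' Scores the positive- and the negative-regulator sets separately per
#' sample with ssGSEA and subtracts:
#' `ppi = ES(positive regulators) - ES(negative regulators)`.
#' By default each direction's scores are range-normalized across the
#' samples of the run before subtraction; set `normalize = FALSE` for the
#' raw difference (the antisymmetry property
#' `computePpi(expr, swapDirections(cat)) == -computePpi(expr, cat)`
#' holds exactly in raw mode).
#'
#' The catalog is restricted to measured genes first; an error is raised if
#' either direction loses all members.
#'
#' @param expr validated gene x sample numeric matrix.
#' @param catalog a [DirectionalCatalog-class]; defaults to the packaged
#'   pyroptosis-regulator catalog.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize per-direction range normalization before subtraction
#'   (default `TRUE`).
#' @return A [PpiTable-class]: columns `sample`, `es_positive`,
#'   `es_negative`, `ppi`, where the stored `es_*` are the values actually
#'   subtracted.
#' @examples
#' co <- workedFixture()
#' computePpi(expressionMatrix(co), fixtureCatalog(co))
#' @export
computePpi <- function(expr, catalog = prgCatalog(), alpha = 0.25,
                       normalize = TRUE) {
  validateExpression(expr)
  res <- restrictToMeasured(catalog, rownames(expr))
  cat2 <- res$catalog
  es <- scoreMatrix(expr,
                    list(positive = cat2@positive, negative = cat2@negative),
                    alpha = alpha, normalize = normalize)
  df <- data.frame(sample = rownames(es),
                   es_positive = es[, "positive"],
                   es_negative = es[, "negative"],
                   ppi = es[, "positive"] - es[, "negative"],
                   row.names = NULL, stringsAsFactors = FALSE)
  .PpiTable(df, alpha = alpha, normalized = normalize)
}

#' Write / read a PPI table as TSV
#'
#' @param ppi a [PpiTable-class] (or compatible data.frame) to write.
#' @param path TSV path.
#' @return For `writePpiTable`, `path` invisibly; for `readPpiTable`, a
#'   data.frame with the four PPI columns.
#' @export
writePpiTable <- function(ppi, path) {
  .writeTsv(as.data.frame(ppi), path)
}

#' @rdname writePpiTable
#' @export
readPpiTable <- function(path) {
  df <- .readTsv(path)
  need <- c("sample", "es_positive", "es_negative", "ppi")
  if (!all(need %in% names(df))) stop("not a PPI table: missing columns")
  df
}
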