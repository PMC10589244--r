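# Shared small utilities: TSV I/O in one fixed dialect, rank-based AUC,
# seed derivation for the generator's sub-streams.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column holds gene symbols, remaining columns one sample each.
#' Values are validated: finite, non-missing, unique gene symbols,
#' at least two genes and one sample.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
  df <- .readTsv(path)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validateExpression(m)
  m
}

#' Write a gene x sample expression matrix as TSV
#'
#' @param expr numeric matrix with gene rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' Validate an expression matrix
#'
#' Enforces the contract every scoring operation assumes: numeric matrix,
#' unique non-blank gene rownames, sample colnames, >= 2 genes, >= 1
#' sample, and no missing or non-finite values (values are rejected, not
#' imputed).
#'
#' @param expr matrix to validate.
#' @return `expr`, invisibly.
#' @export
validateExpression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || any(!nzchar(rownames(expr))))
    stop("expression matrix needs non-blank gene rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene symbols in expression matrix")
  if (nrow(expr) < 2L) stop("expression matrix needs >= 2 genes")
  if (ncol(expr) < 1L) stop("expression matrix needs >= 1 sample")
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr)))
    stop("expression matrix needs unique sample colnames")
  if (any(!is.finite(expr)))
    stop("expression matrix contains missing or non-finite values")
  invisible(expr)
}

#' Rank-based AUC of a score against a binary label
#'
#' Area under the ROC curve computed from the Mann-Whitney identity
#' (probability that a random positive outranks a random negative, ties
#' counted half).
#'
#' @param score numeric scores.
#' @param positive logical labels, same length.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  ok <- is.finite(score) & !is.na(positive)
  score <- score[ok]; positive <- positive[ok]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("rocAuc needs both classes present")
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Derive a deterministic sub-stream seed from the master seed. Offsets keep
# stages independently regenerable; result stays below 2^31.
.subSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 2000L + as.integer(stage)
}

.bh <- function(p) stats::p.adjust(p, method = "BH")
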