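# Expression-based drug-sensitivity prediction and index/IC50 association.
#
# A deliberately simple, fully documented pipeline stands behind the
# module: shared genes are intersected and z-scored per gene within each
# matrix, and per drug a ridge linear model of response on expression is
# fit with the penalty chosen by seeded k-fold cross-validation over a
# fixed grid. Output metadata always records the model so results are not
# mistaken for those of heavier transfer-learning predictors. Orientation
# throughout: lower IC50 = more sensitive.

#' Align and z-score a training and a target expression matrix
#'
#' Intersects genes, drops genes that are constant in either matrix
#' (z-score undefined), and z-scores each gene within each matrix
#' independently.
#'
#' @param train gene x cell-line training expression matrix.
#' @param target gene x sample target expression matrix.
#' @param minShared minimum number of usable shared genes (default 200).
#' @return list with `train`, `target` (aligned, z-scored) and `dropped`
#'   (genes removed and why).
#' @export
homogenizeExpression <- function(train, target, minShared = 200) {
  shared <- intersect(rownames(train), rownames(target))
  missing <- setdiff(union(rownames(train), rownames(target)), shared)
  tr <- train[shared, , drop = FALSE]
  tg <- target[shared, , drop = FALSE]
  sdTr <- apply(tr, 1, stats::sd)
  sdTg <- apply(tg, 1, stats::sd)
  constant <- shared[sdTr == 0 | sdTg == 0]
  keep <- setdiff(shared, constant)
  if (length(keep) < minShared)
    stop(sprintf("only %d usable shared genes (< %d)", length(keep), minShared))
  zrow <- function(m) t(scale(t(m)))
  list(train = zrow(tr[keep, , drop = FALSE]),
       target = zrow(tg[keep, , drop = FALSE]),
       dropped = list(not_shared = missing, constant = constant))
}

# Ridge solution via SVD of the centered design: for X = U D V',
# beta(lambda) = V diag(d / (d^2 + lambda)) U' yc. lambda = 0 reduces to
# least squares; lambda -> Inf sends beta -> 0 so predictions collapse to
# the training mean.
.ridgeBeta <- function(sv, yc, lambda) {
  shrink <- sv$d / (sv$d^2 + lambda)
  drop(sv$v %*% (shrink * crossprod(sv$u, yc)))
}

#' Fit a cross-validated ridge model of drug response on expression
#'
#' Ridge linear model (intercept unpenalized, handled by centering) of one
#' drug's responses on homogenized expression, with the penalty chosen by
#' k-fold cross-validation over `lambdaGrid` (fold assignment seeded, so
#' the fit is deterministic given the seed; ties in CV error break toward
#' the larger penalty).
#'
#' @param expr gene x cell-line matrix (ideally the `train` element of
#'   [homogenizeExpression()]).
#' @param response named numeric per-cell-line response (IC50-like; lower
#'   = more sensitive). Lines with missing response are dropped; >= 10
#'   are required.
#' @param lambdaGrid penalty grid (default `10^seq(-3, 3, 0.5)`).
#' @param nFolds folds for cross-validation (default 10).
#' @param seed integer seed for fold assignment.
#' @return object of class `ridgeIc50`: coefficients, intercept
#'   (training mean), chosen `lambda`, CV error per grid point, genes
#'   used, training size and seed.
#' @export
fitRidgeIc50 <- function(expr, response, lambdaGrid = 10^seq(-3, 3, 0.5),
                         nFolds = 10, seed = 1) {
  stopifnot(is.matrix(expr), !is.null(names(response)))
  lines <- intersect(colnames(expr), names(response)[is.finite(response)])
  if (length(lines) < 10L)
    stop("fitRidgeIc50 needs >= 10 cell lines with responses")
  y <- response[lines]
  if (length(unique(y)) < 2L) stop("degenerate (constant) drug response")
  X <- t(expr[, lines, drop = FALSE])
  nFolds <- min(nFolds, nrow(X))
  set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(nFolds), length.out = nrow(X)))
  cvErr <- rep(0, length(lambdaGrid))
  for (f in seq_len(nFolds)) {
    tr <- foldid != f
    Xtr <- X[tr, , drop = FALSE]
    ctr <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2, ctr)
    yc <- y[tr] - mean(y[tr])
    sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
    Xte <- sweep(X[!tr, , drop = FALSE], 2, ctr)
    for (j in seq_along(lambdaGrid)) {
      beta <- .ridgeBeta(sv, yc, lambdaGrid[j])
      pred <- drop(Xte %*% beta) + mean(y[tr])
      cvErr[j] <- cvErr[j] + sum((y[!tr] - pred)^2)
    }
  }
  cvErr <- cvErr / nrow(X)
  best <- max(which(cvErr <= min(cvErr) + 1e-12))  # ties -> larger penalty
  lambda <- lambdaGrid[best]
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  beta <- .ridgeBeta(sv, y - mean(y), lambda)
  structure(list(beta = stats::setNames(beta, colnames(X)),
                 centers = centers, intercept = mean(y),
                 lambda = lambda, lambdaGrid = lambdaGrid, cvError = cvErr,
                 foldid = stats::setNames(foldid, lines),
                 genes = colnames(X), nTrain = length(lines), seed = seed,
                 model = "z-score homogenization + cross-validated ridge"),
            class = "ridgeIc50")
}

#' @export
print.ridgeIc50 <- function(x, ...) {
  cat(sprintf("ridgeIc50: %s\n  %d genes, %d training lines, lambda = %g (CV over %d points, seed %d)\n",
              x$model, length(x$genes), x$nTrain, x$lambda,
              length(x$lambdaGrid), x$seed))
  invisible(x)
}

#' Predict drug response for new samples
#'
#' @param model a `ridgeIc50` fit.
#' @param expr gene x sample matrix containing every model gene (use the
#'   `target` element of [homogenizeExpression()]).
#' @return named numeric predicted response per sample (finite).
#' @export
predictIc50 <- function(model, expr) {
  stopifnot(inherits(model, "ridgeIc50"))
  if (!all(model$genes %in% rownames(expr)))
    stop("target expression is missing model genes")
  X <- t(expr[model$genes, , drop = FALSE])
  pred <- drop(sweep(X, 2, model$centers) %*% model$beta) + model$intercept
  stats::setNames(pred, colnames(expr))
}

#' Compare predicted drug sensitivity between high and low index groups
#'
#' Two-sided Wilcoxon rank-sum test of per-sample predictions between the
#' high and low groups within each stratum, reporting group medians.
#' Lower values mean more sensitive. Strata with an empty group are
#' skipped and logged.
#'
#' @param predictions named numeric predicted response per sample, or a
#'   sample x drug matrix of predictions.
#' @param groups data.frame from [splitGroups()] (columns `sample`,
#'   `stratum`, `group`).
#' @return data.frame with `stratum`, `drug`, `median_high`, `median_low`,
#'   `p`, `n_high`, `n_low`, `orientation`; skips in `attr(, "skipped")`.
#' @export
predictAndCompare <- function(predictions, groups) {
  if (is.numeric(predictions) && !is.matrix(predictions))
    predictions <- matrix(predictions, ncol = 1,
                          dimnames = list(names(predictions), "drug"))
  rows <- list()
  skipped <- character()
  for (st in sort(unique(groups$stratum))) {
    g <- groups[groups$stratum == st, ]
    hi <- intersect(g$sample[g$group == "high"], rownames(predictions))
    lo <- intersect(g$sample[g$group == "low"], rownames(predictions))
    if (length(hi) < 2L || length(lo) < 2L) {
      skipped <- c(skipped, sprintf("%s: a group has fewer than 2 predicted samples", st))
      next
    }
    for (d in colnames(predictions)) {
      ph <- predictions[hi, d]; pl <- predictions[lo, d]
      p <- if (length(unique(c(ph, pl))) == 1L) 1  # identical predictions
      else suppressWarnings(stats::wilcox.test(ph, pl)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, drug = d,
        median_high = stats::median(ph), median_low = stats::median(pl),
        p = p, n_high = length(hi), n_low = length(lo),
        orientation = "lower IC50 = more sensitive",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame()
  attr(res, "skipped") <- skipped
  res
}

#' Correlation between cell-line index and drug response
#'
#' Computes the directional index on the cell-line expression matrix with
#' the same scoring engine used for tumors, then the Pearson correlation
#' (with p) of the index against each drug's responses across cell lines,
#' missing responses pairwise-dropped. Drugs with a constant response are
#' flagged; fewer than 3 complete pairs is an error for a single drug and
#' a logged skip in the scan.
#'
#' @param panelExpr gene x cell-line expression matrix.
#' @param drugResponse drug x cell-line numeric matrix (IC50-like).
#' @param catalog a [DirectionalCatalog-class] (default packaged catalog).
#' @param alpha,normalize passed to [computePpi()].
#' @return data.frame with `drug`, `r`, `p`, `n`, `note`; the cell-line
#'   [PpiTable-class] in `attr(, "ppi")`.
#' @export
celllinePpiDrugCorrelation <- function(panelExpr, drugResponse,
                                       catalog = prgCatalog(),
                                       alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(drugResponse))
  ppi <- computePpi(panelExpr, catalog, alpha = alpha, normalize = normalize)
  pv <- ppiScores(ppi)
  rows <- list()
  for (d in rownames(drugResponse)) {
    y <- drugResponse[d, ]
    ids <- intersect(names(pv), names(y)[is.finite(y)])
    if (length(ids) < 3L) {
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, r = NA_real_, p = NA_real_, n = length(ids),
        note = "fewer than 3 complete pairs", stringsAsFactors = FALSE)
      next
    }
    cr <- correlatePairs(pv[ids], y[ids], method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      drug = d, r = cr$estimate, p = cr$p, n = cr$n, note = cr$note,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(res, "ppi") <- ppi
  res
}
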