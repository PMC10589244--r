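# Two-group gene ranking and permutation GSEA.
#
# Ranking uses the signal-to-noise ratio between high and low groups with
# the classic desktop sd floor; the enrichment statistic is the weighted
# Kolmogorov-Smirnov running sum (weight p = 1 by default) whose extremum
# (maximum deviation from zero, signed) is the enrichment score. The null
# is built from gene-label permutations -- the only permutation scheme
# available once just the ranked list is retained -- and shared across sets
# of equal size, since under gene relabeling the null ES distribution
# depends on the set only through its size.

#' Rank genes between high and low groups
#'
#' Per-gene signal-to-noise metric
#' `(mean_high - mean_low) / (sd_high + sd_low)`, with each group standard
#' deviation floored at `max(0.2 * |group mean|, 0.2)` to prevent blow-ups
#' on near-constant genes. Genes are returned sorted by decreasing metric,
#' ties broken by gene symbol.
#'
#' @param expr validated gene x sample numeric matrix.
#' @param groups data.frame from [splitGroups()] (columns `sample`,
#'   `group`) or a named character vector of `"high"`/`"low"` labels.
#' @return named numeric vector of metric values, sorted decreasing; the
#'   names are the ranked gene symbols.
#' @export
rankGenes <- function(expr, groups) {
  validateExpression(expr)
  if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$sample)
  groups <- groups[names(groups) %in% colnames(expr)]
  hi <- names(groups)[groups == "high"]
  lo <- names(groups)[groups == "low"]
  if (length(hi) < 2L || length(lo) < 2L)
    stop("rankGenes needs >= 2 samples per group")
  mh <- rowMeans(expr[, hi, drop = FALSE])
  ml <- rowMeans(expr[, lo, drop = FALSE])
  sh <- apply(expr[, hi, drop = FALSE], 1, stats::sd)
  sl <- apply(expr[, lo, drop = FALSE], 1, stats::sd)
  sh <- pmax(sh, pmax(0.2 * abs(mh), 0.2))
  sl <- pmax(sl, pmax(0.2 * abs(ml), 0.2))
  metric <- (mh - ml) / (sh + sl)
  ord <- order(-metric, rownames(expr))
  stats::setNames(metric[ord], rownames(expr)[ord])
}

# ES from sorted hit positions in O(k): the running sum is piecewise linear
# between hits, so its extrema occur immediately after a hit (candidate
# maxima) or immediately before one (candidate minima).
.gseaESFromPositions <- function(pos, wAbs, N) {
  k <- length(pos)
  m <- 1 / (N - k)
  w <- wAbs[pos]
  tot <- sum(w)
  if (tot == 0) w <- rep(1, k) else w <- w / tot
  W <- cumsum(w)
  afterHit <- W - (pos - seq_len(k)) * m
  beforeHit <- afterHit - w
  amax <- max(afterHit)
  bmin <- min(beforeHit, 0)
  if (amax >= -bmin) amax else bmin
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum over a ranked list: at set members the sum
#' increases by `|metric|^p / sum_hits |metric|^p`, at non-members it
#' decreases by `1/(N - n_hits)`. The enrichment score is the extremum of
#' the running sum (maximum deviation from zero, signed; ties resolved
#' towards the positive deviation). With `p = 0` this is the unweighted KS
#' statistic. When all hit weights are zero the hits fall back to equal
#' weights.
#'
#' @param ranked named numeric metric values sorted decreasing (from
#'   [rankGenes()]).
#' @param members gene-set member symbols.
#' @param p metric weight exponent (default 1).
#' @return the enrichment score in \[-1, 1\].
#' @export
gseaScore <- function(ranked, members, p = 1) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  N <- length(ranked)
  pos <- which(names(ranked) %in% members)
  if (length(pos) == 0L || length(pos) >= N)
    stop("degenerate gene set: must hit some but not all ranked genes")
  .gseaESFromPositions(pos, abs(ranked)^p, N)
}

#' Permutation GSEA with normalized enrichment scores and FDR
#'
#' Computes the observed enrichment score for every gene set, builds a
#' gene-label permutation null (shared across sets of equal size), and
#' reports:
#' \itemize{
#'   \item `nes`: ES divided by the mean absolute null ES of matching sign;
#'   \item `p_perm`: one-sided proportion of same-sign null ES at least as
#'     extreme, with +1 smoothing in numerator and denominator;
#'   \item `fdr`: GSEA-style ratio of the tail proportion of the pooled
#'     sign-matched null NES distribution to the tail proportion of the
#'     observed NES values, clipped to \[0, 1\] and then made monotone so a
#'     more extreme |NES| never receives a larger FDR.
#' }
#' Results are deterministic for a fixed seed. Sets whose restriction to
#' the ranked list is degenerate (no hits, or all genes) are dropped and
#' listed in `attr(, "skipped")`; a sign with no null mass yields `NA`
#' NES flagged in the `note` column.
#'
#' @param ranked named numeric metric values sorted decreasing.
#' @param geneSets named list of character vectors.
#' @param nPerm number of gene-label permutations (>= 100; default 1000).
#' @param seed integer seed (mandatory).
#' @param p metric weight exponent (default 1).
#' @return data.frame with `set`, `size`, `es`, `nes`, `p_perm`, `fdr`,
#'   `note`, sorted by decreasing `nes`.
#' @export
gseaPermutation <- function(ranked, geneSets, nPerm = 1000, seed, p = 1) {
  stopifnot(is.list(geneSets), !is.null(names(geneSets)))
  if (missing(seed)) stop("a seed is mandatory for gseaPermutation")
  if (nPerm < 100) stop("nPerm must be >= 100")
  N <- length(ranked)
  wAbs <- abs(ranked)^p
  sizes <- integer(0)
  obs <- numeric(0)
  keep <- character(0)
  skipped <- character(0)
  for (nm in names(geneSets)) {
    k <- sum(names(ranked) %in% geneSets[[nm]])
    if (k == 0L || k >= N) {
      skipped <- c(skipped, sprintf("%s: degenerate after restriction (k = %d)", nm, k))
      next
    }
    keep <- c(keep, nm)
    sizes <- c(sizes, k)
    obs <- c(obs, gseaScore(ranked, geneSets[[nm]], p = p))
  }
  if (length(keep) == 0L) {
    res <- data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_perm = numeric(), fdr = numeric(),
                      note = character(), stringsAsFactors = FALSE)
    attr(res, "skipped") <- skipped
    return(res)
  }
  set.seed(as.integer(seed))
  uk <- sort(unique(sizes))
  nulls <- list()
  for (k in uk) {
    nulls[[as.character(k)]] <- vapply(seq_len(nPerm), function(i) {
      .gseaESFromPositions(sort(sample.int(N, k)), wAbs, N)
    }, numeric(1))
  }
  nes <- p_perm <- rep(NA_real_, length(keep))
  note <- rep("", length(keep))
  nullNES <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    nl <- nulls[[as.character(sizes[i])]]
    mpos <- mean(nl[nl >= 0])
    mneg <- mean(abs(nl[nl < 0]))
    nn <- ifelse(nl >= 0,
                 if (is.nan(mpos)) NA_real_ else nl / mpos,
                 if (is.nan(mneg)) NA_real_ else nl / mneg)
    nullNES[[i]] <- nn
    if (obs[i] >= 0) {
      if (is.nan(mpos) || sum(nl >= 0) == 0L) {
        note[i] <- "no positive null mass"
        next
      }
      nes[i] <- obs[i] / mpos
      p_perm[i] <- (1 + sum(nl >= obs[i])) / (1 + sum(nl >= 0))
    } else {
      if (is.nan(mneg) || sum(nl < 0) == 0L) {
        note[i] <- "no negative null mass"
        next
      }
      nes[i] <- obs[i] / mneg
      p_perm[i] <- (1 + sum(nl <= obs[i])) / (1 + sum(nl < 0))
    }
  }
  pooled <- unlist(nullNES, use.names = FALSE)
  pooled <- pooled[is.finite(pooled)]
  fdr <- rep(NA_real_, length(keep))
  for (i in seq_along(keep)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      nullTail <- sum(pooled >= nes[i]) / max(1L, sum(pooled >= 0))
      obsTail <- sum(nes >= nes[i], na.rm = TRUE) / max(1L, sum(nes >= 0, na.rm = TRUE))
    } else {
      nullTail <- sum(pooled <= nes[i]) / max(1L, sum(pooled < 0))
      obsTail <- sum(nes <= nes[i], na.rm = TRUE) / max(1L, sum(nes < 0, na.rm = TRUE))
    }
    fdr[i] <- min(1, max(0, nullTail / max(obsTail, .Machine$double.eps)))
  }
  # monotone within each sign: each set's FDR becomes the minimum over all
  # sets at most as extreme, so larger |NES| never gets a larger value
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) &
                   (sign(nes) == sgn | (sgn == 1 & nes == 0)))
    if (length(idx) < 2L) next
    ord <- idx[order(-abs(nes[idx]))]
    f <- replace(fdr[ord], is.na(fdr[ord]), 1)
    fdr[ord] <- rev(cummin(rev(f)))
  }
  res <- data.frame(set = keep, size = sizes, es = obs, nes = nes,
                    p_perm = p_perm, fdr = fdr, note = note,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$nes), ]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Over-representation analysis by the hypergeometric test
#'
#' Upper-tail hypergeometric p-value for the overlap of a query gene set
#' with each annotation set (both intersected with the universe first),
#' with Benjamini-Hochberg adjustment across sets.
#'
#' @param query character vector of query genes (must be a subset of the
#'   universe; non-empty).
#' @param universe character vector of background genes.
#' @param annotationSets named list of character vectors.
#' @return data.frame with `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`.
#' @export
oraHypergeometric <- function(query, universe, annotationSets) {
  query <- unique(query); universe <- unique(universe)
  if (length(query) == 0L) stop("empty query gene set")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotationSets), function(nm) {
    K <- length(intersect(annotationSets[[nm]], universe))
    k <- length(intersect(annotationSets[[nm]], query))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$q <- .bh(res$p)
  res
}
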