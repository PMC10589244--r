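# Correlations of the index with immune microenvironment scores,
# immune-cell fractions, immune subtypes, checkpoint expression and
# molecular features; tumor mutation burden and per-gene mutation
# frequencies from MAF-like tables. Upstream deconvolution/purity tools
# (ESTIMATE, CIBERSORT) are consumed as precomputed score tables, never
# reimplemented. Missing values are pairwise-deleted per test.

#' Curated immune checkpoint gene symbols
#'
#' A curated list of 48 immune checkpoint (stimulatory and inhibitory)
#' genes commonly used in pan-cancer checkpoint-expression scans,
#' including the PD-1 axis (PDCD1, CD274, PDCD1LG2), CTLA4, the
#' TNF-receptor superfamily members and T-lymphocyte co-stimulators.
#'
#' @return character vector of 48 gene symbols.
#' @export
checkpointGenes <- function() {
  c("ADORA2A", "BTLA", "BTNL2", "CD160", "CD200", "CD200R1", "CD226",
    "CD244", "CD27", "CD274", "CD276", "CD28", "CD40", "CD40LG", "CD44",
    "CD48", "CD70", "CD80", "CD86", "CTLA4", "HAVCR2", "HHLA2", "ICOS",
    "ICOSLG", "IDO1", "IDO2", "KIR3DL1", "LAG3", "LAIR1", "LGALS9",
    "NRP1", "PDCD1", "PDCD1LG2", "TIGIT", "TMIGD2", "TNFRSF14",
    "TNFRSF18", "TNFRSF25", "TNFRSF4", "TNFRSF8", "TNFRSF9", "TNFSF14",
    "TNFSF15", "TNFSF18", "TNFSF4", "TNFSF9", "VSIR", "VTCN1")
}

#' Correlation of two per-sample vectors
#'
#' Spearman (Pearson on average ranks) or Pearson correlation after
#' pairwise deletion of missing values. Spearman p-values use the exact
#' permutation distribution when n <= 9 and there are no ties, and the
#' t approximation otherwise; Pearson p-values come from the t
#' distribution. A constant vector yields an undefined coefficient,
#' returned flagged rather than as an error.
#'
#' @param x,y numeric vectors of equal length (or named vectors; matched
#'   on names when both are named).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `estimate`, `p`, `n`, `method`, `note` (`""` or
#'   `"constant input"`).
#' @export
correlatePairs <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("correlatePairs needs >= 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(estimate = NA_real_, p = NA_real_, n = n, method = method,
                note = "constant input"))
  if (method == "spearman") {
    noTies <- !anyDuplicated(x) && !anyDuplicated(y)
    exact <- n <= 9L && noTies
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = exact))
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
  }
  list(estimate = unname(ct$estimate), p = ct$p.value, n = n,
       method = method, note = "")
}

#' Scan associations between the index and annotation scores
#'
#' One correlation per stratum x variable between the per-sample index and
#' each numeric column of the score table, with BH adjustment across
#' strata within each variable family and a star flag at raw p < 0.05.
#' Variables or strata with fewer than 3 complete pairs are skipped and
#' logged.
#'
#' @param ppi [PpiTable-class] or data.frame with `sample`, `ppi`.
#' @param scores data.frame with a `sample` column plus numeric score
#'   columns (stromal/immune/ESTIMATE scores, purity, cell fractions,
#'   MSI, stemness, HRD, pathway scores -- any subset).
#' @param method correlation method (default `"spearman"`).
#' @param strata optional named character sample -> stratum; `NULL` pools
#'   all samples into stratum `"all"`.
#' @return data.frame with `stratum`, `variable`, `method`, `estimate`,
#'   `p`, `q`, `n`, `significant`; skips in `attr(, "skipped")`.
#' @export
associationScan <- function(ppi, scores, method = "spearman", strata = NULL) {
  df <- .ppiDF(ppi)
  stopifnot("sample" %in% names(scores))
  vars <- setdiff(names(scores), "sample")
  vars <- vars[vapply(scores[vars], is.numeric, logical(1))]
  pv <- stats::setNames(df$ppi, df$sample)
  if (is.null(strata))
    strata <- stats::setNames(rep("all", nrow(df)), df$sample)
  rows <- list()
  skipped <- character()
  for (st in sort(unique(strata))) {
    ids <- intersect(names(pv)[strata[names(pv)] == st], scores$sample)
    for (v in vars) {
      sv <- stats::setNames(scores[[v]], scores$sample)[ids]
      xv <- pv[ids]
      nOk <- sum(is.finite(sv) & is.finite(xv))
      if (nOk < 3L) {
        skipped <- c(skipped, sprintf("%s/%s: fewer than 3 complete pairs", st, v))
        next
      }
      cr <- correlatePairs(xv, sv, method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, variable = v, method = method,
        estimate = cr$estimate, p = cr$p, n = cr$n,
        note = cr$note, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame()
  if (nrow(res)) {
    res$q <- NA_real_
    for (v in unique(res$variable)) {
      i <- res$variable == v
      res$q[i] <- .bh(res$p[i])
    }
    res$significant <- !is.na(res$p) & res$p < 0.05
  }
  attr(res, "skipped") <- skipped
  res
}

#' Correlation of the index with checkpoint-gene expression
#'
#' Pearson correlation of the per-sample index against the expression of
#' each checkpoint gene, per stratum. Unmeasured genes are reported as
#' missing rows (estimate `NA`, note `"unmeasured"`); constant expression
#' is flagged.
#'
#' @param ppi [PpiTable-class] or data.frame with `sample`, `ppi`.
#' @param expr validated gene x sample numeric matrix.
#' @param genes checkpoint symbols (default [checkpointGenes()]).
#' @param strata optional named character sample -> stratum.
#' @return data.frame with `stratum`, `gene`, `r`, `p`, `n`, `note`.
#' @export
checkpointCorrelation <- function(ppi, expr, genes = checkpointGenes(),
                                  strata = NULL) {
  validateExpression(expr)
  df <- .ppiDF(ppi)
  pv <- stats::setNames(df$ppi, df$sample)
  ids0 <- intersect(names(pv), colnames(expr))
  if (is.null(strata))
    strata <- stats::setNames(rep("all", length(ids0)), ids0)
  rows <- list()
  for (st in sort(unique(strata))) {
    ids <- ids0[strata[ids0] == st]
    for (g in genes) {
      if (!g %in% rownames(expr)) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, gene = g, r = NA_real_, p = NA_real_,
          n = NA_integer_, note = "unmeasured", stringsAsFactors = FALSE)
        next
      }
      if (length(ids) < 3L) next
      cr <- correlatePairs(pv[ids], expr[g, ids], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, gene = g, r = cr$estimate, p = cr$p, n = cr$n,
        note = cr$note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare the index across immune subtypes
#'
#' Per stratum: Kruskal-Wallis omnibus test of the index across immune
#' subtypes (C1-C6), per-subtype medians, and BH-adjusted pairwise
#' Wilcoxon tests. Subtypes with fewer than 2 samples are excluded and
#' logged; strata with fewer than 2 usable subtypes are skipped.
#'
#' @param ppi [PpiTable-class] or data.frame with `sample`, `ppi`.
#' @param ann annotations with `sample`, `cancer_type` and the subtype
#'   column.
#' @param field subtype column name (default `"immune_subtype"`).
#' @return list with `omnibus` (data.frame: stratum, H, p, n), `medians`
#'   (stratum, subtype, median, n), `pairwise` (stratum, subtype pair,
#'   p, q); skips in `attr(, "skipped")`.
#' @export
subtypeCompare <- function(ppi, ann, field = "immune_subtype") {
  df <- merge(.ppiDF(ppi), ann, by = "sample")
  if (!field %in% names(df)) stop("unknown subtype field: ", field)
  omnibus <- medians <- pairwise <- list()
  skipped <- character()
  for (st in sort(unique(df$cancer_type))) {
    sub <- df[df$cancer_type == st & !is.na(df[[field]]), ]
    tab <- table(sub[[field]])
    small <- names(tab)[tab < 2]
    if (length(small)) {
      skipped <- c(skipped, sprintf("%s: subtypes excluded (<2 samples): %s",
                                    st, paste(small, collapse = ",")))
      sub <- sub[!sub[[field]] %in% small, ]
    }
    v <- droplevels(as.factor(as.character(sub[[field]])))
    if (nlevels(v) < 2L) {
      skipped <- c(skipped, sprintf("%s: fewer than 2 usable subtypes", st))
      next
    }
    kw <- stats::kruskal.test(sub$ppi ~ v)
    omnibus[[st]] <- data.frame(stratum = st, H = unname(kw$statistic),
                                p = kw$p.value, n = nrow(sub),
                                stringsAsFactors = FALSE)
    med <- stats::aggregate(sub$ppi, list(subtype = v), stats::median)
    cnt <- as.integer(table(v)[med$subtype])
    medians[[st]] <- data.frame(stratum = st, subtype = med$subtype,
                                median = med$x, n = cnt,
                                stringsAsFactors = FALSE)
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(sub$ppi, v, p.adjust.method = "none"))
    pm <- pw$p.value
    prs <- which(!is.na(pm), arr.ind = TRUE)
    if (nrow(prs)) {
      praw <- pm[prs]
      pairwise[[st]] <- data.frame(
        stratum = st,
        subtype_a = rownames(pm)[prs[, 1]],
        subtype_b = colnames(pm)[prs[, 2]],
        p = praw, q = .bh(praw), stringsAsFactors = FALSE)
    }
  }
  out <- list(
    omnibus = if (length(omnibus)) do.call(rbind, c(omnibus, list(make.row.names = FALSE))) else data.frame(),
    medians = if (length(medians)) do.call(rbind, c(medians, list(make.row.names = FALSE))) else data.frame(),
    pairwise = if (length(pairwise)) do.call(rbind, c(pairwise, list(make.row.names = FALSE))) else data.frame())
  attr(out, "skipped") <- skipped
  out
}

#' Nonsynonymous variant-classification vocabulary
#'
#' The default MAF variant classifications counted as nonsynonymous for
#' tumor mutation burden.
#'
#' @return character vector of classification strings.
#' @export
tmbVocabulary <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

# Full documented MAF vocabulary: nonsynonymous classes plus classes that
# are recognized but not counted.
.mafKnownClasses <- function() {
  c(tmbVocabulary(),
    "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR",
    "RNA", "Targeted_Region")
}

.normalizeMut <- function(mut) {
  aliases <- c(sample = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
               variant_classification = "Variant_Classification")
  for (a in names(aliases)) {
    if (a %in% names(mut) && !aliases[[a]] %in% names(mut))
      names(mut)[names(mut) == a] <- aliases[[a]]
  }
  need <- unname(aliases)
  if (!all(need %in% names(mut)))
    stop("mutation table needs columns: ", paste(need, collapse = ", "))
  mut
}

#' Tumor mutation burden per sample
#'
#' Counts mutation rows whose variant classification belongs to the
#' nonsynonymous vocabulary and divides by the exome size in megabases.
#' Samples in `samples` that have no rows receive TMB 0. Rows with a
#' classification outside the documented MAF vocabulary are excluded with
#' a warning and counted in the `qc` attribute.
#'
#' @param mut MAF-like data.frame (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'   `Variant_Classification`, or lowercase `sample`/`gene`/
#'   `variant_classification` aliases).
#' @param samples character vector of the sample universe; default the
#'   samples present in the table.
#' @param exomeMb exome size in megabases (> 0; default 38).
#' @param nonsynonymous classifications counted (default
#'   [tmbVocabulary()]).
#' @return named numeric vector of mutations/Mb with an attached `qc`
#'   attribute (`n_unknown_class` rows excluded).
#' @export
computeTmb <- function(mut, samples = NULL, exomeMb = 38,
                       nonsynonymous = tmbVocabulary()) {
  if (exomeMb <= 0) stop("exomeMb must be > 0")
  mut <- .normalizeMut(mut)
  if (is.null(samples)) samples <- sort(unique(mut$Tumor_Sample_Barcode))
  unknown <- !mut$Variant_Classification %in% .mafKnownClasses()
  if (any(unknown)) {
    warning(sum(unknown), " mutation rows with unknown variant classification excluded")
    mut <- mut[!unknown, ]
  }
  keep <- mut[mut$Variant_Classification %in% nonsynonymous, ]
  cnt <- table(factor(keep$Tumor_Sample_Barcode, levels = samples))
  tmb <- as.numeric(cnt) / exomeMb
  names(tmb) <- samples
  attr(tmb, "qc") <- list(n_unknown_class = sum(unknown))
  tmb
}

#' Per-gene mutation frequency by stratum
#'
#' Fraction of samples in each stratum carrying at least one (by default
#' nonsilent) mutation row for each gene; multiple rows per sample-gene
#' count once. The sample universe supplies the denominator, so genes
#' absent from the table get frequency 0.
#'
#' @param mut MAF-like data.frame (see [computeTmb()]).
#' @param samples sample universe (denominator).
#' @param genes genes to report.
#' @param strata optional named character sample -> stratum; `NULL` pools
#'   into `"all"`.
#' @param nonsilentOnly restrict to the nonsynonymous vocabulary
#'   (default `TRUE`); `FALSE` counts every known classification.
#' @return data.frame with `stratum`, `gene`, `n_mutated`, `n_samples`,
#'   `frequency`.
#' @export
mutationFrequency <- function(mut, samples, genes, strata = NULL,
                              nonsilentOnly = TRUE) {
  mut <- .normalizeMut(mut)
  if (is.null(strata)) strata <- stats::setNames(rep("all", length(samples)), samples)
  if (nonsilentOnly) mut <- mut[mut$Variant_Classification %in% tmbVocabulary(), ]
  mut <- mut[mut$Tumor_Sample_Barcode %in% samples & mut$Hugo_Symbol %in% genes, ]
  mut <- unique(mut[, c("Tumor_Sample_Barcode", "Hugo_Symbol")])
  rows <- list()
  for (st in sort(unique(strata))) {
    ids <- names(strata)[strata == st]
    if (length(ids) == 0L) next
    sub <- mut[mut$Tumor_Sample_Barcode %in% ids, ]
    for (g in genes) {
      nm <- length(unique(sub$Tumor_Sample_Barcode[sub$Hugo_Symbol == g]))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, gene = g, n_mutated = nm, n_samples = length(ids),
        frequency = nm / length(ids), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Tumor/normal expression ratio per gene
#'
#' For each gene and stratum, the log2 ratio of the mean tumor to mean
#' normal expression on the linear scale. Input on the log2(x+1) scale is
#' back-transformed first (`linearScale = FALSE` treats values as already
#' linear). A zero normal-group mean receives a 1e-9 pseudocount and is
#' flagged. A Wilcoxon rank-sum p-value per gene accompanies the ratio.
#'
#' @param expr validated gene x sample numeric matrix.
#' @param ann annotations with `sample`, `cancer_type`, `tissue`.
#' @param genes genes to report (default: catalog genes present).
#' @param linearScale `FALSE` (default) means `expr` is log2(x+1) and is
#'   back-transformed before averaging.
#' @return data.frame with `stratum`, `gene`, `log2_ratio`, `p`,
#'   `n_tumor`, `n_normal`, `flag`.
#' @export
diffExpressionLog2Ratio <- function(expr, ann, genes = NULL,
                                    linearScale = FALSE) {
  validateExpression(expr)
  if (is.null(genes)) {
    cat58 <- prgCatalog()
    genes <- intersect(c(cat58@positive, cat58@negative), rownames(expr))
  }
  genes <- intersect(genes, rownames(expr))
  ann <- ann[ann$sample %in% colnames(expr), ]
  rows <- list()
  for (st in sort(unique(ann$cancer_type))) {
    sub <- ann[ann$cancer_type == st, ]
    tum <- sub$sample[sub$tissue == "tumor"]
    nor <- sub$sample[sub$tissue == "normal"]
    if (length(tum) == 0L || length(nor) == 0L) next
    for (g in genes) {
      vt <- expr[g, tum]; vn <- expr[g, nor]
      lt <- if (linearScale) vt else 2^vt - 1
      ln <- if (linearScale) vn else 2^vn - 1
      mT <- mean(lt); mN <- mean(ln)
      flag <- ""
      if (mN == 0) { mN <- 1e-9; flag <- "zero normal mean" }
      p <- if (length(vt) >= 1 && length(vn) >= 1)
        suppressWarnings(stats::wilcox.test(vt, vn)$p.value) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, gene = g, log2_ratio = log2(mT / mN), p = p,
        n_tumor = length(tum), n_normal = length(nor), flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
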