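# End-to-end orchestration: score -> group -> survival -> enrichment ->
# associate -> TMB -> drug, with stage-granular logging, per-stratum skip
# reasons, and a machine-readable manifest. Outputs are plain TSVs; the
# manifest records parameters, seeds and per-stage row counts so re-runs
# with an identical config reproduce identical bytes.

#' Assemble a pipeline run configuration
#'
#' Inputs may be given as file paths (the TSV/GMT dialects written by
#' [writeCohort()] and [writeGmt()]) or, for expression/clinical/etc.,
#' left `NULL` to skip the corresponding stage.
#'
#' @param exprPath expression TSV (gene column + samples). Required.
#' @param clinicalPath clinical TSV. Required for survival/association
#'   stages.
#' @param catalog `"prg"` for the packaged catalog or a path to a GMT file
#'   whose first two sets are the positive and negative direction.
#' @param mutationPath,scoresPath,panelExprPath,drugPath optional stage
#'   inputs (MAF-like TSV, score TSV, cell-line expression TSV, drug x
#'   line TSV).
#' @param gmtPath optional GMT of annotation sets for the GSEA stage.
#' @param alpha,normalize scoring parameters (see [computePpi()]).
#' @param splitRule grouping rule (see [splitGroups()]).
#' @param endpoints survival endpoints to scan.
#' @param nPerm GSEA permutations.
#' @param exomeMb TMB denominator in Mb.
#' @param seed master seed for the stochastic stages.
#' @param outDir output directory.
#' @return config list of class `ppiRunConfig`.
#' @export
runConfig <- function(exprPath, clinicalPath = NULL, catalog = "prg",
                      mutationPath = NULL, scoresPath = NULL,
                      panelExprPath = NULL, drugPath = NULL, gmtPath = NULL,
                      alpha = 0.25, normalize = TRUE, splitRule = "median",
                      endpoints = c("os", "dss", "dfs", "pfs"),
                      nPerm = 1000, exomeMb = 38, seed = 1,
                      outDir = tempfile("ppirun")) {
  cfg <- list(exprPath = exprPath, clinicalPath = clinicalPath,
              catalog = catalog, mutationPath = mutationPath,
              scoresPath = scoresPath, panelExprPath = panelExprPath,
              drugPath = drugPath, gmtPath = gmtPath, alpha = alpha,
              normalize = normalize, splitRule = splitRule,
              endpoints = endpoints, nPerm = nPerm, exomeMb = exomeMb,
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "ppiRunConfig"
  cfg
}

.loadCatalog <- function(catalog) {
  if (is(catalog, "DirectionalCatalog")) return(catalog)
  if (identical(catalog, "prg")) return(prgCatalog())
  sets <- readGmt(catalog)
  if (length(sets) < 2L) stop("catalog GMT needs two sets (positive, negative)")
  DirectionalCatalog(sets[[1]], sets[[2]])
}

#' Validate pipeline inputs
#'
#' Checks file existence, expression-matrix invariants, catalog coverage
#' and sample-id consistency across the supplied tables. Hard errors
#' (analysis cannot run) are distinguished from warnings (analysis runs
#' with drops).
#'
#' @param config a [runConfig()].
#' @return data.frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when fully consistent.
#' @export
validateInputs <- function(config) {
  rows <- list()
  note <- function(level, msg)
    rows[[length(rows) + 1L]] <<- data.frame(level = level, message = msg,
                                             stringsAsFactors = FALSE)
  paths <- c(expr = config$exprPath, clinical = config$clinicalPath,
             mutations = config$mutationPath, scores = config$scoresPath,
             panel = config$panelExprPath, drugs = config$drugPath,
             gmt = config$gmtPath)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      note("error", sprintf("%s file not found: %s", nm, paths[[nm]]))
  }
  if (length(rows) == 0L || !any(vapply(rows, function(r) r$level == "error", logical(1)))) {
    expr <- tryCatch(readExpressionMatrix(config$exprPath), error = function(e) e)
    if (inherits(expr, "error")) {
      note("error", paste("expression:", conditionMessage(expr)))
    } else {
      cat2 <- tryCatch(restrictToMeasured(.loadCatalog(config$catalog),
                                          rownames(expr)),
                       error = function(e) e)
      if (inherits(cat2, "error")) {
        note("error", paste("catalog:", conditionMessage(cat2)))
      } else if (length(unlist(cat2$dropped))) {
        note("warning", sprintf("catalog symbols not measured: %s",
                                paste(unlist(cat2$dropped), collapse = ", ")))
      }
      if (!is.null(config$clinicalPath) && file.exists(config$clinicalPath)) {
        ann <- .readTsv(config$clinicalPath)
        if (!all(c("sample", "cancer_type", "tissue") %in% names(ann))) {
          note("error", "clinical table missing sample/cancer_type/tissue")
        } else {
          miss <- setdiff(colnames(expr), ann$sample)
          if (length(miss))
            note("warning", sprintf("clinical table missing scored samples: %s",
                                    paste(utils::head(miss, 10), collapse = ", ")))
        }
      }
      if (!is.null(config$scoresPath) && file.exists(config$scoresPath)) {
        sc <- .readTsv(config$scoresPath)
        if (!"sample" %in% names(sc)) note("error", "scores table has no sample column")
      }
    }
  }
  if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(level = character(), message = character(),
                  stringsAsFactors = FALSE)
}

.stageWrite <- function(df, path, manifest, name, skipped = NULL) {
  .writeTsv(df, path)
  manifest$outputs[[name]] <- list(file = basename(path), rows = nrow(df))
  if (length(skipped)) manifest$skips[[name]] <- skipped
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (score, group, tumor/normal comparison,
#' survival scan, GSEA, association scan + subtype comparison, TMB +
#' mutation frequency, drug prediction/comparison + cell-line
#' correlation), skipping stages whose inputs are absent, and writes one
#' TSV per stage plus `manifest.json` under the configured output
#' directory. A hard validation error aborts before any stage runs.
#' Re-running with an identical config reproduces identical outputs.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the output directory, the manifest, and
#'   the per-stage result objects.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "ppiRunConfig"))
  val <- validateInputs(config)
  if (any(val$level == "error"))
    stop("input validation failed:\n  ",
         paste(val$message[val$level == "error"], collapse = "\n  "))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "ppindex",
    version = as.character(utils::packageVersion("ppindex")),
    parameters = config[setdiff(names(config), "outDir")],
    outputs = list(), skips = list())
  results <- list()

  expr <- readExpressionMatrix(config$exprPath)
  cat2 <- .loadCatalog(config$catalog)
  ppi <- computePpi(expr, cat2, alpha = config$alpha,
                    normalize = config$normalize)
  results$ppi <- ppi
  manifest <- .stageWrite(as.data.frame(ppi),
                          file.path(config$outDir, "ppi.tsv"),
                          manifest, "score")

  ann <- NULL
  strata <- NULL
  if (!is.null(config$clinicalPath)) {
    ann <- .readTsv(config$clinicalPath)
    tum <- ann[ann$tissue == "tumor", ]
    strata <- stats::setNames(tum$cancer_type, tum$sample)
  }
  groups <- splitGroups(ppi, strata = strata, rule = config$splitRule)
  results$groups <- groups
  manifest <- .stageWrite(groups, file.path(config$outDir, "groups.tsv"),
                          manifest, "groups", attr(groups, "skipped"))

  if (!is.null(ann)) {
    rows <- list()
    for (st in sort(unique(ann$cancer_type))) {
      up <- diffPpiUnpaired(ppi, ann, st)
      pr <- diffPpiPaired(ppi, ann, st)
      rows[[st]] <- data.frame(
        stratum = st,
        unpaired_p = if (isSkipped(up)) NA_real_ else up$p,
        median_tumor = if (isSkipped(up)) NA_real_ else up$median_tumor,
        median_normal = if (isSkipped(up)) NA_real_ else up$median_normal,
        paired_p = if (isSkipped(pr)) NA_real_ else pr$p,
        n_pairs = if (isSkipped(pr)) NA_integer_ else pr$n_pairs,
        stringsAsFactors = FALSE)
    }
    dt <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    results$differential <- dt
    manifest <- .stageWrite(dt, file.path(config$outDir, "differential.tsv"),
                            manifest, "differential")

    sc <- survivalScan(ppiScores(ppi), ann, endpoints = config$endpoints,
                       rule = config$splitRule)
    results$survival <- sc
    manifest <- .stageWrite(sc, file.path(config$outDir, "survival.tsv"),
                            manifest, "survival", attr(sc, "skipped"))
  }

  if (!is.null(config$gmtPath) && nrow(groups)) {
    sets <- readGmt(config$gmtPath)
    rows <- list()
    skips <- character()
    for (st in sort(unique(groups$stratum))) {
      g <- groups[groups$stratum == st, ]
      rk <- tryCatch(rankGenes(expr, g), error = function(e) NULL)
      if (is.null(rk)) { skips <- c(skips, sprintf("%s: ranking failed", st)); next }
      gr <- gseaPermutation(rk, sets, nPerm = config$nPerm,
                            seed = .subSeed(config$seed, 10L))
      if (nrow(gr)) rows[[st]] <- cbind(stratum = st, gr)
      skips <- c(skips, attr(gr, "skipped"))
    }
    ge <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame()
    results$gsea <- ge
    manifest <- .stageWrite(ge, file.path(config$outDir, "gsea.tsv"),
                            manifest, "gsea", skips)
  }

  if (!is.null(config$scoresPath) && !is.null(strata)) {
    scores <- .readTsv(config$scoresPath)
    as <- associationScan(ppi, scores, strata = strata)
    results$associations <- as
    manifest <- .stageWrite(as, file.path(config$outDir, "associations.tsv"),
                            manifest, "associations", attr(as, "skipped"))
  }
  if (!is.null(ann) && "immune_subtype" %in% names(ann)) {
    stc <- subtypeCompare(ppi, ann)
    results$subtypes <- stc
    manifest <- .stageWrite(stc$omnibus,
                            file.path(config$outDir, "subtypes.tsv"),
                            manifest, "subtypes", attr(stc, "skipped"))
  }

  if (!is.null(config$mutationPath)) {
    mut <- .readTsv(config$mutationPath)
    samples <- if (!is.null(ann)) ann$sample[ann$tissue == "tumor"]
    else colnames(expr)
    tmb <- computeTmb(mut, samples = samples, exomeMb = config$exomeMb)
    tdf <- data.frame(sample = names(tmb), tmb = as.numeric(tmb),
                      stringsAsFactors = FALSE)
    results$tmb <- tdf
    manifest <- .stageWrite(tdf, file.path(config$outDir, "tmb.tsv"),
                            manifest, "tmb")
    cat3 <- restrictToMeasured(cat2, rownames(expr))$catalog
    mf <- mutationFrequency(mut, samples,
                            c(cat3@positive, cat3@negative), strata = strata)
    results$mutation_frequency <- mf
    manifest <- .stageWrite(mf,
                            file.path(config$outDir, "mutation_frequency.tsv"),
                            manifest, "mutation_frequency")
  }

  if (!is.null(config$panelExprPath) && !is.null(config$drugPath)) {
    panel <- readExpressionMatrix(config$panelExprPath)
    ddf <- .readTsv(config$drugPath)
    drm <- as.matrix(ddf[, -1, drop = FALSE])
    rownames(drm) <- ddf[[1]]
    cor <- celllinePpiDrugCorrelation(panel, drm, cat2,
                                      alpha = config$alpha,
                                      normalize = config$normalize)
    results$drug_correlation <- cor
    manifest <- .stageWrite(cor,
                            file.path(config$outDir, "drug_correlation.tsv"),
                            manifest, "drug_correlation")
    if (nrow(groups)) {
      hom <- homogenizeExpression(panel, expr, minShared = min(200, nrow(panel) - 1))
      preds <- list()
      for (d in rownames(drm)) {
        mdl <- tryCatch(
          fitRidgeIc50(hom$train, drm[d, ], seed = .subSeed(config$seed, 20L)),
          error = function(e) NULL)
        if (!is.null(mdl)) preds[[d]] <- predictIc50(mdl, hom$target)
      }
      if (length(preds)) {
        pm <- do.call(cbind, preds)
        cmp <- predictAndCompare(pm, groups)
        results$drug_comparison <- cmp
        manifest <- .stageWrite(cmp,
                                file.path(config$outDir, "drug_comparison.tsv"),
                                manifest, "drug_comparison",
                                attr(cmp, "skipped"))
      }
    }
  }

  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(outDir = config$outDir, manifest = manifest,
                 results = results))
}
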