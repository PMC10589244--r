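# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: a latent per-tumor activation level drives (i) a planted
# expression shift of the positive regulators (and a downshift of the
# negative ones), (ii) survival hazard, (iii) immune scores and selected
# immune-cell fractions (purity moving oppositely), (iv) optionally the
# mutation rate, and (v) cell-line drug response. Activation is uniform on
# (0, 1) rather than binary so the index behaves as a continuous score
# while binary recovery metrics remain available via thresholding. All
# randomness flows from one master seed through fixed per-stage sub-seeds
# so stages are independently regenerable.

.CIBERSORT_CELLS <- c(
  "B_cells_naive", "B_cells_memory", "Plasma_cells", "T_cells_CD8",
  "T_cells_CD4_naive", "T_cells_CD4_memory_resting",
  "T_cells_CD4_memory_activated", "T_cells_follicular_helper",
  "T_cells_regulatory_Tregs", "T_cells_gamma_delta", "NK_cells_resting",
  "NK_cells_activated", "Monocytes", "Macrophages_M0", "Macrophages_M1",
  "Macrophages_M2", "Dendritic_cells_resting", "Dendritic_cells_activated",
  "Mast_cells_resting", "Mast_cells_activated", "Eosinophils", "Neutrophils")

.PLANTED_CELLS <- c("Macrophages_M1", "T_cells_CD8", "T_cells_regulatory_Tregs")

# Immune subtypes ordered by increasing activation; C2 (IFN-gamma dominant)
# sits at the top and C2 > C3 > C4 holds in expectation, matching the
# pan-cancer observation the generator emulates.
.SUBTYPE_BINS <- c("C5", "C4", "C6", "C1", "C3", "C2")

#' Configuration for the synthetic cohort generator
#'
#' @param n_genes number of genes (must cover catalog + checkpoint genes).
#' @param n_samples total samples (tumors + paired normals).
#' @param n_strata number of pseudo cancer types.
#' @param frac_normal fraction of samples that are paired normals, in
#'   \[0, 1).
#' @param activation_effect delta: log2-units upshift of positive-catalog
#'   genes per unit activation (default 1.5).
#' @param negative_effect_ratio kappa: the negative catalog is shifted by
#'   `-kappa * delta * a` (default 1).
#' @param hazard_beta log-hazard per unit activation; scalar or one value
#'   per stratum (sign configurable per stratum; default 0.8).
#' @param immune_coupling slope of immune scores/fractions on activation
#'   (default 0.6); purity moves as `1 - 0.5 * immune_coupling * a`.
#' @param drug_coupling slope of IC50 decrease per unit activation
#'   (default 1.5; lower IC50 = more sensitive).
#' @param tmb_coupling log-linear coupling of the mutation rate to
#'   activation (default 0 = uncoupled).
#' @param noise_sd per-value expression noise sd in log2 units
#'   (default 1).
#' @param censor_rate approximate censoring fraction in \[0, 1)
#'   (default 0.3).
#' @param n_cell_lines cell-line panel size (default 60).
#' @param drugs drug names for the panel (default the seven
#'   chemotherapy/targeted agents of the pan-cancer comparison).
#' @param seed master seed (mandatory).
#' @return validated configuration list of class `simulationConfig`.
#' @export
simulationConfig <- function(n_genes = 1000, n_samples = 200, n_strata = 4,
                             frac_normal = 0.15, activation_effect = 1.5,
                             negative_effect_ratio = 1, hazard_beta = 0.8,
                             immune_coupling = 0.6, drug_coupling = 1.5,
                             tmb_coupling = 0, noise_sd = 1,
                             censor_rate = 0.3, n_cell_lines = 60,
                             drugs = c("cisplatin", "rapamycin", "gemcitabine",
                                       "paclitaxel", "docetaxel", "sorafenib",
                                       "methotrexate"),
                             seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_genes > 0, n_samples > 0, n_strata > 0, n_cell_lines > 0,
            frac_normal >= 0, frac_normal < 1,
            censor_rate >= 0, censor_rate < 1,
            activation_effect >= 0, noise_sd > 0)
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_strata = as.integer(n_strata), frac_normal = frac_normal,
              activation_effect = activation_effect,
              negative_effect_ratio = negative_effect_ratio,
              hazard_beta = rep_len(hazard_beta, n_strata),
              immune_coupling = immune_coupling,
              drug_coupling = drug_coupling, tmb_coupling = tmb_coupling,
              noise_sd = noise_sd, censor_rate = censor_rate,
              n_cell_lines = as.integer(n_cell_lines), drugs = drugs,
              seed = as.integer(seed))
  class(cfg) <- "simulationConfig"
  cfg
}

.geneUniverse <- function(n_genes) {
  cat58 <- prgCatalog()
  core <- unique(c(cat58@positive, cat58@negative, checkpointGenes()))
  if (n_genes < length(core) + 10L)
    stop(sprintf("n_genes must be >= %d to cover catalog and checkpoint genes",
                 length(core) + 10L))
  c(core, sprintf("G%05d", seq_len(n_genes - length(core))))
}

.simExpression <- function(genes, samples, activation, cfg, stageSeed) {
  set.seed(stageSeed)
  cat58 <- prgCatalog()
  mu <- stats::rnorm(length(genes), mean = 3, sd = 1.5)
  names(mu) <- genes
  m <- matrix(stats::rnorm(length(genes) * length(samples), sd = cfg$noise_sd),
              length(genes), length(samples),
              dimnames = list(genes, samples)) + mu
  shift <- cfg$activation_effect * activation[samples]
  pos <- intersect(cat58@positive, genes)
  neg <- intersect(cat58@negative, genes)
  m[pos, ] <- m[pos, , drop = FALSE] +
    matrix(shift, length(pos), length(samples), byrow = TRUE)
  m[neg, ] <- m[neg, , drop = FALSE] -
    cfg$negative_effect_ratio *
    matrix(shift, length(neg), length(samples), byrow = TRUE)
  pmax(m, 0)
}

.simSurvival <- function(ann, activation, cfg, stageSeed) {
  set.seed(stageSeed)
  baseRate <- 1 / 1000  # events per day
  censRate <- if (cfg$censor_rate > 0)
    baseRate * cfg$censor_rate / (1 - cfg$censor_rate) else 0
  strata <- sort(unique(ann$cancer_type))
  patients <- unique(ann$patient_id)
  pa <- vapply(patients, function(p) {
    i <- which(ann$patient_id == p & ann$tissue == "tumor")[1]
    if (is.na(i)) 0 else activation[ann$sample[i]]
  }, numeric(1))
  pst <- vapply(patients, function(p) ann$cancer_type[ann$patient_id == p][1],
                character(1))
  beta <- stats::setNames(cfg$hazard_beta, strata)[pst]
  out <- list()
  for (ep in c("os", "dss", "dfs", "pfs")) {
    tt <- stats::rexp(length(patients), rate = baseRate * exp(beta * pa))
    cc <- if (censRate > 0) stats::rexp(length(patients), rate = censRate)
    else rep(Inf, length(patients))
    out[[paste0(ep, "_time")]] <- round(pmin(tt, cc), 1)
    out[[paste0(ep, "_event")]] <- as.integer(tt <= cc)
  }
  surv <- data.frame(patient_id = patients, out, stringsAsFactors = FALSE)
  merge(ann, surv, by = "patient_id", sort = FALSE)
}

.simClinical <- function(ann, activation, stageSeed) {
  set.seed(stageSeed)
  n <- nrow(ann)
  a <- activation[ann$sample]
  ann$age <- round(stats::rnorm(n, 60, 10))
  ann$sex <- sample(c("male", "female"), n, replace = TRUE)
  ann$race <- sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.15, 0.05))
  ann$grade <- sample(paste0("G", 1:4), n, replace = TRUE)
  ann$stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE)
  bin <- cut(a, breaks = seq(0, 1, length.out = 7), include.lowest = TRUE,
             labels = .SUBTYPE_BINS)
  subtype <- as.character(bin)
  flip <- stats::runif(n) < 0.1  # label noise
  subtype[flip] <- sample(.SUBTYPE_BINS, sum(flip), replace = TRUE)
  subtype[ann$tissue == "normal"] <- NA_character_
  ann$immune_subtype <- subtype
  ann
}

.simScores <- function(ann, activation, cfg, stageSeed) {
  set.seed(stageSeed)
  tum <- ann$sample[ann$tissue == "tumor"]
  a <- activation[tum]
  n <- length(tum)
  ic <- cfg$immune_coupling
  immune <- 500 + 2500 * ic * a + stats::rnorm(n, sd = 300)
  stromal <- 200 + 1200 * ic * a + stats::rnorm(n, sd = 300)
  purity <- pmin(pmax(1 - 0.5 * ic * a + stats::rnorm(n, sd = 0.05), 0), 1)
  # planted cells couple through the gamma shape so the activation signal
  # survives the compositional normalization at field-typical correlation
  # sizes (rank correlations around 0.3-0.5)
  shapes <- stats::setNames(stats::runif(length(.CIBERSORT_CELLS), 1, 3),
                            .CIBERSORT_CELLS)
  frac <- sapply(.CIBERSORT_CELLS, function(cell) {
    sh <- if (cell %in% .PLANTED_CELLS)
      shapes[[cell]] * (1 + 4 * ic * a) else rep(shapes[[cell]], n)
    stats::rgamma(n, shape = sh)
  })
  frac <- frac / rowSums(frac) * 0.9  # leave head-room below 1
  colnames(frac) <- .CIBERSORT_CELLS
  df <- data.frame(
    sample = tum,
    stromal_score = stromal, immune_score = immune,
    estimate_score = stromal + immune, tumor_purity = purity,
    frac,
    msi = pmax(0.1 - 0.05 * a + stats::rnorm(n, sd = 0.05), 0),
    rnass = pmin(pmax(0.5 - 0.3 * a + stats::rnorm(n, sd = 0.1), 0), 1),
    dnass = pmin(pmax(0.5 - 0.2 * a + stats::rnorm(n, sd = 0.1), 0), 1),
    hrd = pmax(20 - 10 * a + stats::rnorm(n, sd = 8), 0),
    pathway_ifn = 0.8 * a + stats::rnorm(n, sd = 0.3),
    pathway_ctla4 = 0.6 * a + stats::rnorm(n, sd = 0.3),
    pathway_pi3k = 0.4 * a + stats::rnorm(n, sd = 0.3),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

.simMutations <- function(ann, activation, genes, cfg, stageSeed) {
  set.seed(stageSeed)
  tum <- ann$sample[ann$tissue == "tumor"]
  a <- activation[tum]
  lambda <- 76 * exp(cfg$tmb_coupling * a)  # ~2/Mb over 38 Mb at a = 0
  counts <- stats::rpois(length(tum), lambda)
  classes <- c(tmbVocabulary(), "Silent", "Intron")
  probs <- c(0.55, 0.06, 0.01, 0.04, 0.04, 0.02, 0.02, 0.05, 0.01, 0.15, 0.05)
  rows <- data.frame(
    Tumor_Sample_Barcode = rep(tum, counts),
    Hugo_Symbol = sample(genes, sum(counts), replace = TRUE),
    Variant_Classification = sample(classes, sum(counts), replace = TRUE,
                                    prob = probs),
    stringsAsFactors = FALSE)
  rows
}

.simCellLines <- function(genes, cfg, stageSeed) {
  set.seed(stageSeed)
  lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  aL <- stats::runif(cfg$n_cell_lines)
  names(aL) <- lines
  cat58 <- prgCatalog()
  mu <- stats::rnorm(length(genes), mean = 3, sd = 1.5)
  m <- matrix(stats::rnorm(length(genes) * length(lines), sd = cfg$noise_sd),
              length(genes), length(lines),
              dimnames = list(genes, lines)) + mu
  pos <- intersect(cat58@positive, genes)
  neg <- intersect(cat58@negative, genes)
  shift <- cfg$activation_effect * aL
  m[pos, ] <- m[pos, , drop = FALSE] +
    matrix(shift, length(pos), length(lines), byrow = TRUE)
  m[neg, ] <- m[neg, , drop = FALSE] -
    cfg$negative_effect_ratio *
    matrix(shift, length(neg), length(lines), byrow = TRUE)
  m <- pmax(m, 0)
  drugs <- matrix(NA_real_, length(cfg$drugs), length(lines),
                  dimnames = list(cfg$drugs, lines))
  base <- stats::rnorm(length(cfg$drugs), mean = 5, sd = 1)
  for (i in seq_along(cfg$drugs))
    drugs[i, ] <- base[i] - cfg$drug_coupling * aL + stats::rnorm(length(lines), sd = 0.3)
  list(expression = m, drugs = drugs, activation = aL)
}

#' Simulate a synthetic pan-cancer cohort
#'
#' Generates one cohort under a [simulationConfig()]: expression with the
#' planted directional signal, four survival endpoints with
#' activation-linked hazard, clinical covariates and immune subtypes,
#' annotation scores (immune/stromal/ESTIMATE, purity, 22 cell fractions,
#' MSI/stemness/HRD/pathways), a MAF-like mutation table, and a cell-line
#' panel with activation-coupled drug response. Identical config + seed
#' yields a bitwise-identical cohort.
#'
#' @param config a [simulationConfig()].
#' @return A [SyntheticCohort-class].
#' @examples
#' co <- simulateCohort(simulationConfig(n_samples = 40, seed = 1))
#' co
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  genes <- .geneUniverse(config$n_genes)
  nNormal <- round(config$frac_normal * config$n_samples)
  nTumor <- config$n_samples - nNormal
  if (nTumor < config$n_strata) stop("too few tumor samples for the strata")
  strata <- paste0("CT", seq_len(config$n_strata))
  tumorIds <- sprintf("S%04dT", seq_len(nTumor))
  patientIds <- sprintf("P%04d", seq_len(nTumor))
  tumorStrata <- rep_len(strata, nTumor)
  # paired normals reuse the first patients; strata are assigned
  # round-robin, so this spreads normals evenly across strata
  normIdx <- seq_len(nNormal)
  ann <- data.frame(
    sample = c(tumorIds, sprintf("S%04dN", normIdx)),
    patient_id = c(patientIds, patientIds[normIdx]),
    cancer_type = c(tumorStrata, tumorStrata[normIdx]),
    tissue = c(rep("tumor", nTumor), rep("normal", length(normIdx))),
    stringsAsFactors = FALSE)
  set.seed(.subSeed(config$seed, 0L))
  activation <- stats::setNames(c(stats::runif(nTumor), rep(0, length(normIdx))),
                                ann$sample)
  expr <- .simExpression(genes, ann$sample, activation, config,
                         .subSeed(config$seed, 1L))
  ann <- .simSurvival(ann, activation, config, .subSeed(config$seed, 2L))
  ann <- .simClinical(ann, activation, .subSeed(config$seed, 3L))
  scores <- .simScores(ann, activation, config, .subSeed(config$seed, 4L))
  mut <- .simMutations(ann, activation, genes, config, .subSeed(config$seed, 5L))
  cl <- .simCellLines(genes, config, .subSeed(config$seed, 6L))
  cfg <- unclass(config)
  cfg$cell_line_activation <- cl$activation
  new("SyntheticCohort", expression = expr, annotations = ann,
      mutations = mut, scores = scores,
      cellLineExpression = cl$expression, drugResponse = cl$drugs,
      activation = activation, config = cfg)
}

#' Hand-checkable worked fixture cohort
#'
#' A tiny fixed cohort (20 genes x 12 samples: 8 tumors, 4 paired
#' normals) whose values follow a short closed-form rule so every
#' downstream operation can be checked against hand enumeration. The
#' 2-gene positive set is `{CASP1, GSDMD}` and the 2-gene negative set
#' `{EGFR, NEK7}` (retrieve both via [fixtureCatalog()]); tumor samples
#' carry a deterministic activation bump on the positive genes. The
#' mutation table holds 8 rows of which 6 are nonsynonymous, so TMB over
#' 38 Mb is directly checkable.
#'
#' @return A [SyntheticCohort-class] (cell-line slots empty).
#' @export
workedFixture <- function() {
  genes <- c("CASP1", "GSDMD", "EGFR", "NEK7", sprintf("F%02d", 1:16))
  tumors <- sprintf("T%02d", 1:8)
  normals <- sprintf("N%02d", 1:4)
  samples <- c(tumors, normals)
  # base value: ((7*gene + 3*sample) mod 19); tumors add gene-set bumps
  m <- outer(seq_along(genes) * 7, seq_along(samples) * 3, "+") %% 19
  dimnames(m) <- list(genes, samples)
  m <- m + 0.0
  act <- stats::setNames(c(seq(0.1, 0.8, by = 0.1), rep(0, 4)), samples)
  m[c("CASP1", "GSDMD"), tumors] <- m[c("CASP1", "GSDMD"), tumors] +
    matrix(10 * act[tumors], 2, 8, byrow = TRUE)
  m[c("EGFR", "NEK7"), tumors] <- m[c("EGFR", "NEK7"), tumors] -
    matrix(5 * act[tumors], 2, 8, byrow = TRUE)
  ann <- data.frame(
    sample = samples,
    patient_id = c(sprintf("P%02d", 1:8), sprintf("P%02d", 1:4)),
    cancer_type = rep("FIX", 12),
    tissue = c(rep("tumor", 8), rep("normal", 4)),
    os_time = c(100, 200, 300, 400, 500, 600, 700, 800, 100, 200, 300, 400),
    os_event = c(1, 1, 1, 0, 1, 0, 1, 0, 1, 1, 1, 0),
    stringsAsFactors = FALSE)
  mut <- data.frame(
    Tumor_Sample_Barcode = c("T01", "T01", "T02", "T03", "T03", "T03",
                             "T04", "T05"),
    Hugo_Symbol = c("CASP1", "GSDMD", "EGFR", "CASP1", "F01", "F02",
                    "NEK7", "GSDMD"),
    Variant_Classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Silent", "Missense_Mutation",
                               "Frame_Shift_Del", "Splice_Site",
                               "Silent", "Missense_Mutation"),
    stringsAsFactors = FALSE)
  cfg <- list(catalog = DirectionalCatalog(c("CASP1", "GSDMD"),
                                           c("EGFR", "NEK7")),
              seed = 0L, fixture = TRUE)
  new("SyntheticCohort", expression = m, annotations = ann,
      mutations = mut, scores = data.frame(sample = character()),
      cellLineExpression = matrix(numeric(), 0, 0),
      drugResponse = matrix(numeric(), 0, 0),
      activation = act, config = cfg)
}

#' Catalog attached to a fixture or simulated cohort
#'
#' @param cohort a [SyntheticCohort-class].
#' @return the `DirectionalCatalog` the cohort was built around (the
#'   packaged catalog for [simulateCohort()] cohorts).
#' @export
fixtureCatalog <- function(cohort) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!is.null(cohort@config$catalog)) cohort@config$catalog else prgCatalog()
}

#' Write a cohort's tables in the dialects the analysis reads
#'
#' Writes `expression.tsv`, `clinical.tsv`, `mutations.tsv`, `scores.tsv`,
#' `cellline_expression.tsv` and `drug_response.tsv` under `dir`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    scores = file.path(dir, "scores.tsv"),
    cellline_expression = file.path(dir, "cellline_expression.tsv"),
    drug_response = file.path(dir, "drug_response.tsv"))
  writeExpressionMatrix(cohort@expression, paths["expression"])
  .writeTsv(cohort@annotations, paths["clinical"])
  .writeTsv(cohort@mutations, paths["mutations"])
  .writeTsv(cohort@scores, paths["scores"])
  if (ncol(cohort@cellLineExpression)) {
    writeExpressionMatrix(cohort@cellLineExpression, paths["cellline_expression"])
    .writeTsv(data.frame(drug = rownames(cohort@drugResponse),
                         cohort@drugResponse, check.names = FALSE,
                         stringsAsFactors = FALSE),
              paths["drug_response"])
  }
  invisible(paths)
}
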