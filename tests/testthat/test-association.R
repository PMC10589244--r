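test_that("correlation handles monotone, reversed, constant and tiny inputs", {
  expect_equal(correlatePairs(c(1, 2, 3), c(2, 4, 6))$estimate, 1)
  expect_equal(correlatePairs(c(1, 2, 3), c(3, 2, 1))$estimate, -1)
  cst <- correlatePairs(c(1, 2, 3, 4), rep(2, 4))
  expect_true(is.na(cst$estimate))
  expect_equal(cst$note, "constant input")
  expect_error(correlatePairs(c(1, 2), c(3, 4)), ">= 3")
})

test_that("exact Spearman p-values match full permutation enumeration at n = 8", {
  set.seed(3)
  x <- sample(1:8); y <- sample(1:8)
  res <- correlatePairs(x, y, method = "spearman")
  expect_equal(res$p, enumSpearmanP(x, y), tolerance = 1e-10)
  set.seed(8)
  x2 <- rnorm(7); y2 <- rnorm(7)
  res2 <- correlatePairs(x2, y2)
  expect_equal(res2$p, enumSpearmanP(x2, y2), tolerance = 1e-10)
})

test_that("Spearman correlation is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(30); y <- x + rnorm(30)
  base <- correlatePairs(x, y)$estimate
  expect_equal(correlatePairs(exp(x), y)$estimate, base)
  expect_equal(correlatePairs(x, y^3 + 5 * y)$estimate, base)
})

test_that("association scan recovers planted immune couplings with correct signs", {
  set.seed(44)
  co <- simulateCohort(simulationConfig(n_samples = 200, seed = 44))
  ppi <- computePpi(expressionMatrix(co))
  sc <- annotationScores(co)
  res <- associationScan(ppi, sc)
  imm <- res[res$variable == "immune_score", ]
  pur <- res[res$variable == "tumor_purity", ]
  expect_gt(imm$estimate, 0); expect_lt(imm$p, 0.05)
  expect_lt(pur$estimate, 0); expect_lt(pur$p, 0.05)
  for (cell in c("Macrophages_M1", "T_cells_CD8", "T_cells_regulatory_Tregs")) {
    row <- res[res$variable == cell, ]
    expect_gt(row$estimate, 0)
    expect_lt(row$p, 0.05)
  }
  expect_true(all(c("q", "significant") %in% names(res)))
})

test_that("scan skips absent variables and logs them", {
  ppi <- data.frame(sample = paste0("s", 1:6), ppi = rnorm(6))
  scores <- data.frame(sample = paste0("s", 1:6), v1 = rnorm(6),
                       v2 = c(1, 2, NA, NA, NA, NA))
  res <- associationScan(ppi, scores)
  expect_true("v1" %in% res$variable)
  expect_false("v2" %in% res$variable)
  expect_match(attr(res, "skipped"), "v2")
})

test_that("checkpoint correlation flags unmeasured and constant genes and is order-invariant", {
  set.seed(50)
  m <- randomExpr(20, 15)
  rownames(m)[1:2] <- c("PDCD1", "CTLA4")
  m["CTLA4", ] <- 1  # constant
  ppi <- data.frame(sample = colnames(m), ppi = m["PDCD1", ] + rnorm(15, sd = 0.1))
  res <- checkpointCorrelation(ppi, m, genes = c("PDCD1", "CTLA4", "LAG3"))
  expect_gt(res$r[res$gene == "PDCD1"], 0.5)
  expect_equal(res$note[res$gene == "CTLA4"], "constant input")
  expect_equal(res$note[res$gene == "LAG3"], "unmeasured")
  # permuting sample order of both inputs identically leaves r unchanged
  perm <- sample(colnames(m))
  res2 <- checkpointCorrelation(ppi[match(perm, ppi$sample), ],
                                m[, perm], genes = "PDCD1")
  expect_equal(res2$r, res$r[res$gene == "PDCD1"])
})

test_that("subtype comparison recovers the planted ordering and excludes singletons", {
  set.seed(55)
  n <- 120
  subtype <- sample(c("C2", "C3", "C4"), n, replace = TRUE)
  mu <- c(C2 = 2, C3 = 1, C4 = 0)
  ppi <- data.frame(sample = sprintf("s%03d", 1:n),
                    ppi = mu[subtype] + rnorm(n, sd = 0.5))
  ann <- data.frame(sample = ppi$sample, cancer_type = "X", tissue = "tumor",
                    immune_subtype = subtype, stringsAsFactors = FALSE)
  # add a singleton subtype
  ann$immune_subtype[1] <- "C6"
  res <- subtypeCompare(ppi, ann)
  med <- res$medians
  expect_false("C6" %in% med$subtype)
  expect_match(attr(res, "skipped"), "C6")
  expect_gt(med$median[med$subtype == "C2"], med$median[med$subtype == "C3"])
  expect_gt(med$median[med$subtype == "C3"], med$median[med$subtype == "C4"])
  expect_lt(res$omnibus$p, 0.01)
  expect_true(nrow(res$pairwise) == 3)

  # literally identical value multisets per subtype -> H ~ 0, p ~ 1
  ann2 <- data.frame(sample = sprintf("q%02d", 1:30), cancer_type = "X",
                     tissue = "tumor",
                     immune_subtype = rep(c("C2", "C3", "C4"), each = 10),
                     stringsAsFactors = FALSE)
  ppi2 <- data.frame(sample = ann2$sample, ppi = rep(1:10, 3))
  res2 <- subtypeCompare(ppi2, ann2)
  expect_lt(res2$omnibus$H, 1e-8)
  expect_gt(res2$omnibus$p, 0.999)
})

test_that("TMB divides the nonsynonymous count by the exome size", {
  mut <- data.frame(
    Tumor_Sample_Barcode = rep("s1", 10),
    Hugo_Symbol = paste0("g", 1:10),
    Variant_Classification = c(rep("Missense_Mutation", 6), rep("Silent", 4)),
    stringsAsFactors = FALSE)
  tmb <- computeTmb(mut, exomeMb = 38)
  expect_equal(unname(tmb["s1"]), 6 / 38)  # silent rows excluded

  # worked value: 76 nonsynonymous rows over 38 Mb -> 2.0
  mut76 <- data.frame(Tumor_Sample_Barcode = "s1",
                      Hugo_Symbol = paste0("g", 1:76),
                      Variant_Classification = "Missense_Mutation")
  expect_equal(unname(computeTmb(mut76, exomeMb = 38)["s1"]), 2.0)

  # absent samples get zero
  tmb2 <- computeTmb(mut76, samples = c("s1", "s2"), exomeMb = 38)
  expect_equal(unname(tmb2["s2"]), 0)

  # unknown classification excluded with warning + QC count
  mutU <- rbind(mut76, data.frame(Tumor_Sample_Barcode = "s1",
                                  Hugo_Symbol = "gX",
                                  Variant_Classification = "Bogus_Class"))
  expect_warning(tmbU <- computeTmb(mutU, exomeMb = 38), "unknown")
  expect_equal(unname(tmbU["s1"]), 2.0)
  expect_equal(attr(tmbU, "qc")$n_unknown_class, 1)
  expect_error(computeTmb(mut76, exomeMb = 0), "> 0")
})

test_that("TMB is additive over disjoint splits of the mutation table", {
  set.seed(60)
  mut <- data.frame(
    Tumor_Sample_Barcode = sample(paste0("s", 1:5), 80, replace = TRUE),
    Hugo_Symbol = sample(paste0("g", 1:30), 80, replace = TRUE),
    Variant_Classification = sample(c(tmbVocabulary(), "Silent"), 80, TRUE),
    stringsAsFactors = FALSE)
  samples <- paste0("s", 1:5)
  whole <- computeTmb(mut, samples = samples)
  half <- seq_len(40)
  split <- computeTmb(mut[half, ], samples = samples) +
    computeTmb(mut[-half, ], samples = samples)
  expect_equal(as.numeric(whole), as.numeric(split))
})

test_that("mutation frequency counts samples once regardless of row multiplicity", {
  mut <- data.frame(
    Tumor_Sample_Barcode = c("s1", "s1", "s1", "s2", "s3"),
    Hugo_Symbol = c("TP53", "TP53", "TP53", "TP53", "EGFR"),
    Variant_Classification = "Missense_Mutation", stringsAsFactors = FALSE)
  res <- mutationFrequency(mut, samples = paste0("s", 1:4),
                           genes = c("TP53", "EGFR", "KRAS"))
  expect_equal(res$frequency[res$gene == "TP53"], 0.5)   # 2 of 4
  expect_equal(res$frequency[res$gene == "EGFR"], 0.25)
  expect_equal(res$frequency[res$gene == "KRAS"], 0)     # absent gene
})

test_that("tumor/normal log2 expression ratio back-transforms log input", {
  # linear scale: tumor mean 8, normal mean 2 -> 2.0
  m <- matrix(c(8, 8, 2, 2, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  ann <- data.frame(sample = paste0("s", 1:4), cancer_type = "X",
                    tissue = c("tumor", "tumor", "normal", "normal"),
                    stringsAsFactors = FALSE)
  res <- diffExpressionLog2Ratio(m, ann, genes = c("gA", "gB"),
                                 linearScale = TRUE)
  expect_equal(res$log2_ratio[res$gene == "gA"], 2.0)
  expect_equal(res$log2_ratio[res$gene == "gB"], 0.0)

  # log2(x+1) input: values log2(c(8,2)+1) back-transform to 8 and 2
  mlog <- m
  mlog["gA", ] <- log2(c(8, 8, 2, 2) + 1)
  res2 <- diffExpressionLog2Ratio(mlog, ann, genes = "gA")
  expect_equal(res2$log2_ratio, 2.0, tolerance = 1e-12)

  # zero normal mean flagged with pseudocount
  m0 <- m; m0["gA", 3:4] <- 0
  res3 <- diffExpressionLog2Ratio(m0, ann, genes = "gA", linearScale = TRUE)
  expect_equal(res3$flag, "zero normal mean")
  expect_gt(res3$log2_ratio, 30)
})
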