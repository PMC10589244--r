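.annFrom <- function(samples, type, tissue, patient = samples) {
  data.frame(sample = samples, cancer_type = type, tissue = tissue,
             patient_id = patient, stringsAsFactors = FALSE)
}

test_that("unpaired tumor/normal comparison reproduces exact rank-sum p-values", {
  ppi <- data.frame(sample = paste0("s", 1:6),
                    ppi = c(4, 5, 6, 1, 2, 3), stringsAsFactors = FALSE)
  ann <- .annFrom(paste0("s", 1:6), "X",
                  c("tumor", "tumor", "tumor", "normal", "normal", "normal"))
  res <- diffPpiUnpaired(ppi, ann, "X")
  expect_equal(res$p, 0.1)  # 2/20 splits as or more extreme
  expect_equal(res$p, enumRankSumP(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(res$median_tumor, 5)

  # identical multisets -> p = 1
  ppi2 <- data.frame(sample = paste0("s", 1:6), ppi = c(1, 2, 3, 1, 2, 3))
  expect_equal(diffPpiUnpaired(ppi2, ann, "X")$p, 1)

  # single vs single: no resolution
  ann3 <- .annFrom(c("a", "b"), "X", c("tumor", "normal"))
  ppi3 <- data.frame(sample = c("a", "b"), ppi = c(2, 1))
  expect_equal(diffPpiUnpaired(ppi3, ann3, "X")$p, 1)

  # empty group -> skipped with reason
  ann4 <- .annFrom(c("a", "b"), "X", c("tumor", "tumor"))
  out <- diffPpiUnpaired(ppi3, ann4, "X")
  expect_true(isSkipped(out))
  expect_match(attr(out, "reason"), "empty")
})

test_that("paired comparison drops zero differences and matches sign enumeration", {
  samples <- c(paste0("t", 1:3), paste0("n", 1:3))
  ann <- .annFrom(samples, "X", rep(c("tumor", "normal"), each = 3),
                  patient = rep(paste0("p", 1:3), 2))
  ppi <- data.frame(sample = samples, ppi = c(2, 3, 4, 1, 1, 1))
  res <- diffPpiPaired(ppi, ann, "X")
  expect_equal(res$p, 0.25)  # differences {+1,+2,+3}: 2/8 sign patterns
  expect_equal(res$p, enumSignedRankP(c(1, 2, 3)))

  # all-zero differences -> skipped
  ppi0 <- data.frame(sample = samples, ppi = rep(1, 6))
  out <- diffPpiPaired(ppi0, ann, "X")
  expect_true(isSkipped(out))
  expect_match(attr(out, "reason"), "zero")

  # {+1, -1} -> two-sided p = 1
  ann2 <- .annFrom(c("t1", "t2", "n1", "n2"), "X",
                   c("tumor", "tumor", "normal", "normal"),
                   patient = c("p1", "p2", "p1", "p2"))
  ppi2 <- data.frame(sample = c("t1", "t2", "n1", "n2"), ppi = c(2, 0, 1, 1))
  expect_equal(diffPpiPaired(ppi2, ann2, "X")$p, 1)
})

test_that("exact Wilcoxon p-values match full enumeration for combined n <= 12", {
  set.seed(5)
  for (i in 1:12) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(seq_len(40), nx); y <- sample(setdiff(seq_len(40), x), ny)
    ann <- .annFrom(paste0("s", seq_len(nx + ny)), "X",
                    rep(c("tumor", "normal"), c(nx, ny)))
    ppi <- data.frame(sample = ann$sample, ppi = c(x, y))
    expect_equal(diffPpiUnpaired(ppi, ann, "X")$p, enumRankSumP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("median split sends at-threshold samples to the low group", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  g <- splitGroups(x, rule = "median")
  expect_setequal(g$sample[g$group == "low"], c("a", "b"))
  expect_setequal(g$sample[g$group == "high"], c("c", "d"))
  expect_equal(unique(g$threshold_value), 2.5)

  # tie-at-threshold: {1,1,1,5} leaves a 1-sample high group -> skipped
  y <- c(a = 1, b = 1, c = 1, d = 5)
  g2 <- splitGroups(y, rule = "median")
  expect_equal(nrow(g2), 0)
  expect_match(attr(g2, "skipped"), "fewer than 2")

  # top/bottom 30% of n = 10: 3 + 3 kept, 4 discarded
  z <- setNames(1:10, letters[1:10])
  g3 <- splitGroups(z, rule = "top_bottom_30")
  expect_equal(sum(g3$group == "high"), 3)
  expect_equal(sum(g3$group == "low"), 3)
  expect_equal(nrow(g3), 6)
  expect_setequal(g3$sample[g3$group == "high"], c("h", "i", "j"))
})

test_that("log-rank test matches the hypergeometric tally oracle", {
  # identical data in both groups
  t0 <- c(1, 2, 3, 1, 2, 3); e0 <- c(1, 1, 0, 1, 1, 0)
  g0 <- rep(c("A", "B"), each = 3)
  r0 <- logrankTest(t0, e0, g0)
  expect_equal(r0$chi2, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  # A events early, B censored late
  t1 <- c(1, 2, 3, 3); e1 <- c(1, 1, 0, 0); g1 <- c("A", "A", "B", "B")
  r1 <- logrankTest(t1, e1, g1)
  expect_equal(r1$chi2, oracleLogrank(t1, e1, g1), tolerance = 1e-9)

  # random fixture vs oracle, with ties
  set.seed(9)
  t2 <- sample(1:8, 20, replace = TRUE); e2 <- rbinom(20, 1, 0.7)
  g2 <- sample(c("A", "B"), 20, replace = TRUE)
  r2 <- logrankTest(t2, e2, g2)
  expect_equal(r2$chi2, oracleLogrank(t2, e2, g2), tolerance = 1e-9)
  # invariant to group relabeling
  expect_equal(logrankTest(t2, e2, ifelse(g2 == "A", "B", "A"))$chi2, r2$chi2)
  # moving a censoring time that already lies beyond the last event
  # changes nothing: all risk sets at event times are unaffected
  t4 <- c(1, 2, 5, 7); e4 <- c(1, 1, 0, 0); g4 <- c("A", "B", "A", "B")
  base <- logrankTest(t4, e4, g4)
  moved <- logrankTest(c(1, 2, 5, 1000), e4, g4)
  expect_equal(moved$chi2, base$chi2, tolerance = 1e-12)

  # all censored -> sentinel
  r4 <- logrankTest(c(1, 2, 3, 4), c(0, 0, 0, 0), c("A", "A", "B", "B"))
  expect_true(is.na(r4$chi2))
  expect_equal(r4$note, "no_events")
})

test_that("Cox estimate matches a partial-likelihood grid search and inverts under negation", {
  expect_error(coxUnivariate(1:6, rep(1, 6), rep(2, 6)), "constant")

  t0 <- c(3, 5, 7, 2, 11, 9); e0 <- c(1, 1, 0, 1, 1, 1)
  x0 <- c(1, 1, 1, 0, 0, 0)
  fit <- coxUnivariate(t0, e0, x0)
  expect_equal(fit$beta, oracleCoxGrid(t0, e0, x0), tolerance = 1e-3)
  # first-order condition: numeric score at beta-hat is ~0
  h <- 1e-5
  score <- (breslowLogLik(fit$beta + h, t0, e0, x0) -
              breslowLogLik(fit$beta - h, t0, e0, x0)) / (2 * h)
  expect_lt(abs(score), 1e-6)
  # negating the covariate inverts the hazard ratio
  fitNeg <- coxUnivariate(t0, e0, -x0)
  expect_equal(fitNeg$hr, 1 / fit$hr, tolerance = 1e-8)
})

test_that("Cox recovers a planted continuous effect", {
  set.seed(21)
  n <- 300
  a <- runif(n)
  tt <- rexp(n, rate = 0.001 * exp(0.8 * a))
  cc <- rexp(n, rate = 0.0005)
  fit <- coxUnivariate(pmin(tt, cc), as.integer(tt <= cc), a)
  expect_true(fit$converged)
  expect_equal(fit$beta, 0.8, tolerance = 0.35)
})

test_that("survival scan flags an activation-linked hazard as adverse", {
  set.seed(31)
  n <- 300
  a <- runif(n)
  score <- setNames(a + rnorm(n, sd = 0.1), sprintf("s%03d", 1:n))
  tt <- rexp(n, rate = 0.001 * exp(1.2 * a))
  cc <- rexp(n, rate = 0.0004)
  ann <- data.frame(sample = names(score), cancer_type = "CT1",
                    tissue = "tumor",
                    os_time = round(pmin(tt, cc), 1),
                    os_event = as.integer(tt <= cc),
                    stringsAsFactors = FALSE)
  sc <- survivalScan(score, ann, endpoints = "os")
  expect_equal(nrow(sc), 1)
  expect_gt(sc$hr_continuous, 1)
  expect_equal(sc$direction, "adverse")
  expect_lt(sc$cox_p_adj, 0.05)
  expect_lt(sc$logrank_p, 0.05)
})

test_that("survival scan logs strata without events instead of failing", {
  score <- setNames(1:8, paste0("s", 1:8))
  ann <- data.frame(sample = names(score), cancer_type = rep(c("A", "B"), each = 4),
                    tissue = "tumor",
                    os_time = rep(10, 8),
                    os_event = c(1, 1, 0, 1, 0, 0, 0, 0),
                    stringsAsFactors = FALSE)
  sc <- survivalScan(score, ann, endpoints = "os")
  expect_false("B" %in% sc$stratum)
  expect_true(any(grepl("^B/os", attr(sc, "skipped"))))
})

test_that("clinical association tests reduce to the expected statistics", {
  # identical index across sexes -> rank-sum p = 1
  ppi <- data.frame(sample = paste0("s", 1:8), ppi = rep(c(1, 2, 3, 4), 2))
  ann <- .annFrom(paste0("s", 1:8), "X", "tumor")
  ann$sex <- rep(c("m", "f"), each = 4)
  res <- clinicalAssociation(ppi, ann, "sex")
  expect_equal(res$test, "wilcoxon")
  expect_equal(res$p, 1)

  # 2x2 chi-square without continuity correction: [[10,0],[0,10]] -> 20
  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(unname(stats::chisq.test(tab, correct = FALSE)$statistic), 20)
  n <- sum(tab)
  direct <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
  expect_equal(direct, 20)

  # >2 levels uses Kruskal-Wallis and its p is uniform under the null
  set.seed(41)
  pvals <- replicate(300, {
    ppiN <- data.frame(sample = paste0("s", 1:18), ppi = rnorm(18))
    annN <- .annFrom(paste0("s", 1:18), "X", "tumor")
    annN$grade <- rep(c("G1", "G2", "G3"), each = 6)
    clinicalAssociation(ppiN, annN, "grade")$p
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})
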