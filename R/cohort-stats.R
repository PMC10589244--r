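# Differential-index and survival statistics across cancer-type strata.
# Standard tests are delegated to stats:: and survival::; this module owns
# the cohort bookkeeping: stratum selection, tumor/normal pairing, group
# splitting rules, skip logging, and BH adjustment across strata.

.ppiDF <- function(ppi) {
  df <- as.data.frame(ppi)
  if (!all(c("sample", "ppi") %in% names(df)))
    stop("expected a PpiTable or data.frame with columns sample, ppi")
  df
}

.endpointCols <- function(endpoint) {
  list(time = paste0(endpoint, "_time"), event = paste0(endpoint, "_event"))
}

# Shift zero survival times to half a day and reject negatives; zero times
# would make a subject leave the risk set at entry.
.cleanTimes <- function(time) {
  if (any(time < 0, na.rm = TRUE)) stop("negative survival times")
  ifelse(time == 0, 0.5, time)
}

# sentinel for a stratum skipped with a logged reason
.skip <- function(reason) structure(list(), reason = reason, class = "ppiSkipped")

#' Was a per-stratum test skipped?
#'
#' Differential tests return a skip sentinel (with the reason in
#' `attr(, "reason")`) instead of a result when a stratum cannot be
#' tested.
#'
#' @param x a result from [diffPpiUnpaired()] or [diffPpiPaired()].
#' @return `TRUE` if `x` is a skip sentinel.
#' @export
isSkipped <- function(x) inherits(x, "ppiSkipped")

#' Tumor-versus-normal index comparison within one stratum
#'
#' Two-sided Wilcoxon rank-sum test of the index between tumor and normal
#' samples of one cancer type. The exact null distribution is used when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with continuity correction.
#'
#' @param ppi [PpiTable-class] or data.frame with `sample`, `ppi`.
#' @param ann per-sample annotations with `sample`, `cancer_type`, `tissue`.
#' @param stratum cancer type to test.
#' @return list with `statistic` (W), `p`, `median_tumor`, `median_normal`,
#'   `n_tumor`, `n_normal`; or a skip sentinel (see [isSkipped()], reason
#'   in `attr(, "reason")`) if a group is empty.
#' @export
diffPpiUnpaired <- function(ppi, ann, stratum) {
  df <- merge(.ppiDF(ppi), ann, by = "sample")
  df <- df[df$cancer_type == stratum, ]
  x <- df$ppi[df$tissue == "tumor"]
  y <- df$ppi[df$tissue == "normal"]
  if (length(x) == 0L || length(y) == 0L)
    return(.skip(sprintf("stratum %s: empty tumor or normal group", stratum)))
  exact <- (length(x) + length(y)) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_tumor = stats::median(x), median_normal = stats::median(y),
       n_tumor = length(x), n_normal = length(y))
}

#' Paired tumor-versus-normal index comparison within one stratum
#'
#' Wilcoxon signed-rank test on within-patient tumor-minus-normal index
#' differences. Zero differences are dropped before testing (the classic
#' signed-rank convention). Patients without both tissues are ignored.
#'
#' @inheritParams diffPpiUnpaired
#' @return list with `statistic` (V), `p`, `n_pairs` (non-zero pairs), and
#'   `n_dropped_zero`; or a skip sentinel (see [isSkipped()]) when no
#'   complete pairs (or only zero differences) exist.
#' @export
diffPpiPaired <- function(ppi, ann, stratum) {
  df <- merge(.ppiDF(ppi), ann, by = "sample")
  df <- df[df$cancer_type == stratum & !is.na(df$patient_id), ]
  tum <- df[df$tissue == "tumor", c("patient_id", "ppi")]
  nor <- df[df$tissue == "normal", c("patient_id", "ppi")]
  pairs <- merge(tum, nor, by = "patient_id", suffixes = c("_t", "_n"))
  if (nrow(pairs) == 0L)
    return(.skip(sprintf("stratum %s: no complete tumor/normal pairs", stratum)))
  d <- pairs$ppi_t - pairs$ppi_n
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(.skip(sprintf("stratum %s: all paired differences zero", stratum)))
  exact <- length(nz) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_pairs = length(nz), n_dropped_zero = sum(d == 0))
}

#' Split samples into high/low index groups
#'
#' Within each stratum: under the `median` rule, samples strictly above the
#' within-stratum median are `high`, samples at or below it are `low` (so a
#' sample exactly at the median goes to `low`); the `mean` rule is
#' analogous. The `top_bottom_30` rule keeps only the top 30% and bottom
#' 30% of samples by index value (`ceiling(0.3 * n)` each, ordered by value
#' then sample id for determinism) and discards the middle.
#'
#' Strata with fewer than 4 samples, or where a resulting group has fewer
#' than 2 members, are skipped and logged.
#'
#' @param ppi [PpiTable-class], data.frame with `sample`/`ppi`, or a named
#'   numeric vector of scores.
#' @param strata optional named character vector mapping sample -> stratum;
#'   `NULL` treats all samples as one stratum `"all"`.
#' @param rule one of `"median"`, `"mean"`, `"top_bottom_30"`.
#' @return data.frame with `sample`, `stratum`, `group`, `threshold_value`,
#'   `rule`; skipped strata are listed in `attr(, "skipped")`.
#' @export
splitGroups <- function(ppi, strata = NULL, rule = c("median", "mean", "top_bottom_30")) {
  rule <- match.arg(rule)
  if (is.numeric(ppi) && !is.null(names(ppi))) {
    scores <- ppi
  } else {
    df <- .ppiDF(ppi)
    scores <- stats::setNames(df$ppi, df$sample)
  }
  if (is.null(strata)) strata <- stats::setNames(rep("all", length(scores)), names(scores))
  strata <- strata[names(scores)]
  out <- list()
  skipped <- character()
  for (st in sort(unique(strata))) {
    x <- scores[!is.na(strata) & strata == st]
    if (length(x) < 4L) {
      skipped <- c(skipped, sprintf("%s: fewer than 4 samples", st))
      next
    }
    if (rule == "top_bottom_30") {
      k <- ceiling(0.3 * length(x))
      ord <- order(x, names(x))
      ids <- names(x)[ord]
      grp <- stats::setNames(rep(NA_character_, length(x)), ids)
      grp[ids[seq_len(k)]] <- "low"
      grp[ids[seq(length(x) - k + 1L, length(x))]] <- "high"
      grp <- grp[!is.na(grp)]
      thr <- NA_real_
      assigned <- data.frame(sample = names(grp), stratum = st, group = unname(grp),
                             threshold_value = thr, rule = rule,
                             stringsAsFactors = FALSE)
    } else {
      thr <- if (rule == "median") stats::median(x) else mean(x)
      grp <- ifelse(x > thr, "high", "low")
      assigned <- data.frame(sample = names(x), stratum = st, group = unname(grp),
                             threshold_value = thr, rule = rule,
                             stringsAsFactors = FALSE)
    }
    if (sum(assigned$group == "high") < 2L || sum(assigned$group == "low") < 2L) {
      skipped <- c(skipped, sprintf("%s: a group has fewer than 2 samples", st))
      next
    }
    out[[st]] <- assigned
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame(sample = character(), stratum = character(),
                  group = character(), threshold_value = numeric(),
                  rule = character(), stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  res
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square with 1 degree of freedom
#' (deaths at tied times pooled), via `survival::survdiff`. When no events
#' occur at all the test is undefined and a no-event sentinel is returned.
#'
#' @param time non-negative follow-up times (zeros shifted to 0.5).
#' @param event 0/1 event indicators.
#' @param group two-level grouping factor/character.
#' @return list with `chi2`, `p`, `n`, `n_events`; `chi2`/`p` are `NA` with
#'   `note = "no_events"` when no events occurred.
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(event %in% c(0, 1)))
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("logrankTest needs exactly 2 groups")
  if (any(table(group) == 0L)) stop("each group needs >= 1 subject")
  time <- .cleanTimes(time)
  if (sum(event) == 0)
    return(list(chi2 = NA_real_, p = NA_real_, n = length(time),
                n_events = 0L, note = "no_events"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n = length(time), n_events = as.integer(sum(event)))
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood with Breslow tie handling
#' (`survival::coxph`). Requires >= 2 events and a non-constant covariate.
#' Monotone-likelihood (perfect separation) or non-convergence is flagged:
#' the result carries `converged = FALSE` and no usable estimate.
#'
#' @param time non-negative follow-up times (zeros shifted to 0.5).
#' @param event 0/1 event indicators.
#' @param covariate continuous score or 0/1 group indicator.
#' @return list with `beta`, `se`, `hr`, `hr_lower`, `hr_upper` (Wald 95%
#'   CI), `p` (Wald), `n`, `n_events`, `converged`.
#' @export
coxUnivariate <- function(time, event, covariate) {
  stopifnot(length(time) == length(event), length(time) == length(covariate),
            all(event %in% c(0, 1)))
  if (sum(event) < 2) stop("coxUnivariate needs >= 2 events")
  if (length(unique(covariate)) < 2L) stop("covariate is constant")
  time <- .cleanTimes(time)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ covariate, ties = "breslow",
      control = survival::coxph.control(iter.max = 100))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(beta = NA_real_, se = NA_real_, hr = NA_real_,
                hr_lower = NA_real_, hr_upper = NA_real_, p = NA_real_,
                n = length(time), n_events = as.integer(sum(event)),
                converged = FALSE))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  converged <- is.finite(beta) && is.finite(se) && abs(beta) < 15 && se < 50
  if (!converged) {
    beta <- NA_real_; se <- NA_real_
  }
  z <- beta / se
  list(beta = beta, se = se, hr = exp(beta),
       hr_lower = exp(beta - 1.96 * se), hr_upper = exp(beta + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)),
       n = length(time), n_events = as.integer(sum(event)),
       converged = converged)
}

#' Survival scan across cancer types and endpoints
#'
#' For every cancer type x endpoint on tumor samples: splits the cohort
#' into high/low groups ([splitGroups()]), runs the log-rank test between
#' them, and fits univariate Cox models on both the continuous score and
#' the high/low indicator. Hazard ratios above 1 mean a higher score is
#' adverse, below 1 favorable. Raw p-values are reported alongside
#' Benjamini-Hochberg-adjusted values (adjusted across strata within each
#' endpoint and test family).
#'
#' @param score named numeric per-sample values (e.g. `ppiScores(ppi)` or
#'   one gene's expression).
#' @param ann annotations with `sample`, `cancer_type`, `tissue`, and
#'   `<endpoint>_time` / `<endpoint>_event` columns.
#' @param endpoints endpoints to scan (default `os`, `dss`, `dfs`, `pfs`;
#'   only those whose columns exist are used).
#' @param rule group-splitting rule (see [splitGroups()]).
#' @return data.frame, one row per stratum x endpoint, with log-rank and
#'   Cox results, direction label, and BH-adjusted p-values; per-stratum
#'   skip reasons in `attr(, "skipped")`.
#' @export
survivalScan <- function(score, ann, endpoints = c("os", "dss", "dfs", "pfs"),
                         rule = "median") {
  stopifnot(is.numeric(score), !is.null(names(score)))
  ann <- ann[ann$tissue == "tumor" & ann$sample %in% names(score), ]
  endpoints <- endpoints[vapply(endpoints, function(e) {
    all(unlist(.endpointCols(e)) %in% names(ann))
  }, logical(1))]
  rows <- list()
  skipped <- character()
  for (st in sort(unique(ann$cancer_type))) {
    sub <- ann[ann$cancer_type == st, ]
    x <- score[sub$sample]
    grp <- splitGroups(x, rule = rule)
    if (nrow(grp) == 0L) {
      skipped <- c(skipped, sprintf("%s: %s", st,
                                    paste(attr(grp, "skipped"), collapse = "; ")))
      next
    }
    for (ep in endpoints) {
      cols <- .endpointCols(ep)
      t0 <- sub[[cols$time]]
      e0 <- sub[[cols$event]]
      ok <- !is.na(t0) & !is.na(e0)
      if (sum(e0[ok]) < 2) {
        skipped <- c(skipped, sprintf("%s/%s: fewer than 2 events", st, ep))
        next
      }
      gmap <- stats::setNames(grp$group, grp$sample)
      gsub <- gmap[sub$sample]
      okg <- ok & !is.na(gsub)
      lr <- if (length(unique(gsub[okg])) == 2L)
        logrankTest(t0[okg], e0[okg], gsub[okg]) else
          list(chi2 = NA_real_, p = NA_real_, n = sum(okg), n_events = NA_integer_)
      cx <- tryCatch(coxUnivariate(t0[ok], e0[ok], x[sub$sample][ok]),
                     error = function(e) NULL)
      cg <- tryCatch(coxUnivariate(t0[okg], e0[okg],
                                   as.numeric(gsub[okg] == "high")),
                     error = function(e) NULL)
      if (is.null(cx)) {
        skipped <- c(skipped, sprintf("%s/%s: Cox precondition failed", st, ep))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, endpoint = toupper(ep), rule = rule,
        n = cx$n, n_events = cx$n_events,
        logrank_chi2 = lr$chi2, logrank_p = lr$p,
        hr_continuous = cx$hr, hr_lower = cx$hr_lower, hr_upper = cx$hr_upper,
        cox_p = cx$p,
        hr_group = if (is.null(cg)) NA_real_ else cg$hr,
        cox_group_p = if (is.null(cg)) NA_real_ else cg$p,
        direction = ifelse(is.na(cx$hr), NA_character_,
                           ifelse(cx$hr > 1, "adverse", "favorable")),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame()
  if (nrow(res)) {
    res$logrank_p_adj <- NA_real_
    res$cox_p_adj <- NA_real_
    for (ep in unique(res$endpoint)) {
      i <- res$endpoint == ep
      res$logrank_p_adj[i] <- .bh(res$logrank_p[i])
      res$cox_p_adj[i] <- .bh(res$cox_p[i])
    }
    res$significant <- !is.na(res$logrank_p) & res$logrank_p < 0.05
  }
  attr(res, "skipped") <- skipped
  res
}

#' Association between the index and a categorical clinical variable
#'
#' Per stratum: a Wilcoxon rank-sum test on the index when the variable has
#' two non-missing levels, Kruskal-Wallis when more; plus a chi-square test
#' (no continuity correction) of the high/low median-split group against
#' the category. Missing category values are dropped; the chi-square test
#' is skipped when the contingency table has an empty row or column.
#'
#' @param ppi [PpiTable-class] or data.frame with `sample`, `ppi`.
#' @param ann annotations with `sample`, `cancer_type` and the variable.
#' @param variable name of the categorical column in `ann`.
#' @param strata cancer types to test; default all present.
#' @return data.frame with one row per stratum: test used, statistic, `p`,
#'   chi-square statistic and p (or NA), level count, n; skip reasons in
#'   `attr(, "skipped")`.
#' @export
clinicalAssociation <- function(ppi, ann, variable, strata = NULL) {
  df <- merge(.ppiDF(ppi), ann, by = "sample")
  if (!variable %in% names(df)) stop("unknown variable: ", variable)
  if (is.null(strata)) strata <- sort(unique(df$cancer_type))
  rows <- list()
  skipped <- character()
  for (st in strata) {
    sub <- df[df$cancer_type == st & !is.na(df[[variable]]), ]
    v <- as.factor(as.character(sub[[variable]]))
    v <- droplevels(v)
    if (nlevels(v) < 2L) {
      skipped <- c(skipped, sprintf("%s: fewer than 2 levels of %s", st, variable))
      next
    }
    if (nlevels(v) == 2L) {
      tst <- suppressWarnings(stats::wilcox.test(sub$ppi ~ v))
      test <- "wilcoxon"; statv <- unname(tst$statistic)
    } else {
      tst <- stats::kruskal.test(sub$ppi ~ v)
      test <- "kruskal"; statv <- unname(tst$statistic)
    }
    grp <- splitGroups(stats::setNames(sub$ppi, sub$sample))
    chi <- chi_p <- NA_real_
    if (nrow(grp)) {
      tab <- table(stats::setNames(grp$group, grp$sample)[sub$sample], v)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        chi <- unname(ct$statistic); chi_p <- ct$p.value
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = st, variable = variable, test = test,
      statistic = statv, p = tst$p.value,
      chi2 = chi, chi2_p = chi_p,
      n_levels = nlevels(v), n = nrow(sub), stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame()
  attr(res, "skipped") <- skipped
  res
}
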