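# Independent brute-force oracles. Each one walks the definition literally
# (step-by-step loops, full enumeration, grid search) and shares no code
# with the package implementations it checks.

# ssGSEA: literal position-by-position accumulation of P_in - P_out.
oracleSsgsea <- function(ranks, members, alpha) {
  ord <- order(-ranks, names(ranks))
  genes <- names(ranks)[ord]
  rsorted <- ranks[ord]
  N <- length(genes)
  k <- sum(genes %in% members)
  denomIn <- sum(rsorted[genes %in% members]^alpha)
  es <- 0
  win <- 0
  nout <- 0
  for (i in seq_len(N)) {
    if (genes[i] %in% members) win <- win + rsorted[i]^alpha else nout <- nout + 1
    es <- es + win / denomIn - nout / (N - k)
  }
  unname(es)
}

# classic GSEA: literal running sum, extremum signed, ties toward positive.
oracleGsea <- function(metric, members, p) {
  genes <- names(metric)
  N <- length(genes)
  hits <- genes %in% members
  wa <- abs(metric)^p
  denom <- sum(wa[hits])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      run <- run + (if (denom == 0) 1 / sum(hits) else wa[i] / denom)
    } else {
      run <- run - 1 / (N - sum(hits))
    }
    if (abs(run) > abs(best) || (abs(run) == abs(best) && run > best)) best <- run
  }
  unname(best)
}

# two-group log-rank: 2x2 hypergeometric tally at each distinct event time.
oracleLogrank <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  obs <- 0; exp <- 0; varsum <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    obs <- obs + d1
    exp <- exp + d * n1 / n
    if (n > 1) varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (obs - exp)^2 / varsum
}

# Breslow partial log-likelihood and its maximizer on a 1-D grid.
breslowLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracleCoxGrid <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, breslowLogLik, numeric(1), time = time, event = event, x = x)
  grid[which.max(ll)]
}

# exact two-sided rank-sum p by enumeration of all group assignments.
enumRankSumP <- function(x, y) {
  pool <- c(x, y)
  r <- rank(pool)
  nx <- length(x)
  idx <- utils::combn(length(pool), nx)
  stats <- apply(idx, 2, function(i) sum(r[i]))
  obs <- sum(r[seq_len(nx)])
  mu <- nx * (length(pool) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# exact two-sided signed-rank p by enumeration of all sign assignments.
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- signs %*% r
  mu <- sum(r) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# exact two-sided Spearman p by enumeration of all rank permutations
# (distinct values only; feasible to n = 8).
enumSpearmanP <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  P <- perms(seq_len(n))
  rx <- rank(x)
  obs <- stats::cor(rx, rank(y))
  rhos <- apply(P, 1, function(p) stats::cor(rx, p))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# random small expression matrix with unique sample/gene names.
randomExpr <- function(nGenes, nSamples, ties = FALSE) {
  v <- if (ties) sample(1:5, nGenes * nSamples, replace = TRUE)
  else stats::rnorm(nGenes * nSamples)
  matrix(v, nGenes, nSamples,
         dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                         sprintf("s%02d", seq_len(nSamples))))
}
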