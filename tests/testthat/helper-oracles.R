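# Brute-force enumeration oracles, independent of the implementations they
# check. All assume small inputs.

# Exact signed-rank null: enumerate all 2^m sign assignments of the ranked
# absolute differences; one-tailed p is the fraction of assignments with a
# positive-rank sum at least (greater) / at most (less) as extreme.
enumSignedRank <- function(d, alternative = "greater") {
  d <- d[d != 0]
  m <- length(d)
  stopifnot(m >= 1, m <= 12, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v <- as.vector(signs %*% r)
  switch(alternative,
         greater = mean(v >= vObs),
         less = mean(v <= vObs),
         two.sided = min(1, 2 * min(mean(v >= vObs), mean(v <= vObs))))
}

# Exact rank-sum null: enumerate all ways the x-sample can occupy positions
# among the pooled ranks.
enumRankSum <- function(x, y, alternative = "less") {
  nx <- length(x); ny <- length(y)
  stopifnot(nx + ny <= 12, !anyDuplicated(c(x, y)))
  pooled <- rank(c(x, y))
  wObs <- sum(pooled[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  allRanks <- rank(c(x, y))  # pooled ranks 1..nx+ny (no ties)
  w <- apply(idx, 2L, function(ii) sum(sort(allRanks)[ii])) -
    nx * (nx + 1) / 2
  switch(alternative,
         less = mean(w <= wObs),
         greater = mean(w >= wObs),
         two.sided = min(1, 2 * min(mean(w <= wObs), mean(w >= wObs))))
}

# Exact binomial two-sided p by the minimum-likelihood rule.
enumBinomTwoSided <- function(k, n, p0 = 0.5) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Fisher two-sided p by hypergeometric enumeration (minimum-likelihood rule).
enumFisherTwoSided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

fixtureCohort <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- table1Fixture()
    cached
  }
})
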