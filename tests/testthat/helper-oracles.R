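# Independent brute-force oracles, kept deliberately naive (explicit loops,
# textbook definitions) so they share no code path with the implementation.

# Median-of-ratios size factors by explicit loops.
bruteSizeFactors <- function(m) {
  eligible <- c()
  for (g in seq_len(nrow(m))) {
    if (all(m[g, ] > 0)) eligible <- c(eligible, g)
  }
  sf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(0)
    for (g in eligible) {
      geo <- prod(m[g, ])^(1 / ncol(m))
      ratios <- c(ratios, m[g, j] / geo)
    }
    sf[j] <- median(ratios)
  }
  sf
}

# Step-up BH from the definition: adj_(i) = min_{j >= i} m * p_(j) / j.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, min(1, m * sorted[j] / j))
    adj[i] <- min(vals)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins; tables at most as probable as the observed one
# (with the conventional 1e-7 relative tie guard) are summed.
bruteFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, r1, r2, c1)
  pObs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Running-sum enrichment score by an explicit walk down the list.
bruteES <- function(scores, isHit, p = 1) {
  N <- length(scores)
  k <- sum(isHit)
  wsum <- 0
  for (i in seq_len(N)) if (isHit[i]) wsum <- wsum + abs(scores[i])^p
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (isHit[i]) {
      cur <- cur + abs(scores[i])^p / wsum
    } else {
      cur <- cur - 1 / (N - k)
    }
    running[i] <- cur
  }
  mx <- max(running)
  mn <- min(c(running, 0))
  if (mx >= -mn) mx else mn
}

# Group-by mean of correlations by explicit loops.
bruteMeanByType <- function(r, types) {
  out <- list()
  for (ty in unique(types)) {
    for (cl in colnames(r)) {
      vals <- c()
      for (i in seq_len(nrow(r))) {
        if (types[i] == ty) vals <- c(vals, r[i, cl])
      }
      out[[paste(ty, cl)]] <- mean(vals, na.rm = TRUE)
    }
  }
  out
}

# Small random count matrix for I/O and normalization tests.
randomCounts <- function(nGenes = 50, nSamples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(nGenes * nSamples, mu = 50, size = 5), nGenes,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%d", seq_len(nSamples))))
  storage.mode(m) <- "integer"
  m
}

koClones <- c("C2", "C5", "C9", "C17", "C19")
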