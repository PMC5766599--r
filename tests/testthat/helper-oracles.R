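# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with the package internals.

# Exact NB log-likelihood (edgeR parameterisation: var = mu + phi mu^2),
# written directly from the density.
nbLoglikOracle <- function(y, mu, phi) {
  if (phi < 1e-10) return(sum(dpois(y, mu, log = TRUE)))
  a <- 1 / phi
  sum(lgamma(y + a) - lgamma(a) - lgamma(y + 1) +
        y * log(phi * mu / (1 + phi * mu)) - a * log(1 + phi * mu))
}

# Brute-force maximization of the NB GLM log-likelihood over beta by
# coordinate-wise coarse-to-fine grid refinement.
gridMaxNbLoglik <- function(y, X, offset, phi, span = 3, cycles = 40L,
                            points = 25L) {
  p <- ncol(X)
  beta <- rep(0, p)
  # crude start: least squares on shifted log counts
  beta <- tryCatch(qr.solve(X, log(y + 0.5) - offset), error = function(e) beta)
  best <- nbLoglikOracle(y, exp(offset + drop(X %*% beta)), phi)
  for (cy in seq_len(cycles)) {
    for (j in seq_len(p)) {
      grid <- beta[j] + seq(-span, span, length.out = points)
      for (val in grid) {
        b2 <- beta; b2[j] <- val
        ll <- nbLoglikOracle(y, exp(pmin(offset + drop(X %*% b2), 30)), phi)
        if (is.finite(ll) && ll > best) { best <- ll; beta <- b2 }
      }
    }
    span <- span * 0.55
  }
  list(beta = beta, loglik = best)
}

# Full enumeration of the signed-rank null over all 2^n sign assignments.
wilcoxonExactOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(Wnull <= W), mean(Wnull >= W)))
  list(statistic = W, p_value = p)
}

# Exact rank-sum enumeration over all C(m, k) placements of a k-set in a
# ranking of size m (one-sided: set shifted toward rank 1).
rankSumEnumOracle <- function(ranksOfSet, m) {
  k <- length(ranksOfSet)
  sObs <- sum(ranksOfSet)
  sums <- combn(m, k, sum)
  mean(sums <= sObs)
}

# Brute-force percentile edge selection by full sort (independent of the
# package's ordering code).
selectEdgesOracle <- function(corr, fraction) {
  df <- expand.grid(lnc_id = rownames(corr), pcg_id = colnames(corr),
                    stringsAsFactors = FALSE)
  df$r <- mapply(function(a, b) corr[a, b], df$lnc_id, df$pcg_id)
  df <- df[!is.na(df$r), ]
  nSel <- ceiling(fraction * nrow(df))
  posOrd <- df[order(-df$r, df$lnc_id, df$pcg_id), ]
  negOrd <- df[order(df$r, df$lnc_id, df$pcg_id), ]
  list(pos = head(posOrd, nSel), neg = head(negOrd, nSel))
}

# Standardized two-group rank-sum z (tie-corrected), independent coding.
pairZOracle <- function(a, b) {
  N <- length(a) + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_along(a)])
  E <- length(a) * (N + 1) / 2
  V <- length(a) * length(b) / (N * (N - 1)) *
    (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) 0 else (W - E) / sqrt(V)
}

# Small default simulation config used across tests.
tinyConfig <- function(...) {
  args <- list(nFeatures = 200L, nTrueDE = 10L, nTumorConfirm = 40L,
               nNormalConfirm = 12L, plantedSetSize = 20L, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}
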