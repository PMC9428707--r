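# Independent brute-force re-implementations used as oracles. These stay
# deliberately naive (explicit loops, no shared code with the package) so
# that agreement is evidence, not tautology.

# random small expression matrix; values rounded to induce occasional ties
randomSmallMatrix <- function(n_genes, n_samples, tie_prone = TRUE) {
  v <- matrix(stats::rexp(n_genes * n_samples, rate = 0.5),
              n_genes, n_samples)
  if (tie_prone) v <- round(v, 1L)
  dimnames(v) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  ReoMatrix(v, platform = "random")
}

# naive consistent-pair detection: triple loop over (pair, sample)
oracleConsistentPairs <- function(vals, threshold) {
  genes <- rownames(vals)
  n <- nrow(vals)
  s <- ncol(vals)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      n_lt <- 0L
      n_gt <- 0L
      for (col in seq_len(s)) {
        if (vals[i, col] < vals[j, col]) n_lt <- n_lt + 1L
        else if (vals[i, col] > vals[j, col]) n_gt <- n_gt + 1L
      }
      ga <- min(genes[i], genes[j])
      gb <- max(genes[i], genes[j])
      flipped <- ga != genes[i]
      if (n_lt / s > threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = ga, gene_b = gb,
          direction = if (flipped) "a_gt_b" else "a_lt_b",
          frequency = n_lt / s, stringsAsFactors = FALSE)
      } else if (n_gt / s > threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = ga, gene_b = gb,
          direction = if (flipped) "a_lt_b" else "a_gt_b",
          frequency = n_gt / s, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      direction = character(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive reversal degree via explicit per-sample rank loops
oracleReversalDegree <- function(valsCancer, valsNoncancer, geneA, geneB) {
  rankdiff <- function(vals) {
    d <- numeric(ncol(vals))
    for (col in seq_len(ncol(vals))) {
      r <- rank(vals[, col], ties.method = "average")
      d[col] <- abs(r[geneA] - r[geneB])
    }
    mean(d)
  }
  mc <- rankdiff(valsCancer)
  mn <- rankdiff(valsNoncancer)
  c(mc, mn, sqrt(mc * mn))
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins; sums probabilities <= observed (with the usual
# relative tolerance for floating-point equality)
oracleFisherTwoSided <- function(tab) {
  r1 <- sum(tab[1L, ])
  r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  N <- sum(tab)
  prob_of <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  }
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  p_obs <- prob_of(tab[1L, 1L])
  total <- 0
  for (x in lo:hi) {
    p <- prob_of(x)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  min(total, 1)
}

# naive forward selection: for every k classify each sample by counting
# pair orderings in loops; returns the smallest k with maximal gmean
oracleForwardK <- function(gene_low, gene_high, vals, is_pos) {
  m <- length(gene_low)
  gmeans <- numeric(m)
  for (k in seq_len(m)) {
    calls <- logical(ncol(vals))
    for (col in seq_len(ncol(vals))) {
      votes <- 0L
      for (p in seq_len(k)) {
        if (vals[gene_low[p], col] < vals[gene_high[p], col])
          votes <- votes + 1L
      }
      calls[col] <- votes >= ceiling(k / 2)
    }
    sens <- mean(calls[is_pos])
    spec <- mean(!calls[!is_pos])
    gmeans[k] <- sqrt(sens * spec)
  }
  list(k = which.max(gmeans), gmeans = gmeans)
}

# tiny two-class cohort wrapper used across tests
smallCohort <- function(seed, n_genes = 60L, n_planted = 4L,
                        n_pos = 15L, n_neg = 15L,
                        fidelity = 0.95, tie_fraction = 0.02, ...) {
  simulateCohort(simulationConfig(
    n_genes = n_genes, n_planted = n_planted, n_pos = n_pos, n_neg = n_neg,
    fidelity_pos = fidelity, fidelity_neg = fidelity,
    tie_fraction = tie_fraction, seed = seed, ...))
}
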